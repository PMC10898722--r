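# Shared small fixtures, built once per test run.

fix <- local({
  env <- new.env()
  function(name, build) {
    if (is.null(env[[name]])) env[[name]] <- build()
    env[[name]]
  }
})

fix_space3 <- function() fix("space3", function() build_source_space(3))
fix_atlas3 <- function() fix("atlas3", function() build_atlas(fix_space3(), seed = 1))
fix_forward3 <- function() fix("forward3", function() build_lead_field(fix_space3()))

fix_space4 <- function() fix("space4", function() build_source_space(4))
fix_atlas4 <- function() fix("atlas4", function() build_atlas(fix_space4(), seed = 1))
fix_forward4 <- function() fix("forward4", function() build_lead_field(fix_space4()))

# A small feature table with controllable label/feature association, for
# classification-protocol tests that need no signal pipeline. Velocities are
# balanced; scores are drawn so both classes are populated per velocity;
# `signal` shifts a subset of features by label.
make_toy_features <- function(n_per_vel = 30, signal = 0, seed = 1,
                              p_pleasant = c(`0.44` = 0.5, `1` = 0.5,
                                             `2` = 0.5, `4` = 0.5)) {
  withr::with_seed(seed, {
    vels <- rep(c(0.44, 1, 2, 4), each = n_per_vel)
    pleasant <- rbinom(length(vels), 1,
                       p_pleasant[as.character(vels)]) == 1
    score <- ifelse(pleasant, runif(length(vels), 5.1, 9),
                    runif(length(vels), 1, 4.9))
    score <- pmin(9, pmax(1, round(score * 10) / 10))
    score[score == 5] <- 5.1
    X <- matrix(rnorm(length(vels) * 24), ncol = 24)
    X[, 1:6] <- X[, 1:6] + signal * pleasant
    colnames(X) <- feature_columns()
    ft <- cbind(as.data.frame(X), velocity = vels, score = score)
    class(ft) <- c("feature_table", "data.frame")
    ft
  })
}

# Tiny synthetic recording through the real generator: 1 session of a few
# trials on the level-3 head model.
make_tiny_recording <- function(seed = 5, trials = 8, eog = FALSE, ...) {
  space <- fix_space3()
  atlas <- fix_atlas3()
  fwd <- fix_forward3()
  sched <- make_trial_schedule(n_sessions = 1, trials_per_session = trials,
                               seed = seed)
  prof <- participant_profile(seed = seed, ...)
  simulate_recording(sched, prof, fwd, atlas, space, eog = eog)
}

# Spearman correlation between reported score and wind-period alpha band
# power averaged over frontal channels (sensor-side readout, no inverse).
sensor_alpha_score_cor <- function(rec) {
  ev <- rec$events[rec$events$kind == "wind_on", ]
  frontal <- grep("^(Fp|AF|F)", rec$channel_names)
  bp <- vapply(seq_len(nrow(ev)), function(i) {
    idx <- ev$sample[i] + 1024 + seq_len(4096)
    ps <- welch_psd(t(rec$data[frontal, idx]), fs = rec$fs)
    mean(ps$psd[ps$freq >= 8 & ps$freq <= 13, ])
  }, numeric(1))
  cor(ev$score, bp, method = "spearman")
}
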