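#' Pseudo-random wind-velocity trial schedule
#'
#' Three sessions of 40 trials each (120 total) by default, with the four
#' wind velocities balanced (each occurring `trials_per_session / 4` times
#' per session) and the constraint that the same velocity never occurs on two
#' consecutive trials, matching the pseudo-random presentation order of the
#' experiment. Each session is drawn by rejection sampling: permutations are
#' redrawn until the no-consecutive-repeat constraint holds.
#'
#' @param n_sessions Number of sessions.
#' @param trials_per_session Trials per session; must be divisible by the
#'   number of velocities.
#' @param velocities Wind velocities in m/s.
#' @param seed Integer seed.
#' @param max_tries Rejection-sampling cap per session.
#' @return Object of class `trial_schedule`: data frame with `session`,
#'   `trial` (within session), `velocity`.
#' @examples
#' sch <- make_trial_schedule(seed = 1)
#' nrow(sch)              # 120
#' table(sch$velocity)    # 30 each
#' @export
make_trial_schedule <- function(n_sessions = 3, trials_per_session = 40,
                                velocities = c(0.44, 1.0, 2.0, 4.0),
                                seed = NULL, max_tries = 10000) {
  if (trials_per_session %% length(velocities) != 0)
    stop_invalid("`trials_per_session` must be divisible by the number of velocities")
  if (length(velocities) < 2 && trials_per_session > 1)
    stop_invalid("scheduling error: no-repeat constraint unsatisfiable with one velocity")
  with_seed(seed, {
    out <- lapply(seq_len(n_sessions), function(s) {
      for (i in seq_len(max_tries)) {
        v <- draw_norepeat_sequence(velocities,
                                    trials_per_session / length(velocities))
        if (!is.null(v))
          return(data.frame(session = s, trial = seq_along(v), velocity = v))
      }
      stop_invalid("scheduling error: could not satisfy the no-repeat constraint")
    })
    sched <- do.call(rbind, out)
    class(sched) <- c("trial_schedule", "data.frame")
    sched
  })
}

# One attempt at a balanced no-adjacent-repeat sequence: fill slots left to
# right, drawing each velocity with probability proportional to its remaining
# count among those different from the previous slot; NULL when the attempt
# dead-ends (then the caller redraws).
draw_norepeat_sequence <- function(velocities, per_velocity) {
  counts <- rep(per_velocity, length(velocities))
  n <- per_velocity * length(velocities)
  v <- numeric(n)
  prev <- 0L
  for (i in seq_len(n)) {
    cand <- which(counts > 0L)
    if (prev > 0L) cand <- setdiff(cand, prev)
    if (length(cand) == 0L) return(NULL)
    pick <- if (length(cand) == 1L) cand else
      sample(cand, 1L, prob = counts[cand])
    v[i] <- velocities[pick]
    counts[pick] <- counts[pick] - 1L
    prev <- pick
  }
  v
}

#' Participant profile for the synthetic experiment
#'
#' Bundles the behavioural and neural generative parameters of one synthetic
#' participant. Mean pleasantness scores per velocity default to the observed
#' group means (4.3, 5.5, 6.9, 5.3 for 0.44, 1.0, 2.0, 4.0 m/s).
#'
#' @param condition_means Named or positional mean scores per velocity, on the
#'   1-9 visual-analog scale.
#' @param participant_offset Additive score offset of this participant (VAS
#'   units).
#' @param trial_noise_sd Trial-to-trial score noise SD (VAS units).
#' @param effect_beta Fractional band-power amplitude modulation of the six
#'   pleasantness ROIs per VAS unit relative to neutral (score 5); the ROI
#'   carrier amplitude is `roi_amplitude * (1 + effect_beta * (score - 5))`.
#' @param confound_gamma Velocity-coded source amplitude per m/s, placed in
#'   `confound_region` (outside the ROIs).
#' @param roi_amplitude Carrier RMS amplitude of the ROI oscillation at a
#'   neutral score, in units of the per-vertex 1/f background RMS.
#' @param signal_band,confound_band Frequency bands (Hz) of the ROI carrier
#'   and the confound oscillation.
#' @param confound_region Atlas region (without hemisphere suffix) carrying
#'   the velocity-coded activity in both hemispheres.
#' @param sensor_noise_sd White sensor noise RMS in microvolts.
#' @param seed Participant-level seed.
#' @return Object of class `participant_profile` (a list).
#' @export
participant_profile <- function(condition_means = c(`0.44` = 4.3, `1` = 5.5,
                                                    `2` = 6.9, `4` = 5.3),
                                participant_offset = 0,
                                trial_noise_sd = 1.0,
                                effect_beta = 0.15,
                                confound_gamma = 0.5,
                                roi_amplitude = 2.0,
                                signal_band = c(8, 13),
                                confound_band = c(14, 30),
                                confound_region = "superiorparietal",
                                sensor_noise_sd = 2.0,
                                seed = 1L) {
  if (trial_noise_sd < 0) stop_invalid("`trial_noise_sd` must be >= 0")
  if (any(condition_means < 1 | condition_means > 9))
    stop_invalid("`condition_means` must lie within [1, 9]")
  if (roi_amplitude < 0 || confound_gamma < 0 || sensor_noise_sd < 0)
    stop_invalid("amplitudes must be non-negative")
  structure(list(
    condition_means = condition_means,
    participant_offset = participant_offset,
    trial_noise_sd = trial_noise_sd,
    effect_beta = effect_beta,
    confound_gamma = confound_gamma,
    roi_amplitude = roi_amplitude,
    signal_band = signal_band,
    confound_band = confound_band,
    confound_region = confound_region,
    sensor_noise_sd = sensor_noise_sd,
    seed = seed
  ), class = "participant_profile")
}

#' Sample one pleasantness report
#'
#' `clip(round_0.1(mean_v + participant_offset + N(0, trial_noise_sd)), 1, 9)`:
#' the per-velocity condition mean plus the participant's offset plus trial
#' noise, rounded to the 0.1-step grid of the visual-analog scale and clipped
#' to its 1.0-9.0 range. Uses the current RNG state (seed the caller).
#'
#' @param velocity Wind velocity; must match a name/position of the profile's
#'   `condition_means`.
#' @param profile A [participant_profile()].
#' @return A single score in `{1.0, 1.1, ..., 9.0}`.
#' @export
sample_pleasantness <- function(velocity, profile) {
  mu <- condition_mean_of(profile, velocity)
  raw <- mu + profile$participant_offset +
    rnorm(length(velocity), 0, profile$trial_noise_sd)
  pmin(9, pmax(1, round(raw * 10) / 10))
}

condition_mean_of <- function(profile, velocity) {
  cm <- profile$condition_means
  if (!is.null(names(cm))) {
    key <- as.character(as.numeric(velocity))
    bad <- !(key %in% names(cm))
    if (any(bad))
      stop_invalid("velocity ", paste(velocity[bad], collapse = ", "),
                   " has no condition mean in the profile")
    unname(cm[key])
  } else {
    stop_invalid("`condition_means` must be named by velocity")
  }
}
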