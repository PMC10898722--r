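# Cohort orchestration: configuration, per-participant simulation ->
# preprocessing -> inverse -> features -> protocol, and the group report.

#' Cohort run configuration
#'
#' Collects every tunable parameter of the end-to-end synthetic experiment.
#' Defaults reproduce the study conditions: 18 participants, 3 sessions of
#' 40 trials, the four wind velocities with group mean scores
#' 4.3/5.5/6.9/5.3, and the full four-family protocol.
#'
#' @param n_participants Cohort size.
#' @param seed Master seed; every participant/stage seed derives from it.
#' @param level Source-space subdivision level.
#' @param families Classifier families to run.
#' @param n_repetitions Undersampling repetitions per fold.
#' @param budget Hyperparameter search budget per fit.
#' @param effect_beta,confound_gamma,roi_amplitude,trial_noise_sd,
#'   sensor_noise_sd Generator parameters, see [participant_profile()].
#' @param participant_offset_sd SD of the per-participant score offset (VAS
#'   units); offsets are drawn once per participant.
#' @param min_class,min_train_class Inclusion / fold-feasibility thresholds.
#' @param importance Also compute band-ablation importance per participant.
#' @param n_sessions,trials_per_session Trial design.
#' @return Object of class `run_config` (a list).
#' @export
run_config <- function(n_participants = 18, seed = 1L, level = 3,
                       families = CLASSIFIER_FAMILIES, n_repetitions = 5,
                       budget = 50, effect_beta = 0.15, confound_gamma = 0.5,
                       roi_amplitude = 2.0, trial_noise_sd = 1.0,
                       sensor_noise_sd = 2.0, participant_offset_sd = 0.3,
                       min_class = 30, min_train_class = 30,
                       importance = FALSE, n_sessions = 3,
                       trials_per_session = 40) {
  cfg <- as.list(environment())
  cfg$families <- match.arg(families, CLASSIFIER_FAMILIES, several.ok = TRUE)
  if (cfg$n_participants < 1) stop_invalid("validation error: empty cohort")
  if (cfg$budget < 1 || cfg$n_repetitions < 1)
    stop_invalid("validation error: budget and repetitions must be >= 1")
  class(cfg) <- "run_config"
  cfg
}

#' Simulate one participant and extract the feature table
#'
#' Runs schedule generation, the fused simulate-filter-epoch stage
#' ([simulate_epochs()]), the remaining preprocessing stages (bad-channel
#' repair, artifact rejection, average reference, crop), baseline noise
#' covariance, the eLORETA operator, and band-power feature extraction.
#'
#' @param profile A [participant_profile()].
#' @param forward,atlas,space Shared head model objects.
#' @param seed Participant seed.
#' @param n_sessions,trials_per_session Trial design.
#' @return A `feature_table` for the participant's retained trials.
#' @export
simulate_participant <- function(profile, forward, atlas, space,
                                 seed = profile$seed, n_sessions = 3,
                                 trials_per_session = 40) {
  sched <- make_trial_schedule(n_sessions = n_sessions,
                               trials_per_session = trials_per_session,
                               seed = child_seed(seed, 101))
  epochs <- simulate_epochs(sched, profile, forward, atlas, space,
                            seed = child_seed(seed, 102))
  epochs <- detect_and_interpolate_bad_channels(epochs)
  epochs <- reject_artifact_epochs(epochs)
  epochs <- rereference_average(epochs)
  pp <- crop_analysis_window(epochs)
  rm(epochs)
  ncov <- compute_noise_covariance(pp$baseline)
  inv <- compute_eloreta_operator(forward, ncov)
  extract_features(pp$analysis, inv, atlas, baseline = pp$baseline)
}

#' Run a synthetic cohort end to end
#'
#' Builds the shared head model once, then per participant: draw a profile
#' (score offset from `N(0, participant_offset_sd)`), simulate the
#' experiment, preprocess, invert, extract features, apply the inclusion
#' rule, and run the classification protocol. Excluded participants (either
#' class below `min_class` trials) are logged and omitted from group
#' statistics. Group statistics: per-family one-tailed t-test of accuracy
#' against chance with Holm correction, and a repeated-measures ANOVA
#' (Greenhouse-Geisser) across families when more than one family ran.
#'
#' @param config A [run_config()].
#' @return Object of class `cohort_result`: `config`, `participants` (list
#'   with feature table summaries, protocol results, inclusion flags),
#'   `accuracy` (matrix included-participants x families), `group_stats`,
#'   `importance` (if requested), `score_summary` (per-velocity mean/sd of
#'   reported scores across all participants), `excluded` (ids).
#' @export
run_cohort <- function(config = run_config()) {
  stopifnot(inherits(config, "run_config"))
  space <- build_source_space(config$level)
  atlas <- build_atlas(space, seed = child_seed(config$seed, 1))
  forward <- build_lead_field(space)

  participants <- vector("list", config$n_participants)
  for (i in seq_len(config$n_participants)) {
    pseed <- child_seed(config$seed, 1000, i)
    offset <- with_seed(child_seed(pseed, 1),
                        rnorm(1, 0, config$participant_offset_sd))
    prof <- participant_profile(
      participant_offset = offset,
      trial_noise_sd = config$trial_noise_sd,
      effect_beta = config$effect_beta,
      confound_gamma = config$confound_gamma,
      roi_amplitude = config$roi_amplitude,
      sensor_noise_sd = config$sensor_noise_sd,
      seed = pseed)
    ft <- simulate_participant(prof, forward, atlas, space, seed = pseed,
                               n_sessions = config$n_sessions,
                               trials_per_session = config$trials_per_session)
    trials <- label_and_filter(ft, min_class = config$min_class)
    res <- NULL; imp <- NULL
    skip_note <- NULL
    if (trials$included) {
      folds <- make_velocity_folds(trials,
                                   min_train_class = config$min_train_class)
      if (!any(vapply(folds, `[[`, TRUE, "feasible"))) {
        trials$included <- FALSE
        skip_note <- "no feasible leave-one-velocity-out fold"
      }
    }
    if (trials$included) {
      res <- run_protocol(trials, families = config$families,
                          n_repetitions = config$n_repetitions,
                          budget = config$budget,
                          seed = child_seed(pseed, 2),
                          min_train_class = config$min_train_class)
      if (config$importance)
        imp <- band_ablation_importance(
          trials, n_repetitions = config$n_repetitions,
          budget = config$budget, seed = child_seed(pseed, 2),
          min_train_class = config$min_train_class,
          full_result = if ("svm_rbf" %in% config$families) res else NULL)
    }
    participants[[i]] <- list(
      id = i, profile = prof, included = trials$included,
      class_counts = trials$class_counts, protocol = res, importance = imp,
      skip_note = skip_note,
      scores = data.frame(velocity = ft$velocity, score = ft$score))
  }

  included <- which(vapply(participants, `[[`, TRUE, "included"))
  acc <- NULL; group <- NULL; imp_tab <- NULL
  if (length(included) > 0) {
    vals <- vapply(participants[included], function(p)
      p$protocol$participant_mean, numeric(length(config$families)))
    acc <- if (is.matrix(vals)) t(vals) else matrix(vals, ncol = 1)
    rownames(acc) <- included
    colnames(acc) <- config$families
    group <- group_statistics(acc)
    if (config$importance) {
      imp_tab <- t(vapply(participants[included], function(p)
        p$importance$drop, numeric(4)))
      colnames(imp_tab) <- names(eeg_bands())
    }
  }

  all_scores <- do.call(rbind, lapply(participants, `[[`, "scores"))
  score_summary <- aggregate(score ~ velocity, all_scores,
                             function(s) c(mean = mean(s), sd = sd(s)))
  score_summary <- data.frame(velocity = score_summary$velocity,
                              mean = score_summary$score[, "mean"],
                              sd = score_summary$score[, "sd"])

  structure(list(config = config, participants = participants,
                 accuracy = acc, group_stats = group,
                 importance = imp_tab, score_summary = score_summary,
                 excluded = setdiff(seq_along(participants), included)),
            class = "cohort_result")
}

# Per-family t-tests vs chance with Holm correction; RM-ANOVA across
# families when >= 2 families and >= 3 participants.
group_statistics <- function(acc) {
  fams <- colnames(acc)
  if (nrow(acc) < 2) {
    return(list(t_tests = data.frame(family = fams,
                                     mean_accuracy = colMeans(acc),
                                     sd_accuracy = NA_real_, t = NA_real_,
                                     df = NA_real_, p = NA_real_,
                                     p_holm = NA_real_),
                anova = NULL))
  }
  tt <- lapply(fams, function(f) one_sample_t_one_tailed(acc[, f], 0.5))
  p_raw <- vapply(tt, `[[`, 0, "p")
  p_holm <- holm_adjust(p_raw)
  tab <- data.frame(family = fams,
                    mean_accuracy = colMeans(acc),
                    sd_accuracy = apply(acc, 2, sd),
                    t = vapply(tt, `[[`, 0, "t"),
                    df = vapply(tt, `[[`, 0, "df"),
                    p = p_raw, p_holm = p_holm)
  anova_res <- if (length(fams) >= 2 && nrow(acc) >= 3) rm_anova_gg(acc)
               else NULL
  list(t_tests = tab, anova = anova_res)
}

#' Format a cohort report
#'
#' Text tables of per-family mean accuracy (+-sd) with test statistics, the
#' band-importance table if computed, and the per-velocity score
#' distribution summary.
#'
#' @param cohort A `cohort_result`.
#' @return Character vector of report lines (also printed).
#' @export
make_report <- function(cohort) {
  stopifnot(inherits(cohort, "cohort_result"))
  ln <- c(sprintf("Cohort of %d participants (%d excluded), master seed %d",
                  cohort$config$n_participants, length(cohort$excluded),
                  cohort$config$seed),
          "")
  if (!is.null(cohort$group_stats)) {
    ln <- c(ln, "Classification accuracy vs chance (0.5):",
            sprintf("  %-10s %6s %6s %7s %8s %8s",
                    "family", "mean", "sd", "t", "p", "p(Holm)"))
    gt <- cohort$group_stats$t_tests
    for (i in seq_len(nrow(gt)))
      ln <- c(ln, sprintf("  %-10s %6.3f %6.3f %7.2f %8.4f %8.4f",
                          gt$family[i], gt$mean_accuracy[i], gt$sd_accuracy[i],
                          gt$t[i], gt$p[i], gt$p_holm[i]))
    if (!is.null(cohort$group_stats$anova)) {
      a <- cohort$group_stats$anova
      ln <- c(ln, sprintf(
        "  RM-ANOVA across families: F(%.2f, %.2f) = %.2f, GG eps = %.2f, p = %.3f",
        a$epsilon * a$df1, a$epsilon * a$df2, a$F, a$epsilon, a$p_corrected))
    }
    ln <- c(ln, "")
  }
  if (!is.null(cohort$importance)) {
    ln <- c(ln, "Band-ablation importance (accuracy drop):",
            sprintf("  %-6s mean %7.3f  sd %6.3f",
                    colnames(cohort$importance),
                    colMeans(cohort$importance),
                    apply(cohort$importance, 2, sd)),
            "")
  }
  ln <- c(ln, "Reported pleasantness by velocity:",
          sprintf("  %4.2f m/s: mean %4.2f sd %4.2f",
                  cohort$score_summary$velocity, cohort$score_summary$mean,
                  cohort$score_summary$sd))
  cat(paste(ln, collapse = "\n"), "\n")
  invisible(ln)
}

#' @export
print.cohort_result <- function(x, ...) {
  make_report(x)
  invisible(x)
}
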