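# Group statistics and band-ablation feature importance.

#' One-tailed one-sample t-test (upper tail)
#'
#' Tests whether the mean of `values` exceeds `mu0`:
#' `t = (mean - mu0) / (sd / sqrt(n))`, `df = n - 1`, p is the upper-tail
#' probability. Thin wrapper over [stats::t.test()].
#'
#' @param values Numeric vector (n >= 2, non-constant).
#' @param mu0 Null mean (chance level 0.5 for accuracies, 0 for importance).
#' @return List with `t`, `df`, `p`.
#' @export
one_sample_t_one_tailed <- function(values, mu0 = 0.5) {
  if (length(values) < 2) stop_invalid("need at least 2 values")
  if (sd(values) == 0)
    stop_invalid("undefined statistic: values have zero variance")
  ht <- t.test(values, mu = mu0, alternative = "greater")
  list(t = unname(ht$statistic), df = unname(ht$parameter),
       p = unname(ht$p.value))
}

#' Holm-Bonferroni step-down adjustment
#'
#' Sort p-values ascending, multiply the i-th smallest by `m - i + 1`,
#' enforce monotonicity by the running maximum, cap at 1, and return in the
#' original order. Wrapper over [stats::p.adjust()] (method `"holm"`).
#'
#' @param p Vector of p-values in \[0, 1\].
#' @return Adjusted p-values, same order as the input.
#' @export
holm_adjust <- function(p) {
  if (any(p < 0 | p > 1)) stop_invalid("p-values must lie in [0, 1]")
  p.adjust(p, method = "holm")
}

#' One-way repeated-measures ANOVA with Greenhouse-Geisser correction
#'
#' Within-subject one-way ANOVA (subjects x conditions, no missing cells).
#' The Greenhouse-Geisser epsilon is estimated from the sample (biased,
#' divide-by-n) covariance of the conditions:
#' `eps = tr(C S C')^2 / ((k-1) * tr((C S C')^2))` with `C` an orthonormal
#' contrast basis; the corrected p-value uses degrees of freedom
#' `(eps*(k-1), eps*(k-1)*(n-1))`.
#'
#' @param m Numeric matrix, subjects in rows, conditions in columns.
#' @return List with `F`, `df1`, `df2` (uncorrected), `epsilon`,
#'   `p_corrected`.
#' @export
rm_anova_gg <- function(m) {
  m <- as.matrix(m)
  n <- nrow(m); k <- ncol(m)
  if (n < 3 || k < 2) stop_invalid("need >= 3 subjects and >= 2 conditions")
  if (any(is.na(m))) stop_invalid("missing cells are not supported")
  grand <- mean(m)
  cond_mean <- colMeans(m)
  subj_mean <- rowMeans(m)
  ss_cond <- n * sum((cond_mean - grand)^2)
  resid <- m - outer(subj_mean, cond_mean, "+") + grand
  ss_err <- sum(resid^2)
  if (ss_err <= 0 && ss_cond <= 0)
    stop_invalid("undefined statistic: constant data")
  df1 <- k - 1
  df2 <- (k - 1) * (n - 1)
  Fstat <- (ss_cond / df1) / (ss_err / df2)
  # biased sample covariance of conditions
  S <- crossprod(sweep(m, 2, cond_mean)) / n
  Cc <- contr_orthonormal(k)
  CS <- Cc %*% S %*% t(Cc)
  eps <- sum(diag(CS))^2 / (df1 * sum(CS^2))
  eps <- min(1, max(eps, 1 / df1))
  list(F = Fstat, df1 = df1, df2 = df2, epsilon = eps,
       p_corrected = pf(Fstat, eps * df1, eps * df2, lower.tail = FALSE))
}

# Orthonormal basis of the contrast space (rows orthogonal to the constant).
contr_orthonormal <- function(k) {
  h <- stats::contr.helmert(k)
  t(h) / sqrt(colSums(h^2))
}

#' Band-ablation feature importance for one participant
#'
#' Re-runs the classification protocol with the six features of one
#' frequency band removed from both training and test data, under the same
#' master seed as the full run so undersampling draws and tuning search
#' points coincide, and reports the drop in mean accuracy (full - ablated).
#' Repeated over the four bands this gives the participant's importance
#' profile; the RBF-kernel SVM (the best-performing family of the study) is
#' the default scorer.
#'
#' @param trials A `labeled_trial_set`.
#' @param family Classifier family used for scoring.
#' @param bands Band names to ablate.
#' @param n_repetitions,budget,seed,min_train_class As [run_protocol()].
#' @param full_result Optional precomputed full-feature `protocol_result`
#'   under the same parameters (avoids recomputation).
#' @return Object of class `importance_result`: named vector `drop` per
#'   band, plus `full_accuracy` and the per-band ablated accuracies.
#' @export
band_ablation_importance <- function(trials, family = "svm_rbf",
                                     bands = names(eeg_bands()),
                                     n_repetitions = 5, budget = 50,
                                     seed = 1L, min_train_class = 30,
                                     full_result = NULL) {
  if (!all(bands %in% names(eeg_bands())))
    stop_invalid("unknown band name: ",
                 paste(setdiff(bands, names(eeg_bands())), collapse = ", "))
  if (is.null(full_result))
    full_result <- run_protocol(trials, families = family,
                                n_repetitions = n_repetitions,
                                budget = budget, seed = seed,
                                min_train_class = min_train_class)
  full_acc <- full_result$participant_mean[[family]]
  ablated <- vapply(bands, function(b) {
    drop_cols <- grepl(paste0("_", b, "$"), colnames(trials$features))
    sub <- trials
    sub$features <- trials$features[, !drop_cols, drop = FALSE]
    res <- run_protocol(sub, families = family,
                        n_repetitions = n_repetitions, budget = budget,
                        seed = seed, min_train_class = min_train_class)
    res$participant_mean[[family]]
  }, numeric(1))
  structure(list(drop = full_acc - ablated, full_accuracy = full_acc,
                 ablated_accuracy = ablated, family = family),
            class = "importance_result")
}
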