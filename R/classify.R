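# The confound-controlled classification protocol: strict score labelling
# and inclusion rules, leave-one-velocity-out folds, balanced undersampling
# with non-repeating discard sets across repetitions, training-only
# normalization, seeded random hyperparameter search, four classifier
# families, and accuracy aggregation.

CLASSIFIER_FAMILIES <- c("logreg", "svm_linear", "svm_rbf", "ann")

#' Label trials by reported pleasantness and apply the inclusion rule
#'
#' Trials with score > 5.0 are labelled `pleasant`, trials with score < 5.0
#' `unpleasant`; trials at exactly 5.0 (the neutral anchor) are dropped. A
#' participant is excluded from group analysis when either class has fewer
#' than `min_class` trials.
#'
#' @param feature_table A `feature_table`.
#' @param min_class Minimum per-class trial count for inclusion.
#' @return Object of class `labeled_trial_set`: list with `features`
#'   (trials x 24 matrix), `label` (factor pleasant/unpleasant), `velocity`,
#'   `score`, `included` (logical), `class_counts`.
#' @export
label_and_filter <- function(feature_table, min_class = 30) {
  sc <- feature_table$score
  if (any(sc < 1 | sc > 9)) stop_invalid("scores must lie in [1, 9]")
  keep <- sc != 5.0
  ft <- feature_table[keep, , drop = FALSE]
  label <- factor(ifelse(ft$score > 5, "pleasant", "unpleasant"),
                  levels = c("pleasant", "unpleasant"))
  counts <- table(label)
  structure(list(
    features = as.matrix(ft[, feature_columns(), drop = FALSE]),
    label = label,
    velocity = ft$velocity,
    score = ft$score,
    included = all(counts >= min_class),
    class_counts = counts
  ), class = "labeled_trial_set")
}

#' Leave-one-velocity-out fold specifications
#'
#' One fold per wind velocity: its trials form the test set and the three
#' remaining velocities the training set, so the classifier can never exploit
#' velocity identity. A fold is infeasible when either class has fewer than
#' `min_train_class` trials in the original (pre-undersampling) training
#' data.
#'
#' @param trials A `labeled_trial_set`.
#' @param min_train_class Minimum per-class training count for feasibility.
#' @return List of fold specs: `test_velocity`, `train_velocities`,
#'   `feasible`, `train_idx`, `test_idx`.
#' @export
make_velocity_folds <- function(trials, min_train_class = 30) {
  vels <- sort(unique(trials$velocity))
  if (length(vels) < 4)
    stop_invalid("invalid design: all four velocity conditions must be present")
  lapply(vels, function(v) {
    train <- which(trials$velocity != v)
    test <- which(trials$velocity == v)
    counts <- table(trials$label[train])
    list(test_velocity = v,
         train_velocities = setdiff(vels, v),
         feasible = all(counts >= min_train_class),
         train_idx = train, test_idx = test)
  })
}

#' Undersample the majority class of a training set
#'
#' Randomly discards majority-class trials until both classes have the
#' minority count. `used_discards` carries the discard sets of earlier
#' repetitions; draws are repeated until a previously unused discard set is
#' found, so the same training dataset is never reused across repetitions
#' (when the surplus admits distinct subsets; otherwise a fresh random draw
#' is used with a warning).
#'
#' @param labels Factor of training labels.
#' @param seed Integer seed.
#' @param used_discards List of previously used discard index sets.
#' @return List: `keep_idx` (indices into `labels` of the balanced training
#'   set), `discard_idx`, `used_discards` (updated).
#' @export
undersample_training <- function(labels, seed = NULL, used_discards = list()) {
  counts <- table(labels)
  if (any(counts == 0)) stop_invalid("both classes must be non-empty")
  n_min <- min(counts)
  maj <- names(counts)[which.max(counts)]
  maj_idx <- which(labels == maj)
  surplus <- length(maj_idx) - n_min
  if (surplus == 0)
    return(list(keep_idx = seq_along(labels), discard_idx = integer(0),
                used_discards = used_discards))
  n_subsets <- choose(length(maj_idx), surplus)
  with_seed(seed, {
    for (try in seq_len(1000L)) {
      discard <- sort(sample(maj_idx, surplus))
      key <- paste(discard, collapse = ",")
      if (!key %in% vapply(used_discards, paste, "", collapse = ",")) {
        used_discards[[length(used_discards) + 1L]] <- discard
        return(list(keep_idx = setdiff(seq_along(labels), discard),
                    discard_idx = discard, used_discards = used_discards))
      }
      if (length(used_discards) >= n_subsets) {
        warning("all distinct discard subsets exhausted; reusing a random draw")
        return(list(keep_idx = setdiff(seq_along(labels), discard),
                    discard_idx = discard, used_discards = used_discards))
      }
    }
    stop_invalid("could not find an unused discard subset")
  })
}

#' Z-score features with training statistics only
#'
#' Normalizes both partitions with the column means and standard deviations
#' of the (undersampled) training data; no test statistic is ever used.
#'
#' @param train,test Numeric feature matrices.
#' @return List with `train`, `test`, `center`, `scale`.
#' @export
normalize_features <- function(train, test) {
  mu <- colMeans(train)
  sdv <- apply(train, 2, sd)
  if (any(sdv == 0))
    stop_invalid("numerical error: zero-variance training column(s): ",
                 paste(colnames(train)[sdv == 0], collapse = ", "))
  list(train = sweep(sweep(train, 2, mu), 2, sdv, "/"),
       test = sweep(sweep(test, 2, mu), 2, sdv, "/"),
       center = mu, scale = sdv)
}

#' Classifier specification
#'
#' @param family One of `"logreg"`, `"svm_linear"`, `"svm_rbf"`, `"ann"`.
#' @param hyper Optional fixed hyperparameters (a named list); `NULL` means
#'   untuned.
#' @return Object of class `classifier_spec`.
#' @export
classifier_spec <- function(family = CLASSIFIER_FAMILIES, hyper = NULL) {
  family <- match.arg(family)
  structure(list(family = family, hyper = hyper), class = "classifier_spec")
}

# Draw one hyperparameter configuration from the search ranges:
# C, gamma log-uniform on [1e-3, 1e3]; hidden units 4..64; learning rate
# log-uniform [1e-4, 1e-1]; weight decay log-uniform [1e-6, 1e-2];
# batch size {8, 16, 32}; epochs 10..200.
sample_hyper <- function(family) {
  lu <- function(lo, hi) exp(runif(1, log(lo), log(hi)))
  switch(family,
    logreg = list(C = lu(1e-3, 1e3)),
    svm_linear = list(C = lu(1e-3, 1e3)),
    svm_rbf = list(C = lu(1e-3, 1e3), gamma = lu(1e-3, 1e3)),
    ann = list(hidden = sample(4:64, 1), batch_size = sample(c(8L, 16L, 32L), 1),
               lr = lu(1e-4, 1e-1), weight_decay = lu(1e-6, 1e-2),
               epochs = sample(10:200, 1)))
}

fit_classifier <- function(family, X, y, hyper, seed = 1L) {
  if (family == "logreg") {
    glmnet::glmnet(X, y, family = "binomial", alpha = 0,
                   lambda = 1 / (nrow(X) * hyper$C), standardize = FALSE)
  } else if (family %in% c("svm_linear", "svm_rbf")) {
    kern <- if (family == "svm_linear") "linear" else "radial"
    gam <- if (family == "svm_rbf") hyper$gamma else 1 / ncol(X)
    e1071::svm(X, y, kernel = kern, cost = hyper$C, gamma = gam,
               scale = FALSE)
  } else {
    fit_ann(X, as.numeric(y == "pleasant"), hidden = hyper$hidden,
            batch_size = hyper$batch_size, lr = hyper$lr,
            weight_decay = hyper$weight_decay, epochs = hyper$epochs,
            seed = seed)
  }
}

predict_classifier <- function(family, model, X, levels_ref) {
  if (family == "logreg") {
    pr <- predict(model, X, type = "response")[, 1]
    # glmnet models the second factor level as the positive class
    factor(ifelse(pr > 0.5, levels_ref[2], levels_ref[1]), levels = levels_ref)
  } else if (family %in% c("svm_linear", "svm_rbf")) {
    factor(as.character(predict(model, X)), levels = levels_ref)
  } else {
    pr <- predict_ann(model, X)
    factor(ifelse(pr >= 0.5, "pleasant", "unpleasant"), levels = levels_ref)
  }
}

#' Tune hyperparameters by seeded random search
#'
#' A stratified 80/20 split of the balanced training data provides the
#' validation set; `budget` configurations are drawn from the family's
#' search ranges and the configuration with the highest validation accuracy
#' is returned (ties: first drawn). The search is a pluggable stand-in for
#' sequential model-based optimisation; with the small search spaces here a
#' seeded random search is deterministic and adequate.
#'
#' @param X,y Balanced training features/labels.
#' @param spec A [classifier_spec()].
#' @param budget Number of configurations to evaluate (>= 1).
#' @param seed Integer seed.
#' @return The spec with `hyper` set to the tuned values and
#'   `validation_accuracy` attached.
#' @export
tune_hyperparameters <- function(X, y, spec, budget = 50, seed = 1L) {
  if (budget < 1) stop_invalid("`budget` must be >= 1")
  if (nrow(X) < 10) stop_invalid("need at least 10 training trials to tune")
  with_seed(seed, {
    # stratified 80/20 split
    val <- unlist(lapply(levels(y), function(lv) {
      idx <- which(y == lv)
      sample(idx, max(1L, round(0.2 * length(idx))))
    }))
    tr <- setdiff(seq_len(nrow(X)), val)
    best <- NULL; best_acc <- -1
    for (k in seq_len(budget)) {
      hy <- sample_hyper(spec$family)
      model <- fit_classifier(spec$family, X[tr, , drop = FALSE], y[tr], hy,
                              seed = child_seed(seed, k))
      pred <- predict_classifier(spec$family, model, X[val, , drop = FALSE],
                                 levels(y))
      acc <- mean(pred == y[val])
      if (acc > best_acc) { best_acc <- acc; best <- hy }
    }
    spec$hyper <- best
    spec$validation_accuracy <- best_acc
    spec
  })
}

#' Fit a tuned classifier and score it on the test partition
#'
#' @param spec A tuned [classifier_spec()] (`hyper` set).
#' @param train,test Normalized feature matrices.
#' @param train_labels,test_labels Factors.
#' @param seed Seed (ANN initialisation/shuffling).
#' @return Test accuracy in \[0, 1\].
#' @export
train_and_test <- function(spec, train, test, train_labels, test_labels,
                           seed = 1L) {
  if (is.null(spec$hyper)) stop_invalid("spec has no tuned hyperparameters")
  model <- fit_classifier(spec$family, train, train_labels, spec$hyper,
                          seed = seed)
  pred <- predict_classifier(spec$family, model, test, levels(train_labels))
  mean(pred == test_labels)
}

#' Run the full classification protocol for one participant
#'
#' For each of `n_repetitions` repetitions and each feasible
#' leave-one-velocity-out fold and classifier family: undersample the
#' training data (distinct discard sets across repetitions), z-score with
#' training statistics, tune hyperparameters on a stratified validation
#' split, fit, and score on the held-out velocity. The participant's
#' accuracy per family is the mean over feasible folds, then over
#' repetitions.
#'
#' @param trials A `labeled_trial_set` (participant must be included).
#' @param families Classifier families to run.
#' @param n_repetitions Undersampling repetitions.
#' @param budget Tuning budget per fit.
#' @param seed Master seed; per-(repetition, fold, family) child seeds are
#'   derived from it and recorded.
#' @param min_train_class Fold-feasibility threshold.
#' @return Object of class `protocol_result`: `accuracies` (data frame:
#'   repetition, test_velocity, family, accuracy, seed), `participant_mean`
#'   (named per family), `skipped_folds`, `tuned` (list of tuned specs).
#' @export
run_protocol <- function(trials, families = CLASSIFIER_FAMILIES,
                         n_repetitions = 5, budget = 50, seed = 1L,
                         min_train_class = 30) {
  stopifnot(inherits(trials, "labeled_trial_set"))
  families <- match.arg(families, CLASSIFIER_FAMILIES, several.ok = TRUE)
  folds <- make_velocity_folds(trials, min_train_class = min_train_class)
  feasible <- vapply(folds, `[[`, TRUE, "feasible")
  skipped <- vapply(folds[!feasible], `[[`, 0, "test_velocity")
  if (!any(feasible))
    stop_invalid("no feasible folds for this participant")

  rows <- list(); tuned <- list()
  used <- rep(list(list()), length(folds))   # discard history per fold
  for (rep_i in seq_len(n_repetitions)) {
    for (fi in which(feasible)) {
      fold <- folds[[fi]]
      us <- undersample_training(trials$label[fold$train_idx],
                                 seed = child_seed(seed, rep_i, fi),
                                 used_discards = used[[fi]])
      used[[fi]] <- us$used_discards
      bal_idx <- fold$train_idx[us$keep_idx]
      norm <- normalize_features(trials$features[bal_idx, , drop = FALSE],
                                 trials$features[fold$test_idx, , drop = FALSE])
      for (fam in families) {
        fam_seed <- child_seed(seed, rep_i, fi, match(fam, CLASSIFIER_FAMILIES))
        spec <- tune_hyperparameters(norm$train, trials$label[bal_idx],
                                     classifier_spec(fam), budget = budget,
                                     seed = fam_seed)
        acc <- train_and_test(spec, norm$train, norm$test,
                              trials$label[bal_idx],
                              trials$label[fold$test_idx],
                              seed = child_seed(fam_seed, 1L))
        rows[[length(rows) + 1L]] <- data.frame(
          repetition = rep_i, test_velocity = fold$test_velocity,
          family = fam, accuracy = acc, seed = fam_seed)
        tuned[[length(tuned) + 1L]] <- spec
      }
    }
  }
  acc_df <- do.call(rbind, rows)
  # mean over feasible folds within repetition, then over repetitions
  per_rep <- aggregate(accuracy ~ family + repetition, acc_df, mean)
  pmean <- vapply(families, function(f)
    mean(per_rep$accuracy[per_rep$family == f]), numeric(1))
  structure(list(accuracies = acc_df, participant_mean = pmean,
                 skipped_folds = skipped, tuned = tuned, seed = seed,
                 families = families, n_repetitions = n_repetitions,
                 budget = budget),
            class = "protocol_result")
}

#' @export
print.protocol_result <- function(x, ...) {
  cat("<protocol_result>\n")
  for (f in x$families)
    cat(sprintf("  %-10s mean accuracy %.3f\n", f, x$participant_mean[[f]]))
  if (length(x$skipped_folds))
    cat("  skipped folds (test velocity):",
        paste(x$skipped_folds, collapse = ", "), "\n")
  invisible(x)
}
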