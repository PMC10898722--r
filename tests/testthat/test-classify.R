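# Labelling, folds, undersampling, normalization, tuning and the protocol.

test_that("labels follow the strict 5.0 threshold and the inclusion rule", {
  ft <- make_toy_features(n_per_vel = 20, seed = 1)
  ft$score[1] <- 6.9; ft$score[2] <- 4.3; ft$score[3] <- 5.0
  lab <- label_and_filter(ft, min_class = 5)
  expect_equal(as.character(lab$label[1]), "pleasant")
  expect_equal(as.character(lab$label[2]), "unpleasant")
  expect_equal(nrow(lab$features), nrow(ft) - 1)    # the 5.0 trial is gone
  expect_false(any(lab$score == 5))

  # class counts (25, 95): excluded at the 30-trial rule
  ft2 <- make_toy_features(n_per_vel = 30, seed = 2,
                           p_pleasant = c(`0.44` = 0.99, `1` = 0.99,
                                          `2` = 0.99, `4` = 0.2))
  lab2 <- label_and_filter(ft2)
  expect_false(lab2$included)
  expect_true(any(lab2$class_counts < 30))
  ft3 <- make_toy_features(n_per_vel = 30, seed = 3)
  expect_true(label_and_filter(ft3)$included)
})

test_that("velocity folds are disjoint, exhaustive and feasibility-checked", {
  ft <- make_toy_features(n_per_vel = 30, seed = 4)
  lab <- label_and_filter(ft)
  folds <- make_velocity_folds(lab)
  expect_length(folds, 4)
  expect_setequal(vapply(folds, `[[`, 0, "test_velocity"), c(0.44, 1, 2, 4))
  for (f in folds) {
    expect_equal(f$train_velocities, setdiff(c(0.44, 1, 2, 4), f$test_velocity))
    expect_length(intersect(f$train_idx, f$test_idx), 0)
    expect_setequal(lab$velocity[f$test_idx], f$test_velocity)
    expect_false(f$test_velocity %in% lab$velocity[f$train_idx])
  }
  # a fold whose training data lack 30 per class is marked infeasible
  lab29 <- lab
  drop <- which(lab29$velocity != 2 & lab29$label == "pleasant")
  keepn <- length(drop) - 29          # leave 29 pleasant training trials
  sel <- c(drop[seq_len(29)], which(lab29$velocity == 2),
           which(lab29$label == "unpleasant"))
  lab29$features <- lab29$features[sel, ]
  lab29$label <- lab29$label[sel]
  lab29$velocity <- lab29$velocity[sel]
  f2 <- make_velocity_folds(lab29)
  tv <- vapply(f2, `[[`, 0, "test_velocity")
  expect_false(f2[[which(tv == 2)]]$feasible)

  lab_missing <- lab
  keep <- lab$velocity != 4
  lab_missing$velocity <- lab$velocity[keep]
  lab_missing$label <- lab$label[keep]
  lab_missing$features <- lab$features[keep, ]
  expect_error(make_velocity_folds(lab_missing), "invalid design")
})

test_that("undersampling balances classes with distinct discard sets", {
  labels <- factor(c(rep("pleasant", 47), rep("unpleasant", 33)),
                   levels = c("pleasant", "unpleasant"))
  us <- undersample_training(labels, seed = 1)
  expect_equal(as.integer(table(labels[us$keep_idx])), c(33L, 33L))
  # equal counts: identity
  bal <- factor(rep(c("pleasant", "unpleasant"), 10))
  expect_length(undersample_training(bal, seed = 1)$discard_idx, 0)
  # successive repetitions never reuse a discard set
  labels2 <- factor(c(rep("pleasant", 40), rep("unpleasant", 33)),
                    levels = c("pleasant", "unpleasant"))
  used <- list()
  keys <- character(0)
  for (r in 1:5) {
    us2 <- undersample_training(labels2, seed = r, used_discards = used)
    used <- us2$used_discards
    keys <- c(keys, paste(us2$discard_idx, collapse = ","))
  }
  expect_equal(length(unique(keys)), 5)
  # tiny surplus: distinct subsets exhaust, falls back with a warning
  lab3 <- factor(c("pleasant", "pleasant", "unpleasant"),
                 levels = c("pleasant", "unpleasant"))
  used3 <- list()
  for (r in 1:2) {
    u <- undersample_training(lab3, seed = r, used_discards = used3)
    used3 <- u$used_discards
  }
  expect_warning(undersample_training(lab3, seed = 5, used_discards = used3),
                 "exhausted")
})

test_that("normalization uses training statistics only", {
  withr::with_seed(5, {
    tr <- matrix(rnorm(50 * 4, mean = 3), 50)
    te <- matrix(rnorm(20 * 4, mean = -1), 20)
    nm <- normalize_features(tr, te)
    expect_equal(unname(colMeans(nm$train)), rep(0, 4), tolerance = 1e-10)
    expect_equal(unname(apply(nm$train, 2, sd)), rep(1, 4), tolerance = 1e-10)
    # no leakage: test columns are not centred
    expect_gt(max(abs(colMeans(nm$test))), 0.5)
    # location invariance: shifting everything shifts nothing after scaling
    nm2 <- normalize_features(tr + 7, te + 7)
    expect_equal(nm2$train, nm$train, tolerance = 1e-10)
    expect_equal(nm2$test, nm$test, tolerance = 1e-10)
    tr0 <- tr; tr0[, 2] <- 1
    colnames(tr0) <- paste0("f", 1:4)
    expect_error(normalize_features(tr0, te), "zero-variance.*f2")
  })
})

test_that("tuning is deterministic, bounded by budget and can reach perfection", {
  withr::with_seed(6, {
    X <- matrix(rnorm(60 * 6), 60)
    y <- factor(rep(c("pleasant", "unpleasant"), each = 30),
                levels = c("pleasant", "unpleasant"))
    X[y == "pleasant", 1] <- X[y == "pleasant", 1] + 6   # separable
    for (fam in c("logreg", "svm_linear", "svm_rbf", "ann")) {
      s1 <- tune_hyperparameters(X, y, classifier_spec(fam), budget = 5, seed = 42)
      s2 <- tune_hyperparameters(X, y, classifier_spec(fam), budget = 5, seed = 42)
      expect_identical(s1$hyper, s2$hyper)
      # attainability: with a larger search some configuration separates
      # the validation split perfectly
      s3 <- tune_hyperparameters(X, y, classifier_spec(fam), budget = 20,
                                 seed = 42)
      expect_equal(s3$validation_accuracy, 1.0)
    }
    sb1 <- tune_hyperparameters(X, y, classifier_spec("svm_rbf"), budget = 1,
                                seed = 7)
    expect_named(sb1$hyper, c("C", "gamma"))
    expect_error(tune_hyperparameters(X, y, classifier_spec("svm_rbf"),
                                      budget = 0), "budget")
  })
})

test_that("all four families separate well-separated Gaussians and stay at chance on noise", {
  withr::with_seed(8, {
    n <- 60
    d <- 24
    Xtr <- rbind(matrix(rnorm(n * d), n), matrix(rnorm(n * d, mean = 6 / sqrt(d)), n))
    ytr <- factor(rep(c("unpleasant", "pleasant"), each = n),
                  levels = c("pleasant", "unpleasant"))
    Xte <- rbind(matrix(rnorm(30 * d), 30), matrix(rnorm(30 * d, mean = 6 / sqrt(d)), 30))
    yte <- factor(rep(c("unpleasant", "pleasant"), each = 30),
                  levels = c("pleasant", "unpleasant"))
    for (fam in c("logreg", "svm_linear", "svm_rbf", "ann")) {
      spec <- tune_hyperparameters(Xtr, ytr, classifier_spec(fam),
                                   budget = 8, seed = 3)
      acc <- train_and_test(spec, Xtr, Xte, ytr, yte, seed = 4)
      expect_gte(acc, 0.95)
    }
    # shuffled labels: chance band at n_test = 60
    yshuf <- sample(ytr)
    accs <- vapply(c("logreg", "svm_rbf"), function(fam) {
      spec <- tune_hyperparameters(Xtr, yshuf, classifier_spec(fam),
                                   budget = 5, seed = 5)
      train_and_test(spec, Xtr, Xte, yshuf, sample(yte), seed = 6)
    }, numeric(1))
    expect_true(all(accs > 0.3 & accs < 0.7))
  })
})

test_that("duplicating training points leaves the linear SVM unchanged", {
  withr::with_seed(9, {
    X <- matrix(rnorm(40 * 5), 40)
    y <- factor(rep(c("pleasant", "unpleasant"), each = 20),
                levels = c("pleasant", "unpleasant"))
    X[y == "pleasant", ] <- X[y == "pleasant", ] + 1
    Xte <- matrix(rnorm(50 * 5), 50)
    m1 <- e1071::svm(X, y, kernel = "linear", cost = 1, scale = FALSE)
    m2 <- e1071::svm(rbind(X, X), c(y, y), kernel = "linear", cost = 0.5,
                     scale = FALSE)
    # doubling the data at half the cost keeps the same solution (up to
    # the SMO solver's numerical tolerance)
    expect_equal(as.character(predict(m1, Xte)), as.character(predict(m2, Xte)))
    d1 <- attr(predict(m1, Xte, decision.values = TRUE), "decision.values")
    d2 <- attr(predict(m2, Xte, decision.values = TRUE), "decision.values")
    expect_equal(unname(d1), unname(d2), tolerance = 1e-2)
  })
})

test_that("the protocol produces 20 accuracies per family, deterministically", {
  ft <- make_toy_features(n_per_vel = 30, signal = 2, seed = 10)
  lab <- label_and_filter(ft, min_class = 20)
  res <- run_protocol(lab, families = c("logreg", "svm_rbf"),
                      n_repetitions = 5, budget = 2, seed = 77,
                      min_train_class = 20)
  expect_equal(nrow(res$accuracies), 2 * 5 * 4)
  expect_true(all(res$accuracies$accuracy >= 0 & res$accuracies$accuracy <= 1))
  expect_equal(sort(unique(res$accuracies$test_velocity)), c(0.44, 1, 2, 4))
  # separable features: well above chance
  expect_gt(res$participant_mean[["svm_rbf"]], 0.8)
  res2 <- run_protocol(lab, families = c("logreg", "svm_rbf"),
                       n_repetitions = 5, budget = 2, seed = 77,
                       min_train_class = 20)
  expect_identical(res$accuracies, res2$accuracies)
  # infeasible folds are skipped and logged
  ft_imb <- make_toy_features(n_per_vel = 30, seed = 11,
                              p_pleasant = c(`0.44` = 0.1, `1` = 0.9,
                                             `2` = 0.9, `4` = 0.9))
  lab_imb <- label_and_filter(ft_imb, min_class = 10)
  res_imb <- run_protocol(lab_imb, families = "logreg", n_repetitions = 2,
                          budget = 1, seed = 5, min_train_class = 30)
  expect_true(length(res_imb$skipped_folds) >= 1)
  expect_lt(nrow(res_imb$accuracies), 2 * 4)
})

test_that("training sets entering the fitters are always balanced and velocity-disjoint", {
  # guard-object check: wrap the internal fitter path by inspecting the
  # undersample + fold machinery the protocol uses
  ft <- make_toy_features(n_per_vel = 25, seed = 12)
  lab <- label_and_filter(ft, min_class = 15)
  folds <- make_velocity_folds(lab, min_train_class = 15)
  for (f in folds) {
    us <- undersample_training(lab$label[f$train_idx], seed = 1)
    bal <- table(lab$label[f$train_idx][us$keep_idx])
    expect_equal(bal[[1]], bal[[2]])
    expect_false(f$test_velocity %in%
                   lab$velocity[f$train_idx][us$keep_idx])
  }
})
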