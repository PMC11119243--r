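test_that("confusion metrics reproduce hand-computed values", {
  y_true <- c(rep(1L, 50), rep(2L, 50))
  y_pred <- c(rep(1L, 40), rep(2L, 10), rep(1L, 5), rep(2L, 45))
  m <- confusion_metrics(y_true, y_pred)
  expect_identical(m$confusion, c(TP = 40L, FP = 5L, TN = 45L, FN = 10L))
  expect_equal(m$accuracy, 0.85)
  expect_equal(m$recall, 0.8)
  expect_equal(m$precision, 8 / 9)
  expect_equal(m$f1, 2 * (8 / 9) * 0.8 / ((8 / 9) + 0.8), tolerance = 1e-12)

  perfect <- confusion_metrics(y_true, y_true)
  expect_equal(unlist(perfect[c("accuracy", "precision", "recall", "f1")]),
               c(accuracy = 1, precision = 1, recall = 1, f1 = 1))

  all_neg <- confusion_metrics(y_true, rep(2L, 100))
  expect_equal(all_neg$recall, 0)
  expect_equal(all_neg$precision, 0)
  expect_true("precision" %in% all_neg$undefined)
})

test_that("metrics agree with an independent tally over random predictions", {
  set.seed(60)
  for (i in 1:200) {
    n <- sample(5:40, 1)
    yt <- sample(1:2, n, replace = TRUE)
    yp <- sample(1:2, n, replace = TRUE)
    m <- confusion_metrics(yt, yp)
    tp <- 0L; fp <- 0L; tn <- 0L; fn <- 0L
    for (j in seq_len(n)) {
      if (yt[j] == 1 && yp[j] == 1) tp <- tp + 1L
      if (yt[j] == 2 && yp[j] == 1) fp <- fp + 1L
      if (yt[j] == 2 && yp[j] == 2) tn <- tn + 1L
      if (yt[j] == 1 && yp[j] == 2) fn <- fn + 1L
    }
    expect_identical(m$confusion, c(TP = tp, FP = fp, TN = tn, FN = fn))
    expect_equal(m$accuracy, (tp + tn) / n)
    if (tp + fp > 0) expect_equal(m$precision, tp / (tp + fp))
    if (tp + fn > 0) expect_equal(m$recall, tp / (tp + fn))
  }
  expect_error(confusion_metrics(c(1, 3), c(1, 2)), "labels")
})

test_that("every classifier kind separates a linearly separable toy", {
  set.seed(61)
  x <- rbind(matrix(rnorm(40, mean = 3), 20), matrix(rnorm(40, mean = -3), 20))
  y <- rep(1:2, each = 20)
  for (kind in c("svm_rbf", "lda", "ann")) {
    model <- train_classifier(x, y, classifier_spec(kind))
    expect_identical(predict_classifier(model, x), y,
                     info = paste("kind:", kind))
  }
})

test_that("classifiers are deterministic given spec and seed", {
  set.seed(62)
  x <- matrix(rnorm(120), 30)
  y <- rep(1:2, 15)
  xt <- matrix(rnorm(40), 10)
  for (kind in c("svm_rbf", "lda", "ann")) {
    p1 <- predict_classifier(train_classifier(x, y, classifier_spec(kind, seed = 5L)), xt)
    p2 <- predict_classifier(train_classifier(x, y, classifier_spec(kind, seed = 5L)), xt)
    expect_identical(p1, p2, info = paste("kind:", kind))
  }
})

test_that("uninformative features score near chance on held-out data", {
  accs <- sapply(1:10, function(s) {
    set.seed(1000 + s)
    x <- matrix(rnorm(60 * 4), 60)       # features carry no class signal
    y <- rep(1:2, 30)
    model <- train_classifier(x[1:40, ], y[1:40], classifier_spec("svm_rbf"))
    mean(predict_classifier(model, x[41:60, ]) == y[41:60])
  })
  expect_gt(mean(accs), 0.35)
  expect_lt(mean(accs), 0.65)
})

test_that("degenerate training inputs are rejected", {
  x <- matrix(rnorm(20), 10)
  expect_error(train_classifier(x, rep(1L, 10)), "2 trials per class")
  expect_error(train_classifier(x[1:3, ], c(1L, 1L, 2L)), "2 trials per class")
  xb <- x; xb[1, 1] <- NA
  expect_error(train_classifier(xb, rep(1:2, 5)), "finite")
})

test_that("the ridge LDA agrees with MASS::lda on well-conditioned data", {
  set.seed(63)
  x <- rbind(matrix(rnorm(100, 1), 50, 2), matrix(rnorm(100, -1), 50, 2))
  y <- rep(1:2, each = 50)
  ours <- predict_classifier(train_classifier(x, y, classifier_spec("lda")), x)
  ref <- as.integer(predict(MASS::lda(x, grouping = y), x)$class)
  expect_gt(mean(ours == ref), 0.99)
})

test_that("cross-validation is leak-free: test trials never shape training-fold fits", {
  sim <- simulate_mi_eeg(sim_config(n_channels = 6L, informative_channels = 1:2,
                                    trials_per_class = 12L, trial_len_s = 2,
                                    seed = 70L))
  cfg <- default_pipeline_config()
  cfg$select_k <- 3L
  cfg$csp$V <- 1L
  base <- cross_validate(sim$epoched, cfg, folds = 3L, seed = 9L)
  f <- 2L
  te_idx <- which(base$fold_assignment == f)
  corrupted <- sim$epoched
  corrupted$data[te_idx, , ] <- corrupted$data[te_idx, , , drop = FALSE] * 1e4
  again <- cross_validate(corrupted, cfg, folds = 3L, seed = 9L)
  # fold f's training partition is untouched, so its fitted channel set is too
  expect_identical(again$selected_channels[[f]], base$selected_channels[[f]])
  # and the same folds were used (assignment depends only on labels + seed)
  expect_identical(again$fold_assignment, base$fold_assignment)
})

test_that("leaky whole-dataset selection is available but distinct", {
  sim <- simulate_mi_eeg(sim_config(n_channels = 6L, informative_channels = 1:2,
                                    trials_per_class = 10L, trial_len_s = 2,
                                    seed = 71L))
  cfg <- default_pipeline_config()
  cfg$select_k <- 3L
  cfg$csp$V <- 1L
  cfg$leaky_selection <- TRUE
  leaky <- cross_validate(sim$epoched, cfg, folds = 2L, seed = 1L)
  # global selection: every fold sees the same channel set
  expect_identical(leaky$selected_channels[[1]], leaky$selected_channels[[2]])
})

test_that("fold bookkeeping: means recompute and leave-one-out runs M folds", {
  sim <- simulate_mi_eeg(sim_config(n_channels = 4L, informative_channels = 1:2,
                                    trials_per_class = 4L, trial_len_s = 2,
                                    seed = 72L))
  cfg <- default_pipeline_config()
  cfg$csp$V <- 1L
  rep8 <- cross_validate(sim$epoched, cfg, folds = 8L, seed = 2L)
  expect_length(rep8$folds, 8L)
  acc <- vapply(rep8$folds, function(m) m$accuracy, numeric(1))
  expect_equal(rep8$summary$mean[rep8$summary$metric == "accuracy"], mean(acc))
  f1 <- vapply(rep8$folds, function(m) m$f1, numeric(1))
  expect_equal(rep8$summary$mean[rep8$summary$metric == "f1"], mean(f1))
})

test_that("training partitions missing a class raise a stratification error", {
  data <- array(rnorm(6 * 2 * 60), c(6, 2, 60))
  eeg <- epoched_eeg(data, 100, labels = c(1L, rep(2L, 5)))
  cfg <- default_pipeline_config()
  cfg$csp$V <- 1L
  # folds > minority count forces the lone class-1 trial into one fold;
  # when that fold is held out, training lacks class 1
  expect_error(cross_validate(eeg, cfg, folds = 5L, seed = 1L),
               "lacks a class")
})
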