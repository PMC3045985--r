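# Cost-balanced SVM, AUC, specificity-at-sensitivity and cross-validation.

test_that("cost ratio equals #neg / #pos", {
  y1 <- c(rep(0, 66), rep(1, 115))     # the archetypal imbalanced cohort
  expect_equal(cost_ratio(y1), 66 / 115)
  expect_equal(cost_ratio(rep(0:1, 10)), 1)
  expect_equal(cost_ratio(c(rep(0, 10), 1)), 10)
  expect_error(cost_ratio(rep(1, 5)), "both classes")
  # conservation: ratio * #pos = #neg exactly
  expect_equal(cost_ratio(y1) * 115, 66)
})

test_that("rank AUC handles perfect, tied and hand-built score lists", {
  expect_equal(auc(1:10, rep(0:1, each = 5)), 1)
  expect_equal(auc(rep(0.3, 8), rep(0:1, 4)), 0.5)
  # 4 samples, 4 positive-negative pairs, 3 concordant
  expect_equal(auc(c(0.1, 0.4, 0.35, 0.8), c(0, 0, 1, 1)), 0.75)
  expect_error(auc(1:3, c(1, 1, 1)), "both classes")
})

test_that("AUC is antisymmetric under score negation and matches pROC", {
  set.seed(10)
  y <- rep(0:1, each = 30)
  s <- rnorm(60) + y
  expect_equal(auc(s, y) + auc(-s, y), 1)
  skip_if_not_installed("pROC")
  ref <- as.numeric(pROC::auc(pROC::roc(y, s, quiet = TRUE,
                                        direction = "<")))
  expect_equal(auc(s, y), ref)
})

test_that("specificity at sensitivity follows the threshold sweep", {
  y <- rep(0:1, each = 5)
  perfect <- c(1:5, 11:15)
  sp <- spec_at_sensitivity(perfect, y)
  expect_equal(sp$specificity, c(100, 100, 100))
  tied <- rep(2, 10)
  expect_equal(spec_at_sensitivity(tied, y)$specificity, c(0, 0, 0))
  # brute-force oracle on a hand-built 10-sample list
  s <- c(0.1, 0.2, 0.3, 0.55, 0.6, 0.5, 0.7, 0.8, 0.9, 0.95)
  for (lv in c(90, 95, 99)) {
    thr <- sort(unique(s), decreasing = TRUE)
    best <- 0
    for (t in thr)
      if (mean(s[y == 1] >= t) >= lv / 100) { best <- t; break }
    oracle <- 100 * mean(s[y == 0] < best)
    expect_equal(spec_at_sensitivity(s, y, lv)$specificity, oracle)
  }
})

test_that("the SVM separates a separable toy set and is standardised", {
  set.seed(11)
  n <- 40
  y <- rep(0:1, each = n / 2)
  X <- cbind(a = y * 5 + rnorm(n, sd = 0.3),
             b = rnorm(n))
  m <- train_svm(X, y)
  expect_equal(auc(predict(m, X), y), 1)
  expect_error(train_svm(X[c(1, 1), ], y[c(1, 1)]), "degenerate")
})

test_that("duplicating a feature equals sqrt(2)-scaling it in the kernel", {
  # kernel arithmetic: a column appearing twice contributes twice its
  # squared difference to ||x - x'||^2, exactly like scaling it by
  # sqrt(2); after standardisation the two models must agree
  set.seed(12)
  n <- 50
  y <- rep(0:1, each = n / 2)
  a <- y + rnorm(n, sd = 0.8); b <- rnorm(n)
  Xdup <- cbind(a = a, b = b, a2 = a)
  Xscl <- cbind(a = sqrt(2) * scale(a)[, 1], b = b)
  sc1 <- predict(train_svm(Xdup, y), Xdup)
  cfg <- classifier_config()
  m2 <- e1071::svm(x = cbind(Xscl[, 1], scale(b)[, 1]),
                   y = factor(y, levels = c(0, 1)), kernel = "radial",
                   gamma = cfg$gamma, cost = cfg$base_cost,
                   class.weights = c(`0` = 1, `1` = 1), scale = FALSE)
  dv <- attr(predict(m2, cbind(Xscl[, 1], scale(b)[, 1]),
                     decision.values = TRUE), "decision.values")
  sc2 <- as.numeric(dv[, 1])
  if (strsplit(colnames(dv)[1], "/")[[1]][1] != "1") sc2 <- -sc2
  expect_equal(sc1, sc2, tolerance = 1e-6)
})

test_that("permuted labels give chance-level cross-validated AUC", {
  set.seed(13)
  n <- 200
  X <- matrix(rnorm(n * 6), n, 6, dimnames = list(NULL, paste0("f", 1:6)))
  y <- sample(rep(0:1, each = n / 2))
  rep0 <- cross_validate(X, y, classifier_config(n_repeats = 1, seed = 3),
                         select = FALSE)
  expect_gte(rep0$auc_mean, 0.4)
  expect_lte(rep0$auc_mean, 0.6)
})

test_that("cross-validation with nested selection finds planted signal", {
  d <- simulate_feature_table(80, 12, c(1, 2, 3), c(2, 1.5, 1.5), seed = 14)
  rep1 <- cross_validate(d$X, d$y, classifier_config(n_repeats = 2, seed = 5))
  expect_gte(rep1$auc_mean, 0.95)
  expect_length(rep1$auc_per_repeat, 2L)
  expect_equal(nrow(rep1$spec_at_sens), 3L)
  # determinism: identical seeds, identical reports
  rep2 <- cross_validate(d$X, d$y, classifier_config(n_repeats = 2, seed = 5))
  expect_equal(rep1$auc_per_repeat, rep2$auc_per_repeat)
  expect_equal(rep1$scores, rep2$scores)
})

test_that("held-out labels cannot influence selection or the model", {
  d <- simulate_feature_table(60, 8, c(1, 5), c(1.5, 1), seed = 15)
  folds <- histomorph:::make_folds(d$y, 5, seed = 9)
  tr <- folds != 1
  sel_a <- select_features(d$X[tr, ], d$y[tr])
  m_a <- train_svm(d$X[tr, ], d$y[tr], sel_a$final_set)
  # corrupt every held-out label; the training path must be unchanged
  y_bad <- d$y; y_bad[!tr] <- 1 - y_bad[!tr]
  sel_b <- select_features(d$X[tr, ], y_bad[tr])
  m_b <- train_svm(d$X[tr, ], y_bad[tr], sel_b$final_set)
  expect_equal(sel_a$final_set, sel_b$final_set)
  expect_equal(sel_a$mrmr_order, sel_b$mrmr_order)
  expect_equal(predict(m_a, d$X[!tr, ]), predict(m_b, d$X[!tr, ]))
})

test_that("transfer evaluation uses only the training cohort", {
  d1 <- simulate_feature_table(70, 8, c(1, 2), c(2, 1.5), seed = 16)
  d2 <- simulate_feature_table(50, 8, c(1, 2), c(2, 1.5), seed = 17)
  tt <- train_test_transfer(d1$X, d1$y, d2$X, d2$y,
                            classifier_config(seed = 2))
  expect_gt(tt$auc_mean, 0.85)
  # test = train reproduces the training evaluation
  self <- train_test_transfer(d1$X, d1$y, d1$X, d1$y,
                              classifier_config(seed = 2))
  sel <- select_features(d1$X, d1$y)
  m <- train_svm(d1$X, d1$y, sel$final_set)
  expect_equal(self$auc_mean, auc(predict(m, d1$X), d1$y))
  # shuffled test labels: chance level
  set.seed(18)
  sh <- train_test_transfer(d1$X, d1$y, d2$X, sample(d2$y),
                            classifier_config(seed = 2), select = FALSE)
  expect_gte(sh$auc_mean, 0.3); expect_lte(sh$auc_mean, 0.7)
  expect_error(train_test_transfer(d1$X, d1$y, d2$X[, 1:5], d2$y),
               "differ")
})
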