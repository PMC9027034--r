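# SMOTE balancing, RBF-SVM, metrics, cross-validation.

test_that("SMOTE equalises the study's group sizes at the majority count", {
  feats <- toy_features(seed = 2)
  out <- smote_balance(feats, seed = 3)
  counts <- table(out$group)
  expect_true(all(counts == 77))
  expect_equal(sum(!out$synthetic), 120L)
})

test_that("already balanced input gains no synthetic rows", {
  feats <- toy_features(n = c(a = 12, b = 12, c = 12), seed = 4)
  out <- smote_balance(feats, seed = 5)
  expect_equal(nrow(out), nrow(feats))
  expect_false(any(out$synthetic))
  expect_equal(out[names(feats)], feats)
})

test_that("synthetic points are convex combinations of same-class originals", {
  feats <- toy_features(n = c(small = 8, big = 30), d = 4, seed = 6)
  out <- smote_balance(feats, seed = 7)
  fx <- paste0("bin_", 1:4)
  orig <- as.matrix(feats[feats$group == "small", fx])
  syn <- as.matrix(out[out$synthetic, fx])
  expect_equal(unique(out$group[out$synthetic]), "small")
  for (j in seq_len(nrow(syn))) {
    expect_true(is_convex_combination(syn[j, ], orig))
  }
})

test_that("SMOTE is deterministic given a seed and validates class sizes", {
  feats <- toy_features(seed = 8)
  a <- smote_balance(feats, seed = 9)
  b <- smote_balance(feats, seed = 9)
  expect_equal(a, b)
  c_ <- smote_balance(feats, seed = 10)
  expect_false(isTRUE(all.equal(a, c_)))
  small <- toy_features(n = c(tiny = 4, big = 20), seed = 11)
  expect_error(smote_balance(small, k_neighbors = 5), "tiny",
               class = "eegscreen_invalid_argument")
})

test_that("the RBF-SVM separates distant clusters and can memorise", {
  withr::with_seed(12, {
    x <- rbind(matrix(rnorm(40), 20), matrix(rnorm(40) + 10, 20))
    y <- rep(c("a", "b"), each = 20)
  })
  fit <- svm_rbf(x, y)
  expect_equal(as.character(predict(fit, x)), y)
  # memorising configuration: large C, narrow kernel, noisy labels
  withr::with_seed(13, {
    xn <- matrix(rnorm(60 * 2), 60)
    yn <- sample(c("a", "b", "c"), 60, replace = TRUE)
  })
  fit2 <- svm_rbf(xn, yn, cost = 1e6, gamma = 50)
  expect_equal(mean(as.character(predict(fit2, xn)) == yn), 1.0)
  # determinism
  fit3 <- svm_rbf(xn, yn, cost = 1e6, gamma = 50)
  expect_equal(as.character(predict(fit3, xn)), as.character(predict(fit2, xn)))
  expect_error(svm_rbf(x, rep("a", 40)), class = "eegscreen_invalid_argument")
})

test_that("confusion-matrix metrics match the macro one-vs-rest definitions", {
  expect_equal(compute_metrics(diag(c(5, 5, 5))),
               tibble::tibble(accuracy = 1, sensitivity = 1, specificity = 1))
  m <- matrix(c(8, 2, 0,
                1, 7, 2,
                0, 1, 9), 3, byrow = TRUE)
  got <- compute_metrics(m)
  # hand evaluation of the stated formulas
  sens <- mean(c(8 / 10, 7 / 10, 9 / 10))
  spec <- mean(c((7 + 2 + 1 + 9) / (7 + 2 + 1 + 9 + 1),
                 (8 + 0 + 0 + 9) / (8 + 0 + 0 + 9 + 3),
                 (8 + 2 + 1 + 7) / (8 + 2 + 1 + 7 + 2)))
  expect_equal(got$accuracy, 24 / 30)
  expect_equal(got$sensitivity, sens)
  expect_equal(got$specificity, spec)
  expect_equal(compute_metrics(matrix(2, 3, 3))$accuracy, 1 / 3)
  expect_error(compute_metrics(matrix(0, 3, 3)), class = "eegscreen_invalid_argument")
  # a class absent from truth is excluded from the macro means
  m2 <- matrix(c(4, 1, 0,
                 1, 4, 0,
                 0, 0, 0), 3, byrow = TRUE)
  expect_equal(compute_metrics(m2)$sensitivity, mean(c(0.8, 0.8)))
})

test_that("cross-validation is stratified, exhaustive and deterministic", {
  feats <- toy_features(n = c(dementia = 10, mci = 33, healthy = 77),
                        d = 6, shift = 4, seed = 14)
  cv <- cross_validate(feats, folds = 10, seed = 15, select = FALSE)
  expect_equal(sum(cv$confusion_test), 120)
  expect_equal(nrow(cv$folds), 10L)
  # every fold holds roughly 1/10 of each class
  tab <- table(feats$group, cv$fold_assignment)
  expect_true(all(tab["dementia", ] == 1))
  expect_true(all(tab["healthy", ] %in% 7:8))
  cv2 <- cross_validate(feats, folds = 10, seed = 15, select = FALSE)
  expect_identical(cv$fold_assignment, cv2$fold_assignment)
  expect_equal(cv$metrics, cv2$metrics)
  expect_error(cross_validate(feats[1:5, ], folds = 10),
               class = "eegscreen_invalid_argument")
})

test_that("global leakage mode balances before splitting", {
  feats <- toy_features(n = c(dementia = 10, mci = 33, healthy = 77),
                        d = 6, shift = 4, seed = 16)
  cv <- cross_validate(feats, folds = 10, seed = 17, leakage = "global",
                       select = FALSE)
  expect_equal(sum(cv$confusion_test), 3 * 77)
  expect_s3_class(tidy(cv), "tbl_df")
  g <- glance(cv)
  expect_equal(g$leakage, "global")
  expect_true(all(c("train_accuracy", "test_accuracy") %in% names(g)))
})
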