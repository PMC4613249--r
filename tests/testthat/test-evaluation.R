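test_that("confusion metrics evaluate their defining formulas", {
  # TP=3 FN=1 TN=8 FP=2
  yTrue <- c(rep(1, 4), rep(0, 10))
  yPred <- c(1, 1, 1, 0, 1, 1, rep(0, 8))
  m <- computeMetrics(yTrue, yPred)
  expect_equal(m[c("TP", "FN", "FP", "TN")], list(TP = 3L, FN = 1L,
                                                  FP = 2L, TN = 8L))
  expect_equal(m$Sn, 0.75)
  expect_equal(m$Sp, 0.8)
  expect_equal(m$Acc, 11 / 14)
  expect_equal(m$BAcc, 0.775)
  # perfect prediction
  p <- computeMetrics(c(1, 0, 1), c(1, 0, 1))
  expect_equal(unlist(p[c("Sn", "Sp", "Acc", "BAcc")]),
               c(Sn = 1, Sp = 1, Acc = 1, BAcc = 1))
  # headline rates reported for the independent test combine to 0.916
  expect_equal(balancedAccuracy(0.892, 0.940), 0.916)
})

test_that("an absent class yields flagged undefined rates, never silent 0", {
  m <- computeMetrics(rep(1, 5), rep(1, 5))
  expect_true(is.na(m$Sp))
  expect_true(is.na(m$BAcc))
  expect_false(m$defined)
  expect_error(computeMetrics(c(1, 0), c(1)), "equal length")
  expect_error(computeMetrics(c(1, 2), c(1, 0)), "0/1")
})

test_that("Acc decomposes as the class-weighted mean of Sn and Sp", {
  set.seed(33)
  for (i in 1:20) {
    P <- sample(3:30, 1); N <- sample(3:60, 1)
    yTrue <- rep(c(1, 0), c(P, N))
    yPred <- rbinom(P + N, 1, 0.5)
    m <- computeMetrics(yTrue, yPred)
    expect_equal(m$Acc, (P * m$Sn + N * m$Sp) / (P + N))
  }
})

test_that("stratified folds partition each class into near-equal subsets", {
  lab <- rep(c(1L, 0L), c(371, 929))
  folds <- stratifiedKFold(lab, K = 10, seed = 3)
  posSizes <- vapply(folds, function(f) sum(lab[f$test] == 1L), 1L)
  expect_setequal(unique(posSizes), c(37L, 38L))
  expect_equal(sum(posSizes), 371)
  tests <- unlist(lapply(folds, `[[`, "test"))
  expect_equal(sort(tests), seq_along(lab))   # disjoint and exhaustive
  for (f in folds) expect_setequal(c(f$train, f$test), seq_along(lab))
  # K = 2 with 4 per class
  f2 <- stratifiedKFold(rep(c(1L, 0L), each = 4), K = 2, seed = 1)
  expect_equal(vapply(f2, function(f) length(f$test), 1L), c(4L, 4L))
  expect_error(stratifiedKFold(rep(c(1L, 0L), c(3, 50)), K = 10, seed = 1),
               "K = 10")
})

test_that("cross-validation pools fold predictions into one matrix", {
  # oracle stub: the truth is leaked through a feature column, so a
  # label-reading learner scores perfectly
  set.seed(44)
  lab <- rep(c(1L, 0L), c(20, 20))
  v <- cbind(truth = lab, noise = rnorm(40))
  rownames(v) <- paste0("s", 1:40)
  X <- FeatureMatrix(v, lab)
  cv <- crossValidate(X, stubConfig(G = 1, column = "truth"), K = 4,
                      seed = 5)
  expect_equal(unlist(cv$pooled[c("Sn", "Sp", "Acc", "BAcc")]),
               c(Sn = 1, Sp = 1, Acc = 1, BAcc = 1))

  # all-negative stub on a 1:9 dataset: the imbalance pathology
  lab9 <- rep(c(1L, 0L), c(10, 90))
  v9 <- cbind(truth = lab9, noise = rnorm(100))
  rownames(v9) <- paste0("s", 1:100)
  X9 <- FeatureMatrix(v9, lab9)
  cv9 <- crossValidate(X9, stubConfig(G = 1, constant = 0L), K = 2,
                       seed = 6)
  expect_equal(cv9$pooled$Sn, 0)
  expect_equal(cv9$pooled$Sp, 1)
  expect_equal(cv9$pooled$Acc, 0.9)
  expect_equal(cv9$pooled$BAcc, 0.5)  # why Acc misleads under imbalance

  # determinism
  cvA <- crossValidate(X, stubConfig(G = 1), K = 4, seed = 9)
  cvB <- crossValidate(X, stubConfig(G = 1), K = 4, seed = 9)
  expect_identical(cvA$pooled, cvB$pooled)
  expect_length(cvA$perFold, 4)
})
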