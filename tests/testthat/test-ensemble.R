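test_that("buildSubsets partitions G x P sampled negatives into G groups", {
  X <- gaussianMatrix(371, 7266, d = 2, shift = 0, seed = 2)
  subs <- buildSubsets(X, G = 9, seed = 17)
  expect_length(subs, 9)
  negIds <- unlist(lapply(subs, function(s)
    proteinIds(s)[classLabels(s) == 0L]))
  expect_length(negIds, 9 * 371)        # 3339 sampled negatives
  expect_false(anyDuplicated(negIds) > 0)
  for (s in subs) {
    expect_equal(nSamples(s), 742)      # 2P rows
    expect_equal(sum(classLabels(s)), 371)
  }
  # determinism
  subs2 <- buildSubsets(X, G = 9, seed = 17)
  expect_identical(lapply(subs, proteinIds), lapply(subs2, proteinIds))
  # degenerate G = 1: one balanced subset
  one <- buildSubsets(X, G = 1, seed = 1)
  expect_length(one, 1)
  expect_equal(nSamples(one[[1]]), 742)
  expect_error(buildSubsets(gaussianMatrix(10, 20, seed = 1), G = 3, 1),
               "smaller G")
})

test_that("the ensemble separates shifted Gaussian classes", {
  X <- gaussianMatrix(50, 150, d = 5, shift = 2, seed = 5)
  model <- trainEnsemble(X, ensembleConfig(G = 3, numTrees = 50, seed = 9))
  pred <- predictEnsemble(model, X)
  m <- computeMetrics(classLabels(X), pred$labels)
  expect_gte(m$BAcc, 0.95)
  expect_true(all(pred$votes >= 0 & pred$votes <= 3))
})

test_that("training and prediction are deterministic under a seed", {
  X <- gaussianMatrix(30, 90, d = 4, shift = 1, seed = 6)
  hold <- gaussianMatrix(20, 20, d = 4, shift = 1, seed = 60)
  p1 <- predictEnsemble(trainEnsemble(X, ensembleConfig(G = 3, seed = 4)),
                        hold)
  p2 <- predictEnsemble(trainEnsemble(X, ensembleConfig(G = 3, seed = 4)),
                        hold)
  expect_identical(p1, p2)
})

test_that("majority voting follows the votes > G/2 rule", {
  mkStub <- function(outputs) {
    # members are closures returning fixed votes via the pluggable contract
    new("EnsembleModel",
        members = lapply(outputs, function(o) o),
        featureNames = c("f1", "f2"),
        config = list(G = length(outputs), numTrees = 0L, seed = 1L,
                      predictFun = function(fit, x) rep(fit, nrow(x))))
  }
  X <- FeatureMatrix(matrix(0, 1, 2, dimnames = list("p", c("f1", "f2"))))
  expect_equal(predictEnsemble(mkStub(c(1L, 1L, 0L)), X)$labels, 1L)
  expect_equal(predictEnsemble(mkStub(c(1L, 1L, 0L)), X)$votes, 2L)
  # 4 of 9 votes is not a majority
  expect_equal(predictEnsemble(mkStub(rep(c(1L, 0L), c(4, 5))), X)$labels, 0L)
  # identical members vote unanimously
  expect_equal(predictEnsemble(mkStub(rep(1L, 5)), X)$votes, 5L)
  # even G (opt-in): a tie goes to the negative majority-prior class
  expect_equal(predictEnsemble(mkStub(c(1L, 0L)), X)$labels, 0L)
})

test_that("prediction refuses mismatched feature columns", {
  X <- gaussianMatrix(20, 60, d = 3, shift = 2, seed = 8)
  model <- trainEnsemble(X, ensembleConfig(G = 1, numTrees = 20, seed = 2))
  bad <- featureValues(X)
  colnames(bad) <- c("f1", "zzz", "f3")
  expect_error(predictEnsemble(model, FeatureMatrix(bad)), "zzz")
  expect_error(trainEnsemble(FeatureMatrix(featureValues(X),
                                           rep(1L, nSamples(X))),
                             ensembleConfig(G = 1)),
               "both classes")
  expect_error(ensembleConfig(G = 4), "allowAnyG")
})

test_that("model archives round-trip through save and load", {
  X <- gaussianMatrix(20, 60, d = 3, shift = 2, seed = 12)
  hold <- gaussianMatrix(10, 10, d = 3, shift = 2, seed = 13)
  model <- trainEnsemble(X, ensembleConfig(G = 3, numTrees = 20, seed = 3))
  f <- withr::local_tempfile(fileext = ".rds")
  saveEnsemble(model, f)
  back <- loadEnsemble(f)
  expect_identical(predictEnsemble(model, hold), predictEnsemble(back, hold))
})
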