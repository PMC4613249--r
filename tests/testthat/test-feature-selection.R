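test_that("ANOVA F matches the hand-worked two-group example", {
  # groups {1,2,3} and {4,5,6}: grand mean 3.5, group means 2 and 5
  v <- matrix(c(1, 2, 3, 4, 5, 6), 6, 1,
              dimnames = list(paste0("s", 1:6), "f1"))
  r <- anovaRank(FeatureMatrix(v, c(0L, 0L, 0L, 1L, 1L, 1L)))
  expect_equal(r$SSB, 13.5)
  expect_equal(r$SSW, 4)
  expect_equal(r$dfB, 1L)
  expect_equal(r$dfW, 4L)
  expect_equal(r$F, 13.5)
})

test_that("degenerate features rank by the stated conventions", {
  v <- cbind(const = rep(1, 8),                      # SSB = SSW = 0
             sep = rep(c(0, 1), each = 4),           # SSW = 0, SSB > 0
             noise = c(2, 1, 2, 1, 2, 1, 2, 1))
  rownames(v) <- paste0("s", 1:8)
  r <- anovaRank(FeatureMatrix(v, rep(c(0L, 1L), each = 4L)))
  expect_equal(r$name[1], "sep")
  expect_true(is.infinite(r$F[1]))
  expect_equal(r$F[r$name == "const"], 0)
  # equal group means -> F = 0
  expect_equal(r$F[r$name == "noise"], 0)
})

test_that("ANOVA F equals the textbook oracle and t^2 on random data", {
  set.seed(55)
  for (i in 1:30) {
    n1 <- sample(5:20, 1); n2 <- sample(5:20, 1)
    x <- c(rnorm(n1, mean = runif(1, -1, 1)), rnorm(n2))
    lab <- rep(c(1L, 0L), c(n1, n2))
    v <- matrix(x, dimnames = list(paste0("s", seq_along(x)), "f"))
    r <- anovaRank(FeatureMatrix(v, lab))
    expect_equal(r$F, oracleF(x, lab), tolerance = 1e-10)
    tt <- t.test(x[lab == 1], x[lab == 0], var.equal = TRUE)
    expect_equal(r$F, unname(tt$statistic^2), tolerance = 1e-10)
    # F depends only on group membership, not on ordering within groups
    perm <- c(sample(which(lab == 1L)), sample(which(lab == 0L)))
    r2 <- anovaRank(FeatureMatrix(v[perm, , drop = FALSE], lab[perm]))
    expect_equal(r2$F, r$F, tolerance = 1e-12)
  }
})

test_that("ranking orders by F with index tie-breaks and full coverage", {
  X <- gaussianMatrix(15, 15, d = 6, shift = 1, seed = 14)
  r <- anovaRank(X)
  expect_setequal(r$index, 1:6)
  expect_true(all(diff(r$F) <= 0))
  # two identical columns tie; ascending original index wins
  v <- featureValues(X)[, c(1, 1, 2)]
  colnames(v) <- c("a", "b", "c")
  rt <- anovaRank(FeatureMatrix(v, classLabels(X)))
  expect_lt(which(rt$name == "a"), which(rt$name == "b"))
  expect_error(anovaRank(FeatureMatrix(featureValues(X))), "labeled")
  expect_error(anovaRank(gaussianMatrix(2, 1, d = 2, seed = 1)),
               "at least 2")
})

test_that("incremental selection walks nested prefixes and finds the peak", {
  X <- gaussianMatrix(20, 60, d = 6, shift = 2, seed = 18)
  r <- anovaRank(X)
  cfg <- ensembleConfig(G = 3, numTrees = 25, seed = 2)
  res <- incrementalSelection(X, r, cfg, cvFolds = 4, cvSeed = 7)
  expect_equal(res$prefixMetrics$size, 1:6)
  expect_equal(res$optimalIndices, r$index[seq_len(res$optimalSize)])
  expect_equal(max(res$prefixMetrics$BAcc),
               res$prefixMetrics$BAcc[res$prefixMetrics$size ==
                                       res$optimalSize])
  # ties resolve to the smallest prefix
  first_max <- min(which(res$prefixMetrics$BAcc ==
                           max(res$prefixMetrics$BAcc)))
  expect_equal(res$optimalSize, res$prefixMetrics$size[first_max])
  # a stride must not change the metrics of evaluated prefixes
  res2 <- incrementalSelection(X, r, cfg, cvFolds = 4, cvSeed = 7,
                               stride = 2)
  shared <- intersect(res$prefixMetrics$size, res2$prefixMetrics$size)
  expect_equal(res$prefixMetrics[res$prefixMetrics$size %in% shared, ],
               res2$prefixMetrics[res2$prefixMetrics$size %in% shared, ],
               ignore_attr = TRUE)
  expect_error(incrementalSelection(X, r, cfg, cvFolds = 30, cvSeed = 1),
               "smallest class")
})
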