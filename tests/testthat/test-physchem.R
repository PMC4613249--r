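test_that("global parameters match an independent ProtParam implementation", {
  # expected values computed once with Biopython's ProtParam / pI machinery
  cases <- list(
    list(seq = "MKTAYIAKQRQISFVKSHFSRQLEERLGLIEVQAPILSRVGDGTQDNLSGAEKAVQ",
         pI = 9.394994, ii = 43.525, gravy = -0.391071),
    list(seq = "ACDEFGHIKLMNPQRSTVWYACDEFGHIKLMNPQRSTVWYACDEFGHIKL",
         pI = 6.286358, ii = 97.496, gravy = -0.374),
    list(seq = "SSTTSSTTNNQQAAGGILVPSSTTSSTTNNQQAAGGILVPSSTTSSTTNNQQAAGGILVP",
         pI = 5.240009, ii = 55.043333, gravy = -0.315),
    list(seq = strrep("A", 60), pI = 5.570017, ii = 9.833333, gravy = 1.8)
  )
  for (cs in cases) {
    g <- globalPhyschem(cs$seq)
    expect_equal(unname(g["pI"]), cs$pI, tolerance = 1e-3)
    expect_equal(unname(g["instability_index"]), cs$ii, tolerance = 1e-5)
    expect_equal(unname(g["gravy"]), cs$gravy, tolerance = 1e-5)
  }
})

test_that("charged-residue counts, aliphatic index and pI ordering behave", {
  g <- globalPhyschem("DDDD")
  expect_equal(unname(g["n_negative"]), 4)
  expect_equal(unname(g["n_positive"]), 0)
  polyA <- globalPhyschem(strrep("A", 40))
  expect_equal(unname(polyA["gravy"]), 1.8)
  expect_equal(unname(polyA["aliphatic_index"]), 100)
  expect_gt(isoelectricPoint("KKKK"), isoelectricPoint("DDDD"))
  expect_error(globalPhyschem("A"), "L < 2")
})

test_that("auto-covariance matches its closed forms", {
  # homopolymer: every deviation from the sequence mean is zero
  expect_equal(unname(acEncode(strrep("W", 50))), rep(0, 70))
  # two-residue sequence, lambda = 1: AC = -((a - c)^2) / 4
  tab <- propertyTable()
  ac <- acEncode("AC", table = tab, lambdaMax = 1, standardize = FALSE)
  expected <- -((tab["A", ] - tab["C", ])^2) / 4
  expect_equal(unname(ac), unname(expected))
  # translation invariance: adding a constant to a property changes nothing
  shifted <- tab + 5
  expect_equal(unname(acEncode("ACDEFGHIKLAC", tab, 3, standardize = FALSE)),
               unname(acEncode("ACDEFGHIKLAC", shifted, 3,
                               standardize = FALSE)))
})

test_that("auto-covariance agrees with the brute-force double loop", {
  tab <- propertyTable()
  set.seed(77)
  for (i in 1:100) {
    L <- sample(50:200, 1)
    s <- randomSeq(L)
    got <- acEncode(s, table = tab, lambdaMax = 10, standardize = FALSE)
    expect_equal(unname(got), oracleAC(s, tab, 10), tolerance = 1e-12)
  }
})

test_that("auto-covariance is quadratic in scale and reversal invariant", {
  tab <- propertyTable()
  s <- randomSeq(80, seed = 123)
  base <- acEncode(s, tab, 10, standardize = FALSE)
  expect_equal(unname(acEncode(s, tab * 3, 10, standardize = FALSE)),
               unname(9 * base))
  rev_s <- paste(rev(strsplit(s, "")[[1]]), collapse = "")
  expect_equal(acEncode(rev_s, tab, 10, standardize = FALSE),
               base, tolerance = 1e-12)
  expect_error(acEncode("ACDEF", tab, 10), "lambdaMax")
})
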