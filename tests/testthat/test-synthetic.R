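test_that("generators are pure functions of their seed", {
  b1 <- generateBundle(3, 3, seed = 99)
  b2 <- generateBundle(3, 3, seed = 99)
  expect_identical(as.character(b1$records), as.character(b2$records))
  expect_identical(lapply(b1$pssms, pssmScores),
                   lapply(b2$pssms, pssmScores))
  expect_identical(lapply(b1$disorder, disorderScores),
                   lapply(b2$disorder, disorderScores))
  expect_identical(lapply(b1$domains, domainEntries),
                   lapply(b2$domains, domainEntries))
  b3 <- generateBundle(3, 3, seed = 100)
  expect_false(identical(as.character(b1$records),
                         as.character(b3$records)))
})

test_that("generated data respect their declared constraints", {
  b <- generateBundle(5, 5, lengthRange = c(50, 80), signal = 0.7,
                      seed = 12)
  # every sequence passes the dataset filter
  res <- filterDataset(b$records)
  expect_length(res$kept, 10)
  expect_equal(nrow(res$rejected), 0)
  for (id in names(b$records)) {
    L <- nchar(as.character(b$records[[id]]))
    expect_equal(dim(pssmScores(b$pssms[[id]])), c(L, 20L))
    s <- disorderScores(b$disorder[[id]])
    expect_length(s, L)
    expect_true(all(s >= 0 & s <= 1))
  }
  expect_error(generateSequences(2, 2, lengthRange = c(10, 5)), "range")
  expect_error(generateSequences(2, 2, signal = 2), "signal")
})

test_that("signal = 0 produces exchangeable class compositions", {
  # null calibration: the hydroxyl AAC feature should only rarely differ
  # between classes by a Kolmogorov-Smirnov test at alpha = 0.01
  rejections <- 0L
  for (r in 1:30) {
    recs <- generateSequences(25, 25, lengthRange = c(50, 120), signal = 0,
                              seed = 1000 + r)
    fm <- assembleFeatures(recs, families = "composition")
    x <- featureValues(fm)[, "aac_hydroxyl"]
    lab <- classLabels(fm)
    p <- suppressWarnings(ks.test(x[lab == 1], x[lab == 0]))$p.value
    if (p < 0.01) rejections <- rejections + 1L
  }
  expect_lte(rejections, 2L)
})

test_that("perfectly enriched domains separate the classes by themselves", {
  recs <- generateSequences(10, 10, signal = 0, seed = 31)
  doms <- generateDomains(recs, enrichment = 1, negRate = 0, seed = 32)
  v <- t(vapply(names(recs), function(id) domainFeatures(doms[[id]]),
                numeric(15)))
  pred <- as.integer(rowSums(v) > 0)
  m <- computeMetrics(proteinLabels(recs), pred)
  expect_equal(m$BAcc, 1)
})

test_that("a strong compositional signal is learnable by the ensemble", {
  recs <- generateSequences(40, 40, lengthRange = c(50, 120), signal = 1,
                            seed = 71)
  fm <- assembleFeatures(recs, families = "composition")
  cv <- crossValidate(fm, ensembleConfig(G = 1, numTrees = 60, seed = 2),
                      K = 5, seed = 3)
  expect_gte(cv$pooled$BAcc, 0.9)
})

test_that("fixture bundles round-trip through the io layer unchanged", {
  dir <- withr::local_tempdir()
  b <- generateBundle(2, 2, lengthRange = c(50, 60), seed = 8)
  fa <- file.path(dir, "r.fasta")
  writeFasta(b$records, fa)
  expect_identical(as.character(readFasta(fa)), as.character(b$records))
  for (id in names(b$records)) {
    f <- file.path(dir, paste0(id, ".pssm"))
    writePSSM(b$pssms[[id]], f, sequence = as.character(b$records[id]))
    expect_equal(unname(pssmScores(readPSSM(f, b$records[id]))),
                 unname(pssmScores(b$pssms[[id]])))
  }
  fd <- file.path(dir, "dis.tsv")
  writeDisorder(b$disorder, fd)
  expect_equal(lapply(readDisorder(fd), disorderScores)[names(b$disorder)],
               lapply(b$disorder, disorderScores))
  fm <- file.path(dir, "dom.tsv")
  writeDomains(b$domains, fm)
  expect_equal(lapply(readDomains(fm, ids = names(b$records)),
                      domainEntries),
               lapply(b$domains, domainEntries))
})

test_that("experiment runner validates names and reports replicate tables", {
  expect_error(runExperiment("nonsense"), "valid names")
  tab <- runExperiment("g_sweep",
                       params = list(nPos = 10L, replicates = 2L,
                                     nTest = 15L, numTrees = 25L,
                                     Gs = c(1L, 3L)),
                       seed = 5)
  expect_equal(tab$condition, c("G=1", "G=3"))
  expect_true(all(c("Sn_mean", "Sp_sd", "BAcc_mean") %in% names(tab)))
  detail <- attr(tab, "replicates")
  expect_equal(nrow(detail), 4)
})
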