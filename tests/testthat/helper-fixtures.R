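# Shared fixture builders and brute-force oracles, all built in code.

GROUPS <- functionalGroups()
GROUP_NAMES <- names(GROUPS)
AAS <- strsplit("ARNDCQEGHILKMFPSTWYV", "")[[1]]

randomSeq <- function(L, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  paste(sample(AAS, L, replace = TRUE), collapse = "")
}

# map one residue to its group name (oracle-side, independent loop)
oracleGroupOf <- function(ch) {
  for (g in GROUP_NAMES) if (ch %in% GROUPS[[g]]) return(g)
  stop("unknown residue ", ch)
}

# brute-force group dipeptide counts
oracleDPC <- function(seq) {
  chars <- strsplit(seq, "")[[1]]
  L <- length(chars)
  counts <- matrix(0, 10, 10, dimnames = list(GROUP_NAMES, GROUP_NAMES))
  for (i in seq_len(L - 1)) {
    gi <- oracleGroupOf(chars[i]); gj <- oracleGroupOf(chars[i + 1])
    counts[gi, gj] <- counts[gi, gj] + 1
  }
  as.numeric(t(counts)) / (L - 1)
}

# brute-force auto-covariance, double loop straight from the definition
oracleAC <- function(seq, table, lambdaMax) {
  chars <- strsplit(seq, "")[[1]]
  L <- length(chars)
  out <- numeric(0)
  for (j in colnames(table)) {
    P <- table[chars, j]
    mj <- sum(P) / L
    for (lam in seq_len(lambdaMax)) {
      acc <- 0
      for (i in seq_len(L - lam))
        acc <- acc + (P[i] - mj) * (P[i + lam] - mj)
      out <- c(out, acc / (L - lam))
    }
  }
  unname(out)
}

# naive four-loop PSSM group-pair reduction
oraclePSSMGroup <- function(seq, scores) {
  chars <- strsplit(seq, "")[[1]]
  L <- length(chars)
  sc <- 1 / (1 + exp(-scores))
  out <- matrix(0, 10, 10, dimnames = list(GROUP_NAMES, GROUP_NAMES))
  for (gi in GROUP_NAMES) for (gj in GROUP_NAMES) {
    acc <- 0
    for (p in seq_len(L)) {
      if (!(chars[p] %in% GROUPS[[gi]])) next
      for (a in seq_along(AAS))
        if (AAS[a] %in% GROUPS[[gj]]) acc <- acc + sc[p, a]
    }
    out[gi, gj] <- acc / L
  }
  as.numeric(t(out))
}

# textbook one-way ANOVA F for a single feature
oracleF <- function(values, labels) {
  groups <- split(values, labels)
  k <- length(groups); N <- length(values)
  grand <- mean(values)
  SSB <- sum(vapply(groups, function(g) length(g) * (mean(g) - grand)^2, 1))
  SSW <- sum(vapply(groups, function(g) sum((g - mean(g))^2), 1))
  (SSB / (k - 1)) / (SSW / (N - k))
}

# feature matrix of two shifted Gaussian clouds (labels 1 then 0)
gaussianMatrix <- function(nPos, nNeg, d = 5, shift = 2, seed = 1) {
  set.seed(seed)
  v <- rbind(matrix(rnorm(nPos * d, mean = shift), nPos, d),
             matrix(rnorm(nNeg * d), nNeg, d))
  dimnames(v) <- list(paste0("s", seq_len(nPos + nNeg)),
                      paste0("f", seq_len(d)))
  FeatureMatrix(v, rep(c(1L, 0L), c(nPos, nNeg)))
}

# base-learner stub that reads the true label out of a designated column
stubConfig <- function(G = 1L, column = "truth", constant = NULL) {
  ensembleConfig(G = G, seed = 1L,
                 fitFun = function(x, y, seed) NULL,
                 predictFun = function(fit, x) {
                   if (!is.null(constant)) rep(constant, nrow(x))
                   else as.integer(x[, column] > 0.5)
                 })
}

`%||%` <- function(a, b) if (is.null(a)) b else a
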