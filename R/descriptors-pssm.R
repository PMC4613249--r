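#' @include AllClasses.R
NULL

#' Sigmoid (logistic) scaling
#'
#' f(x) = 1 / (1 + exp(-x)); maps raw PSSM log-odds into (0, 1). Strictly
#' increasing, with f(x) + f(-x) = 1 and f(0) = 0.5.
#'
#' @param x numeric.
#' @return numeric in (0, 1).
#' @export
sigmoidScale <- function(x) 1 / (1 + exp(-x))

#' Functional-group-pair PSSM features (100 features)
#'
#' Each PSSM element is sigmoid-scaled, then rows are grouped by the
#' functional group of the sequence residue and columns by the functional
#' group of the target amino acid; feature (g_i, g_j) is the sum of scaled
#' scores over rows in g_i and columns in g_j, divided by the sequence
#' length L. This reduces the L x 20 evolutionary profile to the 10 x 10
#' group-pair space.
#'
#' @inheritParams groupAAC
#' @param profile a [PSSMProfile-class] with L rows.
#' @param scaled apply the sigmoid before aggregation (default TRUE, the
#'   presentation order of the method; set FALSE to aggregate raw scores).
#' @return Named length-100 vector, row-group-major
#'   ("pssm_<g_i>_<g_j>").
#' @export
pssmGroupFeatures <- function(sequence, profile, scaled = TRUE) {
  chars <- strsplit(toupper(as.character(sequence)[1]), "")[[1]]
  sc <- pssmScores(profile)
  L <- length(chars)
  if (nrow(sc) != L)
    stop("PSSM has ", nrow(sc), " rows but sequence has ", L,
         " residues (", proteinIds(profile), ")")
  if (scaled) sc <- sigmoidScale(sc)

  gn <- names(functionalGroups())
  map <- residueGroupMap()
  rowGroup <- factor(map[chars], levels = gn)
  colGroup <- factor(map[profile@alphabet], levels = gn)

  # column-group sums per row, then row-group sums: 10 x 10 matrix
  colSumsByGroup <- sapply(gn, function(g)
    rowSums(sc[, colGroup == g, drop = FALSE]))  # L x 10
  colSumsByGroup <- matrix(colSumsByGroup, nrow = L,
                           dimnames = list(NULL, gn))
  m <- matrix(0, 10, 10, dimnames = list(gn, gn))
  for (g in gn) {
    rows <- which(rowGroup == g)
    if (length(rows))
      m[g, ] <- colSums(colSumsByGroup[rows, , drop = FALSE])
  }
  v <- as.numeric(t(m)) / L  # row-major over (g_i, g_j)
  names(v) <- paste0("pssm_", rep(gn, each = 10), "_", rep(gn, times = 10))
  v
}
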