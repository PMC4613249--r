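#' @include alphabet.R
NULL

.pkgDataEnv <- new.env(parent = emptyenv())

#' The seven-property physicochemical table
#'
#' Residue-level values for hydrophobicity, hydrophilicity, net charge,
#' van der Waals volume, free energy of solution in water, side-chain
#' interaction parameter and average accessible surface area — the seven
#' properties fed into the auto-covariance encoder. The shipped table uses
#' AAindex scales ARGP820101, HOPT810101, KLEP840101, FAUJ880103,
#' CHAM820102, KRIW790103 and CHOC760101; a user table of the same shape
#' (20 rows in order "ARNDCQEGHILKMFPSTWYV", 7 named columns) may be
#' substituted.
#'
#' @param path optional CSV overriding the shipped table.
#' @return 20 x 7 numeric matrix, rownames = residues.
#' @export
propertyTable <- function(path = NULL) {
  if (is.null(path)) {
    if (!is.null(.pkgDataEnv$props)) return(.pkgDataEnv$props)
    path <- system.file("extdata", "aaindex_properties.csv",
                        package = "afpred", mustWork = TRUE)
    cacheIt <- TRUE
  } else cacheIt <- FALSE
  tab <- read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  m <- as.matrix(tab[, -1, drop = FALSE])
  rownames(m) <- tab[[1]]
  if (!identical(rownames(m), AA_ORDER))
    stop("property table rows must be the 20 residues in order ",
         paste(AA_ORDER, collapse = ""))
  if (ncol(m) != 7L) stop("property table must have 7 property columns")
  if (cacheIt) .pkgDataEnv$props <- m
  m
}

.diwv <- function() {
  if (!is.null(.pkgDataEnv$diwv)) return(.pkgDataEnv$diwv)
  path <- system.file("extdata", "diwv.csv", package = "afpred",
                      mustWork = TRUE)
  tab <- read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  m <- as.matrix(tab[, -1, drop = FALSE])
  rownames(m) <- tab[[1]]
  .pkgDataEnv$diwv <- m
  m
}

# Kyte-Doolittle hydropathy, used for GRAVY.
.KD <- c(A = 1.8, R = -4.5, N = -3.5, D = -3.5, C = 2.5, Q = -3.5,
         E = -3.5, G = -0.4, H = -3.2, I = 4.5, L = 3.8, K = -3.9,
         M = 1.9, F = 2.8, P = -1.6, S = -0.8, T = -0.7, W = -0.9,
         Y = -1.3, V = 4.2)

# Bjellqvist/Expasy pKa set, including the residue-specific terminal pKas
# ProtParam applies.
.PKA_POS <- c(Nterm = 7.5, K = 10.0, R = 12.0, H = 5.98)
.PKA_NEG <- c(Cterm = 3.55, D = 4.05, E = 4.45, C = 9.0, Y = 10.0)
.PKA_NTERM <- c(A = 7.59, M = 7.0, S = 6.93, P = 8.36, T = 6.82,
                V = 7.44, E = 7.7)
.PKA_CTERM <- c(D = 4.55, E = 4.75)

.netCharge <- function(counts, pH, pkaPos, pkaNeg) {
  pos <- sum(c(1, counts[c("K", "R", "H")]) /
               (1 + 10^(pH - pkaPos)))
  neg <- sum(c(1, counts[c("D", "E", "C", "Y")]) /
               (1 + 10^(pkaNeg - pH)))
  pos - neg
}

#' Theoretical isoelectric point
#'
#' Bisection on the Henderson-Hasselbalch net-charge curve with the
#' Bjellqvist/Expasy pKa set (side chains D 4.05, E 4.45, C 9.0, Y 10.0,
#' H 5.98, K 10.0, R 12.0; termini 3.55 / 7.5, adjusted for the identity
#' of the terminal residues as in ProtParam).
#'
#' @inheritParams groupAAC
#' @return pI in pH units.
#' @export
isoelectricPoint <- function(sequence) {
  chars <- strsplit(toupper(as.character(sequence)[1]), "")[[1]]
  counts <- table(factor(chars, levels = STANDARD_AA))
  pkaPos <- .PKA_POS
  pkaNeg <- .PKA_NEG
  first <- chars[1]; last <- chars[length(chars)]
  if (first %in% names(.PKA_NTERM)) pkaPos["Nterm"] <- .PKA_NTERM[[first]]
  if (last %in% names(.PKA_CTERM)) pkaNeg["Cterm"] <- .PKA_CTERM[[last]]
  lo <- 0; hi <- 14
  for (i in 1:60) {
    mid <- (lo + hi) / 2
    if (.netCharge(counts, mid, pkaPos, pkaNeg) > 0) lo <- mid else hi <- mid
  }
  (lo + hi) / 2
}

#' Six global physicochemical parameters
#'
#' The ProtParam-style summary used as global features: theoretical pI,
#' counts of negatively (D+E) and positively (R+K) charged residues, the
#' Guruprasad instability index (10/L times the summed dipeptide
#' instability weights), the Ikai aliphatic index
#' (X_Ala + 2.9 X_Val + 3.9 (X_Ile + X_Leu), mole percent) and GRAVY
#' (mean Kyte-Doolittle hydropathy).
#'
#' @inheritParams groupAAC
#' @return Named length-6 numeric vector: pI, n_negative, n_positive,
#'   instability_index, aliphatic_index, gravy.
#' @export
globalPhyschem <- function(sequence) {
  chars <- strsplit(toupper(as.character(sequence)[1]), "")[[1]]
  L <- length(chars)
  if (L < 2L) stop("instability index undefined for L < 2")
  if (!all(chars %in% STANDARD_AA))
    stop("sequence contains non-standard residues")
  diwv <- .diwv()
  inst <- 10 / L * sum(diwv[cbind(chars[-L], chars[-1])])
  molePct <- 100 * table(factor(chars, levels = STANDARD_AA)) / L
  c(pI = isoelectricPoint(sequence),
    n_negative = sum(chars %in% c("D", "E")),
    n_positive = sum(chars %in% c("R", "K")),
    instability_index = inst,
    aliphatic_index = unname(molePct["A"] + 2.9 * molePct["V"] +
                               3.9 * (molePct["I"] + molePct["L"])),
    gravy = mean(.KD[chars]))
}

#' Auto-covariance encoding of physicochemical properties
#'
#' For property j and lag lambda, AC(j, lambda) = (1/(L - lambda)) *
#' sum_{i=1}^{L-lambda} (P_i^j - mean_j)(P_{i+lambda}^j - mean_j), with
#' mean_j the sequence mean of the property. Captures the average
#' interaction between residues lambda positions apart. Each property is
#' standardized to zero mean / unit variance over the 20 residues first
#' (the centering in the definition removes location but not scale;
#' without standardization a large-ranged property would dominate), which
#' can be disabled.
#'
#' @inheritParams groupAAC
#' @param table 20 x 7 property matrix (default [propertyTable()]).
#' @param lambdaMax maximum lag (default 10); requires L > lambdaMax.
#' @param standardize standardize properties across the 20 residues first.
#' @return Named length-(7 * lambdaMax) vector, property-major then lag
#'   ("ac_<property>_<lambda>").
#' @export
acEncode <- function(sequence, table = propertyTable(), lambdaMax = 10L,
                     standardize = TRUE) {
  chars <- strsplit(toupper(as.character(sequence)[1]), "")[[1]]
  L <- length(chars)
  id <- if (!is.null(names(sequence))) names(sequence)[1] else "<sequence>"
  if (L <= lambdaMax)
    stop("sequence ", id, " has length ", L,
         " <= lambdaMax = ", lambdaMax)
  if (standardize) table <- scale(table)
  out <- numeric(0)
  for (j in colnames(table)) {
    P <- table[chars, j]
    Pc <- P - mean(P)
    for (lam in seq_len(lambdaMax)) {
      idx <- seq_len(L - lam)
      out <- c(out, sum(Pc[idx] * Pc[idx + lam]) / (L - lam))
    }
  }
  names(out) <- paste0("ac_", rep(colnames(table), each = lambdaMax), "_",
                       rep(seq_len(lambdaMax), times = ncol(table)))
  out
}
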