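#' @include io-fasta.R assemble.R
NULL

# Functional-group probability profile of the positive class at full
# signal: mass shifted toward hydroxyl / amido / non-polar groups, the
# groups whose composition separates AFPs in the reduced-alphabet space.
.SHIFT_PROFILE <- c(phenyl = 0.02, carboxyl = 0.02, imidazole = 0.01,
                    primary_amine = 0.01, guanidino = 0.01, thiol = 0.01,
                    sulfur = 0.02, amido = 0.20, hydroxyl = 0.25,
                    non_polar = 0.45)

.residueProbs <- function(signal) {
  groups <- functionalGroups()
  base <- lengths(groups) / 20          # uniform over the 20 residues
  p <- (1 - signal) * base + signal * .SHIFT_PROFILE[names(groups)]
  unlist(lapply(names(groups), function(g)
    setNames(rep(p[[g]] / length(groups[[g]]), length(groups[[g]])),
             groups[[g]])))
}

#' Generate labeled synthetic protein sequences
#'
#' Residues are drawn per position from class-specific functional-group
#' frequency profiles: the negative class is uniform over the 20 standard
#' residues, and the positive class shifts probability mass toward the
#' hydroxyl, amido and non-polar groups by an amount proportional to
#' `signal` (signal = 0 makes the classes identically distributed). The
#' reduced-alphabet composition features are therefore the natural
#' detectors of the class signal. Lengths are uniform over `lengthRange`;
#' everything is deterministic under `seed`.
#'
#' @param nPos,nNeg class sizes.
#' @param lengthRange integer range of sequence lengths (default 50-300,
#'   so all sequences pass [filterDataset()]).
#' @param signal class separation in [0, 1].
#' @param seed RNG seed.
#' @return Labeled AAStringSet (ids "pos_i" / "neg_i", positives first).
#' @export
generateSequences <- function(nPos, nNeg, lengthRange = c(50L, 300L),
                              signal = 0.5, seed = 1L) {
  if (lengthRange[1] > lengthRange[2] || lengthRange[1] < 1L)
    stop("invalid length range")
  if (signal < 0 || signal > 1) stop("signal must be in [0, 1]")
  pPos <- .residueProbs(signal)
  pNeg <- .residueProbs(0)
  withSeed(seed, {
    lens <- sample(seq(lengthRange[1], lengthRange[2]), nPos + nNeg,
                   replace = TRUE)
    seqs <- vapply(seq_len(nPos + nNeg), function(i) {
      p <- if (i <= nPos) pPos else pNeg
      paste(sample(names(p), lens[i], replace = TRUE, prob = p),
            collapse = "")
    }, character(1))
  })
  ids <- c(if (nPos) paste0("pos_", seq_len(nPos)),
           if (nNeg) paste0("neg_", seq_len(nNeg)))
  proteinSet(seqs, ids = ids,
             labels = rep(c(1L, 0L), c(nPos, nNeg)))
}

#' Generate a synthetic PSSM profile
#'
#' Integer noise uniform on [-4, 4] per cell, plus a class-dependent bias
#' of round(3 * classSignal) on the columns belonging to the functional
#' group of the row's residue, so group-reduced PSSM features carry the
#' class signal.
#'
#' @param record one named sequence (e.g. `records[i]`).
#' @param classSignal bias strength in [0, 1]; pass 0 for negatives.
#' @param seed RNG seed.
#' @return A [PSSMProfile-class] with integer scores.
#' @export
generatePSSM <- function(record, classSignal = 0, seed = 1L) {
  chars <- strsplit(as.character(record)[1], "")[[1]]
  L <- length(chars)
  map <- residueGroupMap()
  withSeed(seed, {
    sc <- matrix(sample(-4:4, L * 20, replace = TRUE), L, 20)
  })
  bias <- round(3 * classSignal)
  if (bias != 0) {
    colGroup <- map[AA_ORDER]
    for (i in seq_len(L))
      sc[i, colGroup == map[chars[i]]] <-
        sc[i, colGroup == map[chars[i]]] + bias
  }
  PSSMProfile(names(record)[1] %||% "synthetic", sc)
}

#' Generate a synthetic disorder profile
#'
#' Smoothed noise: a window-5 moving average of uniform(0, 1) draws, which
#' stays in [0, 1] and has the short-range autocorrelation of real
#' disorder tracks.
#'
#' @inheritParams generatePSSM
#' @return A [DisorderProfile-class].
#' @export
generateDisorder <- function(record, seed = 1L) {
  L <- nchar(as.character(record)[1])
  withSeed(seed, {
    u <- runif(L + 4L)
  })
  s <- vapply(seq_len(L), function(i) mean(u[i:(i + 4L)]), numeric(1))
  DisorderProfile(names(record)[1] %||% "synthetic", s)
}

#' Generate synthetic domain annotations
#'
#' Each panel entry is assigned to a positive protein with probability
#' `enrichment` and to a negative with the lower probability `negRate`.
#'
#' @param records labeled AAStringSet.
#' @param panel InterPro IDs to draw from.
#' @param enrichment per-entry presence probability for positives.
#' @param negRate per-entry presence probability for negatives.
#' @param seed RNG seed.
#' @return Named list of [DomainAnnotation-class], one per record.
#' @export
generateDomains <- function(records, panel = defaultDomainPanel(),
                            enrichment = 0.6, negRate = 0.02, seed = 1L) {
  lab <- proteinLabels(records)
  if (is.null(lab)) stop("records must be labeled")
  anns <- withSeed(seed, {
    lapply(seq_along(records), function(i) {
      p <- if (lab[i] == 1L) enrichment else negRate
      DomainAnnotation(names(records)[i], panel[runif(length(panel)) < p])
    })
  })
  names(anns) <- names(records)
  anns
}

#' Generate a complete synthetic input bundle
#'
#' Sequences plus matched PSSMs, disorder profiles and domain annotations,
#' all deterministic under `seed` — everything needed to exercise the full
#' five-family pipeline.
#'
#' @inheritParams generateSequences
#' @param enrichment,negRate passed to [generateDomains()].
#' @return list(records, pssms, disorder, domains).
#' @export
generateBundle <- function(nPos, nNeg, lengthRange = c(50L, 120L),
                           signal = 0.5, enrichment = 0.6, negRate = 0.02,
                           seed = 1L) {
  records <- generateSequences(nPos, nNeg, lengthRange, signal, seed)
  lab <- proteinLabels(records)
  pssms <- lapply(seq_along(records), function(i)
    generatePSSM(records[i], classSignal = if (lab[i] == 1L) signal else 0,
                 seed = deriveSeed(seed, i)))
  names(pssms) <- names(records)
  disorder <- lapply(seq_along(records), function(i)
    generateDisorder(records[i], seed = deriveSeed(seed, 100000 + i)))
  names(disorder) <- names(records)
  domains <- generateDomains(records, enrichment = enrichment,
                             negRate = negRate,
                             seed = deriveSeed(seed, 200000))
  list(records = records, pssms = pssms, disorder = disorder,
       domains = domains)
}
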