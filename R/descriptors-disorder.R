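#' @include AllClasses.R
NULL

#' Disorder descriptor block (28 features)
#'
#' Summarizes a per-residue disorder profile as: mean and (population)
#' standard deviation of all scores; number of disorder and non-disorder
#' segments; minimum/maximum lengths of disorder and non-disorder
#' segments; and the average disorder score of each of the 20 residue
#' types. A residue is called disordered when its score >= `threshold`
#' (VSL2's decision boundary 0.5 by default); a segment is a maximal run
#' of same-call residues. When a segment class is absent its min and max
#' are 0; a residue type absent from the sequence gets average score 0
#' (a sentinel, flagged here rather than NA so feature matrices stay
#' complete).
#'
#' @inheritParams groupAAC
#' @param profile a [DisorderProfile-class] of matching length.
#' @param threshold disorder call threshold in (0, 1).
#' @return Named length-28 numeric vector ("dis_<name>").
#' @export
disorderFeatures <- function(sequence, profile, threshold = 0.5) {
  chars <- strsplit(toupper(as.character(sequence)[1]), "")[[1]]
  s <- disorderScores(profile)
  L <- length(chars)
  if (length(s) != L)
    stop("disorder profile length ", length(s),
         " does not match sequence length ", L,
         " (", proteinIds(profile), ")")
  if (!(threshold > 0 && threshold < 1)) stop("threshold must be in (0,1)")

  call <- s >= threshold
  runs <- rle(call)
  disLen <- runs$lengths[runs$values]
  nonLen <- runs$lengths[!runs$values]
  segStats <- function(x) if (length(x)) c(min(x), max(x)) else c(0, 0)

  perAA <- vapply(STANDARD_AA, function(a) {
    idx <- chars == a
    if (any(idx)) mean(s[idx]) else 0
  }, numeric(1))

  out <- c(mean(s),
           sqrt(mean((s - mean(s))^2)),  # population SD
           length(disLen), length(nonLen),
           segStats(disLen), segStats(nonLen),
           perAA)
  names(out) <- c("dis_mean", "dis_sd",
                  "dis_n_disorder_segments", "dis_n_nondisorder_segments",
                  "dis_min_dis_len", "dis_max_dis_len",
                  "dis_min_nondis_len", "dis_max_nondis_len",
                  paste0("dis_avg_", STANDARD_AA))
  out
}
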