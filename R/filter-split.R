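#' @include io-fasta.R
NULL

#' Quality-filter a protein dataset
#'
#' Removes sequences shorter than `minLength` residues (their information
#' content is too low for the descriptor set) and sequences containing the
#' ambiguous letters B, J, O, U, X or Z (or any other character outside the
#' 20 standard amino acids). When a sequence fails both checks the
#' too-short reason is reported.
#'
#' @param x AAStringSet (see [proteinSet()]).
#' @param minLength minimum retained length (default 50).
#' @param forbidden characters that disqualify a sequence.
#' @return list(kept = AAStringSet, rejected = data.frame(id, reason)) with
#'   reason one of "too_short", "nonstandard_residue". Filtering is total
#'   and idempotent.
#' @export
filterDataset <- function(x, minLength = 50L,
                          forbidden = NONSTANDARD_AA) {
  seqs <- as.character(x)
  L <- nchar(seqs)
  badPattern <- paste0("[^", paste(STANDARD_AA, collapse = ""), "]")
  nonstd <- grepl(badPattern, seqs) |
    grepl(paste0("[", paste(forbidden, collapse = ""), "]"), seqs)
  tooShort <- L < minLength
  reason <- ifelse(tooShort, "too_short",
                   ifelse(nonstd, "nonstandard_residue", NA_character_))
  keep <- is.na(reason)
  rejected <- data.frame(id = names(x)[!keep],
                         reason = reason[!keep],
                         stringsAsFactors = FALSE)
  list(kept = x[keep], rejected = rejected)
}

#' Per-class hold-out split
#'
#' Draws, independently within each class, round-half-up(testFraction x
#' class size) records into the test set; the remainder form the training
#' set. With the published class totals 464/9083 and fraction 0.2 this
#' yields a 93/1817 test set and a 371/7266 training set.
#'
#' @param x labeled AAStringSet (every record must carry a 0/1 label).
#' @param testFraction fraction per class placed in the test set.
#' @param seed RNG seed; the same seed reproduces the same partition.
#' @return list(train = AAStringSet, test = AAStringSet).
#' @export
splitHoldout <- function(x, testFraction = 0.2, seed) {
  lab <- proteinLabels(x)
  if (is.null(lab)) stop("splitHoldout needs labeled records")
  if (!(testFraction > 0 && testFraction < 1))
    stop("testFraction must be in (0, 1)")
  testIdx <- integer(0)
  withSeed(seed, {
    for (cl in c(0L, 1L)) {
      idx <- which(lab == cl)
      if (length(idx) < 2L)
        stop("class ", cl, " has fewer than 2 members")
      nTest <- roundHalfUp(testFraction * length(idx))
      testIdx <- c(testIdx, sample(idx, nTest))
    }
  })
  testIdx <- sort(testIdx)
  list(train = x[-testIdx], test = x[testIdx])
}
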