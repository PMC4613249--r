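#' @include alphabet.R
NULL

.groupIndex <- function(sequence) {
  chars <- strsplit(as.character(sequence)[1], "")[[1]]
  map <- residueGroupMap()
  g <- map[chars]
  if (anyNA(g))
    stop("sequence contains non-standard residues: ",
         paste(unique(chars[is.na(g)]), collapse = ", "))
  factor(g, levels = names(functionalGroups()))
}

#' Functional-group amino-acid composition (10 features)
#'
#' f(g_i) = N(g_i) / L over the ten functional groups, where N(g_i) counts
#' residues of group g_i and L is the sequence length. Entries sum to 1.
#'
#' @param sequence one amino-acid sequence (character or AAStringSet
#'   element).
#' @return Named length-10 numeric vector ("aac_<group>").
#' @examples
#' groupAAC("DE")  # carboxyl = 1, everything else 0
#' @export
groupAAC <- function(sequence) {
  g <- .groupIndex(sequence)
  if (!length(g)) stop("empty sequence")
  v <- as.numeric(table(g)) / length(g)
  names(v) <- paste0("aac_", names(functionalGroups()))
  v
}

#' Functional-group dipeptide composition (100 features)
#'
#' f(g_i g_j) = N(g_i g_j) / (L - 1) over the 10 x 10 ordered group pairs,
#' counting the L - 1 overlapping dipeptides. Ordering is row-major in the
#' fixed group order; entries sum to 1.
#'
#' @inheritParams groupAAC
#' @return Named length-100 numeric vector ("dpc_<g_i>_<g_j>").
#' @export
groupDPC <- function(sequence) {
  g <- .groupIndex(sequence)
  L <- length(g)
  if (L < 2L) stop("dipeptide composition needs L >= 2")
  gn <- names(functionalGroups())
  counts <- table(factor(g[-L], levels = gn), factor(g[-1], levels = gn))
  v <- as.numeric(t(counts)) / (L - 1)  # row-major over (g_i, g_j)
  # t() because as.numeric reads column-major; we want g_i outer, g_j inner
  names(v) <- paste0("dpc_", rep(gn, each = 10), "_", rep(gn, times = 10))
  v
}
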