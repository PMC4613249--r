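#' The ten-functional-group reduced amino-acid alphabet
#'
#' Side-chain chemistry partitions the 20 standard residues into ten
#' functional groups: phenyl (F/W/Y), carboxyl (D/E), imidazole (H),
#' primary amine (K), guanidino (R), thiol (C), sulfur (M), amido (Q/N),
#' hydroxyl (S/T) and non-polar (A/G/I/L/V/P). Functional groups positioned
#' to match the ice lattice are implicated in ice binding, which motivates
#' composing sequences over this reduced alphabet rather than the raw one.
#'
#' @return A named list of ten character vectors, one per group, in the
#'   fixed order used by every group-indexed feature block.
#' @examples
#' names(functionalGroups())
#' @export
functionalGroups <- function() {
  list(
    phenyl        = c("F", "W", "Y"),
    carboxyl      = c("D", "E"),
    imidazole     = "H",
    primary_amine = "K",
    guanidino     = "R",
    thiol         = "C",
    sulfur        = "M",
    amido         = c("Q", "N"),
    hydroxyl      = c("S", "T"),
    non_polar     = c("A", "G", "I", "L", "V", "P")
  )
}

# PSI-BLAST's native amino-acid column order; used for PSSMs and all
# per-residue tables.
AA_ORDER <- strsplit("ARNDCQEGHILKMFPSTWYV", "")[[1]]

# residue -> group name lookup (named character vector over the 20 residues)
residueGroupMap <- function() {
  groups <- functionalGroups()
  map <- character(0)
  for (g in names(groups)) {
    m <- rep(g, length(groups[[g]]))
    names(m) <- groups[[g]]
    map <- c(map, m)
  }
  map[AA_ORDER]
}

STANDARD_AA <- AA_ORDER
NONSTANDARD_AA <- c("B", "J", "O", "U", "X", "Z")
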