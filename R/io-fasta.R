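#' @include AllGenerics.R
NULL

#' Construct a labeled protein set
#'
#' Protein datasets are held as a [Biostrings::AAStringSet] whose names are
#' unique protein IDs; optional 0/1 class labels (1 = AFP) live in
#' `mcols(x)$label`. All descriptor and dataset functions take this form.
#'
#' @param sequences character vector of amino-acid sequences or an
#'   AAStringSet.
#' @param ids protein identifiers (defaults to existing names).
#' @param labels optional 0/1 vector (or logical), one per sequence.
#' @return An AAStringSet with names and (if given) `mcols()$label`.
#' @examples
#' ps <- proteinSet(c(p1 = "MKTAYIAK", p2 = "GGGGSSSS"), labels = c(1, 0))
#' @export
proteinSet <- function(sequences, ids = names(sequences), labels = NULL) {
  x <- Biostrings::AAStringSet(sequences)
  if (is.null(ids)) stop("protein IDs are required")
  if (anyDuplicated(ids))
    stop("duplicate protein IDs: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  names(x) <- ids
  if (!is.null(labels)) {
    labels <- as.integer(labels)
    if (length(labels) != length(x) || !all(labels %in% c(0L, 1L)))
      stop("labels must be 0/1, one per sequence")
    S4Vectors::mcols(x)$label <- labels
  }
  x
}

#' Labels stored on a protein set
#' @param x an AAStringSet built by [proteinSet()] or [readFasta()].
#' @return integer 0/1 vector or NULL.
#' @export
proteinLabels <- function(x) {
  mc <- S4Vectors::mcols(x)
  if (!is.null(mc) && "label" %in% colnames(mc)) as.integer(mc$label) else NULL
}

#' Read protein sequences from a FASTA file
#'
#' Sequences are uppercased and a trailing stop character (`*`) is
#' stripped. IDs are the first whitespace-delimited token of each header;
#' duplicated IDs are an error because later annotation joins need unique
#' keys.
#'
#' @param path FASTA file.
#' @return An AAStringSet in file order (empty, with a warning, for an
#'   empty file).
#' @export
readFasta <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path, warn = FALSE)
  nonblank <- which(nzchar(trimws(lines)))
  if (!length(nonblank)) {
    warning("empty FASTA file: ", path)
    return(proteinSet(character(0), ids = character(0)))
  }
  if (!startsWith(trimws(lines[nonblank[1]]), ">"))
    stop("malformed FASTA at line ", nonblank[1],
         ": expected a '>' header, got: ", lines[nonblank[1]])
  x <- Biostrings::readAAStringSet(path)
  seqs <- toupper(as.character(x))
  seqs <- sub("\\*+$", "", seqs)
  ids <- vapply(strsplit(names(x), "\\s+"), `[`, character(1), 1L)
  proteinSet(seqs, ids = ids)
}

#' Write a protein set to FASTA
#' @param x AAStringSet with names.
#' @param path output file (written atomically).
#' @param width line-wrap width.
#' @export
writeFasta <- function(x, path, width = 70L) {
  lines <- character(0)
  seqs <- as.character(x)
  for (i in seq_along(seqs)) {
    s <- seqs[[i]]
    chunks <- substring(s, seq(1, nchar(s), width),
                        pmin(seq(1, nchar(s), width) + width - 1L, nchar(s)))
    lines <- c(lines, paste0(">", names(seqs)[i]), chunks)
  }
  writeLinesAtomic(lines, path)
}
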