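#' @include AllClasses.R
NULL

# Regex for a PSI-BLAST ASCII PSSM data row: position, residue letter, then
# at least 20 numeric fields (the log-odds block; the trailing percentage
# and information columns are ignored).
.pssmRowPattern <- "^\\s*[0-9]+\\s+[A-Z]\\s+(-?[0-9.]+\\s+){19}-?[0-9.]+"

#' Read a PSSM file
#'
#' Accepts either the PSI-BLAST `-out_ascii_pssm` dialect (header lines,
#' one row per residue with position, residue and 20 log-odds columns, of
#' which only the first 20 score columns are read) or, auto-detected, a
#' bare whitespace-delimited L x 20 numeric matrix with no header. Columns
#' follow PSI-BLAST's native order "ARNDCQEGHILKMFPSTWYV".
#'
#' @param path PSSM file.
#' @param record optional named length-1 character (or AAStringSet element)
#'   giving the associated sequence; when supplied, the residue column of
#'   an ASCII PSSM is cross-checked against it and the row count must
#'   match.
#' @param proteinId identifier for the profile; defaults to the record
#'   name or the file name without extension.
#' @return A [PSSMProfile-class].
#' @export
readPSSM <- function(path, record = NULL, proteinId = NULL) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path, warn = FALSE)
  dataIdx <- grep(.pssmRowPattern, lines)

  seqChars <- NULL
  if (!is.null(record)) {
    seqChars <- strsplit(toupper(as.character(record)[1]), "")[[1]]
    if (is.null(proteinId) && !is.null(names(record)))
      proteinId <- names(record)[1]
  }
  if (is.null(proteinId))
    proteinId <- sub("\\.[^.]*$", "", basename(path))

  if (length(dataIdx)) {
    rows <- lines[dataIdx]
    toks <- strsplit(trimws(rows), "\\s+")
    pos <- vapply(toks, function(t) suppressWarnings(as.integer(t[1])), 1L)
    res <- vapply(toks, `[`, character(1), 2L)
    if (any(is.na(pos)) || !identical(pos, seq_along(pos)))
      stop("truncated or disordered PSSM file: positions are not 1..L in ", path)
    scores <- t(vapply(toks, function(t) {
      v <- suppressWarnings(as.numeric(t[3:22]))
      if (anyNA(v)) stop("malformed numeric field in PSSM row of ", path)
      v
    }, numeric(20)))
    if (!is.null(seqChars)) {
      if (length(seqChars) != length(res))
        stop("PSSM has ", length(res), " rows but sequence has ",
             length(seqChars), " residues (", proteinId, ")")
      bad <- which(res != seqChars)
      if (length(bad))
        stop("PSSM residue column disagrees with sequence at position ",
             bad[1], " (", res[bad[1]], " vs ", seqChars[bad[1]], ")")
    }
    return(PSSMProfile(proteinId, scores))
  }

  # bare L x 20 matrix fallback
  nonblank <- lines[nzchar(trimws(lines))]
  if (!length(nonblank)) stop("empty PSSM file: ", path)
  toks <- strsplit(trimws(nonblank), "\\s+")
  nf <- lengths(toks)
  if (!all(nf == 20L))
    stop("cannot parse PSSM file ", path,
         ": neither PSI-BLAST ASCII rows nor a bare L x 20 matrix")
  scores <- t(vapply(toks, function(t) {
    v <- suppressWarnings(as.numeric(t))
    if (anyNA(v)) stop("malformed numeric field in PSSM matrix of ", path)
    v
  }, numeric(20)))
  if (!is.null(seqChars) && nrow(scores) != length(seqChars))
    stop("PSSM has ", nrow(scores), " rows but sequence has ",
         length(seqChars), " residues (", proteinId, ")")
  PSSMProfile(proteinId, scores)
}

#' Write a PSSMProfile in PSI-BLAST ASCII form
#'
#' Emits the header comment, the 20-letter column header and one data row
#' per position, so the result round-trips through [readPSSM()].
#'
#' @param profile a [PSSMProfile-class].
#' @param sequence optional residue sequence used for the residue column;
#'   defaults to "X"-free placeholder "A".
#' @param path output file.
#' @export
writePSSM <- function(profile, path, sequence = NULL) {
  sc <- pssmScores(profile)
  res <- if (!is.null(sequence)) strsplit(toupper(as.character(sequence)[1]), "")[[1]]
         else rep("A", nrow(sc))
  if (length(res) != nrow(sc))
    stop("sequence length does not match PSSM row count")
  header <- c("", "Last position-specific scoring matrix computed",
              paste0("           ", paste(sprintf("%3s", profile@alphabet),
                                          collapse = " ")))
  rows <- vapply(seq_len(nrow(sc)), function(i) {
    paste0(sprintf("%5d %s ", i, res[i]),
           paste(sprintf("%3d", as.integer(round(sc[i, ]))), collapse = " "))
  }, character(1))
  writeLinesAtomic(c(header, rows), path)
}
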