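#' @include AllClasses.R
NULL

.readTSV <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  read.delim(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE,
             check.names = FALSE)
}

.checkNumeric <- function(x, what, path) {
  v <- suppressWarnings(as.numeric(x))
  if (anyNA(v) && !anyNA(x))
    stop("malformed numeric ", what, " in ", path)
  if (anyNA(v)) stop("missing ", what, " values in ", path)
  v
}

#' Read per-residue disorder scores
#'
#' Two dialects are accepted: a two-column table `position<TAB>score` for a
#' single protein (supply `proteinId`), or a three-column table
#' `protein_id<TAB>position<TAB>score` holding several proteins. Scores
#' outside [0, 1] are an error; rows for IDs not in `ids` (when given) are
#' skipped with a warning.
#'
#' @param path TSV file with a header row.
#' @param proteinId ID to assign when the file is the two-column dialect.
#' @param ids optional character vector of known protein IDs.
#' @return A named list of [DisorderProfile-class] objects.
#' @export
readDisorder <- function(path, proteinId = NULL, ids = NULL) {
  tab <- .readTSV(path)
  if (ncol(tab) == 2L) {
    if (is.null(proteinId))
      stop("two-column disorder file needs an explicit proteinId")
    tab <- data.frame(protein_id = proteinId, tab, check.names = FALSE)
  }
  if (ncol(tab) != 3L)
    stop("disorder table must have 2 or 3 columns, got ", ncol(tab))
  names(tab) <- c("protein_id", "position", "score")
  tab$position <- .checkNumeric(tab$position, "position", path)
  tab$score <- .checkNumeric(tab$score, "score", path)
  if (any(tab$score < 0 | tab$score > 1))
    stop("disorder scores outside [0, 1] in ", path)
  if (!is.null(ids)) {
    unknown <- setdiff(unique(tab$protein_id), ids)
    if (length(unknown)) {
      warning("skipping disorder rows for unknown protein IDs: ",
              paste(unknown, collapse = ", "))
      tab <- tab[tab$protein_id %in% ids, , drop = FALSE]
    }
  }
  out <- lapply(split(tab, tab$protein_id), function(d) {
    d <- d[order(d$position), , drop = FALSE]
    if (!identical(as.integer(d$position), seq_len(nrow(d))))
      stop("disorder positions for ", d$protein_id[1],
           " are not contiguous 1..L in ", path)
    DisorderProfile(d$protein_id[1], d$score)
  })
  out[unique(tab$protein_id)]
}

#' Write disorder profiles as a three-column TSV
#' @param profiles list of [DisorderProfile-class].
#' @param path output file.
#' @export
writeDisorder <- function(profiles, path) {
  lines <- "protein_id\tposition\tscore"
  for (p in profiles) {
    s <- disorderScores(p)
    lines <- c(lines, sprintf("%s\t%d\t%s", proteinIds(p), seq_along(s),
                              formatC(s, digits = 17, format = "g")))
  }
  writeLinesAtomic(lines, path)
}

#' Read InterPro domain annotations
#'
#' Two-column TSV `protein_id<TAB>interpro_id`; duplicate (id, entry) pairs
#' collapse to set semantics. With `ids` given, unknown IDs are skipped
#' with a warning and proteins without any row get an empty annotation.
#'
#' @param path TSV file with a header row.
#' @param ids optional character vector of known protein IDs.
#' @return A named list of [DomainAnnotation-class] objects.
#' @export
readDomains <- function(path, ids = NULL) {
  tab <- .readTSV(path)
  if (ncol(tab) != 2L)
    stop("domain table must have 2 columns, got ", ncol(tab))
  names(tab) <- c("protein_id", "entry")
  if (!is.null(ids)) {
    unknown <- setdiff(unique(tab$protein_id), ids)
    if (length(unknown)) {
      warning("skipping domain rows for unknown protein IDs: ",
              paste(unknown, collapse = ", "))
      tab <- tab[tab$protein_id %in% ids, , drop = FALSE]
    }
  }
  out <- lapply(split(tab$entry, tab$protein_id),
                function(e) unique(as.character(e)))
  allIds <- if (is.null(ids)) names(out) else ids
  anns <- lapply(allIds, function(id)
    DomainAnnotation(id, out[[id]] %||% character(0)))
  names(anns) <- allIds
  anns
}

#' Write domain annotations as a two-column TSV
#' @param annotations list of [DomainAnnotation-class].
#' @param path output file.
#' @export
writeDomains <- function(annotations, path) {
  lines <- "protein_id\tinterpro_id"
  for (a in annotations) {
    e <- domainEntries(a)
    if (length(e))
      lines <- c(lines, paste(proteinIds(a), e, sep = "\t"))
  }
  writeLinesAtomic(lines, path)
}

#' Read class labels
#'
#' Two-column TSV `protein_id<TAB>label` with labels 0/1.
#'
#' @param path TSV file with a header row.
#' @return Named integer vector of 0/1 labels.
#' @export
readLabels <- function(path) {
  tab <- .readTSV(path)
  if (ncol(tab) != 2L) stop("label table must have 2 columns")
  lab <- suppressWarnings(as.integer(tab[[2]]))
  if (anyNA(lab) || !all(lab %in% c(0L, 1L)))
    stop("labels must be 0 or 1 in ", path)
  names(lab) <- as.character(tab[[1]])
  if (anyDuplicated(names(lab))) stop("duplicate protein IDs in ", path)
  lab
}

#' Write / read a feature matrix as CSV
#'
#' The CSV has an `id` column, one column per feature and, when the matrix
#' is labeled, a trailing `label` column. Values are written with 17
#' significant digits so the matrix round-trips losslessly.
#'
#' @param x a [FeatureMatrix-class].
#' @param path CSV file.
#' @return `readFeatureMatrix` returns a [FeatureMatrix-class].
#' @export
writeFeatureMatrix <- function(x, path) {
  v <- featureValues(x)
  lab <- classLabels(x)
  header <- paste(c("id", colnames(v), if (!is.null(lab)) "label"),
                  collapse = ",")
  body <- vapply(seq_len(nrow(v)), function(i) {
    paste(c(rownames(v)[i],
            formatC(v[i, ], digits = 17, format = "g"),
            if (!is.null(lab)) lab[i]), collapse = ",")
  }, character(1))
  writeLinesAtomic(c(header, body), path)
}

#' @rdname writeFeatureMatrix
#' @export
readFeatureMatrix <- function(path) {
  tab <- read.csv(path, header = TRUE, check.names = FALSE,
                  stringsAsFactors = FALSE)
  if (names(tab)[1] != "id") stop("feature CSV must start with an id column")
  hasLab <- names(tab)[ncol(tab)] == "label"
  featCols <- setdiff(seq_along(tab)[-1],
                      if (hasLab) ncol(tab) else integer(0))
  v <- as.matrix(tab[, featCols, drop = FALSE])
  if (!is.numeric(v)) stop("non-numeric feature values in ", path)
  rownames(v) <- as.character(tab$id)
  FeatureMatrix(v, if (hasLab) as.integer(tab$label) else integer(0))
}
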