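#' @include AllClasses.R
NULL

#' Default InterPro domain panel (15 entries)
#'
#' The fifteen InterPro entries observed in at least ten training AFPs,
#' in rank order; used as the binary domain feature block so prediction
#' works without re-deriving a panel. [derivePanel()] rebuilds a panel
#' from new annotations.
#'
#' @return Character vector of 15 InterPro IDs.
#' @export
defaultDomainPanel <- function() {
  c("IPR001304", "IPR016186", "IPR016187", "IPR018378", "IPR013032",
    "IPR000742", "IPR000436", "IPR000538", "IPR007110", "IPR013783",
    "IPR000152", "IPR001881", "IPR003599", "IPR018097", "IPR013106")
}

#' Binary domain indicator features
#'
#' vector[k] = 1 iff panel entry k is present in the protein's annotation
#' set; off-panel entries are ignored and a missing annotation is the
#' empty set.
#'
#' @param annotation a [DomainAnnotation-class] or NULL.
#' @param panel ordered character vector of InterPro IDs.
#' @return Named binary vector ("dom_<IPR id>").
#' @export
domainFeatures <- function(annotation, panel = defaultDomainPanel()) {
  entries <- if (is.null(annotation)) character(0)
             else domainEntries(annotation)
  v <- as.numeric(panel %in% entries)
  names(v) <- paste0("dom_", panel)
  v
}

#' Derive a domain panel from labeled annotations
#'
#' Collects entries that occur in at least `minCount` positive-labeled
#' proteins, ordered by descending positive count, ties by lexicographic
#' ID.
#'
#' @param annotations named list of [DomainAnnotation-class].
#' @param labels named 0/1 vector (1 = AFP) covering the annotation IDs.
#' @param minCount minimum number of positives an entry must occur in.
#' @return Character vector (possibly empty, with a warning).
#' @export
derivePanel <- function(annotations, labels, minCount = 10L) {
  if (minCount < 1L) stop("minCount must be >= 1")
  posIds <- names(labels)[labels == 1L]
  entries <- unlist(lapply(annotations[names(annotations) %in% posIds],
                           domainEntries), use.names = FALSE)
  if (!length(entries)) {
    warning("no qualifying InterPro entries; empty panel")
    return(character(0))
  }
  counts <- sort(table(entries), decreasing = TRUE)
  counts <- counts[counts >= minCount]
  if (!length(counts)) {
    warning("no qualifying InterPro entries; empty panel")
    return(character(0))
  }
  ord <- order(-as.numeric(counts), names(counts))
  names(counts)[ord]
}
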