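#' @include descriptors-composition.R descriptors-physchem.R descriptors-disorder.R descriptors-domain.R descriptors-pssm.R
NULL

#' Assemble the hybrid feature matrix
#'
#' Concatenates the five descriptor families in fixed block order —
#' composition (10 AAC + 100 DPC), physicochemical (6 global + 70
#' auto-covariance), disorder (28), domain (15), PSSM (100) — giving the
#' full 329-dimensional hybrid vector per protein when all families are
#' enabled. Families may be disabled; annotations required by an enabled
#' family must be present for every record (no silent imputation).
#'
#' @param records AAStringSet (labels, if present, are carried into the
#'   result).
#' @param pssms named list of [PSSMProfile-class] keyed by protein ID
#'   (required when the pssm family is enabled).
#' @param disorderProfiles named list of [DisorderProfile-class]
#'   (required when the disorder family is enabled).
#' @param domainAnnotations named list of [DomainAnnotation-class];
#'   proteins absent from the list get the empty annotation.
#' @param families character subset of
#'   c("composition", "physchem", "disorder", "domain", "pssm").
#' @param panel domain panel (default [defaultDomainPanel()]).
#' @param propertyTab property matrix for the AC block.
#' @param lambdaMax AC maximum lag.
#' @param disorderThreshold disorder call threshold.
#' @return A [FeatureMatrix-class], rows in input record order.
#' @export
assembleFeatures <- function(records, pssms = NULL, disorderProfiles = NULL,
                             domainAnnotations = NULL,
                             families = c("composition", "physchem",
                                          "disorder", "domain", "pssm"),
                             panel = defaultDomainPanel(),
                             propertyTab = propertyTable(),
                             lambdaMax = 10L, disorderThreshold = 0.5) {
  families <- match.arg(families, several.ok = TRUE)
  ids <- names(records)
  if (is.null(ids)) stop("records must be named")

  needAnn <- function(ann, family) {
    missing <- setdiff(ids, names(ann))
    if (length(missing))
      stop("missing ", family, " annotation for: ",
           paste(missing, collapse = ", "))
  }
  if ("pssm" %in% families) {
    if (is.null(pssms)) stop("pssm family enabled but no PSSM profiles given")
    needAnn(pssms, "PSSM")
  }
  if ("disorder" %in% families) {
    if (is.null(disorderProfiles))
      stop("disorder family enabled but no disorder profiles given")
    needAnn(disorderProfiles, "disorder")
  }

  seqs <- as.character(records)
  rows <- lapply(ids, function(id) {
    s <- seqs[[id]]
    names(s) <- id
    v <- numeric(0)
    if ("composition" %in% families)
      v <- c(v, groupAAC(s), groupDPC(s))
    if ("physchem" %in% families)
      v <- c(v, globalPhyschem(s),
             acEncode(s, table = propertyTab, lambdaMax = lambdaMax))
    if ("disorder" %in% families)
      v <- c(v, disorderFeatures(s, disorderProfiles[[id]],
                                 threshold = disorderThreshold))
    if ("domain" %in% families)
      v <- c(v, domainFeatures(domainAnnotations[[id]], panel = panel))
    if ("pssm" %in% families)
      v <- c(v, pssmGroupFeatures(s, pssms[[id]]))
    v
  })
  m <- do.call(rbind, rows)
  rownames(m) <- ids
  lab <- proteinLabels(records)
  FeatureMatrix(m, lab %||% integer(0))
}
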