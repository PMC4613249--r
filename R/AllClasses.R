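#' @include utils.R alphabet.R
NULL

#' Position-specific scoring matrix for one protein
#'
#' Holds the L x 20 PSI-BLAST log-odds matrix for a protein of length L.
#' Rows are residue positions; columns follow the declared amino-acid order
#' (PSI-BLAST's native "ARNDCQEGHILKMFPSTWYV" by default) and that order is
#' recorded in the object so downstream encoders never guess it.
#'
#' @slot proteinId character(1) identifier matching the sequence record.
#' @slot scores numeric L x 20 matrix of substitution scores.
#' @slot alphabet character(20) column order of `scores`.
#' @exportClass PSSMProfile
setClass("PSSMProfile",
  representation(proteinId = "character", scores = "matrix",
                 alphabet = "character"),
  prototype(alphabet = AA_ORDER)
)

setValidity("PSSMProfile", function(object) {
  msg <- NULL
  if (length(object@proteinId) != 1L) msg <- c(msg, "proteinId must be a single string")
  if (ncol(object@scores) != 20L) msg <- c(msg, "scores must have 20 columns")
  if (length(object@alphabet) != 20L || anyDuplicated(object@alphabet))
    msg <- c(msg, "alphabet must be 20 distinct residues")
  if (!is.numeric(object@scores)) msg <- c(msg, "scores must be numeric")
  if (anyNA(object@scores)) msg <- c(msg, "scores must not contain NA")
  if (is.null(msg)) TRUE else msg
})

#' Per-residue intrinsic disorder profile
#'
#' A vector of per-residue disorder scores in [0, 1] (VSL2-style output),
#' one score per position of the associated sequence.
#'
#' @slot proteinId character(1) identifier.
#' @slot scores numeric vector of length L, each value in [0, 1].
#' @exportClass DisorderProfile
setClass("DisorderProfile",
  representation(proteinId = "character", scores = "numeric")
)

setValidity("DisorderProfile", function(object) {
  msg <- NULL
  if (length(object@proteinId) != 1L) msg <- c(msg, "proteinId must be a single string")
  if (anyNA(object@scores)) msg <- c(msg, "scores must not contain NA")
  else if (length(object@scores) &&
           (min(object@scores) < 0 || max(object@scores) > 1))
    msg <- c(msg, "disorder scores must lie in [0, 1]")
  if (is.null(msg)) TRUE else msg
})

#' InterPro domain annotation for one protein
#'
#' The set of InterPro entry identifiers ("IPR" + 6 digits) assigned to a
#' protein; may be empty. Stored with set semantics (duplicates collapsed).
#'
#' @slot proteinId character(1) identifier.
#' @slot entries character vector of syntactically valid InterPro IDs.
#' @exportClass DomainAnnotation
setClass("DomainAnnotation",
  representation(proteinId = "character", entries = "character")
)

setValidity("DomainAnnotation", function(object) {
  msg <- NULL
  if (length(object@proteinId) != 1L) msg <- c(msg, "proteinId must be a single string")
  if (length(object@entries)) {
    bad <- !grepl("^IPR[0-9]{6}$", object@entries)
    if (any(bad))
      msg <- c(msg, paste0("malformed InterPro IDs: ",
                           paste(object@entries[bad], collapse = ", ")))
    if (anyDuplicated(object@entries))
      msg <- c(msg, "entries must be a set (no duplicates)")
  }
  if (is.null(msg)) TRUE else msg
})

#' Sample-by-feature matrix with labels
#'
#' The numeric design matrix produced by feature assembly: one row per
#' protein, one named column per feature, plus an optional binary class
#' label per row (1 = AFP, 0 = non-AFP). Row order follows input record
#' order; column names are unique and stable, which prediction relies on.
#'
#' @slot values numeric n x d matrix with rownames = protein IDs and
#'   colnames = feature names.
#' @slot labels integer vector of 0/1 labels (length n) or length 0 when
#'   unlabeled.
#' @exportClass FeatureMatrix
setClass("FeatureMatrix",
  representation(values = "matrix", labels = "integer")
)

setValidity("FeatureMatrix", function(object) {
  msg <- NULL
  v <- object@values
  if (!is.numeric(v)) msg <- c(msg, "values must be numeric")
  if (anyNA(v)) msg <- c(msg, "values must not contain missing entries")
  if (is.null(colnames(v)) || anyDuplicated(colnames(v)))
    msg <- c(msg, "feature names must be present and unique")
  if (is.null(rownames(v)) || anyDuplicated(rownames(v)))
    msg <- c(msg, "protein IDs (rownames) must be present and unique")
  if (length(object@labels) &&
      (length(object@labels) != nrow(v) ||
       !all(object@labels %in% c(0L, 1L))))
    msg <- c(msg, "labels must be 0/1 and match the number of rows")
  if (is.null(msg)) TRUE else msg
})

#' Undersampling random-forest ensemble model
#'
#' G base classifiers, each trained on all positives plus one of G disjoint
#' undersampled negative groups, combined at prediction time by majority
#' vote. The training column order is stored and enforced at prediction.
#'
#' @slot members list of G fitted base learners.
#' @slot featureNames character vector: training column order.
#' @slot config list with elements G, numTrees, seed (and any base-learner
#'   extras).
#' @exportClass EnsembleModel
setClass("EnsembleModel",
  representation(members = "list", featureNames = "character",
                 config = "list")
)

setValidity("EnsembleModel", function(object) {
  msg <- NULL
  G <- object@config$G
  if (is.null(G) || length(object@members) != G)
    msg <- c(msg, "config$G must equal the number of members")
  if (!length(object@featureNames))
    msg <- c(msg, "featureNames must be non-empty")
  if (is.null(msg)) TRUE else msg
})

# ---- constructors ----------------------------------------------------------

#' @rdname PSSMProfile-class
#' @param proteinId protein identifier.
#' @param scores L x 20 numeric matrix.
#' @param alphabet column order (default PSI-BLAST native order).
#' @export
PSSMProfile <- function(proteinId, scores, alphabet = AA_ORDER) {
  scores <- as.matrix(scores)
  dimnames(scores) <- list(NULL, alphabet)
  new("PSSMProfile", proteinId = as.character(proteinId),
      scores = scores, alphabet = alphabet)
}

#' @rdname DisorderProfile-class
#' @param proteinId protein identifier.
#' @param scores numeric vector in [0, 1].
#' @export
DisorderProfile <- function(proteinId, scores) {
  new("DisorderProfile", proteinId = as.character(proteinId),
      scores = as.numeric(scores))
}

#' @rdname DomainAnnotation-class
#' @param proteinId protein identifier.
#' @param entries character vector of InterPro IDs (duplicates collapsed).
#' @export
DomainAnnotation <- function(proteinId, entries = character(0)) {
  new("DomainAnnotation", proteinId = as.character(proteinId),
      entries = sort(unique(as.character(entries))))
}

#' @rdname FeatureMatrix-class
#' @param values numeric matrix (rownames = IDs, colnames = feature names).
#' @param labels optional 0/1 vector, one per row.
#' @export
FeatureMatrix <- function(values, labels = integer(0)) {
  new("FeatureMatrix", values = as.matrix(values),
      labels = as.integer(labels))
}

# ---- show methods ----------------------------------------------------------

setMethod("show", "PSSMProfile", function(object) {
  cat("PSSMProfile for", object@proteinId, "—", nrow(object@scores),
      "positions x 20 residues\n")
})

setMethod("show", "DisorderProfile", function(object) {
  cat("DisorderProfile for", object@proteinId, "—", length(object@scores),
      "residues, mean score", round(mean(object@scores), 3), "\n")
})

setMethod("show", "DomainAnnotation", function(object) {
  cat("DomainAnnotation for", object@proteinId, "—",
      length(object@entries), "InterPro entries\n")
})

setMethod("show", "FeatureMatrix", function(object) {
  cat("FeatureMatrix:", nrow(object@values), "proteins x",
      ncol(object@values), "features",
      if (length(object@labels)) sprintf("(%d positive)", sum(object@labels))
      else "(unlabeled)", "\n")
})

setMethod("show", "EnsembleModel", function(object) {
  cat("EnsembleModel: G =", object@config$G, "base learners,",
      length(object@featureNames), "features,", object@config$numTrees,
      "trees each\n")
})
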