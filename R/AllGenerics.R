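#' @include AllClasses.R
NULL

#' Accessors for afpred S4 classes
#'
#' `proteinIds()` returns the identifier(s) carried by an object;
#' `featureNames()` and `featureValues()` expose a FeatureMatrix's column
#' names and numeric matrix; `classLabels()` returns the 0/1 label vector
#' (or NULL when unlabeled); `pssmScores()` and `disorderScores()` return
#' the underlying numeric data; `domainEntries()` the InterPro ID set.
#'
#' @param x an afpred S4 object.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("proteinIds", function(x) standardGeneric("proteinIds"))
#' @rdname accessors
#' @export
setGeneric("featureNames", function(x) standardGeneric("featureNames"))
#' @rdname accessors
#' @export
setGeneric("featureValues", function(x) standardGeneric("featureValues"))
#' @rdname accessors
#' @export
setGeneric("classLabels", function(x) standardGeneric("classLabels"))
#' @rdname accessors
#' @export
setGeneric("pssmScores", function(x) standardGeneric("pssmScores"))
#' @rdname accessors
#' @export
setGeneric("disorderScores", function(x) standardGeneric("disorderScores"))
#' @rdname accessors
#' @export
setGeneric("domainEntries", function(x) standardGeneric("domainEntries"))

#' @rdname accessors
setMethod("proteinIds", "PSSMProfile", function(x) x@proteinId)
#' @rdname accessors
setMethod("proteinIds", "DisorderProfile", function(x) x@proteinId)
#' @rdname accessors
setMethod("proteinIds", "DomainAnnotation", function(x) x@proteinId)
#' @rdname accessors
setMethod("proteinIds", "FeatureMatrix", function(x) rownames(x@values))

#' @rdname accessors
setMethod("featureNames", "FeatureMatrix", function(x) colnames(x@values))
#' @rdname accessors
setMethod("featureNames", "EnsembleModel", function(x) x@featureNames)
#' @rdname accessors
setMethod("featureValues", "FeatureMatrix", function(x) x@values)
#' @rdname accessors
setMethod("classLabels", "FeatureMatrix",
          function(x) if (length(x@labels)) x@labels else NULL)
#' @rdname accessors
setMethod("pssmScores", "PSSMProfile", function(x) x@scores)
#' @rdname accessors
setMethod("disorderScores", "DisorderProfile", function(x) x@scores)
#' @rdname accessors
setMethod("domainEntries", "DomainAnnotation", function(x) x@entries)

#' Subset or relabel a FeatureMatrix
#'
#' `[` subsets rows (proteins) and columns (features) keeping labels in
#' step with rows.
#'
#' @param x a FeatureMatrix.
#' @param i,j row / column indices.
#' @param drop ignored; dimensions are always kept.
#' @param ... unused.
#' @export
setMethod("[", "FeatureMatrix", function(x, i, j, ..., drop = FALSE) {
  v <- x@values
  if (missing(i)) i <- seq_len(nrow(v))
  if (missing(j)) j <- seq_len(ncol(v))
  lab <- if (length(x@labels)) x@labels[i] else integer(0)
  FeatureMatrix(v[i, j, drop = FALSE], lab)
})

#' @rdname accessors
#' @export
setGeneric("nSamples", function(x) standardGeneric("nSamples"))
#' @rdname accessors
setMethod("nSamples", "FeatureMatrix", function(x) nrow(x@values))
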