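#' @include evaluation.R ensemble.R
NULL

#' ANOVA F ranking of features
#'
#' For each feature, the two-group (AFP vs non-AFP) one-way ANOVA F
#' statistic F = MSB/MSW with MSB = SSB/(k-1), MSW = SSW/(N-k),
#' SSB = sum_i n_i (mean_i - grand mean)^2 and SSW the pooled within-group
#' sum of squares. Larger F means the feature separates the classes more
#' strongly. Features are ranked by F descending, ties broken by ascending
#' original index; a feature constant within each group but differing
#' between groups (SSW = 0, SSB > 0) gets F = Inf and ranks first, and
#' F = 0 when SSB = SSW = 0.
#'
#' @param X labeled [FeatureMatrix-class]; each class needs >= 2 members.
#' @return data.frame (one row per feature, in ranked order) with columns
#'   index, name, F, MSB, MSW, SSB, SSW, dfB, dfW.
#' @export
anovaRank <- function(X) {
  lab <- classLabels(X)
  if (is.null(lab)) stop("anovaRank needs a labeled matrix")
  v <- featureValues(X)
  groups <- split(seq_along(lab), lab)
  k <- length(groups)
  if (k < 2L) stop("need two groups")
  ni <- lengths(groups)
  if (any(ni < 2L)) stop("each group needs at least 2 observations")
  N <- length(lab)

  grand <- colMeans(v)
  SSB <- numeric(ncol(v)); SSW <- numeric(ncol(v))
  for (g in groups) {
    m <- colMeans(v[g, , drop = FALSE])
    SSB <- SSB + length(g) * (m - grand)^2
    SSW <- SSW + colSums((v[g, , drop = FALSE] -
                            matrix(m, length(g), ncol(v), byrow = TRUE))^2)
  }
  dfB <- k - 1L; dfW <- N - k
  MSB <- SSB / dfB; MSW <- SSW / dfW
  F <- ifelse(SSW > 0, MSB / MSW, ifelse(SSB > 0, Inf, 0))

  res <- data.frame(index = seq_len(ncol(v)), name = colnames(v),
                    F = F, MSB = MSB, MSW = MSW, SSB = SSB, SSW = SSW,
                    dfB = dfB, dfW = dfW, stringsAsFactors = FALSE)
  res[order(-res$F, res$index), , drop = FALSE]
}

#' Incremental feature selection over an ANOVA ranking
#'
#' Walks the ranked list from the top, evaluating nested prefixes
#' S_i = {f_1, ..., f_i} with the full undersampling-ensemble pipeline
#' under stratified K-fold cross-validation, and returns the smallest
#' prefix attaining the maximum balanced accuracy. A stride > 1 evaluates
#' every stride-th prefix (plus the full set) without changing the metric
#' any evaluated prefix reports.
#'
#' @param X labeled [FeatureMatrix-class].
#' @param ranking data.frame from [anovaRank()] (or any permutation with
#'   an `index` column covering all features).
#' @param config ensemble configuration used for every prefix.
#' @param cvFolds folds (default 10; must not exceed the smaller class).
#' @param cvSeed RNG seed for the fold partition and per-prefix training.
#' @param stride evaluate every stride-th prefix.
#' @return list of class "afpredIFS": rankedIndices, prefixSizes,
#'   prefixMetrics (data.frame size, Sn, Sp, Acc, BAcc), optimalSize,
#'   optimalIndices.
#' @export
incrementalSelection <- function(X, ranking, config = ensembleConfig(),
                                 cvFolds = 10L, cvSeed = 1L, stride = 1L) {
  lab <- classLabels(X)
  if (is.null(lab)) stop("incrementalSelection needs a labeled matrix")
  if (min(table(lab)) < cvFolds)
    stop("cvFolds exceeds the smallest class size")
  idx <- ranking$index
  if (!setequal(idx, seq_len(ncol(featureValues(X)))))
    stop("ranking must cover every feature exactly once")

  sizes <- unique(c(seq(1L, length(idx), by = stride), length(idx)))
  rows <- lapply(sizes, function(i) {
    cv <- crossValidate(X[, idx[seq_len(i)]], config = config,
                        K = cvFolds, seed = cvSeed)
    p <- cv$pooled
    data.frame(size = i, Sn = p$Sn, Sp = p$Sp, Acc = p$Acc, BAcc = p$BAcc)
  })
  metrics <- do.call(rbind, rows)
  best <- metrics$size[which.max(metrics$BAcc)]  # first max = smallest prefix
  structure(list(rankedIndices = idx, prefixSizes = sizes,
                 prefixMetrics = metrics, optimalSize = best,
                 optimalIndices = idx[seq_len(best)]),
            class = "afpredIFS")
}

#' @export
print.afpredIFS <- function(x, ...) {
  cat("Incremental feature selection over", length(x$rankedIndices),
      "ranked features\n")
  cat("Evaluated", nrow(x$prefixMetrics), "prefixes; optimal size",
      x$optimalSize, "with BAcc",
      round(max(x$prefixMetrics$BAcc), 4), "\n")
  invisible(x)
}
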