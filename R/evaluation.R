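#' @include AllClasses.R
NULL

#' Confusion-matrix metrics
#'
#' Sn = TP/(TP+FN), Sp = TN/(TN+FP), Acc = (TP+TN)/total and
#' BAcc = (Sn+Sp)/2 from paired 0/1 truth/prediction vectors. Under class
#' imbalance Acc is dominated by the majority class, so BAcc is the
#' headline measure. If a class is absent the corresponding rate (and
#' BAcc) is NA and `defined` is FALSE — never a silent zero.
#'
#' @param yTrue,yPred equal-length 0/1 vectors.
#' @return list(TP, FP, TN, FN, Sn, Sp, Acc, BAcc, defined).
#' @export
computeMetrics <- function(yTrue, yPred) {
  yTrue <- as.integer(yTrue); yPred <- as.integer(yPred)
  if (length(yTrue) != length(yPred))
    stop("yTrue and yPred must have equal length")
  if (!all(c(yTrue, yPred) %in% c(0L, 1L)))
    stop("labels must be 0/1")
  TP <- sum(yTrue == 1L & yPred == 1L)
  FN <- sum(yTrue == 1L & yPred == 0L)
  TN <- sum(yTrue == 0L & yPred == 0L)
  FP <- sum(yTrue == 0L & yPred == 1L)
  Sn <- if (TP + FN > 0) TP / (TP + FN) else NA_real_
  Sp <- if (TN + FP > 0) TN / (TN + FP) else NA_real_
  list(TP = TP, FP = FP, TN = TN, FN = FN,
       Sn = Sn, Sp = Sp,
       Acc = (TP + TN) / length(yTrue),
       BAcc = if (is.na(Sn) || is.na(Sp)) NA_real_ else (Sn + Sp) / 2,
       defined = !is.na(Sn) && !is.na(Sp))
}

#' Balanced accuracy from sensitivity and specificity
#' @param sn,sp rates in [0, 1].
#' @return (sn + sp) / 2.
#' @export
balancedAccuracy <- function(sn, sp) (sn + sp) / 2

#' Class-stratified K-fold partition
#'
#' Shuffles each class independently and splits it into K near-equal
#' subsets (sizes differing by at most 1); fold k's test set is subset k
#' of each class, so folds are disjoint, exhaustive and preserve the class
#' ratio.
#'
#' @param labels 0/1 vector.
#' @param K number of folds.
#' @param seed RNG seed.
#' @return List of K lists with integer `train` / `test` index vectors.
#' @export
stratifiedKFold <- function(labels, K = 10L, seed) {
  labels <- as.integer(labels)
  folds <- vector("list", K)
  testSets <- replicate(K, integer(0), simplify = FALSE)
  withSeed(seed, {
    for (cl in unique(labels)) {
      idx <- which(labels == cl)
      if (length(idx) < K)
        stop("class ", cl, " has ", length(idx), " members < K = ", K)
      idx <- sample(idx)
      sizes <- rep(length(idx) %/% K, K)
      extra <- length(idx) %% K
      if (extra) sizes[seq_len(extra)] <- sizes[seq_len(extra)] + 1L
      stops <- cumsum(sizes)
      starts <- c(1L, head(stops, -1L) + 1L)
      for (k in seq_len(K))
        testSets[[k]] <- c(testSets[[k]], idx[starts[k]:stops[k]])
    }
  })
  all <- seq_along(labels)
  for (k in seq_len(K))
    folds[[k]] <- list(train = setdiff(all, testSets[[k]]),
                       test = sort(testSets[[k]]))
  folds
}

#' Cross-validated evaluation of the undersampling ensemble
#'
#' Stratified K-fold cross-validation of the full pipeline: inside every
#' fold the negative undersampling is re-drawn and a fresh ensemble is
#' trained, then the held-out fold is predicted. Per-fold predictions are
#' pooled into a single confusion matrix (micro average) for the headline
#' metrics; per-fold reports are retained for inspection because fold-level
#' sensitivity is noisy when positives are few.
#'
#' @param X labeled [FeatureMatrix-class].
#' @param config ensemble configuration from [ensembleConfig()].
#' @param K folds (default 10).
#' @param seed RNG seed driving both the partition and per-fold training.
#' @return list(pooled = metrics list, perFold = list of per-fold metrics).
#' @export
crossValidate <- function(X, config = ensembleConfig(), K = 10L, seed) {
  lab <- classLabels(X)
  if (is.null(lab)) stop("crossValidate needs a labeled matrix")
  folds <- stratifiedKFold(lab, K = K, seed = seed)
  yTrue <- integer(0); yPred <- integer(0)
  perFold <- vector("list", K)
  for (k in seq_len(K)) {
    f <- folds[[k]]
    cfg <- config
    cfg$seed <- deriveSeed(seed, k)
    model <- trainEnsemble(X[f$train, ], cfg)
    pred <- predictEnsemble(model, X[f$test, ])
    yTrue <- c(yTrue, lab[f$test])
    yPred <- c(yPred, pred$labels)
    perFold[[k]] <- computeMetrics(lab[f$test], pred$labels)
  }
  list(pooled = computeMetrics(yTrue, yPred), perFold = perFold)
}
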