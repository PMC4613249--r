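#' @include AllClasses.R evaluation.R
NULL

#' Ensemble configuration
#'
#' G is the ratio of sampled negatives to positives and equally the number
#' of undersampled training subsets / base learners; odd values make vote
#' ties impossible. The base learner is a seeded random forest (ranger);
#' any object with `fit(x, y)` returning something `predict(model, x)`-able
#' to 0/1 labels may be plugged in through `fitFun` / `predictFun`.
#'
#' @param G negatives-to-positives sampling ratio and ensemble size
#'   (default 9; validated against {1, 3, 5, 7, 9, 11, 13, 15} unless
#'   `allowAnyG`).
#' @param numTrees trees per random forest (default 100).
#' @param mtry features tried per split; default floor(sqrt(d)) at fit
#'   time.
#' @param seed master RNG seed for sampling and member training.
#' @param allowAnyG permit G values outside the default validation set
#'   (even G breaks vote ties toward the negative, majority-prior class).
#' @param fitFun,predictFun optional pluggable base learner: `fitFun(x, y,
#'   seed)` with y a 0/1 factor, and `predictFun(fit, x)` returning 0/1.
#' @return list of class "afpredEnsembleConfig".
#' @export
ensembleConfig <- function(G = 9L, numTrees = 100L, mtry = NULL, seed = 1L,
                           allowAnyG = FALSE, fitFun = NULL,
                           predictFun = NULL) {
  G <- as.integer(G)
  if (!allowAnyG && !(G %in% c(1L, 3L, 5L, 7L, 9L, 11L, 13L, 15L)))
    stop("G must be one of 1,3,5,7,9,11,13,15 (or set allowAnyG = TRUE)")
  structure(list(G = G, numTrees = as.integer(numTrees), mtry = mtry,
                 seed = as.integer(seed), fitFun = fitFun,
                 predictFun = predictFun),
            class = "afpredEnsembleConfig")
}

.defaultFit <- function(x, y, seed, numTrees, mtry) {
  d <- data.frame(x, check.names = FALSE)
  d$.y <- factor(y, levels = c(0L, 1L))
  ranger::ranger(dependent.variable.name = ".y", data = d,
                 num.trees = numTrees,
                 mtry = mtry %||% max(1L, floor(sqrt(ncol(x)))),
                 seed = seed, num.threads = 1L,
                 respect.unordered.factors = TRUE)
}

.defaultPredict <- function(fit, x) {
  # fixed seed: ranger breaks tree-vote ties randomly, and prediction must
  # be a pure function of (model, data)
  p <- predict(fit, data.frame(x, check.names = FALSE), num.threads = 1L,
               seed = 42L)
  as.integer(as.character(p$predictions))
}

#' Undersampled training subsets
#'
#' Samples exactly G x P negatives without replacement (P = number of
#' positives), partitions them into G disjoint groups of P, and pairs each
#' group with all P positives, giving G balanced subsets of 2P rows.
#'
#' @param X labeled [FeatureMatrix-class].
#' @param G number of subsets.
#' @param seed RNG seed.
#' @return List of G [FeatureMatrix-class] objects.
#' @export
buildSubsets <- function(X, G, seed) {
  lab <- classLabels(X)
  if (is.null(lab)) stop("buildSubsets needs a labeled matrix")
  pos <- which(lab == 1L); neg <- which(lab == 0L)
  P <- length(pos)
  if (P < 1L) stop("no positive samples")
  if (length(neg) < G * P)
    stop("only ", length(neg), " negatives but G x P = ", G * P,
         "; use a smaller G")
  withSeed(seed, {
    sampled <- sample(neg, G * P)
  })
  groups <- split(sampled, rep(seq_len(G), each = P))
  lapply(groups, function(g) X[c(pos, g), ])
}

#' Train the undersampling random-forest ensemble
#'
#' Builds G balanced subsets via [buildSubsets()] and fits one base
#' learner per subset; member k is seeded deterministically from
#' (config$seed, k) so a config + seed fully reproduces the model.
#'
#' @param X labeled [FeatureMatrix-class] containing both classes.
#' @param config from [ensembleConfig()].
#' @return An [EnsembleModel-class].
#' @export
trainEnsemble <- function(X, config = ensembleConfig()) {
  lab <- classLabels(X)
  if (is.null(lab) || length(unique(lab)) < 2L)
    stop("training matrix must contain both classes")
  subsets <- buildSubsets(X, config$G, config$seed)
  fitFun <- config$fitFun
  members <- lapply(seq_along(subsets), function(k) {
    s <- subsets[[k]]
    memberSeed <- deriveSeed(config$seed, k)
    if (is.null(fitFun))
      .defaultFit(featureValues(s), classLabels(s), memberSeed,
                  config$numTrees, config$mtry)
    else fitFun(featureValues(s), classLabels(s), memberSeed)
  })
  new("EnsembleModel", members = members,
      featureNames = featureNames(X), config = unclass(config))
}

#' Majority-vote prediction
#'
#' Each of the G members votes; an instance is labeled positive iff its
#' positive votes exceed G/2. With odd G ties cannot occur; with even G
#' (opt-in) a tie votes negative, the majority-prior class. The feature
#' columns of `X` must match the training columns exactly.
#'
#' @param model an [EnsembleModel-class].
#' @param X a [FeatureMatrix-class].
#' @return list(labels = 0/1 vector, votes = integer vector in [0, G]).
#' @export
predictEnsemble <- function(model, X) {
  fn <- featureNames(X)
  if (!identical(fn, model@featureNames)) {
    mism <- which(fn[seq_len(min(length(fn), length(model@featureNames)))] !=
                  model@featureNames[seq_len(min(length(fn),
                                                 length(model@featureNames)))])
    detail <- if (length(mism))
      paste0("first mismatched column: ", fn[mism[1]], " vs ",
             model@featureNames[mism[1]])
    else "column sets differ in length"
    stop("feature columns do not match training columns (", detail, ")")
  }
  predictFun <- model@config$predictFun
  memberPreds <- lapply(model@members, function(m) {
    if (is.null(predictFun)) .defaultPredict(m, featureValues(X))
    else predictFun(m, featureValues(X))
  })
  votes <- rowSums(matrix(as.numeric(unlist(memberPreds)),
                          nrow = nrow(featureValues(X))))
  G <- model@config$G
  if (G %% 2L == 1L) stopifnot(all(votes != G / 2))
  list(labels = as.integer(votes > G / 2), votes = as.integer(votes))
}

#' Save / load an ensemble model archive
#'
#' The archive stores members, config, feature names and a format version
#' in a single RDS file.
#'
#' @param model an [EnsembleModel-class].
#' @param path archive file.
#' @export
saveEnsemble <- function(model, path) {
  obj <- list(format = "afpred-ensemble-1", members = model@members,
              featureNames = model@featureNames, config = model@config)
  tmp <- tempfile(tmpdir = dirname(path))
  saveRDS(obj, tmp)
  file.rename(tmp, path)
  invisible(path)
}

#' @rdname saveEnsemble
#' @export
loadEnsemble <- function(path) {
  obj <- readRDS(path)
  if (!identical(obj$format, "afpred-ensemble-1"))
    stop("not an afpred ensemble archive: ", path)
  new("EnsembleModel", members = obj$members,
      featureNames = obj$featureNames, config = obj$config)
}
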