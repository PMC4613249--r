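#' @include synthetic.R feature-selection.R
NULL

.composeMatrix <- function(records, families = "composition") {
  assembleFeatures(records, families = families)
}

.singleRF <- function(train, test, seed, numTrees = 100L) {
  fit <- .defaultFit(featureValues(train), classLabels(train), seed,
                     numTrees, NULL)
  .defaultPredict(fit, featureValues(test))
}

.metricsRow <- function(rep, condition, m) {
  data.frame(replicate = rep, condition = condition,
             Sn = m$Sn, Sp = m$Sp, Acc = m$Acc, BAcc = m$BAcc)
}

.summarize <- function(detail) {
  agg <- lapply(split(detail, detail$condition), function(d) {
    data.frame(condition = d$condition[1],
               Sn_mean = mean(d$Sn), Sn_sd = sd(d$Sn),
               Sp_mean = mean(d$Sp), Sp_sd = sd(d$Sp),
               Acc_mean = mean(d$Acc), Acc_sd = sd(d$Acc),
               BAcc_mean = mean(d$BAcc), BAcc_sd = sd(d$BAcc))
  })
  out <- do.call(rbind, agg[unique(as.character(detail$condition))])
  rownames(out) <- NULL
  attr(out, "replicates") <- detail
  out
}

#' Simulation experiments on synthetic data
#'
#' Reproduces, on the synthetic generator, the qualitative designs used to
#' study the method: \describe{
#'   \item{imbalance_sweep}{train a single random forest on 1:1 ... 1:8
#'     positive:negative training sets (no ensemble) and evaluate on a
#'     balanced held-out set; specificity rises and sensitivity falls with
#'     the ratio.}
#'   \item{ensemble_vs_none}{at ratio 1:9, compare the G = 9 undersampling
#'     ensemble against one forest trained on the full imbalanced set.}
#'   \item{g_sweep}{cross-condition comparison of the ensemble for several
#'     G values.}
#'   \item{size_sweep}{train on 10%...80% of a fixed 1:9 pool; balanced
#'     accuracy grows with training-set size.}
#' }
#' Every condition is replicated with derived seeds; features default to
#' the composition family only, which carries the generator's signal and
#' keeps the dimension small.
#'
#' @param name experiment name.
#' @param params list overriding defaults: nPos (40), signal (0.6),
#'   lengthRange (c(50, 150)), replicates (10), nTest (60 per class),
#'   numTrees (100), families ("composition"), Gs (c(3, 5, 7, 9)),
#'   ratios (1:8), fractions (seq(0.1, 0.8, 0.1)), G (9).
#' @param seed master seed.
#' @return data.frame of per-condition replicate means and SDs of Sn, Sp,
#'   Acc and BAcc, with the per-replicate table in attr(, "replicates").
#' @export
runExperiment <- function(name = c("imbalance_sweep", "ensemble_vs_none",
                                   "g_sweep", "size_sweep"),
                          params = list(), seed = 1L) {
  name <- tryCatch(match.arg(name),
                   error = function(e)
                     stop("unknown experiment; valid names: ",
                          "imbalance_sweep, ensemble_vs_none, g_sweep, ",
                          "size_sweep"))
  p <- modifyList(list(nPos = 40L, signal = 0.6, lengthRange = c(50L, 150L),
                       replicates = 10L, nTest = 60L, numTrees = 100L,
                       families = "composition", Gs = c(3L, 5L, 7L, 9L),
                       ratios = 1:8, fractions = seq(0.1, 0.8, by = 0.1),
                       G = 9L), params)

  genXY <- function(nPos, nNeg, s) {
    recs <- generateSequences(nPos, nNeg, p$lengthRange, p$signal, s)
    .composeMatrix(recs, p$families)
  }

  detail <- switch(name,
    imbalance_sweep = {
      rows <- list()
      for (r in seq_len(p$replicates)) {
        pool <- genXY(p$nPos, max(p$ratios) * p$nPos, deriveSeed(seed, r))
        test <- genXY(p$nTest, p$nTest, deriveSeed(seed, 5000 + r))
        lab <- classLabels(pool)
        negIdx <- which(lab == 0L)
        for (ratio in p$ratios) {
          train <- pool[c(which(lab == 1L),
                          negIdx[seq_len(ratio * p$nPos)]), ]
          pred <- .singleRF(train, test, deriveSeed(seed, 37 * r + ratio),
                            p$numTrees)
          rows[[length(rows) + 1L]] <-
            .metricsRow(r, paste0("1:", ratio),
                        computeMetrics(classLabels(test), pred))
        }
      }
      do.call(rbind, rows)
    },
    ensemble_vs_none = {
      rows <- list()
      for (r in seq_len(p$replicates)) {
        train <- genXY(p$nPos, p$G * p$nPos, deriveSeed(seed, r))
        test <- genXY(p$nTest, p$nTest, deriveSeed(seed, 5000 + r))
        predNone <- .singleRF(train, test, deriveSeed(seed, 11 * r),
                              p$numTrees)
        model <- trainEnsemble(train,
                               ensembleConfig(G = p$G, numTrees = p$numTrees,
                                              seed = deriveSeed(seed, 13 * r)))
        predEns <- predictEnsemble(model, test)$labels
        rows[[length(rows) + 1L]] <-
          .metricsRow(r, "without_ensemble",
                      computeMetrics(classLabels(test), predNone))
        rows[[length(rows) + 1L]] <-
          .metricsRow(r, "with_ensemble",
                      computeMetrics(classLabels(test), predEns))
      }
      do.call(rbind, rows)
    },
    g_sweep = {
      rows <- list()
      for (r in seq_len(p$replicates)) {
        train <- genXY(p$nPos, max(p$Gs) * p$nPos, deriveSeed(seed, r))
        test <- genXY(p$nTest, p$nTest, deriveSeed(seed, 5000 + r))
        for (G in p$Gs) {
          model <- trainEnsemble(train,
                                 ensembleConfig(G = G, numTrees = p$numTrees,
                                                seed = deriveSeed(seed,
                                                                  17 * r + G)))
          pred <- predictEnsemble(model, test)$labels
          rows[[length(rows) + 1L]] <-
            .metricsRow(r, paste0("G=", G),
                        computeMetrics(classLabels(test), pred))
        }
      }
      do.call(rbind, rows)
    },
    size_sweep = {
      poolPos <- p$nPos * 2L
      poolNeg <- p$G * poolPos
      rows <- list()
      for (r in seq_len(p$replicates)) {
        pool <- genXY(poolPos, poolNeg, deriveSeed(seed, r))
        test <- genXY(p$nTest, p$nTest, deriveSeed(seed, 5000 + r))
        lab <- classLabels(pool)
        for (f in p$fractions) {
          nP <- max(2L, roundHalfUp(f * poolPos))
          nN <- p$G * nP
          train <- pool[c(which(lab == 1L)[seq_len(nP)],
                          which(lab == 0L)[seq_len(nN)]), ]
          model <- trainEnsemble(train,
                                 ensembleConfig(G = p$G, numTrees = p$numTrees,
                                                seed = deriveSeed(seed,
                                                                  23 * r + round(100 * f))))
          pred <- predictEnsemble(model, test)$labels
          rows[[length(rows) + 1L]] <-
            .metricsRow(r, sprintf("%d%%", round(100 * f)),
                        computeMetrics(classLabels(test), pred))
        }
      }
      do.call(rbind, rows)
    })
  .summarize(detail)
}
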