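## BestH selection: grid search over holdout rates on a single inner split
## of the training set.

#' The standard holdout-rate grid
#'
#' Eleven rates from 0.10 to 0.60 in steps of 0.05.
#'
#' @return Numeric vector of holdout rates.
#' @export
defaultHGrid <- function() seq(0.10, 0.60, by = 0.05)

#' Select BestH by grid search on an inner split
#'
#' The training rows are split once (seed-fixed) into an inner training set
#' (`Train_Blending`, 80%) and an inner evaluation set (`training_test`,
#' 20%). For each candidate rate H a blending ensemble is fitted on the
#' inner training set with the requested strategy and scored by Pearson
#' accuracy on the inner evaluation set. BestH is the rate attaining the
#' highest inner accuracy; ties break toward the smallest H. A rate whose
#' predictions are constant (undefined correlation) scores `-Inf` with a
#' warning.
#'
#' @param G a [GenotypeMatrix-class].
#' @param y a [PhenotypeVector-class] or numeric vector aligned to `G`.
#' @param trainIdx integer indices of the outer training rows.
#' @param strategy `"random"`, `"CA"` or `"PP"`.
#' @param K number of strata for CA/PP.
#' @param grid candidate holdout rates in (0, 1); default [defaultHGrid()].
#' @param seed integer seed; fixes both the inner split and every per-H fit.
#' @param innerFraction fraction of the training rows held out as the inner
#'   evaluation set (default 0.2).
#' @return A [TuneResult-class].
#' @export
optimizeH <- function(G, y, trainIdx = seq_len(nSamples(G)),
                      strategy = c("random", "CA", "PP"), K = 8L,
                      grid = defaultHGrid(), seed = 1L,
                      innerFraction = 0.2) {
  strategy <- match.arg(strategy)
  if (length(grid) == 0L) stop("grid must be non-empty", call. = FALSE)
  grid <- sort(unique(as.numeric(grid)))
  if (any(grid <= 0 | grid >= 1)) stop("grid rates must be in (0, 1)", call. = FALSE)
  v <- if (is(y, "PhenotypeVector")) y@values else as.numeric(y)
  trainIdx <- as.integer(trainIdx)
  innerSeed <- .deriveSeed(seed, 11L)
  sp <- outerSplit(length(trainIdx), testFraction = innerFraction,
                   seed = innerSeed)
  innerTrain <- trainIdx[sp@trainIdx]
  innerTest <- trainIdx[sp@testIdx]
  acc <- vapply(grid, function(H) {
    ens <- fitBlending(G, v, trainIdx = innerTrain,
                       config = blendConfig(H = H, strategy = strategy,
                                            K = K, seed = seed))
    pred <- .predictRows(ens, G, innerTest)
    if (stats::sd(pred) < 1e-12 || stats::sd(v[innerTest]) < 1e-12) {
      warning(sprintf("undefined inner accuracy at H = %g (constant predictions)", H))
      -Inf
    } else {
      stats::cor(pred, v[innerTest])
    }
  }, numeric(1))
  if (all(!is.finite(acc)))
    stop("inner accuracy undefined for every grid rate", call. = FALSE)
  best <- grid[which.max(acc)]  # first maximum = smallest H on ties
  new("TuneResult", grid = data.frame(H = grid, accuracy = acc),
      bestH = best, innerSeed = innerSeed,
      innerTrainIdx = innerTrain, innerTestIdx = innerTest)
}

#' Tune BestH, then fit on the full training set
#'
#' Runs [optimizeH()] and refits a blending ensemble on all training rows at
#' the selected rate.
#'
#' @inheritParams optimizeH
#' @return List with elements `ensemble` ([BlendEnsemble-class], fitted at
#'   BestH) and `tune` ([TuneResult-class]).
#' @export
fitWithBestH <- function(G, y, trainIdx = seq_len(nSamples(G)),
                         strategy = c("random", "CA", "PP"), K = 8L,
                         grid = defaultHGrid(), seed = 1L,
                         innerFraction = 0.2) {
  strategy <- match.arg(strategy)
  tune <- optimizeH(G, y, trainIdx = trainIdx, strategy = strategy, K = K,
                    grid = grid, seed = seed, innerFraction = innerFraction)
  ens <- fitBlending(G, y, trainIdx = trainIdx,
                     config = blendConfig(H = bestH(tune), strategy = strategy,
                                          K = K, seed = seed))
  list(ensemble = ens, tune = tune)
}
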