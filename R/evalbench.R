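## Accuracy metric, skewness-based strategy recommendation, and the
## repeated-split benchmark of the three blending variants.

#' Pearson prediction accuracy
#'
#' The standard genomic-prediction accuracy: the Pearson correlation between
#' predicted and observed phenotypes.
#'
#' @param pred predicted values.
#' @param obs observed values; same length as `pred`, at least 3 pairs.
#' @return Numeric correlation in \[-1, 1\], with attribute `nPairs`.
#' @export
pearsonAccuracy <- function(pred, obs) {
  pred <- as.numeric(pred); obs <- as.numeric(obs)
  if (length(pred) != length(obs)) stop("length mismatch", call. = FALSE)
  if (length(pred) < 3L) stop("need at least 3 pairs", call. = FALSE)
  if (stats::sd(pred) < 1e-12 || stats::sd(obs) < 1e-12)
    stop("correlation undefined for constant input", call. = FALSE)
  r <- stats::cor(pred, obs)
  attr(r, "nPairs") <- length(pred)
  r
}

#' Adjusted Fisher-Pearson sample skewness
#'
#' `n / ((n-1)(n-2)) * sum(((y - mean) / s)^3)` with `s` the sample standard
#' deviation.
#'
#' @param y numeric vector, length >= 3, non-constant.
#' @return Skewness scalar.
#' @export
sampleSkewness <- function(y) {
  v <- if (is(y, "PhenotypeVector")) y@values else as.numeric(y)
  n <- length(v)
  if (n < 3L) stop("need at least 3 values", call. = FALSE)
  s <- stats::sd(v)
  if (s < 1e-12) stop("skewness undefined for constant input", call. = FALSE)
  n / ((n - 1) * (n - 2)) * sum(((v - mean(v)) / s)^3)
}

#' Recommend a stratification strategy from the trait distribution
#'
#' Near-symmetric (approximately normal) traits favour the
#' phenotype-probability strategy; clearly skewed traits favour the
#' cluster-analysis strategy. The rule is `|skewness| <= threshold` => PP,
#' otherwise CA.
#'
#' @param y numeric trait vector or [PhenotypeVector-class].
#' @param threshold absolute-skewness boundary (default 0.5, a conventional
#'   "moderate skew" cut).
#' @return `"PP"` or `"CA"`, with attribute `skewness`.
#' @export
recommendStrategy <- function(y, threshold = 0.5) {
  sk <- sampleSkewness(y)
  out <- if (abs(sk) <= threshold) "PP" else "CA"
  attr(out, "skewness") <- sk
  out
}

#' Accuracy improvement in percentage points
#'
#' `(accuracy - reference) * 100`: the reporting arithmetic used when
#' comparing a stratified variant against conventional blending.
#'
#' @param accuracy accuracy of the method under comparison.
#' @param reference accuracy of the reference method.
#' @return Percentage-point difference.
#' @export
improvementPP <- function(accuracy, reference) {
  (accuracy - reference) * 100
}

#' Published reference accuracies shipped with the package
#'
#' Small benchmark accuracy tables (Pearson correlations of the three
#' blending variants on public genomic-prediction datasets) used by the
#' reporting-arithmetic checks.
#'
#' @param dataset `"loblolly_pine"` or `"pig"`.
#' @return data.frame with columns `trait`, `blending`, `ca`, `pp`.
#' @export
referenceAccuracies <- function(dataset = c("loblolly_pine", "pig")) {
  dataset <- match.arg(dataset)
  path <- system.file("extdata", paste0(dataset, "_accuracies.tsv"),
                      package = "ssBlendR", mustWork = TRUE)
  utils::read.delim(path, stringsAsFactors = FALSE)
}

#' Benchmark blending variants over repeated outer splits
#'
#' For each repeat: draw an outer train/test split, fit each requested
#' method on the training rows (optionally tuning BestH on an inner split
#' first), and score Pearson accuracy on the test rows. The summary reports
#' per-method mean accuracies and the percentage-point improvement over
#' conventional blending. A method failing on one repeat leaves that cell
#' `NA` (excluded from its mean) with a warning.
#'
#' @param G a [GenotypeMatrix-class].
#' @param y a [PhenotypeVector-class] or numeric vector aligned to `G`.
#' @param methods subset of `c("blending", "ca", "pp")`.
#' @param repeats number of outer splits (default 10).
#' @param testFraction outer test fraction (default 0.2).
#' @param K strata count for CA/PP (default 8).
#' @param tune if `TRUE` (default) select BestH per method and repeat via
#'   [optimizeH()]; if `FALSE` fit at the fixed rate `H`.
#' @param H fixed holdout rate used when `tune = FALSE` (default 0.3).
#' @param grid BestH candidate grid when tuning.
#' @param seed integer base seed; repeat and method seeds derive from it.
#' @return A [BenchmarkReport-class].
#' @export
runBenchmark <- function(G, y, methods = c("blending", "ca", "pp"),
                         repeats = 10L, testFraction = 0.2, K = 8L,
                         tune = TRUE, H = 0.3, grid = defaultHGrid(),
                         seed = 1L) {
  stopifnot(is(G, "GenotypeMatrix"))
  methods <- match.arg(methods, several.ok = TRUE)
  repeats <- as.integer(repeats)
  if (repeats < 1L) stop("repeats must be >= 1", call. = FALSE)
  v <- if (is(y, "PhenotypeVector")) y@values else as.numeric(y)
  n <- nSamples(G)
  stratMap <- c(blending = "random", ca = "CA", pp = "PP")
  rows <- list()
  for (r in seq_len(repeats)) {
    sp <- outerSplit(n, testFraction = testFraction,
                     seed = .deriveSeed(seed, 100L + r))
    for (mth in methods) {
      strat <- stratMap[[mth]]
      fitSeed <- .deriveSeed(seed, 1000L * match(mth, c("blending", "ca", "pp")) + r)
      cell <- tryCatch({
        if (tune) {
          fw <- fitWithBestH(G, v, trainIdx = sp@trainIdx, strategy = strat,
                             K = K, grid = grid, seed = fitSeed)
          ens <- fw$ensemble; hUsed <- bestH(fw$tune)
        } else {
          ens <- fitBlending(G, v, trainIdx = sp@trainIdx,
                             config = blendConfig(H = H, strategy = strat,
                                                  K = K, seed = fitSeed))
          hUsed <- H
        }
        pred <- .predictRows(ens, G, sp@testIdx)
        list(H = hUsed, accuracy = as.numeric(pearsonAccuracy(pred, v[sp@testIdx])))
      }, error = function(e) {
        warning(sprintf("method '%s' failed on repeat %d: %s", mth, r,
                        conditionMessage(e)))
        list(H = NA_real_, accuracy = NA_real_)
      })
      rows[[length(rows) + 1L]] <-
        data.frame(method = mth, rep = r, H = cell$H, accuracy = cell$accuracy)
    }
  }
  perRepeat <- do.call(rbind, rows)
  meanAcc <- vapply(methods, function(mth)
    mean(perRepeat$accuracy[perRepeat$method == mth], na.rm = TRUE), numeric(1))
  ref <- if ("blending" %in% methods) meanAcc[["blending"]] else NA_real_
  summary <- data.frame(method = methods,
                        meanAccuracy = unname(meanAcc),
                        improvementPP = improvementPP(unname(meanAcc), ref))
  new("BenchmarkReport", perRepeat = perRepeat, summary = summary,
      settings = list(methods = methods, repeats = repeats,
                      testFraction = testFraction, K = K, tune = tune,
                      H = H, grid = grid, seed = seed))
}
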