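#' @import methods
NULL

#' GenotypeMatrix: an n x m SNP allele-dosage matrix
#'
#' Container for a biallelic SNP dosage matrix (individuals in rows, markers
#' in columns, expected dosage values in \[0, 2\]). This is the feature space
#' for the base learners and for cluster-analysis stratification. Missing
#' entries are imputed at load time, so a valid object never holds `NA`.
#'
#' @slot sampleIds character vector of individual identifiers (row order).
#' @slot markerIds character vector of marker identifiers (column order).
#' @slot dosages numeric matrix, `length(sampleIds)` x `length(markerIds)`.
#' @slot monomorphic logical vector flagging zero-variance markers; these are
#'   retained (they carry no information but keep marker sets aligned).
#'
#' @seealso [readGenotypes()], [simulateGenotypes()]
#' @export
setClass("GenotypeMatrix",
  slots = c(
    sampleIds   = "character",
    markerIds   = "character",
    dosages     = "matrix",
    monomorphic = "logical"
  )
)

setValidity("GenotypeMatrix", function(object) {
  msg <- character()
  d <- object@dosages
  if (!is.numeric(d)) msg <- c(msg, "dosages must be numeric")
  if (nrow(d) < 2L) msg <- c(msg, "need at least 2 individuals")
  if (ncol(d) < 1L) msg <- c(msg, "need at least 1 marker")
  if (nrow(d) != length(object@sampleIds))
    msg <- c(msg, "sampleIds length must match nrow(dosages)")
  if (ncol(d) != length(object@markerIds))
    msg <- c(msg, "markerIds length must match ncol(dosages)")
  if (length(object@monomorphic) != ncol(d))
    msg <- c(msg, "monomorphic flag length must match ncol(dosages)")
  if (anyNA(d)) msg <- c(msg, "dosages must not contain NA after imputation")
  if (anyDuplicated(object@sampleIds))
    msg <- c(msg, "sampleIds must be unique")
  if (length(msg)) msg else TRUE
})

#' PhenotypeVector: a named quantitative trait vector
#'
#' @slot sampleIds character vector of individual identifiers.
#' @slot values numeric trait values, finite, same order as `sampleIds`.
#' @slot traitName single trait label.
#' @slot nDropped number of individuals removed for missing phenotype at load.
#'
#' @seealso [readPhenotypes()], [simulatePhenotype()]
#' @export
setClass("PhenotypeVector",
  slots = c(
    sampleIds = "character",
    values    = "numeric",
    traitName = "character",
    nDropped  = "integer"
  ),
  prototype = prototype(nDropped = 0L)
)

setValidity("PhenotypeVector", function(object) {
  msg <- character()
  if (length(object@values) != length(object@sampleIds))
    msg <- c(msg, "values and sampleIds must have equal length")
  if (!all(is.finite(object@values)))
    msg <- c(msg, "all phenotype values must be finite")
  if (length(object@traitName) != 1L)
    msg <- c(msg, "traitName must be a single string")
  if (length(msg)) msg else TRUE
})

#' DataSplit: an outer train/test partition
#'
#' Index sets (1-based) partitioning `1..n` into a training set, on which
#' ensembles are fitted and BestH is tuned, and a test set reserved for
#' accuracy evaluation.
#'
#' @slot trainIdx,testIdx integer index vectors; disjoint, union `1..n`.
#' @slot n total number of individuals.
#'
#' @seealso [outerSplit()]
#' @export
setClass("DataSplit",
  slots = c(trainIdx = "integer", testIdx = "integer", n = "integer")
)

setValidity("DataSplit", function(object) {
  msg <- character()
  tr <- object@trainIdx; te <- object@testIdx
  if (length(tr) == 0L || length(te) == 0L)
    msg <- c(msg, "both train and test sets must be non-empty")
  if (length(intersect(tr, te)) > 0L)
    msg <- c(msg, "train and test indices must be disjoint")
  if (!setequal(c(tr, te), seq_len(object@n)))
    msg <- c(msg, "train and test must partition 1..n")
  if (length(msg)) msg else TRUE
})

#' SimParams: configuration of the quantitative-trait simulator
#'
#' @slot n number of individuals.
#' @slot m number of markers.
#' @slot nQtn number of quantitative trait nucleotides (markers with nonzero
#'   effect), at most `m`.
#' @slot h2 target narrow-sense heritability in (0, 1].
#' @slot mafLow,mafHigh bounds for per-marker minor allele frequencies,
#'   in (0, 0.5].
#' @slot seed integer seed controlling all randomness.
#'
#' @seealso [simParams()], [simulateDataset()]
#' @export
setClass("SimParams",
  slots = c(
    n = "integer", m = "integer", nQtn = "integer",
    h2 = "numeric", mafLow = "numeric", mafHigh = "numeric",
    seed = "integer"
  )
)

setValidity("SimParams", function(object) {
  msg <- character()
  if (object@n < 2L) msg <- c(msg, "n must be >= 2")
  if (object@m < 1L) msg <- c(msg, "m must be >= 1")
  if (object@nQtn < 1L || object@nQtn > object@m)
    msg <- c(msg, "nQtn must satisfy 1 <= nQtn <= m")
  if (!(object@h2 > 0 && object@h2 <= 1))
    msg <- c(msg, "h2 must be in (0, 1]")
  if (!(object@mafLow > 0 && object@mafLow <= object@mafHigh &&
        object@mafHigh <= 0.5))
    msg <- c(msg, "need 0 < mafLow <= mafHigh <= 0.5")
  if (length(msg)) msg else TRUE
})

#' SimulatedDataset: genotypes, phenotype and simulation truth
#'
#' Holds a simulated genotype matrix together with the phenotype
#' `y = X beta + e` and the full truth used to generate it: QTN positions,
#' effects, genetic values `g = X[, qtn] beta`, residuals, and the realized
#' heritability `var(g)/var(y)`.
#'
#' @slot G [GenotypeMatrix-class].
#' @slot y [PhenotypeVector-class].
#' @slot qtnIdx integer positions (columns of `G`) of the causal markers.
#' @slot beta numeric QTN effects, one per causal marker.
#' @slot g numeric genetic values.
#' @slot e numeric residuals.
#' @slot realizedH2 realized `var(g)/var(y)`.
#' @slot params the [SimParams-class] that generated the data.
#'
#' @export
setClass("SimulatedDataset",
  slots = c(
    G = "GenotypeMatrix", y = "PhenotypeVector",
    qtnIdx = "integer", beta = "numeric",
    g = "numeric", e = "numeric",
    realizedH2 = "numeric", params = "SimParams"
  )
)

setValidity("SimulatedDataset", function(object) {
  msg <- character()
  if (length(object@qtnIdx) != length(object@beta))
    msg <- c(msg, "qtnIdx and beta must have equal length")
  if (anyDuplicated(object@qtnIdx))
    msg <- c(msg, "qtnIdx must be distinct")
  if (length(object@g) != length(object@e) ||
      length(object@g) != length(object@y@values))
    msg <- c(msg, "g, e and y must have equal length")
  if (max(abs(object@y@values - object@g - object@e)) > 1e-10)
    msg <- c(msg, "y must equal g + e elementwise")
  if (object@realizedH2 < 0 || object@realizedH2 > 1)
    msg <- c(msg, "realizedH2 must lie in [0, 1]")
  if (length(msg)) msg else TRUE
})

#' StratifyConfig: how to build strata and draw the holdout
#'
#' @slot strategy one of `"random"` (simple random holdout, conventional
#'   blending), `"CA"` (k-means clusters of the dosage matrix) or `"PP"`
#'   (equal-width phenotype intervals weighted by kernel-density mass).
#' @slot K number of strata (layers); default 8.
#' @slot seed integer seed.
#' @slot ppGridPoints number of midpoint-rule abscissae used to integrate the
#'   phenotype density over each interval (>= 100).
#' @slot ppBandwidthRule bandwidth selector for the Gaussian kernel density
#'   estimate: `"nrd0"` (Silverman), `"nrd"`, or `"SJ"`.
#' @slot ppEmpirical if `TRUE`, interval weights come from empirical interval
#'   counts rather than integrated density mass.
#' @slot caTopVar optional number of top-variance markers used as the k-means
#'   feature space (`NA` = all markers).
#'
#' @seealso [stratifyConfig()], [stratifyCA()], [stratifyPP()]
#' @export
setClass("StratifyConfig",
  slots = c(
    strategy = "character", K = "integer", seed = "integer",
    ppGridPoints = "integer", ppBandwidthRule = "character",
    ppEmpirical = "logical", caTopVar = "integer"
  )
)

setValidity("StratifyConfig", function(object) {
  msg <- character()
  if (!object@strategy %in% c("random", "CA", "PP"))
    msg <- c(msg, "strategy must be one of 'random', 'CA', 'PP'")
  if (object@K < 1L) msg <- c(msg, "K must be >= 1")
  if (object@ppGridPoints < 100L)
    msg <- c(msg, "ppGridPoints must be >= 100")
  if (!object@ppBandwidthRule %in% c("nrd0", "nrd", "SJ"))
    msg <- c(msg, "ppBandwidthRule must be 'nrd0', 'nrd' or 'SJ'")
  if (length(msg)) msg else TRUE
})

#' StrataAssignment: per-individual stratum labels and sampling weights
#'
#' @slot labels integer stratum label (1..K) per individual.
#' @slot weights length-K probability vector: the target sampling mass per
#'   stratum (sums to 1).
#' @slot occupied length-K member counts per stratum (all > 0; empty strata
#'   are dropped and labels compacted).
#' @slot strategy the strategy that produced the assignment.
#'
#' @seealso [stratifyCA()], [stratifyPP()], [stratifiedSample()]
#' @export
setClass("StrataAssignment",
  slots = c(
    labels = "integer", weights = "numeric",
    occupied = "integer", strategy = "character"
  )
)

setValidity("StrataAssignment", function(object) {
  msg <- character()
  K <- length(object@weights)
  if (length(object@occupied) != K)
    msg <- c(msg, "weights and occupied must have equal length")
  if (any(object@labels < 1L) || any(object@labels > K))
    msg <- c(msg, "labels must lie in 1..K")
  if (any(object@occupied <= 0L))
    msg <- c(msg, "every stratum must be occupied")
  if (sum(object@occupied) != length(object@labels))
    msg <- c(msg, "occupied counts must sum to the number of individuals")
  if (any(object@weights < 0) || abs(sum(object@weights) - 1) > 1e-9)
    msg <- c(msg, "weights must be non-negative and sum to 1")
  if (length(msg)) msg else TRUE
})

#' BlendConfig: configuration of one blending fit
#'
#' @slot H holdout rate in (0, 1): the fraction of the training set that
#'   forms the holdout (meta-training) set; base learners train on the
#'   remaining `1 - H`.
#' @slot stratify a [StratifyConfig-class] choosing the holdout sampler.
#' @slot baseLearnerSettings named list (`svr`, `tree`, `enet`) of
#'   hyperparameter overrides for the base learners.
#' @slot seed integer seed.
#'
#' @seealso [blendConfig()], [fitBlending()]
#' @export
setClass("BlendConfig",
  slots = c(
    H = "numeric", stratify = "StratifyConfig",
    baseLearnerSettings = "list", seed = "integer"
  )
)

setValidity("BlendConfig", function(object) {
  if (!(object@H > 0 && object@H < 1)) "H must be in (0, 1)" else TRUE
})

#' BaseModelBundle: the three fitted first-layer regressors
#'
#' Support vector regression (RBF kernel), a regression tree, and an elastic
#' net, all fitted on the same standardized base-training rows. If the
#' response was constant the bundle degenerates to a constant predictor.
#'
#' @slot models named list with elements `svr`, `tree`, `enet` holding the
#'   fitted model objects (empty when degenerate).
#' @slot constantValue numeric(1) when the bundle predicts a constant,
#'   numeric(0) otherwise.
#' @slot nFeatures number of features (markers) the bundle was trained on.
#'
#' @seealso [fitBaseLearners()], [makeMetaFeatures()]
#' @export
setClass("BaseModelBundle",
  slots = c(models = "list", constantValue = "numeric", nFeatures = "integer")
)

#' MetaModel: the fitted linear meta-learner
#'
#' Ordinary least squares of the holdout responses on the three base-learner
#' predictions plus an intercept; rank-deficient designs get the minimum-norm
#' solution.
#'
#' @slot intercept numeric(1).
#' @slot coefficients numeric(3) aligned to (svr, tree, enet).
#'
#' @seealso [fitMeta()]
#' @export
setClass("MetaModel",
  slots = c(intercept = "numeric", coefficients = "numeric")
)

setValidity("MetaModel", function(object) {
  msg <- character()
  if (length(object@intercept) != 1L || !is.finite(object@intercept))
    msg <- c(msg, "intercept must be a single finite number")
  if (length(object@coefficients) != 3L || !all(is.finite(object@coefficients)))
    msg <- c(msg, "coefficients must be 3 finite numbers")
  if (length(msg)) msg else TRUE
})

#' BlendEnsemble: a fitted two-layer blending ensemble
#'
#' @slot bundle the fitted [BaseModelBundle-class].
#' @slot meta the fitted [MetaModel-class].
#' @slot config the [BlendConfig-class] used.
#' @slot holdoutIdx,baseTrainIdx disjoint index sets (rows of the genotype
#'   matrix) whose union is the training set.
#' @slot featureMeans,featureScales per-marker standardization constants
#'   computed on the base-training rows only.
#' @slot markerIds marker identifiers the ensemble was trained on.
#'
#' @seealso [fitBlending()], [predict,BlendEnsemble-method]
#' @export
setClass("BlendEnsemble",
  slots = c(
    bundle = "BaseModelBundle", meta = "MetaModel", config = "BlendConfig",
    holdoutIdx = "integer", baseTrainIdx = "integer",
    featureMeans = "numeric", featureScales = "numeric",
    markerIds = "character"
  )
)

setValidity("BlendEnsemble", function(object) {
  msg <- character()
  if (length(intersect(object@holdoutIdx, object@baseTrainIdx)) > 0L)
    msg <- c(msg, "holdout and base-train indices must be disjoint")
  if (length(object@featureMeans) != length(object@markerIds) ||
      length(object@featureScales) != length(object@markerIds))
    msg <- c(msg, "standardization constants must match marker count")
  if (length(msg)) msg else TRUE
})

#' TuneResult: the BestH grid search outcome
#'
#' @slot grid data.frame with columns `H` (strictly increasing) and
#'   `accuracy` (inner-split Pearson accuracy; `-Inf` where undefined).
#' @slot bestH the grid value attaining the maximum inner accuracy
#'   (ties broken toward the smallest H).
#' @slot innerSeed seed that fixed the inner split.
#' @slot innerTrainIdx,innerTestIdx the inner Train_Blending / training_test
#'   partition of the outer training set (indices into the full data).
#'
#' @seealso [optimizeH()], [fitWithBestH()]
#' @export
setClass("TuneResult",
  slots = c(
    grid = "data.frame", bestH = "numeric", innerSeed = "integer",
    innerTrainIdx = "integer", innerTestIdx = "integer"
  )
)

setValidity("TuneResult", function(object) {
  msg <- character()
  g <- object@grid
  if (!all(c("H", "accuracy") %in% names(g)))
    msg <- c(msg, "grid must have columns H and accuracy")
  else {
    if (is.unsorted(g$H, strictly = TRUE))
      msg <- c(msg, "grid H values must be strictly increasing")
    if (!object@bestH %in% g$H)
      msg <- c(msg, "bestH must be a grid value")
    else if (g$accuracy[match(object@bestH, g$H)] < max(g$accuracy))
      msg <- c(msg, "bestH must attain the maximum inner accuracy")
  }
  if (length(msg)) msg else TRUE
})

#' BenchmarkReport: repeated-split comparison of blending variants
#'
#' @slot perRepeat data.frame with one row per (method, repeat): columns
#'   `method`, `rep`, `H` (the rate used, BestH when tuned), `accuracy`.
#' @slot summary data.frame with one row per method: `method`,
#'   `meanAccuracy`, `improvementPP` (percentage-point gain over
#'   conventional blending).
#' @slot settings list recording the benchmark configuration and seed.
#'
#' @seealso [runBenchmark()]
#' @export
setClass("BenchmarkReport",
  slots = c(perRepeat = "data.frame", summary = "data.frame", settings = "list")
)
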