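#' Accessors for ssBlendR classes
#'
#' Small accessor generics so user code never touches slots directly.
#'
#' @param x an ssBlendR object.
#' @return The extracted component; see the individual class pages.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("dosages", function(x) standardGeneric("dosages"))
#' @rdname accessors
#' @export
setGeneric("sampleIds", function(x) standardGeneric("sampleIds"))
#' @rdname accessors
#' @export
setGeneric("markerIds", function(x) standardGeneric("markerIds"))
#' @rdname accessors
#' @export
setGeneric("nSamples", function(x) standardGeneric("nSamples"))
#' @rdname accessors
#' @export
setGeneric("nMarkers", function(x) standardGeneric("nMarkers"))
#' @rdname accessors
#' @export
setGeneric("monomorphicMarkers", function(x) standardGeneric("monomorphicMarkers"))
#' @rdname accessors
#' @export
setGeneric("phenoValues", function(x) standardGeneric("phenoValues"))
#' @rdname accessors
#' @export
setGeneric("traitName", function(x) standardGeneric("traitName"))
#' @rdname accessors
#' @export
setGeneric("trainIdx", function(x) standardGeneric("trainIdx"))
#' @rdname accessors
#' @export
setGeneric("testIdx", function(x) standardGeneric("testIdx"))
#' @rdname accessors
#' @export
setGeneric("strataLabels", function(x) standardGeneric("strataLabels"))
#' @rdname accessors
#' @export
setGeneric("strataWeights", function(x) standardGeneric("strataWeights"))
#' @rdname accessors
#' @export
setGeneric("strataCounts", function(x) standardGeneric("strataCounts"))
#' @rdname accessors
#' @export
setGeneric("qtnIndices", function(x) standardGeneric("qtnIndices"))
#' @rdname accessors
#' @export
setGeneric("qtnEffects", function(x) standardGeneric("qtnEffects"))
#' @rdname accessors
#' @export
setGeneric("geneticValues", function(x) standardGeneric("geneticValues"))
#' @rdname accessors
#' @export
setGeneric("realizedH2", function(x) standardGeneric("realizedH2"))
#' @rdname accessors
#' @export
setGeneric("metaModel", function(x) standardGeneric("metaModel"))
#' @rdname accessors
#' @export
setGeneric("metaCoefficients", function(x) standardGeneric("metaCoefficients"))
#' @rdname accessors
#' @export
setGeneric("holdoutIdx", function(x) standardGeneric("holdoutIdx"))
#' @rdname accessors
#' @export
setGeneric("baseTrainIdx", function(x) standardGeneric("baseTrainIdx"))
#' @rdname accessors
#' @export
setGeneric("bestH", function(x) standardGeneric("bestH"))
#' @rdname accessors
#' @export
setGeneric("tuneGrid", function(x) standardGeneric("tuneGrid"))
#' @rdname accessors
#' @export
setGeneric("benchSummary", function(x) standardGeneric("benchSummary"))
#' @rdname accessors
#' @export
setGeneric("benchAccuracies", function(x) standardGeneric("benchAccuracies"))

## ---- methods -------------------------------------------------------------

#' @rdname accessors
setMethod("dosages", "GenotypeMatrix", function(x) {
  d <- x@dosages
  dimnames(d) <- list(x@sampleIds, x@markerIds)
  d
})
#' @rdname accessors
setMethod("sampleIds", "GenotypeMatrix", function(x) x@sampleIds)
#' @rdname accessors
setMethod("sampleIds", "PhenotypeVector", function(x) x@sampleIds)
#' @rdname accessors
setMethod("markerIds", "GenotypeMatrix", function(x) x@markerIds)
#' @rdname accessors
setMethod("nSamples", "GenotypeMatrix", function(x) nrow(x@dosages))
#' @rdname accessors
setMethod("nMarkers", "GenotypeMatrix", function(x) ncol(x@dosages))
#' @rdname accessors
setMethod("monomorphicMarkers", "GenotypeMatrix", function(x) {
  stats::setNames(x@monomorphic, x@markerIds)
})
#' @rdname accessors
setMethod("phenoValues", "PhenotypeVector", function(x) {
  stats::setNames(x@values, x@sampleIds)
})
#' @rdname accessors
setMethod("traitName", "PhenotypeVector", function(x) x@traitName)
#' @rdname accessors
setMethod("trainIdx", "DataSplit", function(x) x@trainIdx)
#' @rdname accessors
setMethod("testIdx", "DataSplit", function(x) x@testIdx)
#' @rdname accessors
setMethod("strataLabels", "StrataAssignment", function(x) x@labels)
#' @rdname accessors
setMethod("strataWeights", "StrataAssignment", function(x) x@weights)
#' @rdname accessors
setMethod("strataCounts", "StrataAssignment", function(x) x@occupied)
#' @rdname accessors
setMethod("qtnIndices", "SimulatedDataset", function(x) x@qtnIdx)
#' @rdname accessors
setMethod("qtnEffects", "SimulatedDataset", function(x) x@beta)
#' @rdname accessors
setMethod("geneticValues", "SimulatedDataset", function(x) x@g)
#' @rdname accessors
setMethod("realizedH2", "SimulatedDataset", function(x) x@realizedH2)
#' @rdname accessors
setMethod("metaModel", "BlendEnsemble", function(x) x@meta)
#' @rdname accessors
setMethod("metaCoefficients", "MetaModel", function(x) {
  c(intercept = x@intercept,
    stats::setNames(x@coefficients, c("svr", "tree", "enet")))
})
#' @rdname accessors
setMethod("metaCoefficients", "BlendEnsemble", function(x) metaCoefficients(x@meta))
#' @rdname accessors
setMethod("holdoutIdx", "BlendEnsemble", function(x) x@holdoutIdx)
#' @rdname accessors
setMethod("baseTrainIdx", "BlendEnsemble", function(x) x@baseTrainIdx)
#' @rdname accessors
setMethod("bestH", "TuneResult", function(x) x@bestH)
#' @rdname accessors
setMethod("tuneGrid", "TuneResult", function(x) x@grid)
#' @rdname accessors
setMethod("benchSummary", "BenchmarkReport", function(x) x@summary)
#' @rdname accessors
setMethod("benchAccuracies", "BenchmarkReport", function(x) x@perRepeat)

## ---- show ----------------------------------------------------------------

setMethod("show", "GenotypeMatrix", function(object) {
  cat(sprintf("GenotypeMatrix: %d individuals x %d markers (%d monomorphic)\n",
              nSamples(object), nMarkers(object), sum(object@monomorphic)))
})

setMethod("show", "PhenotypeVector", function(object) {
  v <- object@values
  cat(sprintf("PhenotypeVector '%s': n = %d, mean = %.4g, sd = %.4g (%d dropped at load)\n",
              object@traitName, length(v), mean(v), stats::sd(v), object@nDropped))
})

setMethod("show", "DataSplit", function(object) {
  cat(sprintf("DataSplit: %d train / %d test of n = %d\n",
              length(object@trainIdx), length(object@testIdx), object@n))
})

setMethod("show", "SimulatedDataset", function(object) {
  p <- object@params
  cat(sprintf(paste0(
    "SimulatedDataset: n = %d, m = %d, %d QTNs, target h2 = %.2f, ",
    "realized h2 = %.4f\n"),
    p@n, p@m, length(object@qtnIdx), p@h2, object@realizedH2))
})

setMethod("show", "StrataAssignment", function(object) {
  cat(sprintf("StrataAssignment (%s): %d strata over %d individuals\n",
              object@strategy, length(object@weights), length(object@labels)))
  cat("  occupied:", paste(object@occupied, collapse = " "), "\n")
  cat("  weights :", paste(sprintf("%.3f", object@weights), collapse = " "), "\n")
})

setMethod("show", "BlendEnsemble", function(object) {
  cfg <- object@config
  cat(sprintf(paste0(
    "BlendEnsemble (%s strategy): H = %.2f, %d base-train + %d holdout rows, ",
    "%d markers\n"),
    cfg@stratify@strategy, cfg@H, length(object@baseTrainIdx),
    length(object@holdoutIdx), length(object@markerIds)))
  co <- metaCoefficients(object)
  cat(sprintf("  meta: %.4g + %.4g*svr + %.4g*tree + %.4g*enet\n",
              co[1], co[2], co[3], co[4]))
})

setMethod("show", "TuneResult", function(object) {
  cat(sprintf("TuneResult: BestH = %.2f over %d grid values\n",
              object@bestH, nrow(object@grid)))
  print(object@grid, row.names = FALSE)
})

setMethod("show", "BenchmarkReport", function(object) {
  cat(sprintf("BenchmarkReport: %d repeats\n",
              object@settings$repeats %||% length(unique(object@perRepeat$rep))))
  print(object@summary, row.names = FALSE)
})
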