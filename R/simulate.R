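## Quantitative-trait simulator: binomial-MAF genotypes, normal QTN effects,
## residual variance calibrated to a target narrow-sense heritability.

#' Create simulation parameters
#'
#' @param n number of individuals (default 3000, the scale of the simulated
#'   study design).
#' @param m number of markers (default 20000).
#' @param nQtn number of causal markers (quantitative trait nucleotides).
#' @param h2 target narrow-sense heritability in (0, 1].
#' @param mafLow,mafHigh bounds of the uniform distribution the per-marker
#'   allele frequencies are drawn from, in (0, 0.5].
#' @param seed integer seed.
#' @return A [SimParams-class].
#' @export
simParams <- function(n = 3000L, m = 20000L, nQtn = 200L, h2 = 0.5,
                      mafLow = 0.05, mafHigh = 0.5, seed = 1L) {
  new("SimParams", n = as.integer(n), m = as.integer(m),
      nQtn = as.integer(nQtn), h2 = as.numeric(h2),
      mafLow = as.numeric(mafLow), mafHigh = as.numeric(mafHigh),
      seed = as.integer(seed))
}

#' Simulate a genotype dosage matrix
#'
#' Each marker j receives an allele frequency `p_j ~ Uniform(mafLow,
#' mafHigh)`; dosages are independent `Binomial(2, p_j)` draws per
#' individual. Markers are independent (no linkage disequilibrium) and there
#' is no population structure: the genotypes are a neutral synthetic stand-in
#' that exercises every downstream algorithm.
#'
#' @param params a [SimParams-class].
#' @return A [GenotypeMatrix-class] with `params@n` rows and `params@m`
#'   columns.
#' @export
simulateGenotypes <- function(params) {
  stopifnot(is(params, "SimParams"))
  validObject(params)
  n <- params@n; m <- params@m
  .withSeed(.deriveSeed(params@seed, 1L), {
    p <- stats::runif(m, params@mafLow, params@mafHigh)
    d <- matrix(stats::rbinom(n * m, size = 2L, prob = rep(p, each = n)),
                nrow = n, ncol = m)
  })
  storage.mode(d) <- "double"
  mono <- .colRangeZero(d)
  new("GenotypeMatrix",
      sampleIds = sprintf("S%0*d", nchar(n), seq_len(n)),
      markerIds = sprintf("M%0*d", nchar(m), seq_len(m)),
      dosages = d, monomorphic = mono)
}

## column-wise (max - min == 0) flags
.colRangeZero <- function(d) {
  res <- logical(ncol(d))
  for (j in seq_len(ncol(d))) {
    cj <- d[, j]
    res[j] <- cj[1L] == max(cj) && cj[1L] == min(cj)
  }
  res
}

#' Simulate a phenotype on an existing genotype matrix
#'
#' Implements the additive model `y = X beta + e`: `nQtn` markers are sampled
#' without replacement as QTNs, their effects are drawn `beta ~ N(0, 1)`, the
#' genetic value is `g = X[, qtn] beta`, and the residual is drawn
#' `e ~ N(0, sigma2_e)` with `sigma2_e = var(g) * (1 - h2) / h2`, calibrated
#' to the realized sample variance of `g` so that `var(g)/var(y)`
#' concentrates tightly on the target heritability. At `h2 = 1` the residual
#' is exactly zero.
#'
#' If all sampled QTNs happen to be monomorphic (`var(g) = 0`) the QTN set is
#' resampled, up to 10 times, before erroring.
#'
#' @param G a [GenotypeMatrix-class].
#' @param params a [SimParams-class]; `params@nQtn` must not exceed
#'   `nMarkers(G)`.
#' @return A [SimulatedDataset-class].
#' @export
simulatePhenotype <- function(G, params) {
  stopifnot(is(G, "GenotypeMatrix"), is(params, "SimParams"))
  validObject(params)
  m <- nMarkers(G); n <- nSamples(G)
  q <- params@nQtn
  if (q > m)
    stop(sprintf("nQtn = %d exceeds the %d available markers", q, m),
         call. = FALSE)
  h2 <- params@h2
  out <- .withSeed(.deriveSeed(params@seed, 2L), {
    qtn <- NULL; beta <- NULL; g <- NULL
    for (attempt in seq_len(10L)) {
      qtn <- sort(sample.int(m, q))
      beta <- stats::rnorm(q, mean = 0, sd = 1)
      g <- drop(G@dosages[, qtn, drop = FALSE] %*% beta)
      if (stats::var(g) > 0) break
      qtn <- NULL
    }
    if (is.null(qtn))
      stop("all sampled QTN sets were monomorphic (var(g) = 0) after 10 attempts",
           call. = FALSE)
    e <- if (h2 == 1) rep(0, n) else {
      sigma2e <- stats::var(g) * (1 - h2) / h2
      stats::rnorm(n, mean = 0, sd = sqrt(sigma2e))
    }
    list(qtn = qtn, beta = beta, g = g, e = e)
  })
  y <- out$g + out$e
  realized <- if (h2 == 1) 1 else stats::var(out$g) / stats::var(y)
  new("SimulatedDataset",
      G = G,
      y = phenotypeVector(y, sampleIds = sampleIds(G), traitName = "simulated"),
      qtnIdx = as.integer(out$qtn), beta = out$beta,
      g = out$g, e = out$e,
      realizedH2 = realized, params = params)
}

#' Simulate genotypes and a phenotype in one call
#'
#' @param params a [SimParams-class].
#' @return A [SimulatedDataset-class].
#' @export
simulateDataset <- function(params) {
  simulatePhenotype(simulateGenotypes(params), params)
}

#' Simulate the 3 x 3 heritability-by-QTN grid
#'
#' Crosses heritabilities \{0.2, 0.5, 0.8\} with QTN counts \{200, 2000,
#' 5000\}, the nine genetic architectures of the simulated study design. QTN
#' counts exceeding `base@m` are capped at `m` (with a warning) and duplicate
#' grid cells are dropped. Per-dataset seeds are derived reproducibly from
#' `base@seed`.
#'
#' @param base a [SimParams-class] providing n, m, MAF bounds and base seed;
#'   its `h2` and `nQtn` are ignored in favour of the grid.
#' @param h2Grid,qtnGrid the grid values; defaults are the standard design.
#' @return A named list of [SimulatedDataset-class], names like `"h0.2_q200"`.
#' @export
simulateGrid <- function(base, h2Grid = c(0.2, 0.5, 0.8),
                         qtnGrid = c(200L, 2000L, 5000L)) {
  stopifnot(is(base, "SimParams"))
  qtnGrid <- as.integer(qtnGrid)
  if (any(qtnGrid > base@m)) {
    warning(sprintf("QTN counts exceeding m = %d capped at m", base@m))
    qtnGrid[qtnGrid > base@m] <- base@m
  }
  qtnGrid <- unique(qtnGrid)
  out <- list()
  k <- 0L
  for (h2 in h2Grid) for (q in qtnGrid) {
    k <- k + 1L
    p <- simParams(n = base@n, m = base@m, nQtn = q, h2 = h2,
                   mafLow = base@mafLow, mafHigh = base@mafHigh,
                   seed = .deriveSeed(base@seed, 1000L + k))
    out[[sprintf("h%g_q%d", h2, q)]] <- simulateDataset(p)
  }
  out
}

#' Write a simulated dataset to disk
#'
#' Writes the genotype CSV, phenotype TSV, a truth TSV (QTN index, marker ID,
#' effect) and a JSON sidecar with the parameters and realized heritability.
#'
#' @param sim a [SimulatedDataset-class].
#' @param prefix output path prefix.
#' @return The four file paths, invisibly.
#' @export
writeSimulatedDataset <- function(sim, prefix) {
  stopifnot(is(sim, "SimulatedDataset"))
  paths <- c(geno = paste0(prefix, "_genotypes.csv"),
             pheno = paste0(prefix, "_phenotypes.tsv"),
             truth = paste0(prefix, "_truth.tsv"),
             meta = paste0(prefix, "_params.json"))
  writeGenotypes(sim@G, paths[["geno"]])
  data.table::fwrite(
    data.table::data.table(sample_id = sampleIds(sim@y),
                           simulated = sim@y@values),
    paths[["pheno"]], sep = "\t")
  data.table::fwrite(
    data.table::data.table(qtn_idx = sim@qtnIdx,
                           marker_id = markerIds(sim@G)[sim@qtnIdx],
                           beta = sim@beta),
    paths[["truth"]], sep = "\t")
  p <- sim@params
  jsonlite::write_json(
    list(n = p@n, m = p@m, nQtn = p@nQtn, h2 = p@h2, mafLow = p@mafLow,
         mafHigh = p@mafHigh, seed = p@seed, realizedH2 = sim@realizedH2),
    paths[["meta"]], auto_unbox = TRUE, digits = NA)
  invisible(paths)
}
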