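## Stratification of individuals for holdout sampling: cluster-analysis (CA)
## strata from k-means on the dosage matrix, or phenotype-probability (PP)
## strata from equal-width phenotype intervals weighted by the kernel-density
## mass of each interval (midpoint Riemann integration).

#' Create a stratification configuration
#'
#' @param strategy `"random"`, `"CA"` or `"PP"`.
#' @param K number of strata (layers); default 8.
#' @param seed integer seed.
#' @param ppGridPoints midpoint-rule abscissae for density integration
#'   (default 1000).
#' @param ppBandwidthRule KDE bandwidth selector: `"nrd0"` (Silverman,
#'   default), `"nrd"` or `"SJ"`.
#' @param ppEmpirical use empirical interval counts instead of integrated
#'   density mass as PP weights.
#' @param caTopVar number of top-variance markers used as k-means features
#'   (`NA` = all markers).
#' @return A [StratifyConfig-class].
#' @export
stratifyConfig <- function(strategy = c("random", "CA", "PP"), K = 8L,
                           seed = 1L, ppGridPoints = 1000L,
                           ppBandwidthRule = "nrd0", ppEmpirical = FALSE,
                           caTopVar = NA_integer_) {
  strategy <- match.arg(strategy)
  new("StratifyConfig", strategy = strategy, K = as.integer(K),
      seed = as.integer(seed), ppGridPoints = as.integer(ppGridPoints),
      ppBandwidthRule = ppBandwidthRule, ppEmpirical = as.logical(ppEmpirical),
      caTopVar = as.integer(caTopVar))
}

## compact labels so strata are numbered 1..K' with every stratum occupied
.compactStrata <- function(labels, weights, strategy) {
  occ <- tabulate(labels, nbins = length(weights))
  keep <- occ > 0L
  if (!all(keep)) {
    relab <- cumsum(keep)
    labels <- relab[labels]
    weights <- weights[keep]
    occ <- occ[keep]
  }
  weights <- weights / sum(weights)
  new("StrataAssignment", labels = as.integer(labels),
      weights = as.numeric(weights), occupied = as.integer(occ),
      strategy = strategy)
}

#' Cluster-analysis (CA) stratification of genotypes
#'
#' Runs k-means with `K` centers on the dosage matrix (optionally restricted
#' to the top-variance markers) and uses cluster memberships as strata.
#' Sampling weights are proportional to cluster sizes, so a stratified draw
#' preserves the genetic composition of the population. Empty clusters are
#' dropped, reducing K with a warning.
#'
#' @param G a [GenotypeMatrix-class].
#' @param config a [StratifyConfig-class].
#' @return A [StrataAssignment-class].
#' @export
stratifyCA <- function(G, config = stratifyConfig("CA")) {
  stopifnot(is(G, "GenotypeMatrix"), is(config, "StratifyConfig"))
  n <- nSamples(G)
  K <- config@K
  if (K > n)
    stop(sprintf("K = %d exceeds the %d individuals", K, n), call. = FALSE)
  X <- G@dosages
  if (!is.na(config@caTopVar) && config@caTopVar < ncol(X)) {
    v <- apply(X, 2L, stats::var)
    X <- X[, order(v, decreasing = TRUE)[seq_len(config@caTopVar)], drop = FALSE]
  }
  nUnique <- nrow(unique(X))
  K2 <- K
  if (nUnique < K2) {
    warning(sprintf("only %d distinct genotype rows; reducing K from %d",
                    nUnique, K2))
    K2 <- nUnique
  }
  if (K2 == 1L) {
    labels <- rep(1L, n)
  } else {
    km <- NULL
    for (attempt in seq_len(25L)) {
      km <- tryCatch(
        .withSeed(.deriveSeed(config@seed, 40L + attempt),
                  stats::kmeans(X, centers = K2, nstart = 10L, iter.max = 50L)),
        error = function(e) NULL)
      if (!is.null(km)) break
    }
    if (is.null(km))
      stop("k-means failed to produce a valid clustering", call. = FALSE)
    labels <- km$cluster
  }
  occ <- tabulate(labels, nbins = max(labels))
  if (sum(occ > 0L) < K2)
    warning(sprintf("k-means left %d empty cluster(s); K reduced",
                    K2 - sum(occ > 0L)))
  .compactStrata(labels, occ / sum(occ), "CA")
}

## Gaussian KDE evaluated at points x for data y with bandwidth h
.gaussKde <- function(x, y, h) {
  rowMeans(stats::dnorm(outer(x, y, "-") / h)) / h
}

.bwFun <- function(rule) {
  switch(rule,
         nrd0 = stats::bw.nrd0,
         nrd  = stats::bw.nrd,
         SJ   = stats::bw.SJ,
         stop(sprintf("unknown bandwidth rule '%s'", rule), call. = FALSE))
}

#' Phenotype-probability (PP) stratification
#'
#' Divides the phenotype range `[min(y), max(y)]` into `K` equal-width
#' intervals (the last interval right-closed), fits a Gaussian kernel
#' density estimate to the phenotype, integrates it over each interval with
#' the midpoint Riemann rule on `ppGridPoints` abscissae, and renormalizes
#' the interval masses to sum to 1. Interval membership gives the stratum
#' labels; the integrated masses give the sampling weights. Intervals
#' containing no individuals are dropped (weights renormalized over the
#' occupied intervals).
#'
#' With `ppEmpirical = TRUE` the weights are the empirical interval
#' frequencies instead of the integrated density mass.
#'
#' @param y a [PhenotypeVector-class] or numeric vector.
#' @param config a [StratifyConfig-class].
#' @return A [StrataAssignment-class].
#' @export
stratifyPP <- function(y, config = stratifyConfig("PP")) {
  stopifnot(is(config, "StratifyConfig"))
  v <- if (is(y, "PhenotypeVector")) y@values else as.numeric(y)
  if (length(v) < 2L || max(v) == min(v))
    stop("phenotype is constant; PP stratification is undefined", call. = FALSE)
  K <- config@K
  breaks <- seq(min(v), max(v), length.out = K + 1L)
  labels <- findInterval(v, breaks, rightmost.closed = TRUE, all.inside = TRUE)
  if (config@ppEmpirical) {
    prob <- tabulate(labels, nbins = K) / length(v)
  } else {
    gp <- config@ppGridPoints
    width <- (max(v) - min(v)) / gp
    mids <- min(v) + (seq_len(gp) - 0.5) * width
    h <- .bwFun(config@ppBandwidthRule)(v)
    dens <- .gaussKde(mids, v, h)
    cell <- findInterval(mids, breaks, rightmost.closed = TRUE,
                         all.inside = TRUE)
    mass <- vapply(seq_len(K),
                   function(k) sum(dens[cell == k]) * width, numeric(1))
    prob <- mass / sum(mass)
  }
  .compactStrata(labels, prob, "PP")
}

#' Integer quotas by largest-remainder apportionment with occupancy caps
#'
#' Apportions `total` draws across strata proportionally to `weights` using
#' the largest-remainder (Hamilton) rule, which guarantees the quotas sum to
#' `total` exactly. A stratum whose real-valued target exceeds its occupancy
#' is capped at the occupancy and the overflow is redistributed across the
#' remaining strata in proportion to their weights; this repeats until no
#' stratum is over-full. Remainder ties are broken toward the lower stratum
#' index.
#'
#' @param weights per-stratum probability weights (non-negative, summing
#'   to 1 after normalization).
#' @param occupied per-stratum member counts.
#' @param total total number of draws; at most `sum(occupied)`.
#' @return Integer quota vector summing to `total`, with
#'   `quota[k] <= occupied[k]` for every stratum.
#' @export
stratumQuotas <- function(weights, occupied, total) {
  K <- length(weights)
  occupied <- as.integer(occupied)
  total <- as.integer(total)
  if (length(occupied) != K) stop("weights/occupied length mismatch", call. = FALSE)
  if (total > sum(occupied))
    stop(sprintf("requested %d draws from %d individuals", total, sum(occupied)),
         call. = FALSE)
  target <- numeric(K)
  fixed <- rep(FALSE, K)
  remT <- as.numeric(total)
  ## cap-and-redistribute on the real-valued targets
  repeat {
    idx <- which(!fixed)
    if (length(idx) == 0L || remT <= 0) break
    w <- weights[idx]
    if (sum(w) <= 0) w <- occupied[idx] / sum(occupied[idx])
    t <- remT * w / sum(w)
    sat <- t >= occupied[idx] - 1e-9
    if (!any(sat)) { target[idx] <- t; break }
    satIdx <- idx[sat]
    target[satIdx] <- occupied[satIdx]
    fixed[satIdx] <- TRUE
    remT <- remT - sum(occupied[satIdx])
  }
  ## largest-remainder rounding of the unsaturated targets
  quota <- floor(target + 1e-9)
  rem <- target - quota
  left <- total - sum(quota)
  ord <- order(-rem, seq_len(K))
  for (j in ord) {
    if (left <= 0L) break
    if (quota[j] < occupied[j]) { quota[j] <- quota[j] + 1L; left <- left - 1L }
  }
  ## caps can still leave units; place them wherever capacity remains,
  ## highest residual weight first
  if (left > 0L) {
    ord2 <- order(-weights, seq_len(K))
    for (j in ord2) {
      while (left > 0L && quota[j] < occupied[j]) {
        quota[j] <- quota[j] + 1L; left <- left - 1L
      }
    }
  }
  as.integer(quota)
}

#' Draw a stratified holdout sample
#'
#' Draws `round(H * n)` individuals: per-stratum quotas come from
#' [stratumQuotas()] applied to the assignment's weights, and quota members
#' are drawn uniformly without replacement within each stratum.
#'
#' @param assignment a [StrataAssignment-class].
#' @param H holdout rate in (0, 1).
#' @param seed integer seed.
#' @return Sorted integer indices of the holdout individuals (positions in
#'   the assignment's label vector); length exactly `round(H * n)`.
#' @export
stratifiedSample <- function(assignment, H, seed = 1L) {
  stopifnot(is(assignment, "StrataAssignment"))
  .assertScalarNumber(H, "H")
  if (H <= 0 || H >= 1) stop("H must be in (0, 1)", call. = FALSE)
  n <- length(assignment@labels)
  total <- as.integer(round(H * n))
  if (total < 1L)
    stop(sprintf("H = %g yields an empty holdout for n = %d", H, n),
         call. = FALSE)
  quota <- stratumQuotas(assignment@weights, assignment@occupied, total)
  .withSeed(seed, {
    picks <- integer(0)
    for (k in seq_along(quota)) {
      if (quota[k] > 0L) {
        members <- which(assignment@labels == k)
        picks <- c(picks, .sampleFrom(members, quota[k]))
      }
    }
    sort(picks)
  })
}

#' Draw a simple random holdout sample
#'
#' The conventional-blending sampler: a uniform random subset of size
#' `round(H * n)`.
#'
#' @param n number of individuals.
#' @param H holdout rate in (0, 1).
#' @param seed integer seed.
#' @return Sorted integer indices of the holdout individuals.
#' @export
randomSample <- function(n, H, seed = 1L) {
  .assertScalarNumber(H, "H")
  if (H <= 0 || H >= 1) stop("H must be in (0, 1)", call. = FALSE)
  n <- as.integer(n)
  total <- as.integer(round(H * n))
  if (total < 1L || total > n)
    stop(sprintf("H = %g yields an invalid holdout size for n = %d", H, n),
         call. = FALSE)
  sort(.withSeed(seed, sample.int(n, total)))
}
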