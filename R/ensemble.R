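## Two-layer blending: SVR + regression tree + elastic net as base learners
## on the non-holdout portion of the training set, and a least-squares linear
## meta-learner on their predictions over the holdout portion. The holdout is
## drawn by a pluggable sampler: simple random (conventional blending) or
## stratified (CA/PP ssBlending).

.defaultLearnerSettings <- function() {
  list(
    svr  = list(kernel = "radial", cost = 1, epsilon = 0.1),
    tree = list(),
    ## explicit lambda path: glmnet's automatic path stops early once the
    ## deviance saturates, which keeps strongly determined linear systems
    ## away from the least-squares limit the meta-layer assumes
    enet = list(alpha = 0.5, nfolds = 5L, lambda.min.ratio = 1e-7,
                nlambda = 100L)
  )
}

#' Create a blending configuration
#'
#' @param H holdout rate in (0, 1): fraction of the training set forming the
#'   holdout (meta-training) set. Base learners train on the remaining
#'   `1 - H`.
#' @param strategy holdout sampler: `"random"` (conventional blending),
#'   `"CA"` or `"PP"` (ssBlending).
#' @param K number of strata for CA/PP (default 8).
#' @param seed integer seed.
#' @param baseLearnerSettings named list (`svr`, `tree`, `enet`) of
#'   hyperparameter overrides merged over the defaults.
#' @param stratify optionally a fully specified [StratifyConfig-class]
#'   (overrides `strategy`/`K`).
#' @return A [BlendConfig-class].
#' @export
blendConfig <- function(H = 0.3, strategy = c("random", "CA", "PP"), K = 8L,
                        seed = 1L, baseLearnerSettings = list(),
                        stratify = NULL) {
  if (is.null(stratify)) {
    strategy <- match.arg(strategy)
    stratify <- stratifyConfig(strategy, K = K, seed = .deriveSeed(seed, 7L))
  }
  settings <- .defaultLearnerSettings()
  for (nm in names(baseLearnerSettings))
    settings[[nm]] <- utils::modifyList(settings[[nm]] %||% list(),
                                        baseLearnerSettings[[nm]])
  new("BlendConfig", H = as.numeric(H), stratify = stratify,
      baseLearnerSettings = settings, seed = as.integer(seed))
}

#' Split a training set into holdout and base-training parts
#'
#' The holdout (fraction `H` of the training rows, which will train the
#' meta-learner) is drawn by the configured sampler: uniformly at random, or
#' by stratified sampling over CA (genotype k-means) or PP (phenotype
#' density) strata built on the training rows only.
#'
#' @param trainIdx integer indices of the training rows.
#' @param config a [BlendConfig-class].
#' @param G a [GenotypeMatrix-class] (needed for CA).
#' @param y a [PhenotypeVector-class] (needed for PP).
#' @return List with `holdoutIdx` and `baseTrainIdx`, disjoint subsets of
#'   `trainIdx` whose union is `trainIdx`.
#' @export
splitHoldout <- function(trainIdx, config, G = NULL, y = NULL) {
  stopifnot(is(config, "BlendConfig"))
  trainIdx <- as.integer(trainIdx)
  nT <- length(trainIdx)
  if (nT < 10L)
    stop(sprintf("need at least 10 training rows, got %d", nT), call. = FALSE)
  strategy <- config@stratify@strategy
  drawSeed <- .deriveSeed(config@seed, 2L)
  pos <- switch(strategy,
    random = randomSample(nT, config@H, seed = drawSeed),
    CA = {
      if (is.null(G)) stop("CA stratification needs the genotype matrix", call. = FALSE)
      sub <- new("GenotypeMatrix", sampleIds = G@sampleIds[trainIdx],
                 markerIds = G@markerIds,
                 dosages = G@dosages[trainIdx, , drop = FALSE],
                 monomorphic = G@monomorphic)
      stratifiedSample(stratifyCA(sub, config@stratify), config@H, seed = drawSeed)
    },
    PP = {
      if (is.null(y)) stop("PP stratification needs the phenotype vector", call. = FALSE)
      v <- if (is(y, "PhenotypeVector")) y@values else as.numeric(y)
      stratifiedSample(stratifyPP(v[trainIdx], config@stratify), config@H,
                       seed = drawSeed)
    })
  holdout <- trainIdx[pos]
  base <- setdiff(trainIdx, holdout)
  if (length(holdout) == 0L || length(base) == 0L)
    stop("holdout split left an empty partition", call. = FALSE)
  list(holdoutIdx = holdout, baseTrainIdx = base)
}

#' Fit the three base learners
#'
#' Fits epsilon-SVR with an RBF kernel (`e1071::svm`; cost 1, epsilon 0.1,
#' gamma `1/m`), a CART regression tree (`rpart`), and an elastic net with
#' mixing 0.5 whose penalty is chosen by internal 5-fold cross-validation
#' (`glmnet::cv.glmnet`), each on the same rows. Features are expected
#' already standardized by the caller; no further scaling is applied inside
#' the learners. A constant response degenerates the bundle to a constant
#' predictor.
#'
#' @param X numeric feature matrix (base-training rows, standardized).
#' @param y numeric responses.
#' @param settings named list (`svr`, `tree`, `enet`) of hyperparameters.
#' @param seed integer seed (controls the elastic-net fold assignment).
#' @return A [BaseModelBundle-class].
#' @export
fitBaseLearners <- function(X, y, settings = list(), seed = 1L) {
  X <- as.matrix(X)
  if (nrow(X) < 5L)
    stop(sprintf("need at least 5 base-training rows, got %d", nrow(X)),
         call. = FALSE)
  if (nrow(X) != length(y)) stop("X rows and y length differ", call. = FALSE)
  full <- .defaultLearnerSettings()
  for (nm in names(settings))
    full[[nm]] <- utils::modifyList(full[[nm]] %||% list(), settings[[nm]])
  if (stats::sd(y) < 1e-12)
    return(new("BaseModelBundle", models = list(),
               constantValue = mean(y), nFeatures = ncol(X)))
  fitOne <- function(tag, fn) {
    tryCatch(fn(), error = function(e)
      stop(sprintf("base learner '%s' failed: %s", tag, conditionMessage(e)),
           call. = FALSE))
  }
  svr <- fitOne("svr", function() {
    do.call(e1071::svm, c(list(x = X, y = y, type = "eps-regression",
                               scale = FALSE), full$svr))
  })
  df <- as.data.frame(X)
  names(df) <- paste0("V", seq_len(ncol(X)))
  df$.y <- y
  tree <- fitOne("tree", function() {
    do.call(rpart::rpart, c(list(formula = .y ~ ., data = df,
                                 method = "anova"), full$tree))
  })
  Xg <- if (ncol(X) < 2L) cbind(X, 0) else X
  enet <- fitOne("enet", function() {
    es <- full$enet
    init <- glmnet::glmnet(Xg, y, alpha = es$alpha, nlambda = 5L)
    lmax <- max(init$lambda)
    lam <- exp(seq(log(lmax), log(lmax * es$lambda.min.ratio),
                   length.out = es$nlambda))
    .withSeed(.deriveSeed(seed, 3L),
              glmnet::cv.glmnet(Xg, y, alpha = es$alpha, nfolds = es$nfolds,
                                lambda = lam))
  })
  new("BaseModelBundle",
      models = list(svr = svr, tree = tree, enet = enet),
      constantValue = numeric(0), nFeatures = ncol(X))
}

## predictions of the three base learners on (standardized) rows of X
.predictBundle <- function(bundle, X) {
  X <- as.matrix(X)
  if (ncol(X) != bundle@nFeatures)
    stop(sprintf("feature count mismatch: bundle trained on %d, got %d",
                 bundle@nFeatures, ncol(X)), call. = FALSE)
  if (length(bundle@constantValue) == 1L) {
    z <- matrix(bundle@constantValue, nrow = nrow(X), ncol = 3L)
    colnames(z) <- c("svr", "tree", "enet")
    return(z)
  }
  df <- as.data.frame(X)
  names(df) <- paste0("V", seq_len(ncol(X)))
  Xg <- if (ncol(X) < 2L) cbind(X, 0) else X
  z <- cbind(
    svr  = as.numeric(stats::predict(bundle@models$svr, X)),
    tree = as.numeric(stats::predict(bundle@models$tree, newdata = df)),
    enet = as.numeric(stats::predict(bundle@models$enet, newx = Xg,
                                     s = "lambda.min"))
  )
  if (!all(is.finite(z))) stop("non-finite base-learner prediction", call. = FALSE)
  z
}

#' Base-learner predictions as meta-learner features
#'
#' @param bundle a fitted [BaseModelBundle-class].
#' @param X standardized feature matrix.
#' @return `nrow(X)` x 3 matrix with columns (svr, tree, enet).
#' @export
makeMetaFeatures <- function(bundle, X) {
  stopifnot(is(bundle, "BaseModelBundle"))
  .predictBundle(bundle, X)
}

#' Fit the linear meta-learner
#'
#' Ordinary least squares of the holdout responses on the three base-learner
#' predictions plus an intercept. Rank-deficient designs (base learners are
#' often strongly correlated) get the minimum-norm least-squares solution
#' via the Moore-Penrose pseudoinverse.
#'
#' @param metaFeatures holdout x 3 matrix from [makeMetaFeatures()].
#' @param yHoldout holdout responses.
#' @return A [MetaModel-class].
#' @export
fitMeta <- function(metaFeatures, yHoldout) {
  Z <- as.matrix(metaFeatures)
  if (ncol(Z) != 3L) stop("meta features must have 3 columns", call. = FALSE)
  if (nrow(Z) != length(yHoldout)) stop("row/response length mismatch", call. = FALSE)
  if (nrow(Z) < 2L)
    stop(sprintf("need at least 2 holdout rows to fit the meta model, got %d",
                 nrow(Z)), call. = FALSE)
  A <- cbind(1, Z)
  coef <- drop(MASS::ginv(A) %*% yHoldout)
  new("MetaModel", intercept = coef[1L], coefficients = coef[2:4])
}

#' Fit a blending ensemble
#'
#' End-to-end fit on the training rows: (1) draw the holdout by the
#' configured sampler; (2) standardize features with base-training
#' statistics only; (3) fit the three base learners on the base-training
#' rows; (4) compute their predictions over the holdout; (5) fit the linear
#' meta-learner on those predictions. Each layer is trained once.
#'
#' @param G a [GenotypeMatrix-class].
#' @param y a [PhenotypeVector-class] or numeric vector aligned to `G`.
#' @param trainIdx integer indices of the training rows (default: all rows).
#' @param config a [BlendConfig-class].
#' @return A [BlendEnsemble-class].
#' @export
fitBlending <- function(G, y, trainIdx = seq_len(nSamples(G)),
                        config = blendConfig()) {
  stopifnot(is(G, "GenotypeMatrix"))
  v <- if (is(y, "PhenotypeVector")) y@values else as.numeric(y)
  if (length(v) != nSamples(G))
    stop("phenotype length must match genotype rows", call. = FALSE)
  trainIdx <- as.integer(trainIdx)
  parts <- splitHoldout(trainIdx, config, G = G, y = v)
  bt <- parts$baseTrainIdx; ho <- parts$holdoutIdx
  Xbt <- G@dosages[bt, , drop = FALSE]
  mu <- colMeans(Xbt)
  sg <- apply(Xbt, 2L, stats::sd)
  sg[sg < 1e-12] <- 1
  std <- function(M) sweep(sweep(M, 2L, mu, "-"), 2L, sg, "/")
  bundle <- fitBaseLearners(std(Xbt), v[bt],
                            settings = config@baseLearnerSettings,
                            seed = .deriveSeed(config@seed, 5L))
  Zho <- makeMetaFeatures(bundle, std(G@dosages[ho, , drop = FALSE]))
  meta <- fitMeta(Zho, v[ho])
  new("BlendEnsemble", bundle = bundle, meta = meta, config = config,
      holdoutIdx = ho, baseTrainIdx = bt,
      featureMeans = mu, featureScales = sg, markerIds = G@markerIds)
}

## predictions on selected rows of a genotype matrix (internal fast path)
.predictRows <- function(ensemble, G, idx) {
  X <- G@dosages[idx, , drop = FALSE]
  Xs <- sweep(sweep(X, 2L, ensemble@featureMeans, "-"),
              2L, ensemble@featureScales, "/")
  Z <- .predictBundle(ensemble@bundle, Xs)
  drop(ensemble@meta@intercept + Z %*% ensemble@meta@coefficients)
}

#' Predict phenotypes with a fitted blending ensemble
#'
#' Applies the meta-learner to the three base-learner predictions on the new
#' rows, after standardizing with the stored base-training constants. The
#' marker set must match the one the ensemble was trained on.
#'
#' @param object a [BlendEnsemble-class].
#' @param newdata a [GenotypeMatrix-class] or numeric dosage matrix with the
#'   training markers as columns.
#' @param ... ignored.
#' @return Numeric prediction vector, named by sample ID when available.
#' @export
setMethod("predict", "BlendEnsemble", function(object, newdata, ...) {
  if (is(newdata, "GenotypeMatrix")) {
    if (!identical(markerIds(newdata), object@markerIds)) {
      missing <- setdiff(object@markerIds, markerIds(newdata))
      stop(sprintf("marker set mismatch; %d training marker(s) missing%s",
                   length(missing),
                   if (length(missing))
                     paste0(" (first: ", missing[1L], ")") else ""),
           call. = FALSE)
    }
    p <- .predictRows(object, newdata, seq_len(nSamples(newdata)))
    names(p) <- sampleIds(newdata)
    p
  } else {
    X <- as.matrix(newdata)
    if (ncol(X) != length(object@markerIds))
      stop(sprintf("expected %d marker columns, got %d",
                   length(object@markerIds), ncol(X)), call. = FALSE)
    Xs <- sweep(sweep(X, 2L, object@featureMeans, "-"),
                2L, object@featureScales, "/")
    Z <- .predictBundle(object@bundle, Xs)
    drop(object@meta@intercept + Z %*% object@meta@coefficients)
  }
})
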