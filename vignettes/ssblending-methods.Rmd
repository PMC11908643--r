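---
title: "Stratified-sampling blending: model, design choices and limitations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Stratified-sampling blending: model, design choices and limitations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ssBlendR)
```

## The two-layer model

Blending predicts a quantitative phenotype from SNP dosages with two layers
trained once each. The training rows are split into a *base-training* part
(fraction `1 - H`) and a *holdout* part (fraction `H`). Three base
regressors are fitted on the base-training rows:

- epsilon-SVR with an RBF kernel (`e1071::svm`; cost 1, epsilon 0.1,
  gamma `1/m` — the package defaults),
- a CART regression tree (`rpart`, ANOVA method, default complexity),
- an elastic net with mixing 0.5 whose penalty is chosen by internal
  5-fold cross-validation (`glmnet::cv.glmnet`).

Their predictions over the holdout rows form a holdout-by-3 design on which
an ordinary-least-squares meta-model (with intercept) is fitted. Final
predictions are the meta-model applied to the three base predictions.

Two conventions deserve a note because the terminology in the field is
loose. First, `H` here is the fraction that trains the *meta*-learner; the
base learners see `1 - H`. This is the standard blending convention and is
what makes rates in the 0.1–0.6 range sensible. Second, the meta design
includes an intercept, and rank-deficient designs (the base learners are
often nearly collinear) are resolved by the minimum-norm least-squares
solution via the Moore–Penrose pseudoinverse rather than by erroring: on
full-rank designs this is exactly the normal-equations solution.

Features are standardized (per-marker mean/sd) using base-training
statistics only; the holdout and any test data are standardized with those
same constants, so no information leaks from holdout or test rows into the
base learners. Responses are left unscaled. Whether to standardize dosages
at all is an open choice in the field; standardizing makes the SVR kernel
and elastic-net penalty behave consistently across MAF spectra, and the
meta-layer is indifferent to it.

The elastic net is given an explicit 100-point lambda path down to
`1e-7 * lambda_max` instead of glmnet's automatic path. The automatic path
stops early once the deviance saturates, which prevents the learner from
reaching the near-least-squares limit on strongly determined, low-noise
systems; an explicit path makes "elastic net at vanishing penalty equals
least squares" hold to about `1e-3` in prediction, which the test suite
asserts.

## Stratified holdout sampling

Conventional blending draws the holdout uniformly at random. The two
stratified strategies replace that draw:

**CA (cluster analysis).** k-means with `K` centers (default `K = 8`
layers) on the raw dosage matrix; cluster memberships are the strata.
Sampling quotas are proportional to cluster sizes, so the holdout preserves
the genetic composition of the training set. Whether to allocate equally or
proportionally across clusters is genuinely open; proportional allocation
is the choice here because it keeps the holdout representative of the
population rather than over-weighting small, atypical clusters. Base R's
Hartigan–Wong k-means with `nstart = 10` and a seed-controlled restart loop
stands behind this step; duplicate-row degeneracies (which can break a
start) are retried, and a K larger than the number of distinct rows is
reduced with a warning. An optional top-variance marker filter
(`caTopVar`) bounds the clustering cost on very wide matrices.

**PP (phenotype probability).** The range `[min(y), max(y)]` is divided
into `K` equal-width intervals (last interval right-closed). A Gaussian
kernel density estimate with Silverman's rule-of-thumb bandwidth (`bw.nrd0`;
`nrd`/`SJ` selectable) is integrated over each interval by the midpoint
Riemann rule on 1000 abscissae, and the renormalized interval masses are
the sampling weights. The estimator and quadrature rule are deliberately
plain: at 1000 grid points the midpoint rule's error is far below the
sampling noise of any draw. Whether quotas should follow the integrated
mass or the empirical interval counts is ambiguous in principle; integrated
mass is the default (it is what the density construction is for) and
`ppEmpirical = TRUE` switches to counts. Empty intervals are dropped and
weights renormalized over occupied strata.

**Quotas.** Real-valued stratum targets `weight * round(H * n)` are
converted to integers by largest-remainder (Hamilton) apportionment — the
only standard scheme that guarantees the quotas sum to the target exactly —
with remainder ties broken toward the lower stratum index. A target
exceeding a stratum's occupancy is capped and the overflow redistributed
across the remaining strata in proportion to their weights, iterating until
feasible (always, since the total never exceeds n). With `K = 1` the whole
construction collapses to simple random sampling, which the test suite
verifies distributionally (subset-frequency comparison over thousands of
seeded draws at n = 8, H = 0.5).

## BestH tuning

Accuracy is sensitive to `H`, so the package tunes it: the training set is
split once (seed-fixed) 80/20 into an inner training part and an inner
evaluation part; each rate in the grid `0.10, 0.15, ..., 0.60` (11 values)
is fitted on the inner training part and scored by Pearson accuracy on the
inner evaluation part; the maximizer is BestH, ties breaking toward the
smaller rate (the cheaper meta-training set). The final model is refitted
on the full training set at BestH. One inner split — not repeated
cross-validation — keeps the cost linear in the grid size and preserves
blending's train-once character; the same stratification strategy is used
inside tuning as in the final fit so that tuning measures the procedure
actually deployed. The 80/20 inner ratio is a convention; nothing in the
procedure pins it, and it is exposed as `innerFraction`.

## The simulator

`simulateDataset()` implements `y = X beta + e` directly: per-marker allele
frequencies `p_j ~ Uniform(0.05, 0.5)`, dosages `Binomial(2, p_j)`
independent across markers and individuals, `nQtn` causal markers sampled
without replacement, effects `beta ~ N(0, 1)`, and residuals
`e ~ N(0, var(g) (1 - h2) / h2)` calibrated against the *realized* sample
variance of `g = X[, qtn] beta`. Calibrating to the realized rather than
expected genetic variance makes the realized heritability concentrate
tightly on the target (mean within about 0.005 of the target over 20
replicates at n = 1000); at `h2 = 1` the residual is exactly zero. The
scale of `beta` is immaterial because the residual calibration absorbs it.
`simulateGrid()` crosses `h2 in {0.2, 0.5, 0.8}` with
`nQtn in {200, 2000, 5000}` — nine genetic architectures, labelled
`h0.2_q200` through `h0.8_q5000`; QTN counts above `m` are capped with a
warning so the grid runs at reduced scale.

What the simulator does *not* emulate: linkage disequilibrium, population
structure, dominance or epistasis, and realistic allele-frequency spectra.
The genotypes are exchangeable noise with additive signal. Consequently CA
strata on simulated data are clusters of noise, and passing tests show that
the machinery is correct and unbiased — not that stratification will help
on any particular real dataset, where its value comes precisely from the
structure the simulator omits. On unstructured simulated data the three
variants are statistically close, which is the expected behaviour.

## Numerical and degenerate-input choices

- Missing dosages (NA or -9) are imputed at load with the per-marker mean;
  observed entries are never altered; zero-variance markers are kept but
  flagged.
- Constant responses: the base-learner bundle degenerates to a constant
  predictor; Pearson accuracy on constant vectors is an error by contract
  (the tuner converts it to `-Inf` for a rate, and errors only if every
  rate is undefined).
- All randomness is seed-derived: every function that draws takes a seed,
  internal streams are derived with a fixed integer hash, and the RNG state
  of the calling session is restored afterwards. Identical seeds give
  bit-identical ensembles, predictions and benchmark reports.
- Sample-ID alignment keeps the genotype-file order of the intersection;
  indices are 1-based throughout and never written to files (files carry
  IDs).

## Benchmarking and strategy choice

`runBenchmark()` repeats outer 80/20 splits (the outer ratio is a
configurable convention — nothing in the procedure fixes it), fits each
requested variant per split (optionally tuning BestH each time), scores
Pearson accuracy on the test rows, and reports per-method means plus the
improvement over conventional blending in percentage points
(`(acc - acc_blending) * 100`). The test suite runs these benchmarks at
reduced scale — typically n = 300–600 individuals, m = 200–500 markers, 10
repeats or 21 runs across the heritability grid — sizes chosen so the full
suite stays in the minutes range while the quantities under test (means
over repeats) are stable.

The skewness rule in `recommendStrategy()` encodes the qualitative
observation that PP works best when the trait is approximately normal:
near-symmetric traits (|adjusted Fisher–Pearson skewness| at or below 0.5,
a conventional "moderate skew" boundary, configurable) get PP, clearly
skewed traits get CA.

## Known limitations

- No LD, structure or non-additive genetics in the simulator (above).
- The regression-tree base learner is a standard CART tree; exotic tree
  induction schemes are out of scope, and any regressor with the same
  fit/predict surface could stand in.
- No quality control: call-rate/MAF/HWE filtering and dimensionality
  reduction are assumed done upstream; an optional top-variance filter for
  CA clustering is plumbing, not QC.
- Single-trait only; no significance testing of method differences — the
  benchmark reports means and per-repeat values so any downstream test can
  be applied.
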