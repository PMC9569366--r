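---
title: "TopoMed: models, assumptions, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{TopoMed: models, assumptions, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

TopoMed implements an analysis pipeline that links the strength of ordinal
parental-belief survey responses to multiscale topological properties of
youth resting-state functional brain networks and to cognitive task scores.
This vignette is the package's account of the underlying models, the
parameters that matter, and the choices made where the design was genuinely
open. It states no empirical result that the test suite or
`scripts/acceptance.R` does not itself compute.

## The analysis model

The pipeline starts at parcel-level BOLD time series (one matrix of
parcels x timepoints per run per subject) and proceeds in five stages.

**Connectivity.** `peakCrossCorr()` estimates, for each parcel pair, the
Pearson correlation of the overlapping segments at every lag in
`[-max_lag, max_lag]` (each lag re-centered and re-normalized), and stores
the signed value at the lag maximizing `|rho|`. With `max_lag = 0` this is
exactly the Pearson correlation matrix, which anchors the estimator to a
textbook oracle. `mutualInformation()` provides the method-dependence
check: a plug-in estimate (nats) from equal-width 2-D histograms, chosen
over kernel or k-NN estimators because it is deterministic and
hand-checkable (a deterministic two-bin mapping must give exactly
`ln 2`). When a subject has several runs, `selectRun()` keeps the run with
the lowest median upper-triangle connectivity: regions at rest are weakly
synchronized, and residual artifacts inflate apparent connectivity, so the
lowest-median run is the cleanest.

**Thresholding.** `populationThreshold()` computes, per subject, the
moderate-outlier cutoff `q = median + 1.5 IQR` of the upper-triangle
values, and returns the upper bound of the normal-theory 95% confidence
interval of the mean of `q`, i.e. `mean(q) + 1.96 sd(q)/sqrt(n)`. A
percentile-bootstrap variant is available (`method = "bootstrap"`). Values
at or above the threshold become edge weights; everything below —
including all negative correlations — is zeroed. A magnitude-based rule
(`on_abs = TRUE`) is exposed for sensitivity analyses, but the default
follows the reading that only moderate and high *positive* synchrony
constitutes an edge.

**Graph metrics.** `computeAllScales()` evaluates properties at three
scales: the whole-brain graph, each (network, hemisphere) induced
subgraph, and individual nodes. Per-metric weighting conventions follow
the common brain-connectivity-toolbox conventions while keeping every
metric oracle-checkable:

* global efficiency — mean inverse shortest-path distance on edge lengths
  `1/weight` (hop counts on the binary view); unreachable pairs contribute
  zero;
* global/local clustering — transitivity and per-node triangle density on
  the binary view, with a geometric-mean (Onnela) weighted variant behind
  a flag;
* modularity — weighted Newman–Girvan Q, solved *exactly* by exhaustive
  partition search for graphs of up to 8 nodes and by deterministic,
  seeded Louvain above that (small graphs therefore agree with a
  brute-force oracle to machine precision);
* small-worldness — `(C/C_rand)/(L/L_rand)` against 20 (configurable)
  degree-preserving Maslov–Sneppen rewirings, seeded; disconnected graphs
  are reduced to the largest component and flagged;
* natural connectivity — `ln((1/N) sum_k exp(lambda_k))`, evaluated in
  max-shifted form for numerical stability;
* spectral stability — the largest adjacency eigenvalue;
* eigenvector centrality — shifted power iteration (shift = max weighted
  degree, which makes the dominant eigenvalue unique on bipartite-like
  graphs without changing eigenvectors), scaled to unit maximum;
* median connectivity — within-network and network-to-rest medians on the
  *raw* pre-threshold values by default, avoiding threshold-induced zero
  inflation (a thresholded variant is available by passing the adjacency).

Metrics that do not exist on a given graph (clustering with no connected
triples, centrality of an edgeless graph) carry `NA`, never a silent zero.
The single exception is efficiency of an edgeless graph, which is a true
zero under the unreachable-pairs-contribute-zero convention.

**Inference.** `fitOLSStandardized()` z-scores continuous variables
(binaries and dummies are left unscaled) so coefficients are standardized
betas, drops incomplete rows listwise, and reports per-term p-values with
BH- or BY-adjusted companions. `runMediation()` fits the four path
models — belief to score (A), belief to property (B), property to score
(C), and the full model score ~ belief + property + covariates (D) — with
one common covariate set so the models are comparable. The indirect effect
is `a*b` (a from B, b from D) with Sobel inference
(`z = ab / sqrt(b^2 se_a^2 + a^2 se_b^2)`). `runModeration()` enters the
ordinal moderator as dummies against level 1 ("not at all") plus
property-by-level interactions, reports the simple slope at each level
with a delta-method SE, and measures the moderation effect size as
`f^2 = (R2_full - R2_reduced)/(1 - R2_full)`. `siteAdjustment()` predicts
multinomial site membership from demographics and appends each subject's
own-site probability as a covariate (inverse-probability weights behind a
flag). `splitSampleValidate()` repeats a seeded 75/25 split (100 repeats
by default) and reports per-repeat AIC and CV(RMSE) = RMSE(validation) /
|mean(observed validation outcome)|; a range normalizer is available for
outcomes centered near zero.

### Open design points and how they were decided

* **FDR families.** Which tests share a family is not dictated by the
  model. TopoMed adjusts within explicit, caller-visible sets: per-model
  terms inside `fitOLSStandardized()`, and the pair {indirect, direct}
  within one mediation analysis for classification ("partial" needs both
  significant, "full" a significant indirect effect with nonsignificant
  direct path). Callers running many belief-property-score triplets
  should pool the relevant p-values and call `fdrAdjust()` over the
  family they intend.
* **Ordinal coding.** Path models default to a linear-in-levels belief
  term (one beta per belief), matching single-coefficient reporting;
  dummy coding against level 1 is reserved for moderation and exposed as
  `ordinal_coding = "dummy_ref1"` elsewhere.
* **Covariate sets.** All four path models share the same covariates,
  including the motion-censored fraction whenever network measures appear
  in any of them, keeping parameter counts comparable across paths.

## The synthetic cohort generator

No generative model for this kind of data is canonical, so the generator
uses the simplest forms that reproduce every association the analysis
assumes, and its defaults *are* the emulated study conditions.

* **Covariates** (`generateCovariates()`): age ~ Normal(120, 9.6) months
  (median 120, IQR about 13), 52.1% female, 67.1% white, 19.7% Hispanic;
  income and education are cut from a correlated latent bivariate normal
  (r = 0.45) with bracket probabilities matching the emulated cohort's
  margins; BMI, family size, togetherness, uniform site assignment, and a
  motion-censored fraction bounded at 10% (the retention rule for runs).
* **Beliefs** (`generateBeliefs()`): each 5-level item is an ordinal cut
  of a latent normal with negative loadings (-0.25) on z-scored income and
  education, a family-level religiosity factor (loading 0.8) shared by the
  seven religious items, and a correlated (r = 0.4) family-values factor
  for the three non-religious items. Cut points are standard-normal
  quintiles, so with all loadings zero the levels are exactly uniform;
  with the defaults the latent variance exceeds one and the levels pile
  up at the extremes, the U-shape typical of belief surveys. Youth
  service attendance (0–4) and importance of religion (1–4) load
  positively (0.7) on mean religious-belief strength.
* **Time series** (`generateTimeSeries()`): zero-mean Gaussian signals
  with unit variance and a block covariance — within-network correlation
  0.5, between-network 0.08, runs of 375 frames (the run length of the
  emulated acquisition). Each subject carries a connectivity propensity
  (SD `subject_sd = 0.06` on the within-network correlation), and the
  targeted network's correlation is decremented by
  `belief_topology_d * subject_sd * (belief - 1)/4`, so the level-5 vs
  level-1 gap equals `belief_topology_d` subject-level SDs — the planted
  Cohen's d. The covariance is verified positive semi-definite before
  sampling. The last run adds a global artifact signal that *inflates*
  all pairwise correlations, the way residual motion does; the
  lowest-median selection rule then correctly prefers a clean run. (An
  elevated-white-noise corruption was rejected: it *lowers* median
  connectivity, so the selection rule would systematically pick the
  corrupted run and halve every retained correlation.)
* **Scores** (`generateTaskScores()`): on the standardized scale,
  score* = c' z(belief) + b z(mediator) + m z(belief)z(mediator) + small
  income/age/togetherness terms + Normal(0, noise_sd) noise, rescaled so
  the Flanker-like task has median 97 and IQR 19 (94/23 for the
  Card-Sort-like task; 10/4 for the Matrix-Reasoning-like score, which
  carries only the income term). Defaults plant a = -0.15, b = 0.15,
  c' = -0.10, moderation = -0.10, noise_sd = 0.97, so the standardized
  outcome has variance near one and fitted standardized betas estimate
  the planted values with negligible attenuation.
* **Two modes.** `mode = "matrix"` emits the mediator directly
  (`a z(belief) + sqrt(1-a^2) noise`) for fast statistics-only studies;
  `mode = "topology"` generates full time series and uses the subject's
  true targeted within-network correlation as the mediator, exercising
  the entire connectivity-to-metrics path.

**Why these conditions.** The population threshold is deliberately
conservative: per-subject `q` sits in the far tail of the mostly-null
connectivity distribution, and the signed peak-over-lags values of null
pairs are bimodal (near ±max|rho|), which further widens the IQR. Under
short runs or weak within-network synchrony the thresholded graphs are
empty. Runs of 375 frames with within-network correlation 0.5 yield
adjacency matrices in which the large majority of within-network edges
and essentially no between-network edges survive — sparse,
network-dominated graphs, which is the regime the analysis is about.

**What passing tests do and do not show.** The generator's signals are
temporally white, noise is Gaussian, effects are linear, and ordinal items
come from a single-factor latent model. Real BOLD is autocorrelated,
head-motion artifacts are structured, atlas geometry induces distance-
dependent correlations, and real effect transmission need not be linear.
Tests passing on this cohort demonstrate that the estimators recover the
structure they assume, with correct calibration under the null — not that
real data satisfy those assumptions. The planted topology d is recovered
cleanly from the subject-level property; estimating the property through
finite runs attenuates it, which is why the time-series route is checked
for direction and the effect-size band is checked on the subject-level
mediator.

## Numerical and determinism choices

* Peak-lag ties resolve to the smallest |lag|, negative before positive;
  the upper triangle is mirrored so the matrix is exactly symmetric and
  the lag matrix exactly antisymmetric.
* All generator stages, the Louvain optimizer, small-world rewiring,
  bootstrap thresholds, and validation splits run under locally scoped
  seeds (`withLocalSeed`), restoring the caller's RNG state; identical
  (config, seed) reproduces every artifact byte for byte.
* Percentages in survey summaries are rounded half-up to two decimals,
  matching printed-table conventions (`roundHalfUp()`), not R's
  round-half-even.
* Power iteration runs to a 1e-10 max-norm tolerance on the normalized
  iterate (tightened to 1e-12 where comparisons at 1e-8 are required).
* Degenerate inputs error with the offending identifier (zero-variance
  parcels, parcels missing from the map, aliased design columns, unknown
  survey levels, unknown config keys) rather than propagating NaN.

## Problem sizes used by the shipped tests

The test suite and acceptance script were sized for a single-CPU desk
run: null calibration uses 200 replicate cohorts of n = 500 in matrix
mode; power, recovery, and validation use matrix-mode cohorts of
n = 2000 (50–60 seeds); the end-to-end pipeline checks use 120 subjects,
32 parcels, and 200 timepoints; the planted-d band is measured as the
mean over replicate cohorts of n = 2000. These sizes are the package's
default demonstration scale, not limits of the implementation — the same
code paths run unchanged at larger cohort, parcel, and run sizes.

## Known limitations

* The mutual-information estimator has the usual plug-in bias (small
  positive MI for independent signals at finite T); tests budget for it.
* Small-worldness is undefined (NA) for triangle-free graphs and is
  computed on the largest component of disconnected graphs.
* The propensity-style site adjustment conditions on the own-site
  membership probability; it does not implement full inverse-probability
  weighting inference (the weight column variant is provided, but
  downstream fits treat it as data).
* The mediation classification depends on the chosen FDR family; users
  testing many triplets should adjust across their full family rather
  than relying on the per-call pair adjustment.
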