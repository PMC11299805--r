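---
title: "Detecting evolutionary singularities by phylogenetic posterior prediction"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting evolutionary singularities by phylogenetic posterior prediction}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phylopred)
```

## The problem

A lineage is an *evolutionary singularity* for a trait when its observed
value cannot be reconciled with what the pattern of correlated evolution
across its clade predicts for that branch. The motivating application is
relative brain size in canids: domestication is widely credited with
dramatic brain-size reduction in the dog, but that claim is usually made by
comparing the dog only with the grey wolf. The clade-level question —
*given body mass, the phylogeny, and how brain size covaries with body size
across all canids, is the dog's brain smaller than predicted?* — needs a
formal interspecific test. The same machinery applies post hoc to any other
tip that looks aberrant (in canids, the hibernating common raccoon dog).

## Model

Let `y` be log10 brain volume (ml) and `x` log10 body mass (g) across `n`
observed species, and `C` the Brownian-motion variance–covariance matrix of
the phylogeny (entry `C[i, j]` = root-to-MRCA path length, `C[i, i]` = the
tip's root-to-tip distance). With Pagel's lambda scaling the off-diagonal
of `C`,

    y ~ N( beta0 + beta1 * x , sigma2 * V(lambda) ),
    V(lambda) = lambda * C + (1 - lambda) * diag(C)

`lambda = 1` is pure Brownian residual evolution, `lambda = 0` makes
species independent. All logarithms in the package are base 10; masses are
grams, volumes millilitres, and the loaders reject any other unit
annotation.

### Priors and sampling

The Bayesian layer uses deliberately weak, standard defaults:

* `beta`: improper flat prior. Its full conditional is the Gaussian
  centred on the GLS estimate with covariance `sigma2 (X'V^-1 X)^-1`.
* `sigma2`: Jeffreys-style `1/sigma2`. Its full conditional is
  inverse-gamma `IG(n/2, S/2)` with `S` the `V`-inverse quadratic form of
  the current residuals.
* `lambda`: uniform on `[0, 1]`, updated by Metropolis with a reflected
  Gaussian proposal (initial SD 0.1). The proposal scale adapts only
  during burn-in (multiplicative Robbins–Monro step toward ~30%
  acceptance) and is frozen afterwards, so the retained chain satisfies
  detailed balance.
* tree identity: redrawn uniformly from the supplied tree set every
  iteration. This treats the random polytomy resolutions as exchangeable
  and marginalises the prediction over them rather than selecting among
  them; the alternative — treating the tree index as a sampled parameter
  with a likelihood-driven update — is deliberately not implemented.

Default chain settings are 100 burn-in iterations, 200 000 sampling
iterations, thinning 100 — i.e. 2000 retained samples, the standard
configuration for this analysis. The sampler is written in C++
(RcppArmadillo) but draws all randomness from R's RNG, so a single
`set.seed` derived from the configuration reproduces every run
bit-for-bit.

### Prediction and verdict

The focal species' trait value is *excluded from the fit* (supplying a
trait table that still contains the focal row is a hard error) while its
tip *remains in the tree*; the tip's covariances are used only at
prediction. For each retained sample the focal value is drawn from the
partitioned-Gaussian conditional

    mean = x_f' beta + c_f' V_obs^-1 (y - X beta)
    var  = sigma2 * ( v_ff - c_f' V_obs^-1 c_f )

with `c_f` the focal/observed covariance block of `V(lambda)` for that
sample's tree. The 2000 draws form the posterior-predictive distribution;
the species is declared a singularity when its observed value lies outside
the central 95% quantile interval. The one-tailed `p_below` (proportion of
draws below the observed value) is reported alongside because it is the
conventional summary for "how small is this brain relative to prediction";
the verdict itself is two-tailed.

## Preprocessing

* **Unit conversion.** Sources reporting brain mass are converted with the
  fixed published regression `log10(volume) = -0.102 + 1.053 log10(mass)`;
  the coefficients are constants, not refitted. Conversion applies only
  when volume is absent — an observed volume always wins.
* **Species means.** Multi-source records are averaged on the raw scale
  and then log-transformed (a log-scale averaging option exists). Species
  lacking any brain datum are removed loudly, into a rejection report with
  reason codes. Source weighting by sample size is not applied by default;
  the loader records `n_sources` so a weighted variant can be layered on.
* **Repeatability.** Whether multi-source species values are consistent is
  quantified by the one-way ANOVA intraclass correlation with the
  Lessells–Boag `n0` correction for unbalanced designs, truncated at 0
  when `MS_among < MS_within`. Confidence intervals come from a parametric
  bootstrap (normal components at the observed group sizes) because it
  behaves uniformly across unbalanced designs; the percentile interval is
  widened, if necessary, to contain the point estimate. The estimator is
  applied to values as supplied (hence exactly affine-invariant); a
  `log_scale` switch is provided for traits spanning orders of magnitude.

## Tree handling

* **Grafting.** Taxa missing from the source phylogeny (the dog next to
  the grey wolf; a dingo or an extinct relative for extra contrast near
  the focal split) are added by `graft_tip`, which attaches a new stem at
  a chosen depth along the sister's terminal branch. The paper-level
  analyses never specify those stem lengths, so they are explicit
  arguments with a documented short default (1% of the sister branch,
  stem length equal to attach depth, keeping ultrametry). All pre-existing
  pairwise covariances are provably unchanged.
* **Polytomy resolution.** Unresolved nodes are resolved by sequential
  random pairing of the node's children with zero-length new internal
  branches. Zero lengths mean every root-to-tip distance — and therefore
  the Brownian covariance structure — is identical across resolutions at
  non-polytomy entries, which is the conservative convention when no
  branch-length rule is available. For a trifurcation the scheme is
  exactly uniform over the three rooted resolutions (and the test suite
  checks this by chi-square against enumeration); for higher-order
  polytomies it is uniform over pairing histories, which slightly favours
  balanced shapes relative to uniform-over-topologies — immaterial here
  because the zero-length convention makes all resolutions
  covariance-equivalent anyway.

## Synthetic data: what it emulates, what it does not

`simulation_spec()` defaults define the package's reference study
conditions: 25 species (a canid-scale clade), Yule topology rescaled to
unit depth, allometric intercept −0.1 and slope 0.47 on log10 axes,
residual rate `sigma2 = 0.015` (≈0.12 log10-ml residual SD at the tips),
`lambda = 0.41` (the posterior mean scale reported for canid brain
allometry), predictor root state 3.8 log10 g with Brownian rate 0.25
(covering roughly 1–45 kg), three measurement sources per species with 10%
within-species CV. The generator reproduces the model's assumptions
*exactly* — Brownian predictor, lambda-scaled Gaussian residuals, a
deterministic additive shift on one focal tip, lognormal measurement
error. Passing calibration on these data therefore validates the
inferential machinery, not the model's adequacy for real clades: real
data bring non-Brownian evolution, correlated measurement error,
body-mass error in the predictor, and non-ultrametric uncertainty that
the generator deliberately omits (extinct, non-contemporaneous tips are
out of scope).

## Validation results computed by the test suite

The acceptance tests and `scripts/acceptance.R` recompute all of the
following; none is asserted from memory:

* exact agreement (1e-8) of the predictive moments with a brute-force
  partitioned-Gaussian oracle, and of the GLS log-likelihood with a direct
  multivariate-normal density;
* conjugate-oracle agreement of the fixed-lambda sampler with the
  closed-form posterior mean (within Monte Carlo error over 20 random
  small instances);
* calibration of the 95%-CI rule over 500 null replicates at reduced
  chain length (20 000 iterations, thinning 10). Two designs are run.
  The test suite draws the focal "observation" from the *fitted*
  posterior predictive, which must escape its own 95% interval 5% of the
  time — a self-consistency check of the interval and verdict machinery.
  `scripts/acceptance.R` additionally measures the frequentist type-I
  error at fixed generator-truth parameters, with lambda estimated and
  with lambda fixed at its generating value. Individual 150–500-replicate
  batches carry a binomial standard error near 1–1.5%, and across the
  batches we have run the estimated-lambda rate averages slightly below
  the nominal 5% at n = 25 while growing the clade moves it toward
  nominal — mild small-sample conservatism consistent with parameter
  (especially lambda) uncertainty widening the predictive interval. A
  conservative outlier test understates, never overstates, evidence for
  singularity, which is the safe direction for this application;
* power ≈98% against a focal deficit of 3 conditional predictive SDs
  (the deficit is applied to the focal tip's true conditional mean, i.e.
  it replaces the tip's own residual draw, isolating the shift being
  tested);
* posterior-mean recovery of the slope within ±0.05 and lambda within
  ±0.15 over 50 replicate studies;
* repeatability: exact match to the hand-computed variance-components
  table on a balanced toy, and ≥90% bootstrap-CI coverage of the panel
  intraclass correlation.

Replicate counts (500/200/50) and the reduced chain length were chosen
once as the package's reference validation sizes — large enough that the
binomial error on each rate is well inside the asserted bands.

## Numerical choices

* All covariance solves go through Cholesky; a near-singular matrix gets
  one retry with a `1e-10` relative diagonal jitter (logged). Zero-length
  cherries among *observed* tips are the usual cause; jitter leaves
  results unchanged at the reported precision.
* Non-positive conditional predictive variances (possible at
  `lambda -> 1` with a zero-length focal cherry) are clipped at `1e-12`
  and counted in the result object.
* Lambda profiling evaluates a grid then refines by golden-section
  search; exact likelihood ties break toward the smaller lambda (the
  flat-likelihood case, e.g. a star tree, thus reports 0).
* Trait simulation draws multivariate normals via eigendecomposition with
  negative eigenvalues clamped at zero, tolerating the PSD-but-singular
  covariances that zero-length branches create.
* Tip labels are normalised (spaces to underscores) at every load point;
  matching is otherwise exact and case-sensitive.

## Limitations

* Single predictor only; no measurement-error model for body mass; no
  OU/kappa/delta alternatives to lambda-scaled Brownian motion.
* The tree set enters as exchangeable draws; posterior tree weights are
  not computed.
* The 95% rule at 25 species is conservative (see above); users comparing
  a marginal `p_below` against 0.025/0.05 should remember the verdict is
  defined by the credible interval, not by the one-tailed proportion.
* Reproducing a published canid analysis requires that study's species
  trait table and dated tree; the package ships only the printed per-breed
  focal values plus a synthetic backbone generator, so cross-study numeric
  agreement cannot be checked offline.
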