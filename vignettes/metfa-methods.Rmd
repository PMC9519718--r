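---
title: "Methods: integrated factor analytic mixed models for MET data"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: integrated factor analytic mixed models for MET data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette documents the statistical model, the estimation machinery,
the design decisions taken where the design was genuinely open, and the
limits of what the synthetic-data validation shows. It states no empirical
result beyond what the test suite and `scripts/acceptance.R` themselves
compute.

## Model

Plot-level phenotypes from `v` genotypes in `p` environments (each with
one or more trials containing complete replicate blocks) follow

$$ y = X\tau + Zu + Z_p u_p + e, $$

where `tau` holds one fixed mean per environment, `u` is the
`vp`-vector of additive genotype-by-environment (GE) effects with
$\mathrm{var}(u) = G_e \otimes G_g$, `u_p` holds random block-within-trial
effects with one variance per environment, and `e` has independent
per-environment residual variances. $G_g = MM'/m$ is the VanRaden genomic
relationship matrix from `m` column-centred marker scores (an identity
relationship is accepted for marker-free analyses). All variance matrices
are aligned at the environment level. Two-dimensional spatial residual
models are deliberately outside the package's scope; the per-environment
iid residual takes their place.

Optionally the fixed effects can be re-expressed as an overall mean plus a
fixed regression on the known covariates with a random residual
environment effect (`fit_options(fixed_covariates = TRUE)`, variance
`sigma2_omega`); the default keeps per-environment means, the classical
"environments as correlated traits" treatment.

### Variance families

`vm_spec()` declares $G_e$. Latent families (`fa`, `fam`) regress GE
effects on estimated environmental loadings; `fam` adds explicit genotype
intercepts whose simple main effects are plain averages across
environments. Known-covariate families regress on the prepared covariate
matrix `S` (each column centred and scaled to unit length): `rreg1`/
`rreg2` without translational invariance, `far` with a reduced-rank factor
model across the main effect and all covariate slopes (translationally
invariant). The integrated family `ifa` writes the loadings as
$\Lambda = S\Lambda_s + \Gamma\Lambda_r$ with $\Gamma$ an orthonormal
basis of the orthogonal complement of $\mathrm{col}(S)$, so factors mix
known (predictable) and latent (observable) directions while staying
translationally invariant.

Two constructions deserve note:

* **Projection basis.** $\Gamma$ is taken as the first $p-q$ columns of
  $I - S(S'S)^{-1}S'$ and then orthonormalised by QR. The leading columns
  of the projector can be ill-conditioned; orthonormalising preserves the
  chosen subspace (the package verifies the projector leaves $\Gamma$
  invariant) while guaranteeing a full-rank $B=[S\,\Gamma]$. When fewer
  latent columns are wanted (`n_latent`), the leading columns after
  orthonormalisation are kept, deterministically.
* **Reduced latent rank** (`ifa` with `k_r < k`): the latent block
  $\Lambda_r$ has structurally zero columns beyond `k_r`. This is the only
  reading consistent with the published parameter count of the
  4-known/3-latent configuration (108 at `p = 24`, `q = 18`), which
  `count_parameters()` reproduces by enumerating free entries.

## Estimation

REML estimates maximise the residual log-likelihood by
average-information (AI) updates. During estimation the factor families
use the standard identification constraints: score variances fixed at
one and zeros in the upper-right of the stacked loadings.

* **Likelihood evaluators.** Two exact evaluators share the AI loop. The
  general evaluator assembles the mixed model equations with the
  Kronecker inverse $G_e^{-1}\otimes G_g^{-1}$ and handles any design
  (missing plots, unequal replication). For balanced complete-block
  designs an eigen-rotation of the genotype dimension
  ($G_g = QLQ'$) decouples the GE block into one $p\times p$ system per
  eigen-coordinate plus a low-rank absorption correction, reducing the
  per-iteration cost from cubic in `vp` to linear in `v`. The two agree to
  numerical precision (tested), and a third, independent dense textbook
  implementation in the test helpers checks both.
* **Safeguards.** Steps are halved when the likelihood decreases;
  parameters pinned at a bound with negative gradient are held fixed for
  that round (active set); the AI matrix is Levenberg-regularised when
  needed. Specific variances have a floor (`psi_floor = 1e-8`) so $G_e$
  stays invertible, diagonal-essential variances of the `id`/`diag`/
  `comp`/`mdiag` families share it, and residual variances are floored
  relative to the phenotype variance. A numerically semidefinite $G_e$ is
  rejected outright rather than risked through a near-zero Cholesky pivot.
* **Convergence** when the maximum relative parameter change is below
  `1e-6` and the relative likelihood change below `1e-8` (both
  user-settable); the iteration trace is stored on the fit and accepted
  steps never decrease the likelihood.
* **Starting values** are deterministic: block means are swept before
  forming genotype means; per-environment residual and block variances
  come from the within-genotype residual mean square; the genetic
  structure is seeded from the leading eigenvectors of the regularised
  sample genetic covariance, rotated into the constrained form, with
  specific variances taking the remainder of the diagonal.
* **GRM ridge.** $MM'/m$ from centred markers is rank deficient (zero row
  sums). When $G_g$ is numerically singular a ridge of
  `1e-6 * mean(diag(G_g))` is added inside the solves (settable via
  `fit_options(grm_ridge=)`) and reported on the fit.
* **AIC** is $-2\ell + 2m$ with `m` counting estimated variance
  parameters only — genetic plus `p` block plus `p` residual (plus one
  when the random environment term is on). Fixed effects are not counted;
  this is the convention that reproduces published MET model-selection
  tables from their likelihoods and counts.

## Rotation and interpretation

`rotate_solution()` maps constrained estimates to principal axes through
the SVD $B\Lambda^{*} = UD^{1/2}V'$: composite loadings become the
orthonormal `U`, score variances the squared singular values in
decreasing order, and scores rotate in tandem, leaving $G_e$ and all
fitted effects unchanged (tested to `1e-10`). Sign convention: factor one
is oriented so its mean loading is positive — in small datasets fitted
first factors can have mixed signs, in which case a warning lists the
negative-loading environments rather than failing silently; higher
factors are oriented to non-negative mean loading, exact zeros left
alone. `B^{-1}` is applied by linear solve, never an explicit inverse.

Variance-explained measures follow the standard definitions:
$\bar v = 100\,\mathrm{tr}(D)/\mathrm{tr}(G_e)$,
$\bar v_s = 100\,\mathrm{tr}(S\Lambda_s D \Lambda_s'S')/\mathrm{tr}(G_e)$,
with per-environment, per-factor and per-covariate decompositions.
Per-environment `v_sj` may exceed `v_j` (known and latent covariates are
not orthogonal environment-wise); no clipping is applied. Per-covariate
shares need not sum to $\bar v_s$ because covariates are correlated;
per-factor shares do sum exactly (tested to `1e-10`). For the
environment-correlation heatmaps, correlations are computed from the
common-factor part only (known part, or known plus latent), excluding the
specific variances so the two views are comparable; a flag re-includes
them. Display order comes from average-linkage agglomerative clustering
on one minus the correlation, with ties resolved deterministically by the
clustering algorithm's input order.

Two printed conventions are followed as printed, not "corrected": the
IFA generalised-main-effect mean latent loading divides by `p` (not
`p - q`), and in leave-one-environment-out prediction the latent mean
loading of a training fit divides by `p - 1` while future-environment
prediction divides by `p`. The covariate-wise "covariance" column of
summary tables is exposed only through the squared-projection shares
(`v_li`), as its published definition (a square root of a squared
quantity) does not determine a sign.

## Prediction and cross-validation

`loeo_cv()` refits the whole model for each left-out environment —
loadings, score EBLUPs, everything — on the remaining `p - 1`
environments. Covariates are re-centred and re-scaled on the training
environments only, and the latent basis is rebuilt, so no information
from the left-out environment reaches the fit (a perturbation test
asserts this exactly). The left-out environment's covariates are
transformed with the training offsets and divisors. Scores are
genotype-level quantities and need no data from the target environment.
Observed genotype means are simple arithmetic means of non-missing plot
values. Accuracy is the Pearson correlation over genotypes with data in
the environment, undefined (flagged, never fabricated) below three such
genotypes. Families without a predictable component (`fa`, `fam`) refuse
environment prediction rather than returning a constant.

## The synthetic MET generator

`simulate_met()` draws data with exactly the generative structure the
models assume: scores $f \sim N(0, D\otimes G_g)$, deviations
$\delta \sim N(0, \Psi\otimes G_g)$, environment means, block effects and
residual noise per environment, assembled into complete replicate blocks
with a configurable missing-plot rate (masking never removes a genotype
from every environment). Defaults emulate a late-stage row-crop MET:
environment means 1.7 (sd 0.4, yield-like units), mean per-environment
additive genetic variance ≈ 0.03 with roughly three quarters in the
common factors and the rest specific, block variance 0.02, plot residual
variances 0.04–0.10, missing rate 6.54%, two replicate blocks. For the
integrated family the generated first factor is predominantly latent with
all-positive loadings (non-crossover GEI, known share ≈ 20%) and higher
factors predominantly known-covariate-driven (crossover GEI, known share
≈ 90%): this mirrors the structure that fitted integrated models
typically report on real METs — the first factor carries scale
heterogeneity while weather- and soil-driven factors carry rank changes —
and it is also what makes the known-loading subspace
statistically identifiable — with a vanishing known component a factor's
known direction is undetermined and no estimator could recover it.

What the generator does **not** emulate — and hence what passing tests do
not establish about real data: spatial field trend and AR1×AR1 residual
correlation; partially overlapping trial designs where different subsets
of genotypes appear per trial; selection and relatedness drift across
cycles; multi-year transient GEI; covariate measurement error. Marker
simulation is binomial per locus without linkage.

## Validation problem sizes

The suites use deliberately chosen sizes: dense-oracle likelihood checks
on all ten families at `v` 17–25, `p` 4–5 with 7% missing plots (five
seeds each); IFA/FA equivalence at `p = 6`, square basis, `k` 1–2;
parameter recovery at `v = 200`, `p = 16`, `q = 4`, two blocks, twenty
seeds (trace of $G_e$ within 15%, known-subspace principal angle within
15 degrees on average); cross-validation null calibration over 200
pure-noise replicates at `p = 4`, `v = 20`. These sizes exercise every
code path (both evaluators, missing data, all families) while keeping a
full run in the minutes range on a single core.

## Known limitations

* The independent (non-translation-invariant) integrated formulation is
  not implemented; only the dependent formulation is.
* Spatial residual modelling, pedigree relationship matrices,
  allele-frequency-weighted GRM variants, multi-trait models and Bayesian
  estimation are out of scope.
* `rreg1`/`rreg2` are fitted as specified but are neither scale nor
  translationally invariant; the invariance tests cover `far`/`ifa` only.
* With `k` close to the number of informative directions, factor
  solutions can collapse (a zero singular value); rotation then fails
  loudly with the factor index rather than returning an arbitrary basis.
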