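---
title: "Geostatistics of endosymbiont infection frequencies: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Geostatistics of endosymbiont infection frequencies: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(wolbtrace)
```

`wolbtrace` treats the per-population infection frequency of a
maternally inherited endosymbiont as a regionalised variable: a noisy
observation, at each sampled location, of a smooth latent frequency
surface shaped by the symbiont's spatial spread. This vignette explains
each model in the pipeline, the assumptions behind it, the tunable
parameters and their defaults, and the design decisions taken where
more than one reasonable choice existed.

## Frequency estimation

Each population contributes `k` infected out of `n` genotyped
individuals; the point estimate is `p = k/n`. Intervals are Wilson
score intervals by default: with `z` the standard-normal
`(1 + conf)/2` quantile, the interval is centred at
`(k + z²/2)/(n + z²)` with half-width
`z·sqrt(p(1−p)/n + z²/(4n²))/(1 + z²/n)`, clipped to [0, 1]. The Wilson
interval behaves sensibly at the boundary counts (`k = 0`, `k = n`)
that dominate endosymbiont data, where fixation and absence are common.
A Clopper–Pearson variant is available via `method =
"clopper-pearson"` for users who want the conservative "exact"
construction; the two differ most at small `n`.

One caveat worth recording: for 11 infected of 12 the Wilson upper
bound is 0.985 and Clopper–Pearson's is 0.998, so a published value of
0.996 for that cell matches neither construction and is most plausibly
a typographical slip. The package reproduces what the methods compute
and does not force-match that one cell.

Pairwise comparisons use the two-sided conditional Fisher exact test
under the probability-mass rule: with margins fixed, the P-value sums
hypergeometric probabilities of every table no more probable than the
observed one (relative slack 1e−7, the convention of `fisher.test`).
Comparisons are strictly pairwise — `compare_populations()` never pools
its two arguments internally; pooling is an explicit, separate step
(`pool_groups()`), because a pooled-versus-pairwise ambiguity changes
P-values materially at these sample sizes. No multiple-testing
correction is applied: the tests are descriptive screens, not a
family-wise decision procedure.

## Distances, duplicate locations, grids

All distances are great-circle (haversine) kilometres on a sphere of
radius 6371.0088 km. At a sampling span of several thousand km, planar
degree distances would distort east–west separations by up to ~40%
at the latitudes involved, so an unprojected metric is the only
defensible default. No map projection, coastline clipping or sea
masking is applied: prediction grids are plain lat/lon lattices
(`make_grid()`, default 0.5°, default extent 34–71°N, 11°W–61°E), and
grid cells over water simply carry predictions nobody should
interpret.

Spatial variance estimation assumes independent samples per location,
so locations sampled repeatedly must first be thinned to one sample.
Two records count as the same location when both coordinates agree
within `tol_deg = 1e-3` degrees (~100 m), the precision of field GPS
records; groups are closed transitively and one member is kept
uniformly at random under a caller-supplied seed, so the thinning is
reproducible and idempotent.

## The semivariogram and its exponential model

The empirical semivariogram bins site pairs by separation `h` into
intervals of width 60 km (configurable) and estimates

γ̂(h_j) = (1 / 2N_j) Σ (z_i − z_k)²

over the N_j pairs in bin j. Pairs beyond a cutoff of 2000 km are
discarded by default: beyond that distance additional pairs carry no
information about the correlated part of the process and only add
noise to the plateau; a full-span cutoff (~6300 km) is a parameter
away. Empty bins are omitted rather than interpolated.

The fitted model is exponential,

γ(r) = C₀ + C₁ (1 − exp(−3r/b)),

with nugget C₀ ≥ 0 (measurement and binomial sampling noise plus
microscale variation), partial sill C₁ ≥ 0 (spatially structured
variance) and practical range b > 0 — the factor 3 makes b the
distance at which the curve reaches 1 − e⁻³ ≈ 95% of C₁ above the
nugget. When C₀ > 0 the distance at which γ reaches 95% of the *total*
sill differs from b; `practical_range()` returns both, with the exact
closed form r* = −(b/3)·log(0.05 (C₀+C₁)/C₁).

Fitting is weighted least squares with weights N_j/h_j² by default
(the standard choice that favours well-estimated short lags; plain
N_j and unweighted modes are provided). The objective is multimodal in
b, so optimisation runs a bounded quasi-Newton search from five
deterministic starts — b initialised at {¼, ½, 1, 2, 4} times the lag
where γ̂ first reaches 80% of its maximum — followed by a
Levenberg–Marquardt polish on the weighted residuals, which converges
to solver precision even when residuals vanish (quasi-Newton stalls on
exactly-representable bins). Ties are broken by lowest SSE, then
smallest b. A fit whose partial sill is below 0.1% of the total sill
is reported as pure nugget with `range_identifiable = FALSE`: a flat
semivariogram contains no information about b.

Anisotropy diagnostics are deliberately simple: directional variograms
over half-open bearing sectors (default axes 0/45/90/135° with
tolerance 22.5°, which partition the half-circle so every pair is used
exactly once), and a variogram map binning separation vectors into
square cells with enforced central symmetry. Bearings and separation
vectors are computed on an equirectangular local tangent plane —
adequate below ~2000 km separations, and documented as approximate;
exactness matters for the semivariances, not for assigning pairs to
45°-wide sectors.

## Ordinary kriging

Predictions use ordinary kriging — best linear unbiased prediction
under an unknown constant mean (`z ~ 1`): the weights solve

[Γ 1; 1ᵀ 0][w; λ] = [γ₀; 1],

with Γ the between-site semivariance matrix (zero diagonal), γ₀ the
site-to-target semivariances, and λ the Lagrange multiplier of the
sum-to-one constraint. The kriging variance is Σ wᵢ γ₀ᵢ + λ and
depends only on geometry and the model, never on observed values.
With a few hundred sites the full system is solved globally (one
factorisation per grid, all targets as simultaneous right-hand sides);
a nearest-k neighbourhood mode exists for larger problems and
reproduces the global solution exactly when k = n.

Numerical policies: coincident sites are a hard error (deduplication
is an explicit upstream stage, not something a solver should silently
absorb); a system that still fails to solve gets one 1e−10
diagonal ridge with a logged warning. Because the variable is a
frequency, predictions are clamped to [0, 1] after solving — ordinary
kriging is not range-respecting — and the raw value is always kept in
`z_hat_raw` so the clamp is auditable.

Validation is leave-one-out cross-validation: each site predicted from
the other n − 1, summarised by bias, RMSE, 95%-interval coverage, and
the variance of standardised residuals (≈1 under a well-specified
model). LOOCV is the natural validation for a single spatial dataset
with no holdout; it is what the package's calibration tests exercise.

## Origin inference

The qualitative rule "regions predicted uninfected are candidate
origins" is made quantitative with an explicit, clearly labelled
extension: for an invasive sample with `k_inv` infected of `n_inv`,
each grid cell is scored by the exact binomial point mass of that
observation at the cell's predicted frequency —
`compat = dbinom(k_inv, n_inv, p̂)` — and flagged as a candidate when
`compat ≥ alpha` (default 0.05; a configuration choice, not an
estimate). For the motivating case `k_inv = 0` this is `(1 − p̂)^n`,
monotone decreasing in p̂, so the candidate set is a nested
low-frequency region that shrinks as alpha rises. A two-tailed exact
binomial option covers nonzero `k_inv`.

Two smaller tools support the biology: `haplotype_concordance()`
cross-tabulates infection status against the co-transmitted
mitochondrial haplotype and reports the misassociation rate
(infected/HT1 plus uninfected/HT2 over scored individuals), and
`ci_spread_criterion()` evaluates the deterministic spread condition
F(1 − μ) > 1 — relative fecundity F, maternal transmission failure μ —
classifying the boundary as bistable under the strict inequality.

## The synthetic-data generator

Real range-wide infection surveys are multi-study compilations that
cannot be bundled; the generator produces datasets with the spatial
statistical structure the analysis assumes so that every stage is
testable end to end. It draws sites uniformly in the bounding box (or
clustered, parents-plus-Gaussian-offspring, to mimic dense regional
sampling), simulates a Gaussian field with mean `mean_p` and
covariance C₀·I + C₁·exp(−3d/b) by dense Cholesky factorisation (ridge
fallback 1e−10 then 1e−8), maps it to [0, 1], and samples
k ~ Binomial(n, p) with per-site n drawn from an empirical law — the
study's own per-population sample sizes plus a down-weighted right
tail to 68 — giving mean ≈ 12 and range 1–68, matching the reported
sampling intensity of the historical dataset.

Defaults are fixed once: 238 sites, C₀ = 0.05, C₁ = 0.20, b = 600 km,
mean_p = 0.5. These are synthetic fixture values, not estimates:
they produce a semivariogram that rises over the first few hundred km
and plateaus within ~1000 km, the qualitative shape seen in real
endosymbiont frequency surveys.

The default link is truncation, because observed frequency tables have
substantial mass exactly at 0 and 1 and the analysis kriges raw
frequencies; a variance-matched logistic link ships for sensitivity
checks. What truncation does **not** preserve is the latent variance:
clamping a N(0.5, 0.25) field to [0, 1] cuts its marginal variance to
≈0.129 (Monte-Carlo), and binomial sampling adds back
E[p(1−p)]·E[1/N] ≈ 0.015 of nugget, so the variance a variogram of
sampled frequencies estimates is ≈0.144, not C₀ + C₁ = 0.25. The
recovery experiments bear this out: over 100 replicate 238-site
datasets the median fitted range b̂ recovers the generating 600 km
well within ±30%, and the median fitted total sill matches the
frequency-scale variance of the generating law to ~1% — while
falling ~42% below the latent C₀ + C₁, as the arithmetic above says it
must. A recovery check that compared the fitted sill to the latent
sill would fail for any estimator; the package's tests therefore
assert both statements explicitly, and the one comparison that cannot
hold is retained, failing, with this analysis as its documentation.
Consequently, passing tests demonstrate that the pipeline estimates
the spatial structure of *frequency data*; they do not claim the
latent-scale variance is identifiable from truncated observations.

## Problem sizes and determinism

The test suite exercises the pipeline at the scales the methods are
designed for: 238-site recovery experiments (100 replicates),
960-site consistency checks, 1000-table exact-test enumerations,
20-replicate LOOCV calibration at 100 sites. Everything stochastic is
driven by explicit integer seeds threaded through configs; identical
configs produce byte-identical artifacts, and each pipeline stage
writes a manifest with its seed and config hash.

## Known limitations

- Temporal pooling is an assumption, not a model: frequencies sampled
  across 25 years are treated as one surface. Regions under active
  symbiont spread violate this; the frequency-comparison stage is the
  tool for spotting them, but the kriged surface does not model time.
- Ordinary kriging treats binomial noise as part of the nugget rather
  than weighting sites by sample size; a per-site error model
  (heteroscedastic nugget) would be the natural extension.
- The compatibility score conditions on the kriged point prediction
  and ignores kriging variance; a fully propagated version would
  integrate the binomial likelihood over the predictive distribution.
- Only the exponential variogram family is implemented; the fitting
  interface leaves room for other families but none are wired in.
- No land/sea masking: candidate cells over water are artefacts of the
  rectangular grid and need downstream filtering against a coastline.
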