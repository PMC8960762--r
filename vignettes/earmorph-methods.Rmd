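---
title: "Methods: middle-ear morphometry and phylogenetic comparative analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: middle-ear morphometry and phylogenetic comparative analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(earmorph)
```

`earmorph` implements a complete comparative workflow for avian middle-ear
morphology: landmark-based trait measurement, allometric phylogenetic
regression with model selection, ordination of size-corrected traits, and a
Bayesian ordinal model for interaural connectivity. This vignette records the
models, their assumptions, the numerical choices, and the design decisions
that were genuinely open.

## Landmark morphometry

A specimen is digitised as named 3D points (umbo, columella tip,
extrastapedius tip and base, footplate centre) and ordered rings (tympanic
rim, footplate rim, round-window rim, cochlear-aqueduct rim), all in
millimetres (`landmark_set()`, `read_fcsv()`).

**Base planes and areas.** Anatomical apertures are nearly planar but never
exactly so. Every area is therefore the shoelace area of the ring projected
onto its own total-least-squares plane (SVD of the centred ring; normal =
smallest singular vector). Projecting onto the ring's own plane — rather than
a global axis — makes all measures invariant to rigid motion of the specimen,
which the test suite checks to 1e-9 relative. Collinear rings and
self-intersecting projected polygons are errors, not silently repaired: a
crossing projected outline means a digitisation fault that an area cannot
summarise honestly.

**Conical-eardrum traits.** Umbo height is the unsigned distance from the
umbo to the tympanic-rim plane (landmarks do not encode which side is
lateral, so the sign is not meaningful). The membrane angle is the mean,
over rim points, of the angle between the rim-to-umbo segment and the base
plane; for a right cone of height h over a rim of radius r every summand is
atan(h/r), which the tests exploit as an exact oracle. The columella offset
is measured in-plane (projection onto the base plane) rather than in 3D;
the in-plane reading is the one that determines the second-order lever, and
it keeps the measure independent of how deep the tip sits.

**Lever arms.** The published figure leaves the lever fulcrum unspecified.
We define it as the rim point nearest the projected columella tip. This
convention has the property the figure implies: as the columella moves to
the eardrum centre the ratio l1/l2 falls monotonically to 1 (no lever), and
for a tip lying between fulcrum and umbo the ratio is ≥ 1 (a second-order
lever).

**Species means** average each component measure arithmetically and then
*recompute* the two ratio fields from the averaged components, so a species
record satisfies the same internal identities (area_ratio = TM/footplate,
lever_ratio = l1/l2) as a specimen record. Averaging ratios directly would
not.

**Repeatability** is one-way random-effects ICC(1,1),
(MSB − MSW)/(MSB + (k0 − 1)·MSW) with the standard unbalanced-design
replicate coefficient k0; the estimator form is our choice since the study
context does not pin one down.

## Phylogenetic regression

All continuous traits and head mass enter on the natural-log scale. The
natural-log convention is fixed by the reporting identity the package uses:
a group coefficient β means the group's trait value is 100·exp(β) percent of
the reference group's at equal head mass (e.g. β = −1.20 → 30 %,
β = −2.7 → 7 %).

`fit_pgls()` fits y = Xβ + ε with ε ~ N(0, σ²C(λ)): C is the Brownian
covariance of the tree (shared root-to-ancestor path lengths, computed via
ape and not assumed ultrametric), and C(λ) multiplies its off-diagonals by
Pagel's λ ∈ [0, 1]. λ = 0 is an ordinary regression; λ = 1 keeps the full
tree structure. λ is estimated by profiling the multivariate-normal ML
log-likelihood with a bounded scalar optimizer (tolerance 1e-6) run on each
half of [0, 1] and compared against the λ ∈ {0, 0.5, 1} anchor values, so a
locally flat profile cannot trap the search; boundary optima are legitimate
estimates. Fits use ML rather than REML throughout because AICc comparisons
span different fixed-effect structures.

**Parameter counting.** AICc = −2ℓ + 2k + 2k(k+1)/(n−k−1) with k counting
the regression coefficients *plus σ² and λ*, since both are ML-estimated.
Other software counts differently; the convention is stated here so
cross-checks can adjust.

**Model selection** follows the parsimony rule: among candidates within
ΔAICc < 2 of the minimum, pick the fewest-parameter model, breaking ties by
lower AICc. The all-species candidate set is {head mass, + group,
× group} with terrestrial as reference; aquatic-only analyses add
{+ dive score, × dive score} with surface-foraging as reference. Dive score
enters as a numeric 0–4 covariate (a single slope), matching the additive
phrasing of the candidate set, not as an ordered factor.

**Coefficient tests** are two-sided t tests at α = 0.05 with n − p degrees
of freedom, using standard errors from the unbiased residual variance.
Adjusted R² is computed on the λ-whitened GLS scale against the GLS
intercept-only fit; it is reported for comparability but never used for
selection.

## Phylogenetic PCA

The pPCA input is, by pipeline wiring (asserted in tests), exactly the
matrix of head-mass-only PGLS residuals per trait. The GLS root state
a = (1ᵀC⁻¹1)⁻¹1ᵀC⁻¹X centres the data; the evolutionary covariance
E = (X−1a)ᵀC⁻¹(X−1a)/(n−1) is eigendecomposed; scores are (X−1a)V.
Two open choices were resolved as follows:

* λ is fixed at 1 inside the pPCA (an option allows any value): the
  residuals are already size-corrected, and re-estimating λ per component
  would entangle ordination with signal estimation.
* Covariance mode is the default (an option allows correlation mode): the
  inputs are residuals in comparable natural-log units, so rescaling each
  trait to unit variance would discard real differences in evolutionary
  variability.

Component signs are fixed (largest-magnitude loading positive) so repeated
runs are identical. On a star tree with equal tip lengths the procedure
collapses to ordinary covariance PCA, which the tests verify to 1e-8.

## Ecological classification

Maximum dive depths (m) map to the 0–4 score with bins <1, 1–10, 10.1–30,
30.1–100, >100. As printed, the bins leave (10, 10.1) undefined; depths are
rounded to one decimal before binning, which makes the one-decimal bin labels
a total partition and is the resolution at which such depths are reported.
Group labels are normalised to four canonical tokens; anything else is an
error naming the offending rows. Terrestrial species without depth data
score 0 by definition.

## Bayesian phylogenetic ordinal regression

Interaural connectivity (interaural canal, interbullar passage) is a 3-level
ordered state. The model is cumulative-logit with a phylogenetic random
effect:

P(y_i ≤ k) = logistic(τ_k − x_iᵀβ − u_i),  u ~ MVN(0, σ_u²·C_scaled),

with C scaled to unit maximum diagonal so σ_u is identified in liability
units. Priors are weakly informative: slopes N(0, 5), thresholds
Student-t(3, 0, 2.5) subject to τ1 < τ2, σ_u half-Student-t(3, 0, 2.5).
The threshold prior deserves emphasis: with one observation per species the
per-species effect u_i can in principle classify every observation
perfectly, and under improper flat thresholds the posterior then drifts
along a quasi-separation ridge on which τ, β and σ_u inflate together
without bound. A weakly-informative threshold prior anchors the latent
scale and restores calibrated decisions. Even so, σ_u remains weakly
identified in this design and slope posteriors are scale-inflated relative
to the generating value — visible in the huge estimates and standard errors
such models produce in practice — which is why inference is by the interval
*decision* (reject when the 95 % equal-tailed credible interval excludes
zero) rather than by the point estimate. A `priors` argument exposes all
scales for sensitivity analysis; the tests demonstrate that an anchored
variance prior (half-t scale 0.5) recovers a generating slope of 2 within
its posterior spread.

Sampling is Metropolis-within-Gibbs, written in C++ for speed: scalar
random-walk updates for β and τ (three refreshes per cycle, as these are
cheap and strongly correlated a posteriori), site-wise updates of u using
the precision matrix of C_scaled, a log-scale update of σ_u, and a joint
rescaling move of (σ_u, u) that breaks the funnel correlation between the
variance and its effects. Step sizes adapt toward a 0.44 acceptance rate
during the first half of each chain, which is discarded as burn-in. Defaults
are 2 chains of 6000 iterations. Each chain's Mersenne-Twister stream is
seeded from the user seed, so runs are bit-reproducible; split-chain Rhat is
reported per parameter and values above 1.1 raise a convergence warning.
With σ_u fixed at 0 the posterior means agree with a maximum-likelihood
cumulative-logit fit within one posterior standard deviation (tested at
n = 500), and the sampler was cross-checked against an independent Gibbs
implementation of the identical model.

## Synthetic data: what it emulates, and what it does not

The generators reproduce the *structure* of a comparative middle-ear study
so that every stage has known truth:

* `sim_tree(n, seed)`: a pure-birth tree conditioned on n tips, rescaled to
  unit height. Defaults use n = 130, the scale of the real sampling.
* `sim_traits()`: log head mass uniform on [log 4.5 g, log 660 g] (roughly
  two orders of magnitude, the passerine-to-penguin span, so allometric
  slopes are well identified); each log trait is intercept −1 + slope 0.6 ×
  log head mass + group offset + ε with ε ~ MVN(0, σ²C(λ)), σ² = 0.1
  (residual sd ≈ 0.32 log units) and λ = 1 by default. Default group
  offsets (0, −0.33, −0.56, −1.20) sit on the scale of the strongest
  reported aquatic effects. Groups are assigned to contiguous clades by
  default so ecology and phylogeny are confounded as in real data; an
  i.i.d. option exists for calibration experiments that need the
  confounding removed.
* `sim_ordinal()`: latent liability xᵀβ + u + logistic noise cut at ordered
  thresholds (defaults ±1), u ~ MVN(0, σ_u²·C_scaled).
* `sim_ear_geometry()`: a regular-polygon tympanic rim (default radius 3 mm,
  64 points) in a random orientation; umbo = cone apex over the rim centre
  (default height 1.2 mm, giving the terrestrial-like 22° membrane angle);
  columella tip over a point offset 1 mm toward the first rim vertex, so
  the lever truth is exact (l1 = r, l2 = r − offset); smaller apertures
  carry proportionally fewer landmarks, as a digitiser would place them.
  The truth record stores the *polygon-exact* areas of the noise-free rings
  (0.16 % below πr² at 64 points). Isotropic Gaussian noise, when enabled,
  perturbs every coordinate.

What passing tests on these data do **not** show: the generators use
circular apertures, exact cones and a single allometric law with
group-constant offsets, whereas real eardrums are elliptical and saddled,
real allometries vary by trait, measurement error is anisotropic, and real
ecological groups are polyphyletic in more complex ways than contiguous
clades. Recovery on synthetic data validates the estimators and wiring, not
the biology of any particular dataset.

## Problem sizes and numerical tolerances

The test and acceptance suites run: λ recovery with 50 replicates of
200-tip trees (medians ≥ 0.9 at λ = 1 truth and ≤ 0.1 at λ = 0); model
selection with 100 replicates of 130-tip trees at group effects of 3 or
more residual standard deviations (recovery well above the 80 % reference
line); ordinal decision rates with 20 replicates of 100-tip star trees
(reject at β = 2, retain at β = 0); and ICC recovery on 50 × 5 designs.
These sizes make the whole suite run in a couple of minutes while keeping
Monte-Carlo error far from each decision boundary. Geometric identities are
asserted to 1e-9 (rigid invariance), covariance oracles to 1e-9, OLS/GLS
equivalence to 1e-10, and eigen-level agreement to 1e-8. Cholesky
factorisation backs every C⁻¹ application; a 1e-12 diagonal jitter guards
the generator's factorisations of λ-degenerate covariances.

## Known limitations

* Polygonal areas understate smooth-aperture areas by the inscribed-polygon
  deficit (≈ (2π²/3)/m² for m points); with ≥ 32 points this is below 0.7 %
  and far below digitisation noise.
* The λ profile is unimodal in all data we generate; pathological profiles
  with multiple interior optima would be found only at the three anchors
  plus two interval searches.
* The ordinal model's σ_u is weakly identified with one observation per
  species (see above); its posterior depends materially on the prior scale,
  and slope magnitudes should not be over-interpreted.
* `match_tips()` substitutions are exact one-to-one renames; fuzzy or
  taxonomic matching is out of scope.
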