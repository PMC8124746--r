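---
title: "Methods: seasonal spectral detectability of shrub encroachment"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: seasonal spectral detectability of shrub encroachment}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(shrubsep)
```

## The problem and the model

Shrub encroachment into grassland is spectrally subtle at low cover: a
quadrat's reflectance is, to first order, a linear mixture of the pure
spectra (endmembers) of its cover classes, so at 10–20% shrub cover the
shrub contribution is a small perturbation of a grass/forb/dead-matter
background. `shrubsep` operationalises three complementary ways of
asking when that perturbation becomes detectable from 1-nm field
spectra (350–2500 nm):

1. a **rank-correlation scan**: Spearman's r between reflectance and
   visually estimated shrub cover at each wavelength, thresholded at
   the analytic two-tailed critical value;
2. **distributional separability** between cover groups at each
   wavelength, using five univariate statistics (M, Bhattacharyya,
   Divergence, Transformed Divergence, Jeffries-Matusita) computed from
   per-group means and standard deviations under a per-wavelength
   normal model;
3. **broadband inference**: after resampling to multispectral sensor
   bands, classical one-way ANOVA across cover groups per band with
   Tukey HSD post-hoc pairs, read out as the minimum cover whose group
   differs significantly from the shrub-free group.

The separability statistics assume per-wavelength normality within each
group; a Shapiro-Wilk diagnostic (`normality_diagnostic()`) quantifies
how well that holds but never blocks the pipeline — with small groups a
non-parametric alternative would cost more than the mild non-normality
it avoids, and downstream region aggregation dampens the effect of
individual wavelengths.

Treating wavelengths univariately is deliberate: it measures each
wavelength's own discriminating power without conditioning on
neighbours, which is what a band-selection question needs, and it
avoids estimating an ill-conditioned 1668-dimensional covariance from
groups of 10–60 spectra.

## Tunable parameters

| Parameter | Default | Units | Rationale |
|---|---|---|---|
| grid | 350–2500, step 1 | nm | field spectroradiometer range |
| water mask | 1350–1430, 1750–1980, 2330–2500 | nm | atmospheric water-vapour noise windows; 1668 valid points remain |
| outlier screen `k` | 3 | SD | single-pass screen for quadrat-shifting artefacts |
| cluster `k_range` | 2–15 | — | covers plausible cover stratifications of 128 quadrats |
| index panel | CH, silhouette, DB, KL, point-biserial | — | five standard internal-validity indices with interior optima (see below) |
| correlation `alpha` | 0.05 | — | two-tailed, per wavelength; no multiplicity correction (each wavelength is a separate band-selection question); a family-wise option exists but is off by default |
| TD/JM thresholds | 1.8 / 1.5 | — | good / moderate separability cut-offs on the 0–2 scale |
| `min_region_width_nm` | 10 | nm | sub-10-nm runs are narrower than any deployable band |
| Tukey levels | 0.05, 0.1 | — | conventional and screening-level significance |
| `var_floor` | off (1e-8 when enabled) | reflectance² | degenerate zero-variance wavelengths are an error unless explicitly floored |

Mask intervals are closed on both ends. Cover-group intervals are
half-open `(low, high]`, with group 1 defined as exactly 0% cover — a
qualitative state (shrub present vs absent), not a binned range — and
the pure-shrub endmember set appended as the final group rather than
clustered, since ~100% cover spectra would otherwise dominate the
cluster geometry.

## Choosing the number of clusters

Each index in the panel votes for its best k; the modal vote wins, ties
going to the smallest k (prefer the simpler stratification). Two
well-known indices (Dunn, McClain-Rao) were considered and rejected:
on smooth mixture spectra both are monotone in k and always vote at an
edge of the range, which degrades the majority rule to its tie-break.
The shipped panel — Calinski-Harabasz, average silhouette width,
Davies-Bouldin, Krzanowski-Lai, point-biserial — has interior optima on
both blob-structured and transect-like data. Krzanowski-Lai is computed
from within-cluster sums of squares on a k-range widened by one on each
side, with the dimension exponent `2/p` retained (at p ≈ 1668 it is
close to a plain successive-difference ratio).

Breakpoints between cover groups are the midpoints between the cover
ranges of adjacent clusters after ordering clusters by mean cover and
merging clusters whose ranges overlap. Breakpoints that delimit an
empty group are pruned: the forced 0% rule otherwise leaves the first
interval unpopulated whenever the lowest cluster contains only
shrub-free quadrats, which would distort the balance criterion used to
pick between the K-means- and Ward-derived candidate schemes (minimum
variance of group counts).

## The synthetic transect generator

`generate_scene()` emulates the statistical structure the analysis
assumes, not any particular site:

- **Endmembers** are smooth parametric curves: a visible baseline with
  an NPV slope, Gaussian chlorophyll wells at 450/680 nm, a logistic
  red edge, an NIR plateau with gradual SWIR roll-off, and leaf-water
  wells at 970/1200/1450/1940 nm. Season scalars strengthen chlorophyll
  and water absorption into summer and brighten/flatten the visible in
  fall (senescence). The shrub endmember carries the highest NIR
  plateau and water depth; its leaves flush early, so its chlorophyll
  is already full in spring.
- **Shrub cover** along the transect is a moving-average-smoothed
  Gaussian field squashed through a logistic, with the intercept solved
  numerically so the realized mean equals the configured 20% cover;
  values below 3% collapse to exact zeros, giving a realistic
  population of truly shrub-free quadrats (~20 of 128). The default
  correlation length is 15 m (patches span several 3-m quadrats).
- **Composition**: the non-shrub remainder is split among green grass,
  forb, standing dead, litter and bare soil by a season-specific
  Dirichlet draw (standing dead dominating in fall, green grass peaking
  in summer). PAI, soil moisture and biomass covariates are tied to the
  green fraction with seasonal baselines.
- **Spectra**: five replicates per quadrat share the linear mixture and
  differ by iid Gaussian instrument noise (SD 0.01 reflectance);
  endmember libraries hold ten noisy pure-shrub spectra per season.
  With `noise_sd = 0` the mixture identity is exact, which the tests
  assert.
- **LIT patches**: each occupied quadrat cell contributes a canopy
  interval of length `cover × cell width` centred on the quadrat;
  overlaps are merged before summing, so line-intercept cover tracks
  the transect's true mean cover.
- **Reproducibility**: all randomness flows from one integer seed
  through tagged sub-streams (`sub_seed()`), one per quadrat, season,
  replicate and purpose, so a scene is bit-reproducible and independent
  of how many draws other components consume.

**Planted strata mode** (`strata = c(0, 0.15, 0.45, 0.8)`) is a
designed recovery experiment: contiguous quadrat blocks at fixed cover
levels, background composition drawn once per stratum with only tight
per-quadrat jitter, cover level being the controlled factor. This is
the configuration under which the pipeline's parameter-recovery
properties are tested (stratum-to-group recovery, the NIR ensemble
region, the minimum separable group).

What the generator does **not** emulate — and what passing tests
therefore do not demonstrate about real data: nonlinear (multiple
scattering) mixing, within-quadrat spatial structure, canopy shadowing
and illumination geometry, spectrally correlated instrument noise,
observer bias in visual estimation beyond quantization, and multi-year
dynamics. Recovery results on scenes are statements about the
pipeline's correctness, not about field detectability limits.

## Numerical choices

- Jeffries-Matusita uses the `2(1 − e^(−B))` convention so JM and TD
  share the 0–2 scale and threshold table; the √-variant would top out
  at √2.
- The moderate band is operationally `1.5 < v < 1.8`; 1.8 belongs to
  "good", 1.5 to "poor".
- Group moments use the sample SD (n−1) throughout.
- Zero-variance wavelengths raise an error naming the wavelengths;
  an explicit variance floor (1e-8) exists for degenerate synthetic
  groups such as pure endmember sets at zero noise.
- The Spearman critical value uses the t-approximation
  `r_c = t/√(n−2+t²)` for n > 30 (0.1736 at n = 128, printed as 0.17);
  for n ≤ 8 the permutation null is enumerated exhaustively, and for
  9–30 a seeded Monte-Carlo permutation (2×10⁵ draws) is used, both
  with the table convention: the smallest attainable |r| whose
  exceedance probability is ≤ α.
- K-means runs 10 restarts from a fixed seed keeping the best
  within-cluster sum of squares; Ward uses `ward.D2` on Euclidean
  distances. Ties in the majority vote go to the smallest k.
- CSV round-trips write 6 significant digits; masked cells serialize
  as empty fields and are restored as masked on read.
- Visual-cover quantization rounds half to even (R's `round`); the
  5–10% band uses the nearest-5% rule (so 7 → 5, 8 → 10), reading the
  coarse regime as applying from 5% upward to avoid a three-rule
  scheme.

## Problem sizes

The test-suite and examples run single-season 128-quadrat scenes
(641 spectra of 2151 channels each including endmembers, 1668 valid
wavelengths after masking); the full three-season pipeline over two
sensors completes in well under a minute on one core. The acceptance
sweep evaluates the separability statistics on 10,000 random normal
pairs.

## Known limitations

- The balanced-scheme breakpoint derivation replaces an analyst's
  judgement; on real libraries an ecologist may prefer hand-set
  breakpoints, which `assign_cover_groups()` accepts directly.
- Spatial autocorrelation along the transect inflates the effective
  correlation among wavelength-wise tests; significance is calibrated
  marginally, not jointly, and no autocorrelation-adjusted effective
  sample size is applied.
- Bundled band sets are Gaussian approximations at nominal
  centers/FWHMs; use `load_band_responses()` with official SRF tables
  for sensor-faithful band values.
- Classical ANOVA assumes homogeneous group variances; a Welch option
  is available (`oneway.test` with `var.equal = FALSE` underlies it)
  but the default matches the classical procedure.
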