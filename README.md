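# shrubsep

Woody plant encroachment — shrubs expanding into grassland — degrades
grassland ecosystems, and catching it early from remote sensing is hard:
at low cover the shrub signal is buried in a mixture of grass, forbs,
standing dead material, litter and soil, and the best season and
wavelengths for detection are not obvious. `shrubsep` implements, as a
tested and reusable R pipeline, the field-spectroscopy workflow for
answering three questions about a grassland transect:

1. **When** (which season) is shrub cover most spectrally apparent?
2. **Where** (which wavelengths, and which broadband sensor bands) does
   shrub cover separate from its background?
3. **How much** shrub cover must be present before it is statistically
   detectable?

It is aimed at vegetation spectroscopists and rangeland remote-sensing
researchers working with 1-nm field reflectance libraries (350–2500 nm)
collected over quadrats along a transect, together with visual cover
estimates and biophysical covariates.

## What the pipeline does

- **Preprocessing** — water-absorption windows (1350–1430, 1750–1980,
  2330–2500 nm) are masked; replicate spot spectra are averaged per
  quadrat; biophysical variables are screened at 3 standard deviations
  (single pass, per season).
- **Cover grouping** — quadrat spectra are clustered (K-means and Ward,
  Euclidean distance) with the cluster count chosen by majority vote of
  five internal-validity indices over k = 2–15; cover breakpoints are
  derived from each clustering and the most balanced scheme is kept.
  The 0%-cover quadrats always form group 1 and the pure-shrub
  endmember spectra form the final (~100%) group.
- **Correlation scan** — Spearman rank correlation between reflectance
  and visual shrub cover at every wavelength, against the analytic
  two-tailed critical value (r_c = 0.17 at n = 128, α = 0.05).
- **Separability** — five univariate statistics per wavelength between
  the 0%-cover group and every other group, for univariate normals with
  moments (μ₁, σ₁), (μ₂, σ₂):

  - M-statistic: `M = |μ₁−μ₂| / (σ₁+σ₂)` — separation when M > 1
  - Bhattacharyya: `B = (μ₁−μ₂)²/(4(σ₁²+σ₂²)) + ½ ln[((σ₁²+σ₂²)/2)/(σ₁σ₂)]`
  - Divergence: `D = ½(σ₁²/σ₂² + σ₂²/σ₁² − 2) + ½(μ₁−μ₂)²(1/σ₁² + 1/σ₂²)`
  - Transformed Divergence: `TD = 2(1 − e^(−D/8))`
  - Jeffries-Matusita: `JM = 2(1 − e^(−B))`

  TD and JM saturate at 2 (maximal separability) and are thresholded
  (≥ 1.8 good, 1.51–1.79 moderate, ≤ 1.5 poor). Reported regions are
  contiguous runs ≥ 10 nm wide where **both** TD and JM pass the
  threshold (ensemble rule), broken at masked windows.
- **Broadband simulation** — spectra are resampled to Landsat-8-like
  and Sentinel-2-like bands through spectral response functions
  (bundled parametric Gaussians; official SRF tables can be loaded),
  then each band is tested with one-way ANOVA across cover groups and
  Tukey HSD post-hoc comparisons at the 0.05 and 0.1 levels, yielding
  the minimum statistically detectable shrub cover and a per-band
  importance tally.

Because no public field dataset accompanies this workflow, the package
includes a first-class synthetic transect generator
(`generate_scene()`): parametric endmember spectra with seasonal
chlorophyll/water/senescence modulation, a spatially autocorrelated
shrub-cover field along a 381-m, 128-quadrat transect, linear spectral
mixing with instrument noise, visual-cover quantization (nearest 1%
below 5% and above 90%, nearest 5% in between) and line-intercept
(LIT) patch sampling. Every pipeline stage is exercised end to end on
these scenes.

## Worked example

```r
library(shrubsep)

scene <- generate_scene(transect_config(seed = 42, seasons = "spring"))
lib   <- average_replicates(mask_water_regions(scene$library))
X     <- library_matrix(lib)
cover <- scene$quadrats$vis_shrub

spearman_critical(nrow(X))$r_critical_2dp
#> [1] 0.17

prof <- spearman_profile(X, cover)
head(significant_regions(prof), 3)
#>   low_nm high_nm sign     peak_r peak_wavelength
#> 1    350     721    - -0.6252332             425
#> 2    726    1349    +  0.9049723            1287
#> 3   1431    1480    - -0.6688541            1448
```

Reflectance correlates negatively with shrub cover in the visible
(chlorophyll absorption) and SWIR (leaf water), positively on the NIR
plateau — the classic green-vegetation contrast pattern.

```r
k   <- optimal_cluster_count(X, "kmeans")$k
sch <- build_cover_scheme(list(cluster_spectra(X, k, "kmeans"),
                               cluster_spectra(X, k, "ward")),
                          cover, n_endmembers = 10)
sch
#> <cover_group_scheme>
#>   group 1: 0% shrub cover (n = 23)
#>   group 2: <100% shrub cover (n = 105)
#>   group 3: ~100% (endmembers) shrub cover (n = 10)

g1 <- subset_library(lib, sch$group_of == 1)
em <- mask_water_regions(scene$endmember_library)
p  <- separability_profile(g1, em, pair = c("1", "endmember"),
                           season = "spring")
head(ensemble_regions(p), 5)
#>   low_nm high_nm width_nm    klass    basis
#> 1    418     433       16     good ensemble
#> 2    435     501       67     good ensemble
#> 3    551     560       10 moderate ensemble
#> 4    638     710       73     good ensemble
#> 5    732    1349      618     good ensemble
```

Pure shrub separates well from shrub-free grassland in the blue, red,
NIR and SWIR, with only moderate separation at the 550-nm green peak —
where green vegetation and its background look alike. The full
pipeline, including broadband ANOVA/Tukey and the
minimum-detectable-cover summary, runs as

```r
res <- run_pipeline(pipeline_config(scene = transect_config(seed = 42)),
                    out_dir = "results/run42")
res$min_detectable$minimum
```

or from a shell via the bundled script
(`system.file("exec", "shrubsep", package = "shrubsep")`):

```sh
shrubsep simulate --seed 42 --out scene/
shrubsep run --seed 42 --out results/
```

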