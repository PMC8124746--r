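Package: shrubsep
Title: Seasonal Spectral Separability of Shrub Encroachment in Grasslands
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for deciding when and where shrub encroachment into
    grassland is spectrally detectable from field spectroscopy. The package
    preprocesses 1-nm field reflectance libraries (water-absorption masking,
    replicate averaging, 3-SD outlier screening), clusters quadrat spectra
    into shrub-cover groups (K-means and Ward with a majority-rule optimal
    cluster count), scans wavelengths with Spearman rank correlation against
    visual shrub cover, computes five univariate separability statistics
    (M-statistic, Bhattacharyya, Divergence, Transformed Divergence,
    Jeffries-Matusita) with ensemble threshold classification and region
    extraction, resamples spectra to broadband sensor bands through spectral
    response functions, and compares cover groups per band with one-way
    ANOVA and Tukey HSD to report the minimum detectable shrub cover. A
    synthetic transect generator (linear spectral mixing over parametric
    endmembers with spatially autocorrelated shrub cover and seasonal
    modulation) makes the full pipeline testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    cluster,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
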