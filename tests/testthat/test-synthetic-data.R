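test_that("endmember spectra show the expected qualitative contrasts", {
  e <- default_endmembers()
  w <- grid_wavelengths(wavelength_grid())
  gg <- generate_endmember(e$green_grass, "summer")
  expect_lt(gg$reflectance[w == 680], gg$reflectance[w == 550])
  expect_lt(gg$reflectance[w == 550], gg$reflectance[w == 800])
  dead <- generate_endmember(e$standing_dead, "summer")
  vis <- dead$reflectance[w >= 400 & w <= 700]
  expect_true(all(diff(vis) >= -1e-12))
  sh_s <- generate_endmember(e$shrub, "summer")
  sh_f <- generate_endmember(e$shrub, "fall")
  expect_gt(sh_f$reflectance[w == 550], sh_s$reflectance[w == 550])
  # all outputs are proper reflectances
  for (k in names(e)) for (se in c("spring", "summer", "fall")) {
    r <- generate_endmember(e[[k]], se)$reflectance
    expect_true(all(r >= 0 & r <= 1))
  }
})

test_that("the default transect geometry yields 128 quadrats", {
  sc <- quick_scene(seed = 1)
  expect_equal(length(unique(sc$quadrats$quadrat_id)), 128L)
  expect_equal(nrow(sc$quadrats), 128L)
  expect_equal(length(sc$library), 128L * 5L)
  expect_error(transect_config(length_m = 381, spacing_m = 7), "divide")
})

test_that("true top-layer fractions sum to one and spectra are linear mixtures", {
  sc <- generate_scene(transect_config(seed = 2, seasons = "summer",
                                       noise_sd = 0, n_replicates = 1))
  classes <- c("shrub", "green_grass", "forb", "standing_dead", "litter",
               "bare_soil")
  fr <- as.matrix(sc$quadrats[, paste0("cover_", classes)]) / 100
  expect_true(all(abs(rowSums(fr) - 1) < 1e-9))
  # with zero noise each quadrat spectrum equals the weighted endmember sum
  em <- sapply(classes, function(cl)
    sc$endmember_spectra$summer[[cl]]$reflectance)
  i <- 40
  mix <- as.vector(em %*% fr[i, ])
  expect_equal(sc$library$spectra[[i]]$reflectance, mix, tolerance = 1e-12)
})

test_that("scenes are deterministic in the seed and differ across seeds", {
  a <- quick_scene(seed = 9)
  b <- quick_scene(seed = 9)
  c <- quick_scene(seed = 10)
  expect_identical(a$quadrats, b$quadrats)
  expect_identical(a$library$spectra[[17]]$reflectance,
                   b$library$spectra[[17]]$reflectance)
  expect_false(identical(a$quadrats$cover_shrub, c$quadrats$cover_shrub))
})

test_that("shrub cover field is spatially autocorrelated along the transect", {
  sc <- quick_scene(seed = 4)
  f <- sc$quadrats$cover_shrub
  a <- stats::acf(f, lag.max = 10, plot = FALSE)$acf
  expect_gt(a[2], a[11])
  expect_gt(a[2], 0.3)
})

test_that("a zero-mean shrub field leaves every quadrat shrub-free", {
  sc <- generate_scene(transect_config(seed = 5, seasons = "summer",
                                       shrub_mean = 0))
  expect_true(all(sc$quadrats$cover_shrub == 0))
  expect_equal(simulate_lit(sc)$cover_pct, 0)
})

test_that("planted strata mode assigns exact cover blocks", {
  sc <- generate_scene(transect_config(seed = 3, seasons = "spring",
                                       strata = c(0, 0.15, 0.45, 0.8)))
  q <- sc$quadrats
  expect_true(all(q$cover_shrub[q$stratum == 1] == 0))
  expect_true(all(abs(q$cover_shrub[q$stratum == 3] - 45) < 10))
  expect_equal(sort(unique(q$stratum)), 1:4)
})

test_that("line-intercept summary merges overlaps and scales by transect length", {
  expect_equal(simulate_lit(matrix(numeric(0), 0, 2), length_m = 381),
               list(cover_pct = 0, density_per_m = 0, n_patches = 0L,
                    total_length_m = 0))
  one <- matrix(c(100, 138.1), 1, 2)
  expect_equal(simulate_lit(one, length_m = 381)$cover_pct, 10, tolerance = 1e-9)
  dup <- matrix(c(50, 60, 50, 60), 2, 2, byrow = TRUE)
  expect_equal(simulate_lit(dup, length_m = 100)$total_length_m, 10)
  expect_equal(simulate_lit(dup, length_m = 100)$n_patches, 1L)
  part <- matrix(c(0, 10, 5, 20), 2, 2, byrow = TRUE)
  expect_equal(simulate_lit(part, length_m = 100)$total_length_m, 20)
})

test_that("visual-cover quantizer follows the 1%/5% rule and is idempotent", {
  expect_equal(quantize_cover(0), 0)
  expect_equal(quantize_cover(c(12.4, 37.6)), c(10, 40))
  expect_equal(quantize_cover(c(93.7, 3.4)), c(94, 3))
  expect_equal(quantize_cover(c(7, 8)), c(5, 10))
  expect_error(quantize_cover(-1), "\\[0, 100\\]")
  expect_error(quantize_cover(101), "\\[0, 100\\]")
  x <- seq(0, 100, by = 0.25)
  expect_equal(quantize_cover(quantize_cover(x)), quantize_cover(x))
})

test_that("scene writer produces the documented CSV bundle", {
  sc <- generate_scene(transect_config(length_m = 30, spacing_m = 3,
                                       seasons = "summer", n_replicates = 2,
                                       n_endmembers = 3, seed = 8))
  dir <- file.path(tempdir(), "scene_out")
  paths <- write_scene(sc, dir)
  expect_true(all(file.exists(paths)))
  back <- read_spectral_library(paths[["library"]])
  expect_equal(length(back), length(sc$library))
})
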