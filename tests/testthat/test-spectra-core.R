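test_that("default grid spans 350-2500 nm at 1 nm with 2151 points", {
  g <- wavelength_grid()
  expect_equal(g$n, 2151L)
  wl <- grid_wavelengths(g)
  expect_equal(wl[1], 350)
  expect_equal(wl[length(wl)], 2500)
  expect_error(wavelength_grid(500, 400), "start")
  expect_error(wavelength_grid(350, 2500, 0), "step")
})

test_that("spectrum construction validates reflectance range and mask", {
  g <- tiny_grid()
  expect_error(spectrum(c(0.1, 0.2), g), "length")
  expect_error(spectrum(rep(-0.1, 5), g), "outside")
  expect_error(spectrum(rep(1.6, 5), g), "outside")
  expect_warning(spectrum(rep(1.2, 5), g), "panel calibration")
  s <- spectrum(c(0.1, NA, 0.3, 0.4, 0.5), g)
  expect_equal(sum(s$valid_mask), 4)
})

test_that("masking the water windows leaves 1668 valid points and is idempotent", {
  s <- spectrum(rep(0.3, 2151))
  m1 <- mask_water_regions(s)
  # oracle: enumerate the default grid and count points inside the windows
  wl <- grid_wavelengths(s$grid)
  in_win <- (wl >= 1350 & wl <= 1430) | (wl >= 1750 & wl <= 1980) |
    (wl >= 2330 & wl <= 2500)
  expect_equal(sum(in_win), 483)
  expect_equal(sum(m1$valid_mask), 1668)
  expect_true(all(is.na(m1$reflectance[in_win])))
  m2 <- mask_water_regions(m1)
  expect_identical(m2$valid_mask, m1$valid_mask)
  expect_identical(m2$reflectance, m1$reflectance)
})

test_that("empty mask list is the identity and full mask degenerates cleanly", {
  s <- spectrum(rep(0.3, 2151))
  expect_identical(mask_water_regions(s, mask_regions(matrix(numeric(0), 0, 2))),
                   s)
  full <- mask_water_regions(s, mask_regions(list(c(350, 2500))))
  expect_equal(sum(full$valid_mask), 0)
  lib <- spectral_library(list(full, full), data.frame(
    sample_id = c("a", "b"), quadrat_id = c("a", "b"),
    season = "summer", replicate = 1:2, position_m = NA))
  expect_error(group_moments(lib), NA)  # moments exist but are empty
  expect_length(group_moments(lib)$mu, 0)
  expect_error(mask_water_regions(s, mask_regions(list(c(100, 400)))),
               "bounds")
})

test_that("replicate averaging is the mean at valid points with all-valid mask rule", {
  g <- tiny_grid()
  lib1 <- flat_library(0.25, g)
  expect_equal(average_replicates(lib1)$spectra[[1]]$reflectance,
               lib1$spectra[[1]]$reflectance)
  lib2 <- flat_library(c(0.2, 0.4), g, quadrat = c("Q1", "Q1"),
                       replicate = 1:2)
  avg <- average_replicates(lib2)
  expect_length(avg, 1)
  expect_equal(avg$spectra[[1]]$reflectance, rep(0.3, g$n))
  # point masked in one replicate is masked in the mean
  lib2$spectra[[1]] <- mask_water_regions(lib2$spectra[[1]],
                                          mask_regions(list(c(350, 351))))
  avg2 <- average_replicates(lib2)
  expect_equal(avg2$spectra[[1]]$valid_mask, c(FALSE, FALSE, TRUE, TRUE, TRUE))
})

test_that("mean of five noisy replicates concentrates at the base spectrum", {
  g <- wavelength_grid(400, 899, 1)
  base <- 0.3 + 0.1 * sin(seq(0, 3, length.out = g$n))
  set.seed(101)
  specs <- lapply(1:5, function(r)
    spectrum(base + rnorm(g$n, 0, 0.01), g, sample_id = paste0("r", r),
             season = "summer", replicate = r))
  lib <- spectral_library(specs, data.frame(
    sample_id = paste0("r", 1:5), quadrat_id = "Q1", season = "summer",
    replicate = 1:5, position_m = 0))
  avg <- average_replicates(lib)
  # SD of the mean is 0.01/sqrt(5); 0.02 is ~4.5 SD
  expect_true(all(abs(avg$spectra[[1]]$reflectance - base) < 0.02))
})

test_that("averaging commutes with masking on valid points", {
  g <- tiny_grid(8)
  set.seed(3)
  specs <- lapply(1:4, function(r)
    spectrum(runif(8, 0.1, 0.5), g, sample_id = paste0("r", r),
             season = "fall", replicate = r))
  lib <- spectral_library(specs, data.frame(
    sample_id = paste0("r", 1:4), quadrat_id = "Q1", season = "fall",
    replicate = 1:4, position_m = 0))
  reg <- mask_regions(list(c(352, 354)))
  a <- average_replicates(mask_water_regions(lib, reg))$spectra[[1]]
  b <- mask_water_regions(average_replicates(lib), reg)$spectra[[1]]
  expect_identical(a$valid_mask, b$valid_mask)
  expect_equal(a$reflectance[a$valid_mask], b$reflectance[b$valid_mask])
})

test_that("write/read round-trips a library bit-exactly, masked cells as empties", {
  g <- tiny_grid()
  lib <- flat_library(c(0.123456, 0.2), g)
  lib$spectra[[2]] <- mask_water_regions(lib$spectra[[2]],
                                         mask_regions(list(c(351, 352))))
  path <- file.path(tempdir(), "lib_roundtrip.csv")
  write_spectral_library(lib, path)
  # masked cells serialize as empty strings
  raw <- readLines(path)
  expect_true(any(grepl(",$|,,", raw)))
  back <- read_spectral_library(path)
  expect_equal(length(back), length(lib))
  for (i in seq_along(lib$spectra)) {
    expect_identical(back$spectra[[i]]$valid_mask, lib$spectra[[i]]$valid_mask)
    expect_equal(back$spectra[[i]]$reflectance, lib$spectra[[i]]$reflectance)
  }
  expect_equal(back$meta$season, lib$meta$season)
})

test_that("reader rejects malformed files and writer rejects empty libraries", {
  p <- file.path(tempdir(), "bad_grid.csv")
  writeLines(c("wavelength_nm,s1", "350,0.1", "351,0.2", "353,0.3"), p)
  expect_error(read_spectral_library(p), "uniform")
  p2 <- file.path(tempdir(), "bad_cell.csv")
  writeLines(c("wavelength_nm,s1", "350,0.1", "351,oops", "352,0.3"), p2)
  expect_error(read_spectral_library(p2), "non-numeric")
  expect_error(read_spectral_library(file.path(tempdir(), "nope.csv")),
               "not found")
  lib <- flat_library(0.3)
  lib$spectra <- list()
  expect_error(write_spectral_library(lib, tempfile()), "empty")
  # duplicate keys rejected at construction
  expect_error(
    spectral_library(flat_library(c(0.1, 0.2))$spectra,
                     data.frame(sample_id = c("a", "b"),
                                quadrat_id = c("Q1", "Q1"),
                                season = "summer", replicate = c(1L, 1L),
                                position_m = NA)),
    "duplicate")
})
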