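# Independent numerical oracles for the separability statistics between
# two univariate normals: the Bhattacharyya distance as
# -ln integral sqrt(p1 p2), and the divergence as the symmetric
# Kullback-Leibler integral (p1 - p2) ln(p1/p2).
bhatt_quadrature <- function(m1, s1, m2, s2) {
  f <- function(x) sqrt(dnorm(x, m1, s1) * dnorm(x, m2, s2))
  lo <- min(m1 - 12 * s1, m2 - 12 * s2)
  hi <- max(m1 + 12 * s1, m2 + 12 * s2)
  -log(integrate(f, lo, hi, rel.tol = 1e-12)$value)
}
divergence_quadrature <- function(m1, s1, m2, s2) {
  f <- function(x) (dnorm(x, m1, s1) - dnorm(x, m2, s2)) *
    (dnorm(x, m1, s1, log = TRUE) - dnorm(x, m2, s2, log = TRUE))
  lo <- min(m1 - 14 * s1, m2 - 14 * s2)
  hi <- max(m1 + 14 * s1, m2 + 14 * s2)
  integrate(f, lo, hi, rel.tol = 1e-12)$value
}

test_that("all five statistics vanish for coincident distributions", {
  m <- pairwise_metrics(0.4, 0.05, 0.4, 0.05)
  expect_equal(unlist(m), c(M = 0, B = 0, D = 0, TD = 0, JM = 0))
})

test_that("closed forms match the quadrature oracles on reference cases", {
  m <- pairwise_metrics(0, 1, 1, 1)
  expect_equal(m$M, 0.5)
  expect_equal(m$B, 0.125)
  expect_equal(m$D, 1)
  expect_equal(m$TD, 2 * (1 - exp(-1 / 8)))
  expect_equal(m$JM, m$TD)  # equal variances
  expect_equal(round(m$JM, 4), 0.2350)
  expect_equal(m$B, bhatt_quadrature(0, 1, 1, 1), tolerance = 1e-10)
  expect_equal(m$D, divergence_quadrature(0, 1, 1, 1), tolerance = 1e-10)

  m2 <- pairwise_metrics(0, 1, 0, 2)
  expect_equal(m2$M, 0)
  expect_equal(m2$D, 1.125)
  expect_equal(m2$B, 0.5 * log(1.25))
  expect_equal(round(m2$B, 4), 0.1116)
  expect_equal(m2$B, bhatt_quadrature(0, 1, 0, 2), tolerance = 1e-10)
  expect_equal(m2$D, divergence_quadrature(0, 1, 0, 2), tolerance = 1e-10)
})

test_that("closed-form B matches quadrature to 1e-8 over a random sweep", {
  set.seed(41)
  for (i in 1:200) {
    m1 <- runif(1, -3, 3); m2 <- runif(1, -3, 3)
    s1 <- runif(1, 0.2, 2.5); s2 <- runif(1, 0.2, 2.5)
    expect_equal(pairwise_metrics(m1, s1, m2, s2)$B,
                 bhatt_quadrature(m1, s1, m2, s2), tolerance = 1e-8)
  }
})

test_that("equal variances force TD == JM to machine precision", {
  set.seed(42)
  for (i in 1:100) {
    mu <- runif(2, -5, 5); s <- runif(1, 0.1, 3)
    m <- pairwise_metrics(mu[1], s, mu[2], s)
    expect_equal(m$D, 8 * m$B, tolerance = 1e-12)
    expect_lt(abs(m$TD - m$JM), 1e-12)
  }
})

test_that("metrics are symmetric, monotone in mean separation, and bounded", {
  set.seed(43)
  for (i in 1:50) {
    m1 <- runif(1, -2, 2); m2 <- runif(1, -2, 2)
    s1 <- runif(1, 0.1, 2); s2 <- runif(1, 0.1, 2)
    a <- pairwise_metrics(m1, s1, m2, s2)
    b <- pairwise_metrics(m2, s2, m1, s1)
    expect_equal(a, b, tolerance = 1e-14)
  }
  deltas <- seq(0, 6, by = 0.25)
  vals <- pairwise_metrics(0, 0.7, deltas, 1.1)
  for (col in c("M", "B", "D", "TD", "JM"))
    expect_true(all(diff(vals[[col]]) > 0))
  expect_true(all(vals$TD < 2 & vals$JM < 2))
  sat <- pairwise_metrics(0, 1, 20, 1)  # |dmu|/sigma = 20
  expect_gt(sat$TD, 1.999)
  expect_gt(sat$JM, 1.999)
})

test_that("zero variance errors unless an explicit floor is requested", {
  expect_error(pairwise_metrics(0, 0, 1, 1), "zero or negative SD")
  m <- pairwise_metrics(0, 0, 1, 1, var_floor = 1e-8)
  expect_true(is.finite(m$TD))
})

test_that("profiles between spectra groups classify wavelengths correctly", {
  X1 <- blob_matrix(list(0.20), n_per = 8, sd = 0.004, n_wl = 40, seed = 44)
  X2 <- blob_matrix(list(0.30), n_per = 8, sd = 0.004, n_wl = 40, seed = 45)
  p <- separability_profile(matrix_library(X1), matrix_library(X2),
                            pair = c("1", "6"), season = "summer")
  # ~25x mean offset / pooled SD: saturates everywhere
  expect_true(all(p$TD > 1.9))
  expect_true(all(p$class_TD == "good"))
  self <- separability_profile(matrix_library(X1), matrix_library(X1))
  expect_true(all(abs(self$TD) < 1e-12))
  expect_true(all(self$class_TD == "poor"))
  expect_error(separability_profile(matrix_library(X1),
                                    matrix_library(X2[, 1:10])),
               "share wavelengths")
})

test_that("threshold classes follow the published rules", {
  expect_equal(classify_value("TD", 1.85), "good")
  expect_equal(classify_value("TD", 1.8), "good")
  expect_equal(classify_value("JM", 1.6), "moderate")
  expect_equal(classify_value("JM", 1.5), "poor")
  expect_equal(classify_value("TD", 0.2), "poor")
  expect_equal(classify_value("M", 1.01), "good")
  expect_equal(classify_value("M", 0.99), "poor")
  expect_error(classify_value("B", 1), "no threshold")
  expect_error(classify_value("TD", NaN), "non-finite")
})

mk_profile <- function(wl, td, jm) {
  data.frame(wavelength = wl, TD = td, JM = jm)
}

test_that("ensemble regions require both TD and JM and a 10 nm width", {
  wl <- 350:1200
  none <- mk_profile(wl, rep(1.2, length(wl)), rep(1.1, length(wl)))
  expect_equal(nrow(ensemble_regions(none)), 0)
  td <- rep(1.0, length(wl)); jm <- rep(1.0, length(wl))
  run <- wl >= 718 & wl <= 979
  td[run] <- 1.9; jm[run] <- 1.9
  r <- ensemble_regions(mk_profile(wl, td, jm))
  expect_equal(nrow(r), 1)
  expect_equal(r$low_nm, 718)
  expect_equal(r$high_nm, 979)
  expect_equal(r$klass, "good")
  # an 8 nm qualifying run is dropped
  td2 <- rep(1.0, length(wl)); jm2 <- td2
  td2[wl >= 500 & wl <= 507] <- 1.95; jm2[wl >= 500 & wl <= 507] <- 1.95
  expect_equal(nrow(ensemble_regions(mk_profile(wl, td2, jm2))), 0)
  # TD good but JM only moderate -> moderate ensemble region
  td3 <- rep(1.9, length(wl)); jm3 <- rep(1.6, length(wl))
  r3 <- ensemble_regions(mk_profile(wl, td3, jm3))
  expect_equal(r3$klass, "moderate")
})

test_that("regions break at masked gaps and a TD-only fallback is labelled", {
  wl <- c(1300:1349, 1431:1480)  # water window removed between the runs
  p <- mk_profile(wl, rep(1.9, length(wl)), rep(1.9, length(wl)))
  r <- ensemble_regions(p)
  expect_equal(nrow(r), 2)
  expect_equal(r$low_nm, c(1300, 1431))
  p2 <- mk_profile(350:500, rep(1.9, 151), rep(1.2, 151))
  expect_equal(nrow(ensemble_regions(p2)), 0)
  fb <- ensemble_regions(p2, td_fallback = TRUE)
  expect_equal(fb$basis, "td_only")
  expect_equal(fb$klass, "good")
})

test_that("normality diagnostic calibrates under the null and flags heavy tails", {
  set.seed(46)
  Xn <- matrix(rnorm(30 * 300), 30, 300)
  colnames(Xn) <- seq_len(300)
  dn <- normality_diagnostic(Xn)
  expect_gt(dn$pass_fraction, 0.90)
  expect_lt(dn$pass_fraction, 0.99)
  set.seed(47)
  Xt <- matrix(rt(30 * 300, df = 2), 30, 300)
  colnames(Xt) <- seq_len(300)
  expect_lt(normality_diagnostic(Xt)$pass_fraction, 0.80)
  Xc <- matrix(0.5, 5, 3); colnames(Xc) <- 1:3
  dc <- normality_diagnostic(Xc)
  expect_true(all(dc$table$reason == "zero variance"))
  expect_equal(dc$pass_fraction, 0)
  expect_error(normality_diagnostic(Xn[1:2, ]), ">= 3")
})
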