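# Small in-code fixtures shared across test files.

# tiny uniform grid for fast I/O and masking tests
tiny_grid <- function(n = 5, start = 350, step = 1) {
  wavelength_grid(start, start + (n - 1) * step, step)
}

# library of `n` flat spectra at given levels on a tiny grid
flat_library <- function(levels, grid = tiny_grid(), season = "summer",
                         quadrat = NULL, replicate = NULL) {
  n <- length(levels)
  if (is.null(quadrat)) quadrat <- sprintf("Q%02d", seq_len(n))
  if (is.null(replicate)) replicate <- rep(1L, n)
  spectra <- lapply(seq_len(n), function(i)
    spectrum(rep(levels[i], grid$n), grid,
             sample_id = sprintf("s%02d", i), season = season,
             replicate = replicate[i]))
  meta <- data.frame(sample_id = sprintf("s%02d", seq_len(n)),
                     quadrat_id = quadrat, season = season,
                     replicate = replicate, position_m = NA_real_,
                     stringsAsFactors = FALSE)
  spectral_library(spectra, meta)
}

# matrix of gaussian-ish noisy spectra around per-group mean vectors,
# used for clustering and separability tests
blob_matrix <- function(centers, n_per, sd = 0.005, n_wl = 50, seed = 1) {
  set.seed(seed)
  X <- do.call(rbind, lapply(centers, function(mu)
    matrix(stats::rnorm(n_per * n_wl, mu, sd), n_per, n_wl)))
  colnames(X) <- seq(400, by = 1, length.out = n_wl)
  X
}

# spectra-group matrix -> spectral_library on a small grid
matrix_library <- function(X, season = "summer") {
  g <- wavelength_grid(as.numeric(colnames(X)[1]),
                       as.numeric(colnames(X)[ncol(X)]), 1)
  lib <- lapply(seq_len(nrow(X)), function(i)
    spectrum(pmin(pmax(X[i, ], 0), 1), g,
             sample_id = sprintf("b%03d", i), season = season))
  spectral_library(lib)
}

# quick single-season synthetic scene used by several files
quick_scene <- function(seed = 7, seasons = "spring", ...) {
  generate_scene(transect_config(seed = seed, seasons = seasons, ...))
}
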