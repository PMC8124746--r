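#' Parametric endmember spectra
#'
#' Each pure cover class is modelled as a smooth function of wavelength:
#' a visible baseline with a non-photosynthetic (NPV) slope, Gaussian
#' chlorophyll absorption wells at 450 and 680 nm (their shoulders shape
#' the 550 nm green peak), a logistic red edge rising to an NIR plateau,
#' a gradual SWIR roll-off, and Gaussian leaf-water wells at 970, 1200,
#' 1450 and 1940 nm. Season scalars multiply chlorophyll depth, water
#' depth, NIR plateau, visible baseline and NPV slope, which encodes the
#' phenology that matters for shrub detection: chlorophyll absorption
#' strengthens into summer and collapses in fall, water absorption peaks
#' in summer, and the visible baseline brightens in fall as canopies
#' senesce.
#'
#' @param kind One of `"green_grass"`, `"shrub"`, `"forb"`,
#'   `"standing_dead"`, `"litter"`, `"bare_soil"`.
#' @param chlorophyll_depth Fractional depth of the 450/680 nm wells, in
#'   `[0, 1)`.
#' @param red_edge_pos Red-edge inflection wavelength (nm, in 690-760).
#' @param nir_plateau NIR plateau reflectance.
#' @param water_depth Fractional depth of the 1450/1940 nm wells.
#' @param npv_slope Visible-range slope (reflectance per 1000 nm).
#' @param vis_base Visible baseline reflectance near 550 nm.
#' @param swir_drop Fractional decline of the plateau from 1300 to 2500 nm.
#' @param season_scalars Named list of per-season multiplier vectors, each
#'   with elements `chl`, `water`, `nir`, `vis`, `npv`.
#' @return An `endmember_params` object.
#' @export
endmember_params <- function(kind, chlorophyll_depth, red_edge_pos,
                             nir_plateau, water_depth, npv_slope,
                             vis_base, swir_drop = 0.4,
                             season_scalars = NULL) {
  kinds <- c("green_grass", "shrub", "forb", "standing_dead", "litter",
             "bare_soil")
  kind <- match.arg(kind, kinds)
  if (red_edge_pos < 690 || red_edge_pos > 760)
    stop("endmember_params: red_edge_pos must lie in [690, 760] nm")
  if (is.null(season_scalars))
    season_scalars <- list(
      spring = c(chl = 1, water = 1, nir = 1, vis = 1, npv = 1),
      summer = c(chl = 1, water = 1, nir = 1, vis = 1, npv = 1),
      fall   = c(chl = 1, water = 1, nir = 1, vis = 1, npv = 1))
  structure(list(kind = kind, chlorophyll_depth = chlorophyll_depth,
                 red_edge_pos = red_edge_pos, nir_plateau = nir_plateau,
                 water_depth = water_depth, npv_slope = npv_slope,
                 vis_base = vis_base, swir_drop = swir_drop,
                 season_scalars = season_scalars),
            class = "endmember_params")
}

#' Default endmember parameter set
#'
#' Defaults encode the qualitative contrasts a northern mixed-grass
#' transect exhibits: green vegetation with strong chlorophyll and water
#' absorption; shrub with the highest NIR plateau and water content (its
#' leaves flush early, so chlorophyll is already full in spring); dead
#' material and litter with a sloped, featureless visible and weak water
#' wells; soil dark and nearly flat.
#'
#' @return Named list of [endmember_params()], one per cover class.
#' @export
default_endmembers <- function() {
  sc <- function(spr, sum_, fal) list(spring = spr, summer = sum_, fall = fal)
  list(
    green_grass = endmember_params(
      "green_grass", chlorophyll_depth = 0.65, red_edge_pos = 715,
      nir_plateau = 0.42, water_depth = 0.35, npv_slope = 0.02,
      vis_base = 0.10,
      season_scalars = sc(
        c(chl = 0.80, water = 0.90, nir = 0.92, vis = 1.00, npv = 1.0),
        c(chl = 1.00, water = 1.00, nir = 1.00, vis = 1.00, npv = 1.0),
        c(chl = 0.35, water = 0.55, nir = 0.80, vis = 1.55, npv = 3.0))),
    shrub = endmember_params(
      "shrub", chlorophyll_depth = 0.70, red_edge_pos = 720,
      nir_plateau = 0.55, water_depth = 0.55, npv_slope = 0.01,
      vis_base = 0.10, swir_drop = 0.45,
      season_scalars = sc(
        c(chl = 1.00, water = 0.95, nir = 0.92, vis = 1.00, npv = 1.0),
        c(chl = 1.00, water = 1.00, nir = 1.00, vis = 1.00, npv = 1.0),
        c(chl = 0.50, water = 0.70, nir = 0.85, vis = 1.30, npv = 2.0))),
    forb = endmember_params(
      "forb", chlorophyll_depth = 0.60, red_edge_pos = 710,
      nir_plateau = 0.47, water_depth = 0.40, npv_slope = 0.02,
      vis_base = 0.11,
      season_scalars = sc(
        c(chl = 0.85, water = 0.90, nir = 0.90, vis = 1.00, npv = 1.0),
        c(chl = 1.00, water = 1.00, nir = 1.00, vis = 1.00, npv = 1.0),
        c(chl = 0.40, water = 0.55, nir = 0.80, vis = 1.45, npv = 2.5))),
    standing_dead = endmember_params(
      "standing_dead", chlorophyll_depth = 0, red_edge_pos = 700,
      nir_plateau = 0.38, water_depth = 0.12, npv_slope = 0.25,
      vis_base = 0.19, swir_drop = 0.25,
      season_scalars = sc(
        c(chl = 1, water = 1.1, nir = 1.00, vis = 0.95, npv = 1.0),
        c(chl = 1, water = 1.0, nir = 1.00, vis = 1.00, npv = 1.0),
        c(chl = 1, water = 0.8, nir = 1.02, vis = 1.10, npv = 1.1))),
    litter = endmember_params(
      "litter", chlorophyll_depth = 0, red_edge_pos = 700,
      nir_plateau = 0.32, water_depth = 0.10, npv_slope = 0.20,
      vis_base = 0.16, swir_drop = 0.20,
      season_scalars = sc(
        c(chl = 1, water = 1.1, nir = 1, vis = 1, npv = 1),
        c(chl = 1, water = 1.0, nir = 1, vis = 1, npv = 1),
        c(chl = 1, water = 0.8, nir = 1, vis = 1.05, npv = 1))),
    bare_soil = endmember_params(
      "bare_soil", chlorophyll_depth = 0, red_edge_pos = 700,
      nir_plateau = 0.28, water_depth = 0.08, npv_slope = 0.12,
      vis_base = 0.15, swir_drop = 0.10,
      season_scalars = sc(
        c(chl = 1, water = 1.3, nir = 1, vis = 0.95, npv = 1),
        c(chl = 1, water = 1.5, nir = 1, vis = 0.90, npv = 1),
        c(chl = 1, water = 1.2, nir = 1, vis = 1.00, npv = 1))))
}

gauss_well <- function(wl, center, width) exp(-((wl - center) / width)^2)

#' Generate a pure-class endmember spectrum
#'
#' Evaluates the parametric endmember model for one class and season on a
#' wavelength grid. The construction is deterministic; the `seed` argument
#' is accepted for interface symmetry with the stochastic generators and
#' ignored.
#'
#' @param params An [endmember_params()] object.
#' @param season `"spring"`, `"summer"` or `"fall"`.
#' @param grid Wavelength grid (default 350-2500 nm at 1 nm).
#' @param seed Ignored (the model is deterministic).
#' @return A [spectrum()] with reflectance in `[0, 1]` (values outside are
#'   clipped with a warning).
#' @export
generate_endmember <- function(params, season = "summer",
                               grid = wavelength_grid(), seed = NULL) {
  stopifnot(inherits(params, "endmember_params"))
  season <- match.arg(season, c("spring", "summer", "fall"))
  sc <- params$season_scalars[[season]]
  wl <- grid_wavelengths(grid)

  chl <- params$chlorophyll_depth * sc[["chl"]]
  wat <- params$water_depth * sc[["water"]]
  nir <- params$nir_plateau * sc[["nir"]]
  vis <- params$vis_base * sc[["vis"]]
  npv <- params$npv_slope * sc[["npv"]]

  vis_level <- vis + npv * (wl - 550) / 1000
  chl_fac <- 1 - chl * gauss_well(wl, 450, 60) - chl * gauss_well(wl, 680, 50)
  vis_level <- pmax(vis_level * chl_fac, 0.005)

  edge <- stats::plogis((wl - params$red_edge_pos) / 12)
  plateau <- nir * (1 - params$swir_drop * pmin(1, pmax(0, (wl - 1300) / 1200)))
  base <- vis_level * (1 - edge) + plateau * edge

  water_fac <- 1 -
    wat * 0.15 * gauss_well(wl, 970, 30) -
    wat * 0.25 * gauss_well(wl, 1200, 40) -
    wat * gauss_well(wl, 1450, 55) -
    wat * 0.90 * gauss_well(wl, 1940, 70)
  refl <- base * pmax(water_fac, 0)

  if (any(refl < 0) || any(refl > 1)) {
    warning("generate_endmember: reflectance clipped to [0, 1]")
    refl <- pmin(pmax(refl, 0), 1)
  }
  spectrum(refl, grid, sample_id = paste(params$kind, season, sep = "_"),
           season = season)
}

#' Deterministic sub-stream seeds
#'
#' All scene randomness flows from one integer seed. Sub-streams (the
#' cover field, per-quadrat compositions, per-replicate noise, endmember
#' replicates, covariates) get their own seed by folding small integer
#' tags into the master seed with a multiplicative congruential step, so
#' each component is reproducible independently of how many draws the
#' others consume.
#'
#' @param seed Master integer seed.
#' @param ... Integer tags identifying the sub-stream.
#' @return An integer seed in `[0, 2^31 - 2]`.
#' @export
sub_seed <- function(seed, ...) {
  x <- as.double(seed) %% 2147483647
  for (tag in c(...)) x <- (x * 69069 + as.double(tag)) %% 2147483647
  as.integer(x)
}

#' Transect scene configuration
#'
#' @param length_m Transect length (m); default 381.
#' @param spacing_m Quadrat spacing (m); default 3, so the default transect
#'   holds `381/3 + 1 = 128` quadrats.
#' @param seasons Character vector of seasons to simulate.
#' @param shrub_mean Mean shrub cover fraction of the smoothed random
#'   field (default 0.20, a typical encroached-grassland spring value).
#' @param corr_length_m Correlation length (m) of shrub patches; default 15.
#' @param strata Optional vector of planted shrub-cover fractions; when
#'   given, quadrats are assigned to contiguous blocks at those exact
#'   cover levels (plus jitter `strata_jitter`) instead of the random
#'   field. Used for parameter-recovery experiments.
#' @param strata_jitter SD of the jitter added to non-zero strata.
#' @param noise_sd Instrument noise SD added per wavelength and replicate.
#' @param n_replicates Replicate spectra per quadrat (default 5).
#' @param n_endmembers Pure-shrub endmember spectra per season (default 10).
#' @param season_cover_scale Named multipliers of shrub cover by season
#'   (shrub canopy area shrinks slightly after spring).
#' @param seed Master integer seed (mandatory for reproducible scenes).
#' @return A `transect_config` list.
#' @export
transect_config <- function(length_m = 381, spacing_m = 3,
                            seasons = c("spring", "summer", "fall"),
                            shrub_mean = 0.20, corr_length_m = 15,
                            strata = NULL, strata_jitter = 0.02,
                            noise_sd = 0.01, n_replicates = 5,
                            n_endmembers = 10,
                            season_cover_scale = c(spring = 1, summer = 0.92,
                                                   fall = 0.88),
                            seed = 1L) {
  if (abs(length_m / spacing_m - round(length_m / spacing_m)) > 1e-9)
    stop("transect_config: spacing_m must divide length_m")
  structure(list(length_m = length_m, spacing_m = spacing_m,
                 seasons = seasons, shrub_mean = shrub_mean,
                 corr_length_m = corr_length_m, strata = strata,
                 strata_jitter = strata_jitter, noise_sd = noise_sd,
                 n_replicates = n_replicates, n_endmembers = n_endmembers,
                 season_cover_scale = season_cover_scale,
                 seed = as.integer(seed)),
            class = "transect_config")
}

# Spatially autocorrelated fraction field: white noise smoothed by a
# moving average of width ~ corr_length, standardized, then squashed
# through a logistic centred on the target mean.
shrub_fraction_field <- function(n, mean_frac, corr_length_m, spacing_m,
                                 seed) {
  set.seed(seed)
  z <- stats::rnorm(n + 40)
  w <- max(1L, round(corr_length_m / spacing_m))
  if (w > 1) {
    z <- stats::filter(z, rep(1 / w, w), sides = 2)
    z <- z[!is.na(z)]
  }
  z <- z[seq_len(n)]
  z <- (z - mean(z)) / stats::sd(z)
  # calibrate the logistic intercept so the realized field hits the target
  # mean cover before the sparse tail collapses to true zeros
  a <- stats::uniroot(
    function(a) mean(stats::plogis(a + 1.6 * z)) - max(mean_frac, 1e-3),
    c(-20, 20))$root
  f <- stats::plogis(a + 1.6 * z)
  f[f < 0.03] <- 0  # sparse tail collapses to true zero-shrub quadrats
  f
}

dirichlet1 <- function(alpha) {
  g <- stats::rgamma(length(alpha), shape = alpha, rate = 1)
  stats::setNames(g / sum(g), names(alpha))
}

season_dirichlet_conc <- function(season) {
  # green_grass, forb, standing_dead, litter, bare_soil concentrations;
  # standing dead dominates the remainder in fall, green grass peaks in
  # summer, litter and soil stay minor.
  switch(season,
         spring = c(green_grass = 3.2, forb = 1.8, standing_dead = 3.8,
                    litter = 1.0, bare_soil = 0.2),
         summer = c(green_grass = 3.9, forb = 1.9, standing_dead = 3.7,
                    litter = 0.7, bare_soil = 0.1),
         fall   = c(green_grass = 2.8, forb = 1.6, standing_dead = 5.4,
                    litter = 0.4, bare_soil = 0.1))
}

#' Generate a synthetic encroachment transect scene
#'
#' Builds the full data bundle the analysis pipeline consumes: a quadrat
#' table of true and visually quantized cover fractions with biophysical
#' covariates (PAI, soil moisture, biomass), replicate reflectance spectra
#' per quadrat as linear mixtures of the class endmembers plus Gaussian
#' instrument noise, a pure-shrub endmember library, and shrub canopy
#' patch intervals along the transect for line-intercept sampling.
#'
#' @param config A [transect_config()].
#' @param endmembers Endmember parameter list (default
#'   [default_endmembers()]).
#' @param grid Wavelength grid.
#' @return A `synthetic_scene` with elements `quadrats` (data frame),
#'   `library` (replicate [spectral_library()]), `endmember_library`
#'   (pure-shrub [spectral_library()]), `patches` (two-column matrix of
#'   patch intervals, m), `config`, `endmember_spectra` (list by class and
#'   season).
#' @export
generate_scene <- function(config = transect_config(),
                           endmembers = default_endmembers(),
                           grid = wavelength_grid()) {
  stopifnot(inherits(config, "transect_config"))
  pos <- seq(0, config$length_m, by = config$spacing_m)
  n <- length(pos)
  classes <- c("shrub", "green_grass", "forb", "standing_dead", "litter",
               "bare_soil")

  # base shrub fraction along the transect
  if (!is.null(config$strata)) {
    k <- length(config$strata)
    block <- rep(seq_len(k), each = ceiling(n / k))[seq_len(n)]
    set.seed(sub_seed(config$seed, 1L))
    f0 <- config$strata[block] +
      ifelse(config$strata[block] > 0,
             stats::rnorm(n, 0, config$strata_jitter), 0)
    f0 <- pmin(pmax(f0, 0), 0.97)
    strata_id <- block
  } else {
    f0 <- shrub_fraction_field(n, config$shrub_mean, config$corr_length_m,
                               config$spacing_m, sub_seed(config$seed, 1L))
    strata_id <- NA_integer_
  }

  # endmember spectra per class x season (deterministic)
  em <- list()
  for (se in config$seasons)
    em[[se]] <- lapply(endmembers, generate_endmember, season = se,
                       grid = grid)

  quad_rows <- list()
  spectra <- list()
  meta_rows <- list()
  biomass_scale <- c(shrub = 500, green_grass = 420, forb = 150,
                     standing_dead = 700, litter = 300, bare_soil = 0)
  sm_base <- c(spring = 0.148, summer = 0.183, fall = 0.189)
  pai_base <- c(spring = 1.6, summer = 2.3, fall = 1.9)

  for (si in seq_along(config$seasons)) {
    se <- config$seasons[si]
    scale <- config$season_cover_scale[[se]]
    # planted strata emulate a designed experiment: the background
    # composition is fixed per stratum (drawn once), with only tight
    # per-quadrat jitter, so cover level is the controlled factor
    stratum_comp <- NULL
    if (!is.null(config$strata)) {
      stratum_comp <- lapply(seq_along(config$strata), function(s) {
        set.seed(sub_seed(config$seed, 5L, s, si))
        dirichlet1(season_dirichlet_conc(se))
      })
    }
    for (q in seq_len(n)) {
      shrub_f <- f0[q] * scale
      set.seed(sub_seed(config$seed, 2L, q, si))
      rest <- if (is.null(stratum_comp)) {
        (1 - shrub_f) * dirichlet1(season_dirichlet_conc(se))
      } else {
        (1 - shrub_f) * dirichlet1(150 * stratum_comp[[strata_id[q]]] + 1e-3)
      }
      frac <- c(shrub = shrub_f, rest)[classes]
      stopifnot(abs(sum(frac) - 1) < 1e-9)

      # covariates tied to green fraction and season
      green <- frac[["shrub"]] + frac[["green_grass"]] + frac[["forb"]]
      pai <- max(0.1, pai_base[[se]] * (0.55 + 0.9 * green) +
                   stats::rnorm(1, 0, 0.15))
      sm <- min(1, max(0, sm_base[[se]] + 0.04 * frac[["shrub"]] +
                         stats::rnorm(1, 0, 0.02)))
      biomass <- biomass_scale[classes] * frac *
        exp(stats::rnorm(length(classes), 0, 0.15))

      qid <- sprintf("Q%03d", q)
      row <- data.frame(quadrat_id = qid, position_m = pos[q], season = se,
                        stratum = strata_id[min(q, length(strata_id))],
                        stringsAsFactors = FALSE)
      for (cl in classes) row[[paste0("cover_", cl)]] <- 100 * frac[[cl]]
      for (cl in classes)
        row[[paste0("vis_", cl)]] <- quantize_cover(100 * frac[[cl]])
      row$pai <- pai
      row$soil_moisture <- sm
      for (cl in classes) row[[paste0("biomass_", cl)]] <- biomass[[cl]]
      quad_rows[[length(quad_rows) + 1]] <- row

      # linear mixture + per-replicate instrument noise
      mix <- Reduce(`+`, Map(function(cl, f) f * em[[se]][[cl]]$reflectance,
                             classes, frac))
      for (r in seq_len(config$n_replicates)) {
        set.seed(sub_seed(config$seed, 3L, q, si, r))
        refl <- mix + stats::rnorm(grid$n, 0, config$noise_sd)
        refl <- pmin(pmax(refl, 0), 1)
        sid <- sprintf("%s_%s_r%d", qid, se, r)
        spectra[[length(spectra) + 1]] <-
          spectrum(refl, grid, sample_id = sid, season = se, replicate = r)
        meta_rows[[length(meta_rows) + 1]] <-
          data.frame(sample_id = sid, quadrat_id = qid, season = se,
                     replicate = r, position_m = pos[q],
                     stringsAsFactors = FALSE)
      }
    }
  }

  # pure-shrub endmember library (>= 10 samples per season)
  em_spectra <- list()
  em_meta <- list()
  for (si in seq_along(config$seasons)) {
    se <- config$seasons[si]
    base <- em[[se]][["shrub"]]$reflectance
    for (j in seq_len(config$n_endmembers)) {
      set.seed(sub_seed(config$seed, 4L, si, j))
      refl <- pmin(pmax(base + stats::rnorm(grid$n, 0, config$noise_sd), 0), 1)
      sid <- sprintf("EM%02d_%s", j, se)
      em_spectra[[length(em_spectra) + 1]] <-
        spectrum(refl, grid, sample_id = sid, season = se, replicate = 1L)
      em_meta[[length(em_meta) + 1]] <-
        data.frame(sample_id = sid, quadrat_id = sprintf("EM%02d", j),
                   season = se, replicate = 1L, position_m = NA_real_,
                   stringsAsFactors = FALSE)
    }
  }

  # canopy patch intervals: one patch per occupied quadrat cell, centred
  # on the quadrat, with intercepted length = fraction x cell width
  half <- config$spacing_m / 2
  occ <- which(f0 > 0)
  patches <- cbind(low_m = pmax(0, pos[occ] - half * f0[occ]),
                   high_m = pmin(config$length_m, pos[occ] + half * f0[occ]))

  structure(list(
    quadrats = do.call(rbind, quad_rows),
    library = spectral_library(spectra, do.call(rbind, meta_rows)),
    endmember_library = if (length(em_spectra))
      spectral_library(em_spectra, do.call(rbind, em_meta)) else NULL,
    patches = patches,
    endmember_spectra = em,
    config = config
  ), class = "synthetic_scene")
}

#' @export
print.synthetic_scene <- function(x, ...) {
  cat(sprintf(
    "<synthetic_scene> %d quadrats x %d seasons; %d replicate spectra; %d endmembers\n",
    length(unique(x$quadrats$quadrat_id)), length(x$config$seasons),
    length(x$library), length(x$endmember_library)))
  invisible(x)
}

#' Line-intercept transect summary
#'
#' Computes percent shrub cover and patch density from canopy patch
#' intervals along the transect line: overlapping patches are merged, the
#' merged intercepted lengths are summed and divided by the transect
#' length.
#'
#' @param scene A `synthetic_scene`, or a two-column matrix of patch
#'   intervals (m) if `length_m` is also given.
#' @param length_m Transect length; taken from the scene config if omitted.
#' @return List with `cover_pct`, `density_per_m`, `n_patches` (after
#'   merging) and `total_length_m`.
#' @export
simulate_lit <- function(scene, length_m = NULL) {
  if (inherits(scene, "synthetic_scene")) {
    patches <- scene$patches
    length_m <- scene$config$length_m
  } else {
    patches <- scene
    if (is.null(length_m)) stop("simulate_lit: length_m required")
  }
  if (is.null(patches) || nrow(patches) == 0)
    return(list(cover_pct = 0, density_per_m = 0, n_patches = 0L,
                total_length_m = 0))
  o <- order(patches[, 1])
  lo <- patches[o, 1]; hi <- patches[o, 2]
  m_lo <- lo[1]; m_hi <- hi[1]
  merged <- list()
  for (i in seq_along(lo)[-1]) {
    if (lo[i] <= m_hi) m_hi <- max(m_hi, hi[i])
    else { merged[[length(merged) + 1]] <- c(m_lo, m_hi); m_lo <- lo[i]; m_hi <- hi[i] }
  }
  merged[[length(merged) + 1]] <- c(m_lo, m_hi)
  merged <- do.call(rbind, merged)
  total <- sum(merged[, 2] - merged[, 1])
  list(cover_pct = 100 * total / length_m,
       density_per_m = nrow(merged) / length_m,
       n_patches = nrow(merged),
       total_length_m = total)
}

#' Visual cover quantization
#'
#' Emulates field visual cover estimation: cover is recorded to the
#' nearest 1% when below 5% or above 90%, and to the nearest 5%
#' otherwise. Ties round half to even (R's `round`). The quantizer is
#' idempotent.
#'
#' @param true_pct Numeric vector of true percent cover in `[0, 100]`.
#' @return Quantized percent cover in `[0, 100]`.
#' @export
quantize_cover <- function(true_pct) {
  if (any(is.na(true_pct)) || any(true_pct < 0) || any(true_pct > 100))
    stop("quantize_cover: input must lie in [0, 100]")
  fine <- true_pct < 5 | true_pct > 90
  out <- ifelse(fine, round(true_pct), 5 * round(true_pct / 5))
  pmin(pmax(out, 0), 100)
}

#' Write scene tables to CSV
#'
#' @param scene A `synthetic_scene`.
#' @param dir Output directory (created if needed).
#' @return Named character vector of written paths, invisibly.
#' @export
write_scene <- function(scene, dir) {
  stopifnot(inherits(scene, "synthetic_scene"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  qp <- file.path(dir, "quadrats.csv")
  utils::write.csv(scene$quadrats, qp, row.names = FALSE)
  lp <- file.path(dir, "library.csv")
  write_spectral_library(scene$library, lp)
  ep <- file.path(dir, "endmembers.csv")
  if (!is.null(scene$endmember_library))
    write_spectral_library(scene$endmember_library, ep)
  else ep <- NA_character_
  pp <- file.path(dir, "patches.csv")
  utils::write.csv(as.data.frame(scene$patches), pp, row.names = FALSE)
  invisible(c(quadrats = qp, library = lp, endmembers = ep, patches = pp))
}
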