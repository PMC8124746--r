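#' Pipeline configuration
#'
#' Settings for a full transect analysis. Input is either a synthetic
#' scene (the default; `seed` is then mandatory) or CSV paths written by
#' [write_scene()] / [write_spectral_library()].
#'
#' @param scene Optional [transect_config()] for synthetic input.
#' @param library_path,quadrats_path,endmembers_path,patches_path CSV
#'   inputs used when `scene` is `NULL`.
#' @param mask A [mask_regions()] object (default: the three water
#'   windows).
#' @param cluster_methods Clustering methods used for candidate schemes.
#' @param k_range Candidate cluster counts (default 2:15).
#' @param index_panel Validity-index panel for the majority rule.
#' @param alpha Two-tailed level for the correlation scan (default 0.05).
#' @param min_region_width_nm Minimum separable-region width (default 10).
#' @param td_fallback Emit TD-only regions when the ensemble is empty.
#' @param sensors Band sets to simulate (names for [default_band_set()]).
#' @param outlier_vars Quadrat variables screened at 3 SD.
#' @param seed Master seed.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(scene = transect_config(),
                            library_path = NULL, quadrats_path = NULL,
                            endmembers_path = NULL, patches_path = NULL,
                            mask = mask_regions(),
                            cluster_methods = c("kmeans", "ward"),
                            k_range = 2:15,
                            index_panel = default_index_panel(),
                            alpha = 0.05,
                            min_region_width_nm = 10,
                            td_fallback = TRUE,
                            sensors = c("landsat8_like", "sentinel2_like"),
                            outlier_vars = c("pai", "soil_moisture"),
                            seed = NULL) {
  if (!is.null(scene)) {
    stopifnot(inherits(scene, "transect_config"))
    if (!is.null(seed)) scene$seed <- as.integer(seed)
    seed <- scene$seed
  }
  if (is.null(seed)) stop("pipeline_config: seed is mandatory")
  structure(list(scene = scene, library_path = library_path,
                 quadrats_path = quadrats_path,
                 endmembers_path = endmembers_path,
                 patches_path = patches_path, mask = mask,
                 cluster_methods = cluster_methods, k_range = k_range,
                 index_panel = index_panel, alpha = alpha,
                 min_region_width_nm = min_region_width_nm,
                 td_fallback = td_fallback, sensors = sensors,
                 outlier_vars = outlier_vars, seed = as.integer(seed)),
            class = "pipeline_config")
}

stage_msg <- function(stage, ...) {
  message(sprintf("[%s] %s", stage, sprintf(...)))
}

#' Run the full shrub-detectability pipeline
#'
#' Executes, in order: load or generate the scene; mask water windows and
#' average replicates; biophysical outlier screening, seasonal summaries
#' and differences, and the line-intercept comparison; per-season cover
#' grouping (majority-rule k, K-means + Ward candidates, balanced-scheme
#' selection); the wavelength-wise Spearman scan; separability profiles
#' and ensemble regions of the 0%-cover group against every other group;
#' broadband resampling; per-band ANOVA and Tukey HSD; and the
#' minimum-detectable-cover summary. All tables are returned and, when
#' `out_dir` is given, written as CSV together with a JSON run manifest.
#'
#' @param config A [pipeline_config()].
#' @param out_dir Optional output directory.
#' @return A `pipeline_result` list of all stage outputs.
#' @export
run_pipeline <- function(config = pipeline_config(seed = 1), out_dir = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  res <- list(config = config)

  stage <- "load"
  if (!is.null(config$scene)) {
    stage_msg(stage, "generating synthetic scene (seed %d)", config$seed)
    scene <- generate_scene(config$scene)
  } else {
    if (is.null(config$library_path) || !file.exists(config$library_path))
      stop(sprintf("[%s] spectral library not found: %s", stage,
                   config$library_path %||% "<missing>"))
    stage_msg(stage, "reading %s", config$library_path)
    scene <- list(
      library = read_spectral_library(config$library_path),
      quadrats = utils::read.csv(config$quadrats_path,
                                 stringsAsFactors = FALSE),
      endmember_library = if (!is.null(config$endmembers_path))
        read_spectral_library(config$endmembers_path) else NULL,
      patches = if (!is.null(config$patches_path))
        as.matrix(utils::read.csv(config$patches_path)) else NULL,
      config = NULL)
    class(scene) <- "synthetic_scene"
  }
  res$quadrats <- scene$quadrats

  stage <- "preprocess"
  stage_msg(stage, "masking water windows and averaging replicates")
  lib <- average_replicates(mask_water_regions(scene$library, config$mask))
  emlib <- if (!is.null(scene$endmember_library))
    mask_water_regions(scene$endmember_library, config$mask) else NULL
  res$library <- lib

  stage <- "biophys"
  screened <- remove_outliers(scene$quadrats, config$outlier_vars)
  res$outlier_log <- screened$log
  res$seasonal_summary <- seasonal_summary(screened$table)
  res$seasonal_differences <- tryCatch(
    seasonal_difference(screened$table),
    error = function(e) NULL)
  if (!is.null(scene$patches)) {
    lit <- simulate_lit(scene$patches,
                        length_m = if (!is.null(scene$config))
                          scene$config$length_m else
                            max(scene$quadrats$position_m))
    res$lit <- lit
    first_season <- unique(scene$quadrats$season)[1]
    res$lit_comparison <- compare_lit_quadrat(lit, scene$quadrats,
                                              first_season)
  }

  seasons <- unique(lib$meta$season)
  res$seasons <- list()
  for (se in seasons) {
    stage <- sprintf("season:%s", se)
    stage_msg(stage, "cover grouping")
    sres <- list()
    slib <- subset_library(lib, lib$meta$season == se)
    X <- library_matrix(slib)
    qt <- scene$quadrats[scene$quadrats$season == se, , drop = FALSE]
    qt <- qt[match(slib$meta$quadrat_id, qt$quadrat_id), , drop = FALSE]
    cover <- qt$vis_shrub

    results <- list()
    for (m in config$cluster_methods) {
      ok <- optimal_cluster_count(X, method = m, k_range = config$k_range,
                                  index_panel = config$index_panel,
                                  seed = config$seed)
      results[[m]] <- cluster_spectra(X, ok$k, method = m,
                                      seed = config$seed)
      results[[m]]$index_votes <- ok$votes
    }
    semlib <- if (!is.null(emlib))
      subset_library(emlib, emlib$meta$season == se) else NULL
    n_em <- if (is.null(semlib)) 0 else length(semlib)
    scheme <- build_cover_scheme(results, cover, n_endmembers = n_em)
    sres$cluster_results <- results
    sres$scheme <- scheme

    stage_msg(stage, "correlation scan")
    if (length(unique(cover)) > 1) {
      prof <- spearman_profile(X, cover, alpha = config$alpha)
      sres$correlation_profile <- prof
      sres$correlation_regions <- significant_regions(prof)
    } else {
      stage_msg(stage, "cover constant; correlation scan skipped")
      sres$correlation_profile <- NULL
      sres$correlation_regions <- NULL
    }

    stage_msg(stage, "separability vs 0%% cover group")
    g1 <- which(scheme$group_of == 1)
    sres$separability <- list()
    if (length(g1) >= 2) {
      lib1 <- subset_library(slib, g1)
      targets <- setdiff(seq_len(scheme$n_groups), 1L)
      for (g in targets) {
        idx <- which(scheme$group_of == g)
        gl <- if (length(idx) > 0) subset_library(slib, idx) else NULL
        if (scheme$includes_endmember_group && g == scheme$n_groups) {
          gl <- if (is.null(gl)) semlib else
            spectral_library(c(gl$spectra, semlib$spectra),
                             rbind(gl$meta, semlib$meta))
        }
        if (is.null(gl) || length(gl) < 2) next
        p <- separability_profile(lib1, gl, pair = c("1", as.character(g)),
                                  season = se, var_floor = 1e-8)
        sres$separability[[as.character(g)]] <- list(
          profile = p,
          regions = ensemble_regions(p, config$min_region_width_nm,
                                     td_fallback = config$td_fallback))
      }
    }

    stage_msg(stage, "broadband resampling and group comparison")
    sres$bands <- list()
    for (sn in config$sensors) {
      bs <- default_band_set(sn)
      vals_q <- resample_to_bands(slib, bs)
      grp <- scheme$group_of
      if (!is.null(semlib) && scheme$includes_endmember_group) {
        vals_e <- resample_to_bands(semlib, bs)
        vals <- rbind(vals_q, vals_e)
        grp <- c(grp, rep(scheme$n_groups, length(semlib)))
      } else vals <- vals_q
      tab <- table(grp)
      if (sum(tab >= 2) < 2) {
        stage_msg(stage, "fewer than two populated groups; skipping %s", sn)
        sres$bands[[sn]] <- list(values = vals, group = grp, anova = NULL,
                                 tukey = NULL)
        next
      }
      an <- suppressWarnings(anova_by_band(vals, grp))
      tk <- suppressWarnings(tukey_by_band(vals, grp, season = se))
      sres$bands[[sn]] <- list(values = vals, group = grp, anova = an,
                               tukey = tk)
    }
    res$seasons[[se]] <- sres
  }

  stage <- "summary"
  all_tukey <- do.call(rbind, unlist(lapply(res$seasons, function(s)
    lapply(s$bands, function(b) b$tukey)), recursive = FALSE))
  if (is.null(all_tukey) || nrow(all_tukey) == 0) {
    res$min_detectable <- list(
      minimum = data.frame(season = seasons, level = NA_real_,
                           min_group = NA_integer_,
                           cover_range = "none detectable", bands = "",
                           stringsAsFactors = FALSE),
      band_importance = NULL)
  } else {
    first_scheme <- res$seasons[[1]]$scheme
    res$min_detectable <- min_detectable_cover(all_tukey, first_scheme)
  }

  if (!is.null(out_dir)) write_pipeline_outputs(res, out_dir)
  class(res) <- "pipeline_result"
  res
}

`%||%` <- function(a, b) if (is.null(a)) b else a

write_pipeline_outputs <- function(res, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  wcsv <- function(x, name)
    utils::write.csv(x, file.path(out_dir, name), row.names = FALSE)
  wcsv(res$quadrats, "quadrats.csv")
  wcsv(res$seasonal_summary, "seasonal_summary.csv")
  if (!is.null(res$seasonal_differences))
    wcsv(res$seasonal_differences$direction, "seasonal_differences.csv")
  if (!is.null(res$lit_comparison)) wcsv(res$lit_comparison, "lit_comparison.csv")
  for (se in names(res$seasons)) {
    s <- res$seasons[[se]]
    write_cover_scheme(s$scheme, file.path(out_dir,
                                           sprintf("scheme_%s.csv", se)))
    if (!is.null(s$correlation_profile)) {
      wcsv(as.data.frame(s$correlation_profile),
           sprintf("correlation_profile_%s.csv", se))
      wcsv(s$correlation_regions, sprintf("correlation_regions_%s.csv", se))
    }
    regs <- do.call(rbind, lapply(names(s$separability), function(g) {
      r <- s$separability[[g]]$regions
      if (nrow(r)) cbind(season = se, group = g, r) else NULL
    }))
    if (!is.null(regs)) wcsv(regs, sprintf("separability_regions_%s.csv", se))
    for (sn in names(s$bands)) {
      wcsv(cbind(sample_id = rownames(s$bands[[sn]]$values),
                 as.data.frame(s$bands[[sn]]$values)),
           sprintf("band_values_%s_%s.csv", sn, se))
      if (!is.null(s$bands[[sn]]$tukey))
        wcsv(s$bands[[sn]]$tukey, sprintf("tukey_%s_%s.csv", sn, se))
    }
  }
  wcsv(res$min_detectable$minimum, "min_detectable.csv")
  if (!is.null(res$min_detectable$band_importance))
    wcsv(res$min_detectable$band_importance, "band_importance.csv")
  manifest <- list(
    seed = res$config$seed,
    alpha = res$config$alpha,
    sensors = res$config$sensors,
    k_range = range(res$config$k_range),
    r_version = as.character(getRversion()),
    package_version = as.character(utils::packageVersion("shrubsep")),
    timestamp = format(Sys.time(), tz = "UTC"))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(out_dir)
}
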