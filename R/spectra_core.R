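#' Wavelength grids
#'
#' A `wavelength_grid` is a uniform 1-D sampling of wavelengths in
#' nanometres. Field spectroradiometers in grassland spectroscopy deliver
#' surface reflectance on a 1-nm grid from 350 to 2500 nm (2151 points),
#' which is the default here.
#'
#' @param start_nm,stop_nm Grid limits in nm (`start_nm < stop_nm`).
#' @param step_nm Grid spacing in nm (positive).
#' @return An object of class `wavelength_grid` with elements `start_nm`,
#'   `stop_nm`, `step_nm` and `n` (number of grid points).
#' @examples
#' g <- wavelength_grid()
#' g$n  # 2151
#' @export
wavelength_grid <- function(start_nm = 350, stop_nm = 2500, step_nm = 1) {
  stopifnot(is.numeric(start_nm), is.numeric(stop_nm), is.numeric(step_nm))
  if (!(start_nm < stop_nm)) stop("wavelength_grid: start_nm must be < stop_nm")
  if (!(step_nm > 0)) stop("wavelength_grid: step_nm must be > 0")
  n <- floor((stop_nm - start_nm) / step_nm) + 1L
  structure(
    list(start_nm = start_nm, stop_nm = stop_nm, step_nm = step_nm,
         n = as.integer(n)),
    class = "wavelength_grid"
  )
}

#' Wavelengths of a grid
#'
#' @param grid A `wavelength_grid`.
#' @return Numeric vector of wavelengths (nm), length `grid$n`.
#' @export
grid_wavelengths <- function(grid) {
  stopifnot(inherits(grid, "wavelength_grid"))
  grid$start_nm + grid$step_nm * (seq_len(grid$n) - 1)
}

grids_identical <- function(a, b) {
  isTRUE(all.equal(a$start_nm, b$start_nm)) &&
    isTRUE(all.equal(a$stop_nm, b$stop_nm)) &&
    isTRUE(all.equal(a$step_nm, b$step_nm))
}

#' @export
print.wavelength_grid <- function(x, ...) {
  cat(sprintf("<wavelength_grid> %g-%g nm, step %g nm (%d points)\n",
              x$start_nm, x$stop_nm, x$step_nm, x$n))
  invisible(x)
}

#' Single reflectance spectrum
#'
#' A `spectrum` couples reflectance values with a wavelength grid and a
#' validity mask. Masked grid points (e.g. atmospheric water-absorption
#' windows) carry `NA` reflectance and are excluded from every downstream
#' computation. Reflectances are dimensionless fractions; values slightly
#' above 1 (up to 1.5) occur in field data near panel calibration and are
#' accepted with a warning, anything below 0 or above 1.5 is rejected.
#'
#' @param reflectance Numeric vector of reflectance fractions, one per grid
#'   point; `NA` allowed only where `valid_mask` is `FALSE`.
#' @param grid A `wavelength_grid` (default 350-2500 nm at 1 nm).
#' @param valid_mask Logical vector per grid point; defaults to
#'   `!is.na(reflectance)`.
#' @param sample_id Sample identifier.
#' @param season One of `"spring"`, `"summer"`, `"fall"` (or `NA`).
#' @param replicate Positive integer replicate number.
#' @return A `spectrum` object.
#' @export
spectrum <- function(reflectance, grid = wavelength_grid(),
                     valid_mask = NULL, sample_id = NA_character_,
                     season = NA_character_, replicate = 1L) {
  stopifnot(inherits(grid, "wavelength_grid"))
  reflectance <- as.numeric(reflectance)
  if (length(reflectance) != grid$n)
    stop(sprintf("spectrum: reflectance length %d != grid length %d",
                 length(reflectance), grid$n))
  if (is.null(valid_mask)) valid_mask <- !is.na(reflectance)
  valid_mask <- as.logical(valid_mask)
  if (length(valid_mask) != grid$n)
    stop("spectrum: valid_mask length must equal grid length")
  if (!is.na(season) && !season %in% c("spring", "summer", "fall"))
    stop("spectrum: season must be spring, summer or fall")
  vals <- reflectance[valid_mask]
  if (anyNA(vals) || any(!is.finite(vals)))
    stop("spectrum: non-finite reflectance at valid grid points")
  if (any(vals < 0) || any(vals > 1.5))
    stop("spectrum: reflectance outside [0, 1.5] at valid points")
  if (any(vals > 1))
    warning("spectrum: reflectance in (1, 1.5] accepted (panel calibration overshoot)")
  reflectance[!valid_mask] <- NA_real_
  structure(
    list(grid = grid, reflectance = reflectance, valid_mask = valid_mask,
         sample_id = as.character(sample_id), season = season,
         replicate = as.integer(replicate)),
    class = "spectrum"
  )
}

#' @export
print.spectrum <- function(x, ...) {
  cat(sprintf("<spectrum> %s [%s, rep %d]: %d/%d valid points, %g-%g nm\n",
              x$sample_id, x$season, x$replicate, sum(x$valid_mask),
              x$grid$n, x$grid$start_nm, x$grid$stop_nm))
  invisible(x)
}

#' Spectral library
#'
#' An ordered collection of [spectrum()] objects sharing one wavelength
#' grid, keyed by `(quadrat_id, season, replicate)`. The per-sample
#' metadata table carries the key plus the quadrat position along the
#' transect.
#'
#' @param spectra List of `spectrum` objects.
#' @param meta Data frame with one row per spectrum: `sample_id`,
#'   `quadrat_id`, `season`, `replicate`, `position_m`. Constructed from the
#'   spectra if omitted (quadrat_id taken as sample_id, position unknown).
#' @return A `spectral_library`.
#' @export
spectral_library <- function(spectra, meta = NULL) {
  stopifnot(is.list(spectra), length(spectra) > 0)
  lapply(spectra, function(s) stopifnot(inherits(s, "spectrum")))
  g <- spectra[[1]]$grid
  for (s in spectra) {
    if (!grids_identical(s$grid, g))
      stop("spectral_library: all spectra must share one wavelength grid")
  }
  if (is.null(meta)) {
    meta <- data.frame(
      sample_id = vapply(spectra, `[[`, "", "sample_id"),
      quadrat_id = vapply(spectra, `[[`, "", "sample_id"),
      season = vapply(spectra, `[[`, "", "season"),
      replicate = vapply(spectra, `[[`, 1L, "replicate"),
      position_m = NA_real_,
      stringsAsFactors = FALSE
    )
  }
  stopifnot(nrow(meta) == length(spectra),
            all(c("sample_id", "quadrat_id", "season", "replicate") %in%
                  names(meta)))
  if (!"position_m" %in% names(meta)) meta$position_m <- NA_real_
  key <- paste(meta$quadrat_id, meta$season, meta$replicate, sep = "|")
  if (anyDuplicated(key))
    stop("spectral_library: duplicate (quadrat_id, season, replicate) keys")
  names(spectra) <- meta$sample_id
  structure(list(grid = g, spectra = spectra, meta = meta),
            class = "spectral_library")
}

#' @export
print.spectral_library <- function(x, ...) {
  cat(sprintf("<spectral_library> %d spectra on %g-%g nm grid; seasons: %s\n",
              length(x$spectra), x$grid$start_nm, x$grid$stop_nm,
              paste(unique(x$meta$season), collapse = ", ")))
  invisible(x)
}

#' @export
length.spectral_library <- function(x) length(x$spectra)

#' Reflectance matrix of a library
#'
#' @param lib A `spectral_library`.
#' @param valid_only Drop wavelengths masked in any spectrum (default TRUE).
#' @return Numeric matrix, samples in rows, wavelengths in columns, with
#'   column names the wavelengths in nm and row names the sample ids.
#' @export
library_matrix <- function(lib, valid_only = TRUE) {
  stopifnot(inherits(lib, "spectral_library"))
  wl <- grid_wavelengths(lib$grid)
  X <- t(vapply(lib$spectra, `[[`, numeric(lib$grid$n), "reflectance"))
  colnames(X) <- wl
  rownames(X) <- lib$meta$sample_id
  if (valid_only) {
    keep <- Reduce(`&`, lapply(lib$spectra, `[[`, "valid_mask"))
    X <- X[, keep, drop = FALSE]
  }
  X
}

#' Water-absorption mask regions
#'
#' Closed wavelength intervals to exclude from analysis. Defaults are the
#' three atmospheric water-vapour windows where field spectra are dominated
#' by noise: 1350-1430, 1750-1980 and 2330-2500 nm.
#'
#' @param regions Two-column matrix or list of `c(low, high)` pairs (nm).
#' @return A `mask_regions` object (matrix with columns `low_nm`, `high_nm`).
#' @export
mask_regions <- function(regions = default_water_regions()) {
  if (is.list(regions)) regions <- do.call(rbind, regions)
  regions <- matrix(as.numeric(regions), ncol = 2)
  colnames(regions) <- c("low_nm", "high_nm")
  if (nrow(regions) > 0 && any(regions[, 1] > regions[, 2]))
    stop("mask_regions: low > high in a region")
  structure(regions, class = c("mask_regions", "matrix"))
}

#' @rdname mask_regions
#' @export
default_water_regions <- function() {
  matrix(c(1350, 1430,
           1750, 1980,
           2330, 2500), ncol = 2, byrow = TRUE,
         dimnames = list(NULL, c("low_nm", "high_nm")))
}

#' Clip mask regions to a grid's bounds
#'
#' Intersects each region with the grid span and drops regions that fall
#' entirely outside it, so the default water windows can be applied to
#' spectra covering only part of the full range.
#'
#' @param regions A [mask_regions()] object.
#' @param grid A `wavelength_grid`.
#' @return A clipped `mask_regions` object.
#' @export
clip_mask_regions <- function(regions, grid) {
  regions <- mask_regions(unclass(regions))
  if (nrow(regions) == 0) return(regions)
  lo <- pmax(regions[, "low_nm"], grid$start_nm)
  hi <- pmin(regions[, "high_nm"], grid$stop_nm)
  keep <- lo <= hi
  mask_regions(cbind(lo[keep], hi[keep]))
}

#' Mask water-absorption regions of a spectrum or library
#'
#' Sets the validity mask to `FALSE` at every grid point falling inside any
#' of the given closed intervals (inclusive endpoints). Idempotent.
#'
#' @param x A `spectrum` or `spectral_library`.
#' @param regions A [mask_regions()] object (default: the three water
#'   windows).
#' @return Object of the same class with updated masks.
#' @export
mask_water_regions <- function(x, regions = mask_regions()) {
  UseMethod("mask_water_regions")
}

#' @export
mask_water_regions.spectrum <- function(x, regions = mask_regions()) {
  regions <- mask_regions(unclass(regions))
  wl <- grid_wavelengths(x$grid)
  if (nrow(regions) > 0 &&
      (any(regions[, "low_nm"] < x$grid$start_nm) ||
       any(regions[, "high_nm"] > x$grid$stop_nm)))
    stop("mask_water_regions: region outside grid bounds")
  drop <- rep(FALSE, length(wl))
  for (i in seq_len(nrow(regions)))
    drop <- drop | (wl >= regions[i, "low_nm"] & wl <= regions[i, "high_nm"])
  x$valid_mask <- x$valid_mask & !drop
  x$reflectance[!x$valid_mask] <- NA_real_
  x
}

#' @export
mask_water_regions.spectral_library <- function(x, regions = mask_regions()) {
  x$spectra <- lapply(x$spectra, mask_water_regions, regions = regions)
  x
}

#' Average replicate spectra
#'
#' Collapses each `(quadrat_id, season)` group of replicate spectra to its
#' arithmetic mean, the standard reduction from repeated 0.5-m spot
#' measurements to one spectrum per 1 x 1 m quadrat. A wavelength is valid
#' in the mean only if it is valid in every replicate.
#'
#' @param lib A `spectral_library`.
#' @return A `spectral_library` with one spectrum per (quadrat, season),
#'   `replicate = 1`, `sample_id = "<quadrat>_<season>"`.
#' @export
average_replicates <- function(lib) {
  stopifnot(inherits(lib, "spectral_library"))
  key <- paste(lib$meta$quadrat_id, lib$meta$season, sep = "|")
  groups <- split(seq_along(lib$spectra), key)
  # keep first-appearance order rather than alphabetical
  groups <- groups[unique(key)]
  out <- vector("list", length(groups))
  meta <- vector("list", length(groups))
  for (i in seq_along(groups)) {
    idx <- groups[[i]]
    if (length(idx) == 0) stop("average_replicates: empty replicate group")
    R <- vapply(lib$spectra[idx], `[[`, numeric(lib$grid$n), "reflectance")
    V <- vapply(lib$spectra[idx], `[[`, logical(lib$grid$n), "valid_mask")
    if (is.null(dim(R))) { R <- matrix(R, ncol = 1); V <- matrix(V, ncol = 1) }
    valid <- apply(V, 1, all)
    m <- rowMeans(R)
    m[!valid] <- NA_real_
    q <- lib$meta$quadrat_id[idx[1]]
    se <- lib$meta$season[idx[1]]
    out[[i]] <- spectrum(m, lib$grid, valid_mask = valid,
                         sample_id = paste(q, se, sep = "_"),
                         season = se, replicate = 1L)
    meta[[i]] <- data.frame(sample_id = paste(q, se, sep = "_"),
                            quadrat_id = q, season = se, replicate = 1L,
                            position_m = lib$meta$position_m[idx[1]],
                            stringsAsFactors = FALSE)
  }
  spectral_library(out, do.call(rbind, meta))
}

fmt6 <- function(x) {
  out <- ifelse(is.na(x), "", formatC(x, digits = 6, format = "g"))
  out
}

#' Write a spectral library to wide CSV
#'
#' Writes two UTF-8 comma-separated files: `<path>` with the wavelength
#' column first and one column per sample (reflectance to 6 significant
#' digits; masked points as empty cells), and a metadata sidecar
#' `<path minus .csv>_meta.csv` with columns `sample_id, quadrat_id,
#' season, replicate, position_m`. [read_spectral_library()] on the result
#' reproduces the library exactly at the written precision.
#'
#' @param lib A `spectral_library` (non-empty).
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_spectral_library <- function(lib, path) {
  stopifnot(inherits(lib, "spectral_library"))
  if (length(lib$spectra) == 0) stop("write_spectral_library: empty library")
  wl <- grid_wavelengths(lib$grid)
  df <- data.frame(wavelength_nm = wl)
  for (i in seq_along(lib$spectra))
    df[[lib$meta$sample_id[i]]] <- fmt6(lib$spectra[[i]]$reflectance)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE, na = "")
  utils::write.csv(lib$meta, meta_path(path), row.names = FALSE)
  invisible(path)
}

meta_path <- function(path) sub("\\.csv$", "_meta.csv", path)

#' Read a spectral library from wide CSV
#'
#' Inverse of [write_spectral_library()]. The wavelength column must be a
#' uniform grid; empty cells become masked points.
#'
#' @param path CSV path written by [write_spectral_library()] (a
#'   `<path>_meta.csv` sidecar is read when present).
#' @return A `spectral_library`.
#' @export
read_spectral_library <- function(path) {
  if (!file.exists(path)) stop("read_spectral_library: file not found: ", path)
  df <- utils::read.csv(path, check.names = FALSE,
                        colClasses = "character")
  if (ncol(df) < 2) stop("read_spectral_library: need wavelength + >=1 sample column")
  wl <- suppressWarnings(as.numeric(df[[1]]))
  if (anyNA(wl)) stop("read_spectral_library: non-numeric wavelength cell")
  steps <- diff(wl)
  if (length(steps) < 1 || any(abs(steps - steps[1]) > 1e-9))
    stop("read_spectral_library: wavelength column is not a uniform grid")
  g <- wavelength_grid(wl[1], wl[length(wl)], steps[1])
  mp <- meta_path(path)
  meta <- if (file.exists(mp)) {
    utils::read.csv(mp, stringsAsFactors = FALSE)
  } else {
    data.frame(sample_id = names(df)[-1], quadrat_id = names(df)[-1],
               season = NA_character_,
               replicate = 1L, position_m = NA_real_,
               stringsAsFactors = FALSE)
  }
  spectra <- vector("list", ncol(df) - 1)
  for (j in 2:ncol(df)) {
    cell <- df[[j]]
    blank <- is.na(cell) | cell == ""
    val <- suppressWarnings(as.numeric(cell))
    if (any(is.na(val) & !blank))
      stop(sprintf("read_spectral_library: non-numeric cell in column '%s' (row %d)",
                   names(df)[j], which(is.na(val) & !blank)[1]))
    mrow <- match(names(df)[j], meta$sample_id)
    if (is.na(mrow))
      stop("read_spectral_library: sample '", names(df)[j], "' missing from metadata")
    spectra[[j - 1]] <- spectrum(val, g, valid_mask = !blank,
                                 sample_id = names(df)[j],
                                 season = meta$season[mrow],
                                 replicate = meta$replicate[mrow])
  }
  spectral_library(spectra, meta[match(names(df)[-1], meta$sample_id), ])
}

#' Subset a spectral library
#'
#' @param lib A `spectral_library`.
#' @param idx Logical or integer index into samples.
#' @return A `spectral_library` with the selected spectra.
#' @export
subset_library <- function(lib, idx) {
  stopifnot(inherits(lib, "spectral_library"))
  spectral_library(lib$spectra[idx], lib$meta[idx, , drop = FALSE])
}
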