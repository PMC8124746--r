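#' Band spectral response
#'
#' @param name Band label.
#' @param wavelengths Wavelengths (nm) at which the response is tabulated.
#' @param response Relative response weights (non-negative, max > 0;
#'   normalized to peak 1 on construction).
#' @return A `band_response`.
#' @export
band_response <- function(name, wavelengths, response) {
  stopifnot(length(wavelengths) == length(response))
  if (any(response < 0)) stop("band_response: negative response")
  if (max(response) <= 0) stop("band_response: all-zero response")
  o <- order(wavelengths)
  structure(list(name = name, wavelengths = wavelengths[o],
                 response = response[o] / max(response)),
            class = "band_response")
}

#' Band set
#'
#' @param sensor Sensor label.
#' @param bands List of [band_response()] objects with unique names.
#' @return A `band_set`.
#' @export
band_set <- function(sensor, bands) {
  nm <- vapply(bands, `[[`, "", "name")
  if (anyDuplicated(nm)) stop("band_set: duplicate band names")
  names(bands) <- nm
  structure(list(sensor = sensor, bands = bands), class = "band_set")
}

#' @export
print.band_set <- function(x, ...) {
  cat(sprintf("<band_set> %s: %s\n", x$sensor,
              paste(names(x$bands), collapse = ", ")))
  invisible(x)
}

#' Load spectral response functions from long-format CSV
#'
#' Expected columns: `sensor`, `band`, `wavelength_nm`, `response`.
#' Responses are normalized to peak 1 per band.
#'
#' @param path CSV path.
#' @param grid Wavelength grid used to bound-check wavelengths.
#' @return A [band_set()] (one file = one sensor).
#' @export
load_band_responses <- function(path, grid = wavelength_grid()) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  stopifnot(all(c("sensor", "band", "wavelength_nm", "response") %in%
                  names(df)))
  if (any(df$response < 0))
    stop("load_band_responses: negative response value")
  if (any(df$wavelength_nm < grid$start_nm | df$wavelength_nm > grid$stop_nm))
    stop("load_band_responses: wavelength outside grid bounds")
  if (length(unique(df$sensor)) != 1)
    stop("load_band_responses: expected a single sensor per file")
  bands <- lapply(split(df, df$band), function(g)
    band_response(g$band[1], g$wavelength_nm, g$response))
  band_set(df$sensor[1], bands[unique(df$band)])
}

#' Synthesize parametric band responses
#'
#' Gaussian bands use `sigma = fwhm / 2.3548` (so the response is 0.5 at
#' `center +- fwhm/2`); boxcar bands are 1 on `[center - fwhm/2,
#' center + fwhm/2]` and 0 elsewhere.
#'
#' @param spec Data frame with columns `name`, `center_nm`, `fwhm_nm`,
#'   `shape` (`"gaussian"` or `"boxcar"`).
#' @param sensor Sensor label.
#' @param grid Wavelength grid on which responses are tabulated.
#' @return A [band_set()].
#' @export
synth_band_responses <- function(spec, sensor = "synthetic",
                                 grid = wavelength_grid()) {
  stopifnot(all(c("name", "center_nm", "fwhm_nm", "shape") %in% names(spec)))
  if (any(spec$fwhm_nm <= 0)) stop("synth_band_responses: fwhm must be > 0")
  if (any(spec$center_nm < grid$start_nm | spec$center_nm > grid$stop_nm))
    stop("synth_band_responses: center outside grid")
  if (anyDuplicated(spec$name)) stop("synth_band_responses: duplicate band names")
  wl <- grid_wavelengths(grid)
  bands <- lapply(seq_len(nrow(spec)), function(i) {
    sh <- match.arg(spec$shape[i], c("gaussian", "boxcar"))
    r <- if (sh == "gaussian") {
      sigma <- spec$fwhm_nm[i] / (2 * sqrt(2 * log(2)))
      exp(-0.5 * ((wl - spec$center_nm[i]) / sigma)^2)
    } else {
      as.numeric(wl >= spec$center_nm[i] - spec$fwhm_nm[i] / 2 &
                   wl <= spec$center_nm[i] + spec$fwhm_nm[i] / 2)
    }
    keep <- r > 1e-6
    band_response(spec$name[i], wl[keep], r[keep])
  })
  band_set(sensor, bands)
}

#' Bundled parametric band sets
#'
#' Gaussian approximations of multispectral sensor bands at their nominal
#' centers and full widths at half maximum: a Landsat-8-like set (blue,
#' green, red, NIR, SWIR-1, SWIR-2) and a Sentinel-2-like set adding the
#' three red-edge bands and the water-vapour band. These are parametric
#' stand-ins for official response tables, which can be supplied through
#' [load_band_responses()].
#'
#' @param sensor `"landsat8_like"` or `"sentinel2_like"`.
#' @param grid Wavelength grid.
#' @return A [band_set()].
#' @export
default_band_set <- function(sensor = c("landsat8_like", "sentinel2_like"),
                             grid = wavelength_grid()) {
  sensor <- match.arg(sensor)
  spec <- if (sensor == "landsat8_like") {
    data.frame(
      name = c("blue", "green", "red", "NIR", "SWIR_1", "SWIR_2"),
      center_nm = c(482, 561, 655, 865, 1609, 2201),
      fwhm_nm = c(60, 57, 37, 28, 85, 187),
      shape = "gaussian", stringsAsFactors = FALSE)
  } else {
    data.frame(
      name = c("blue", "green", "red", "red_edge_1", "red_edge_2",
               "red_edge_3", "NIR", "water_vapor", "SWIR_1", "SWIR_2"),
      center_nm = c(492, 560, 665, 704, 740, 783, 833, 945, 1614, 2202),
      fwhm_nm = c(66, 36, 31, 15, 15, 20, 106, 21, 91, 175),
      shape = "gaussian", stringsAsFactors = FALSE)
  }
  synth_band_responses(spec, sensor, grid)
}

#' Resample a spectrum to broadband values
#'
#' Band value = response-weighted mean reflectance over the band's valid
#' wavelengths: `sum(R * rho) / sum(R)`. A band whose support is entirely
#' masked yields `NA`.
#'
#' @param s A [spectrum()], or a `spectral_library` (then a sample-by-band
#'   matrix is returned).
#' @param bands A [band_set()].
#' @return Named numeric vector of band reflectances (or matrix for a
#'   library).
#' @export
resample_to_bands <- function(s, bands) {
  stopifnot(inherits(bands, "band_set"))
  if (inherits(s, "spectral_library")) {
    out <- t(vapply(s$spectra, resample_to_bands,
                    numeric(length(bands$bands)), bands = bands))
    rownames(out) <- s$meta$sample_id
    return(out)
  }
  stopifnot(inherits(s, "spectrum"))
  wl <- grid_wavelengths(s$grid)
  vapply(bands$bands, function(b) {
    w <- stats::approx(b$wavelengths, b$response, xout = wl,
                       yleft = 0, yright = 0)$y
    w[!s$valid_mask] <- 0
    if (sum(w) <= 0) return(NA_real_)
    sum(w * s$reflectance, na.rm = TRUE) / sum(w)
  }, 0)
}

#' Effective (equivalent) bandwidth of a band response
#'
#' Equivalent width `sum(R * dlambda) / max(R)` — the width of the boxcar
#' with the same peak and integrated response. For a boxcar this is its
#' width; for a Gaussian it is `fwhm * sqrt(pi / (4 ln 2)) ~= 1.0645 fwhm`.
#'
#' @param b A [band_response()].
#' @return Width in nm.
#' @export
effective_bandwidth <- function(b) {
  stopifnot(inherits(b, "band_response"))
  wl <- b$wavelengths
  if (length(wl) == 1) return(0)
  # trapezoidal integral over the tabulated support
  sum(diff(wl) * (utils::head(b$response, -1) + utils::tail(b$response, -1)) / 2) /
    max(b$response)
}
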