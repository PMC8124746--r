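#' Two-tailed critical value of the Spearman rank correlation
#'
#' For n > 30 the Student-t approximation is used:
#' `r_c = t / sqrt(n - 2 + t^2)` with `t` the two-tailed quantile at
#' `df = n - 2`. For n <= 30 the permutation null of the rank correlation
#' is evaluated directly — exhaustively for n <= 8, otherwise by seeded
#' Monte-Carlo — and the `1 - alpha` quantile of `|r|` is returned.
#'
#' @param n Sample size (>= 4).
#' @param alpha Two-tailed significance level (default 0.05).
#' @param n_perm Monte-Carlo permutations for 8 < n <= 30 (default 2e5).
#' @param seed Seed for the Monte-Carlo branch.
#' @return List with `r_critical` (full precision), `r_critical_2dp`
#'   (display rounding), `n`, `alpha`, `method`.
#' @examples
#' spearman_critical(128)$r_critical_2dp  # 0.17
#' @export
spearman_critical <- function(n, alpha = 0.05, n_perm = 2e5, seed = 1L) {
  if (n < 4) stop("spearman_critical: n must be >= 4")
  if (n > 30) {
    t <- stats::qt(1 - alpha / 2, df = n - 2)
    rc <- t / sqrt(n - 2 + t^2)
    method <- "t-approximation"
  } else {
    base <- seq_len(n)
    rs <- if (n <= 8) {
      perms <- all_permutations(n)
      apply(perms, 1, function(p) stats::cor(base, p, method = "spearman"))
    } else {
      set.seed(seed)
      replicate(n_perm, stats::cor(base, sample(base), method = "spearman"))
    }
    # smallest attainable |r| whose exceedance probability is <= alpha
    # (the convention of published Spearman critical-value tables)
    av <- sort(unique(abs(rs)))
    exceed <- vapply(av, function(v) mean(abs(rs) >= v - 1e-12), 0)
    rc <- av[which(exceed <= alpha)[1]]
    method <- if (n <= 8) "exact permutation" else "Monte-Carlo permutation"
  }
  list(r_critical = rc, r_critical_2dp = round(rc, 2), n = n,
       alpha = alpha, method = method)
}

all_permutations <- function(n) {
  if (n == 1) return(matrix(1, 1, 1))
  sub <- all_permutations(n - 1)
  out <- matrix(0L, nrow(sub) * n, n)
  r <- 0
  for (i in seq_len(n)) {
    block <- cbind(i, ifelse(sub >= i, sub + 1L, sub))
    out[r + seq_len(nrow(sub)), ] <- block
    r <- r + nrow(sub)
  }
  out
}

#' Wavelength-wise Spearman correlation with shrub cover
#'
#' Computes the tie-corrected Spearman rank correlation between
#' reflectance and visually estimated shrub cover at every valid
#' wavelength along the transect, flags wavelengths whose |r| reaches
#' the analytic two-tailed critical value, and records the sign.
#'
#' @param X Sample-by-wavelength reflectance matrix (e.g.
#'   [library_matrix()] of the averaged library) or `spectral_library`.
#' @param cover Per-sample shrub cover percent (not constant, n >= 4).
#' @param alpha Two-tailed significance level (default 0.05), applied
#'   per wavelength.
#' @param family_wise Apply a Bonferroni family-wise correction across
#'   wavelengths (the critical value is computed at
#'   `alpha / n_wavelengths`); off by default, matching the
#'   per-wavelength reading of a band-selection scan.
#' @return A `correlation_profile` data frame: `wavelength`, `r`,
#'   `significant`, `sign`; attributes `n`, `r_critical`, `alpha`.
#' @export
spearman_profile <- function(X, cover, alpha = 0.05, family_wise = FALSE) {
  if (inherits(X, "spectral_library")) X <- library_matrix(X)
  X <- as.matrix(X)
  n <- nrow(X)
  if (n < 4) stop("spearman_profile: need n >= 4")
  if (length(cover) != n) stop("spearman_profile: cover length mismatch")
  if (length(unique(cover)) == 1)
    stop("spearman_profile: cover is constant; correlation undefined")
  eff_alpha <- if (family_wise) alpha / ncol(X) else alpha
  rc <- spearman_critical(n, eff_alpha)
  r <- suppressWarnings(
    as.vector(stats::cor(X, cover, method = "spearman")))
  out <- data.frame(wavelength = as.numeric(colnames(X)), r = r,
                    significant = !is.na(r) & abs(r) >= rc$r_critical,
                    sign = ifelse(r >= 0, "+", "-"),
                    stringsAsFactors = FALSE)
  attr(out, "n") <- n
  attr(out, "r_critical") <- rc$r_critical
  attr(out, "alpha") <- alpha
  class(out) <- c("correlation_profile", "data.frame")
  out
}

#' Signed significant-correlation regions
#'
#' Maximal contiguous runs of significant wavelengths sharing one sign,
#' broken at masked water windows. No width filter is applied here (one
#' wavelength is a valid run); each run carries its peak |r|.
#'
#' @param profile A [spearman_profile()] result.
#' @return Data frame: `low_nm`, `high_nm`, `sign`, `peak_r`,
#'   `peak_wavelength`, sorted by `low_nm`.
#' @export
significant_regions <- function(profile) {
  stopifnot(all(c("wavelength", "r", "significant", "sign") %in%
                  names(profile)))
  step <- if (nrow(profile) > 1) min(diff(profile$wavelength)) else 1
  rows <- list()
  for (sg in c("-", "+")) {
    runs <- contiguous_runs(profile$wavelength,
                            profile$significant & profile$sign == sg, step)
    if (is.null(runs)) next
    for (i in seq_len(nrow(runs))) {
      inside <- profile$wavelength >= runs[i, "low"] &
        profile$wavelength <= runs[i, "high"]
      pk <- which.max(abs(profile$r) * inside)
      rows[[length(rows) + 1]] <- data.frame(
        low_nm = runs[i, "low"], high_nm = runs[i, "high"], sign = sg,
        peak_r = profile$r[pk], peak_wavelength = profile$wavelength[pk],
        stringsAsFactors = FALSE)
    }
  }
  if (!length(rows))
    return(data.frame(low_nm = numeric(), high_nm = numeric(),
                      sign = character(), peak_r = numeric(),
                      peak_wavelength = numeric(), stringsAsFactors = FALSE))
  out <- do.call(rbind, rows)
  out <- out[order(out$low_nm), , drop = FALSE]
  rownames(out) <- NULL
  out
}
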