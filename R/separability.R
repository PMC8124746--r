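#' Univariate spectral separability statistics
#'
#' Closed forms for the five standard class-separability statistics
#' between two univariate normal distributions, evaluated elementwise, so
#' all arguments may be vectors over wavelengths:
#' \deqn{M = |\mu_1 - \mu_2| / (\sigma_1 + \sigma_2)}
#' \deqn{B = \frac{(\mu_1-\mu_2)^2}{4(\sigma_1^2+\sigma_2^2)} +
#'   \frac12 \ln\!\frac{(\sigma_1^2+\sigma_2^2)/2}{\sigma_1\sigma_2}}
#' \deqn{D = \frac12\left(\frac{\sigma_1^2}{\sigma_2^2} +
#'   \frac{\sigma_2^2}{\sigma_1^2} - 2\right) +
#'   \frac12 (\mu_1-\mu_2)^2 \left(\frac1{\sigma_1^2}+\frac1{\sigma_2^2}\right)}
#' \deqn{TD = 2(1 - e^{-D/8}), \quad JM = 2(1 - e^{-B})}
#' M has no upper bound interpretation beyond its >1 rule; B and D grow
#' without bound; TD and JM saturate at 2 (maximal separability). When
#' the two distributions coincide all five are 0.
#'
#' @param mu1,sd1,mu2,sd2 Means and standard deviations of the two
#'   groups (vectors recycled to a common length; all SDs must be > 0
#'   unless `var_floor` is set).
#' @param var_floor Optional variance floor: SDs below `sqrt(var_floor)`
#'   are raised to it instead of erroring (default `NULL` = strict).
#' @return Data frame with columns `M`, `B`, `D`, `TD`, `JM`.
#' @examples
#' pairwise_metrics(0, 1, 1, 1)  # M = 0.5, B = 0.125, D = 1
#' @export
pairwise_metrics <- function(mu1, sd1, mu2, sd2, var_floor = NULL) {
  n <- max(length(mu1), length(sd1), length(mu2), length(sd2))
  mu1 <- rep_len(mu1, n); sd1 <- rep_len(sd1, n)
  mu2 <- rep_len(mu2, n); sd2 <- rep_len(sd2, n)
  if (!is.null(var_floor)) {
    sd1 <- pmax(sd1, sqrt(var_floor))
    sd2 <- pmax(sd2, sqrt(var_floor))
  }
  bad <- which(sd1 <= 0 | sd2 <= 0)
  if (length(bad))
    stop("pairwise_metrics: zero or negative SD at position(s) ",
         paste(utils::head(bad, 5), collapse = ", "),
         "; supply var_floor to floor degenerate variances explicitly")
  v1 <- sd1^2; v2 <- sd2^2
  dmu2 <- (mu1 - mu2)^2
  M <- sqrt(dmu2) / (sd1 + sd2)
  B <- dmu2 / (4 * (v1 + v2)) + 0.5 * log(((v1 + v2) / 2) / (sd1 * sd2))
  D <- 0.5 * (v1 / v2 + v2 / v1 - 2) + 0.5 * dmu2 * (1 / v1 + 1 / v2)
  data.frame(M = M, B = B, D = D,
             TD = 2 * (1 - exp(-D / 8)),
             JM = 2 * (1 - exp(-B)))
}

#' Per-wavelength moments of a spectra group
#'
#' @param lib A `spectral_library` (or reflectance matrix from
#'   [library_matrix()]).
#' @return List with `mu`, `sd` (sample SD, n-1), `n` and `wavelength`.
#' @export
group_moments <- function(lib) {
  X <- if (inherits(lib, "spectral_library")) library_matrix(lib) else as.matrix(lib)
  if (nrow(X) < 2) stop("group_moments: need >= 2 spectra")
  list(mu = colMeans(X),
       sd = apply(X, 2, stats::sd),
       n = nrow(X),
       wavelength = as.numeric(colnames(X)))
}

#' Separability profile between two spectra groups
#'
#' Computes per-wavelength group moments (sample SD) for two groups of
#' quadrat spectra sharing a grid and mask, then all five separability
#' statistics at every valid wavelength, with per-metric threshold
#' classes.
#'
#' @param group_a,group_b `spectral_library` objects or reflectance
#'   matrices with identical wavelength columns; each needs >= 2 spectra.
#' @param pair Optional length-2 labels for the two groups.
#' @param season Optional season label carried into the profile.
#' @param var_floor Optional variance floor forwarded to
#'   [pairwise_metrics()] (default `NULL`: zero-variance wavelengths are
#'   an error listing the offending wavelengths).
#' @return A `separability_profile` data frame: `wavelength`, `M`, `B`,
#'   `D`, `TD`, `JM`, `class_M`, `class_TD`, `class_JM`, with attributes
#'   `pair`, `season`, `n`.
#' @export
separability_profile <- function(group_a, group_b, pair = c("a", "b"),
                                 season = NA_character_, var_floor = NULL) {
  ma <- group_moments(group_a)
  mb <- group_moments(group_b)
  if (length(ma$mu) != length(mb$mu) ||
      any(abs(ma$wavelength - mb$wavelength) > 1e-9))
    stop("separability_profile: groups must share wavelengths and mask")
  if (is.null(var_floor)) {
    zv <- ma$sd <= 0 | mb$sd <= 0
    if (any(zv))
      stop("separability_profile: zero variance at wavelength(s) ",
           paste(utils::head(ma$wavelength[zv], 8), collapse = ", "))
  }
  m <- pairwise_metrics(ma$mu, ma$sd, mb$mu, mb$sd, var_floor = var_floor)
  out <- data.frame(wavelength = ma$wavelength, m)
  out$class_M <- classify_value("M", out$M)
  out$class_TD <- classify_value("TD", out$TD)
  out$class_JM <- classify_value("JM", out$JM)
  attr(out, "pair") <- pair
  attr(out, "season") <- season
  attr(out, "n") <- c(ma$n, mb$n)
  class(out) <- c("separability_profile", "data.frame")
  out
}

#' Threshold classification of separability values
#'
#' TD and JM (range 0-2): >= 1.8 good, above 1.5 and below 1.8 moderate,
#' <= 1.5 poor. M: > 1 good, otherwise poor (M has no moderate class).
#' B and D have no upper bound and therefore no defined classes.
#'
#' @param metric `"M"`, `"TD"` or `"JM"`.
#' @param value Numeric vector of finite values.
#' @return Character vector in `c("good", "moderate", "poor")`.
#' @export
classify_value <- function(metric, value) {
  if (any(!is.finite(value))) stop("classify_value: non-finite value")
  switch(metric,
    M = ifelse(value > 1, "good", "poor"),
    TD = ,
    JM = ifelse(value >= 1.8, "good",
                ifelse(value > 1.5, "moderate", "poor")),
    stop("classify_value: no threshold rule for metric '", metric, "'"))
}

# maximal runs of TRUE in `flag`, broken where wavelengths are not
# contiguous (mask gaps); returns (low, high) wavelength pairs
contiguous_runs <- function(wavelength, flag, step = 1) {
  idx <- which(flag)
  if (!length(idx)) return(NULL)
  brk <- c(0, which(diff(idx) > 1 |
                      abs(diff(wavelength[idx]) - step) > 1e-9),
           length(idx))
  out <- list()
  for (i in seq_len(length(brk) - 1)) {
    seg <- idx[(brk[i] + 1):brk[i + 1]]
    out[[i]] <- c(low = wavelength[seg[1]], high = wavelength[seg[length(seg)]])
  }
  do.call(rbind, out)
}

#' Ensemble extraction of separable wavelength regions
#'
#' Good regions are maximal contiguous wavelength runs where both TD and
#' JM are >= 1.8; moderate regions are runs where both exceed 1.5 without
#' qualifying as good. Runs are broken at masked water windows, and runs
#' narrower than `min_width_nm` are dropped. When the ensemble yields no
#' region at all and `td_fallback` is `TRUE`, TD-only regions are emitted
#' and labelled as such (useful in fall, when JM saturates low).
#'
#' @param profile A [separability_profile()].
#' @param min_width_nm Minimum region width in nm (default 10; width of a
#'   run from `low` to `high` on a 1-nm grid is `high - low + 1`).
#' @param td_fallback Emit TD-only regions when the ensemble is empty.
#' @return Data frame: `low_nm`, `high_nm`, `width_nm`, `klass`
#'   (`"good"`/`"moderate"`), `basis` (`"ensemble"` or `"td_only"`),
#'   sorted by `low_nm`. Zero rows when nothing qualifies.
#' @export
ensemble_regions <- function(profile, min_width_nm = 10, td_fallback = FALSE) {
  stopifnot(all(c("TD", "JM", "wavelength") %in% names(profile)))
  step <- if (nrow(profile) > 1) min(diff(profile$wavelength)) else 1
  build <- function(good_flag, mod_flag, basis) {
    rows <- list()
    for (kl in c("good", "moderate")) {
      fl <- if (kl == "good") good_flag else mod_flag
      runs <- contiguous_runs(profile$wavelength, fl, step)
      if (is.null(runs)) next
      for (i in seq_len(nrow(runs))) {
        w <- runs[i, "high"] - runs[i, "low"] + step
        if (w >= min_width_nm)
          rows[[length(rows) + 1]] <- data.frame(
            low_nm = runs[i, "low"], high_nm = runs[i, "high"],
            width_nm = w, klass = kl, basis = basis,
            stringsAsFactors = FALSE)
      }
    }
    if (!length(rows))
      return(data.frame(low_nm = numeric(), high_nm = numeric(),
                        width_nm = numeric(), klass = character(),
                        basis = character(), stringsAsFactors = FALSE))
    out <- do.call(rbind, rows)
    out[order(out$low_nm), , drop = FALSE]
  }
  good <- profile$TD >= 1.8 & profile$JM >= 1.8
  mod <- (profile$TD > 1.5 & profile$JM > 1.5) & !good
  out <- build(good, mod, "ensemble")
  if (nrow(out) == 0 && td_fallback) {
    good_td <- profile$TD >= 1.8
    mod_td <- profile$TD > 1.5 & !good_td
    out <- build(good_td, mod_td, "td_only")
  }
  rownames(out) <- NULL
  out
}

#' Shapiro-Wilk normality diagnostic per wavelength
#'
#' Advisory check run before a separability analysis: the per-wavelength
#' Shapiro-Wilk test at `alpha` over one group's spectra, with the
#' fraction of wavelengths passing. Field spectra groups are typically
#' normal at 84-100% of wavelengths; the diagnostic never blocks the
#' pipeline. Zero-variance wavelengths (where the test is undefined) are
#' reported as failures with a reason.
#'
#' @param lib A `spectral_library` or reflectance matrix (>= 3 spectra).
#' @param alpha Significance level (default 0.05).
#' @return List with `table` (wavelength, p, pass, reason) and
#'   `pass_fraction`.
#' @export
normality_diagnostic <- function(lib, alpha = 0.05) {
  X <- if (inherits(lib, "spectral_library")) library_matrix(lib) else as.matrix(lib)
  if (nrow(X) < 3) stop("normality_diagnostic: need >= 3 spectra")
  wl <- as.numeric(colnames(X))
  p <- rep(NA_real_, ncol(X))
  reason <- rep("", ncol(X))
  for (j in seq_len(ncol(X))) {
    x <- X[, j]
    if (stats::sd(x) == 0) { reason[j] <- "zero variance"; next }
    p[j] <- stats::shapiro.test(x)$p.value
  }
  pass <- !is.na(p) & p >= alpha
  list(table = data.frame(wavelength = wl, p = p, pass = pass,
                          reason = reason, stringsAsFactors = FALSE),
       pass_fraction = mean(pass))
}
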