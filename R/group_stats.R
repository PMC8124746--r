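#' One-way ANOVA per broadband band
#'
#' Tests, band by band, whether mean band reflectance differs among
#' shrub-cover groups. Groups with fewer than 2 members are excluded with
#' a warning.
#'
#' @param values Sample-by-band numeric matrix (e.g. from
#'   [resample_to_bands()] on a library).
#' @param group Integer group id per sample (row).
#' @param welch Use Welch's heteroscedastic ANOVA instead of the
#'   classical equal-variance F test (default `FALSE`).
#' @return Data frame: `band`, `F`, `p`, `df_between`, `df_within`.
#' @export
anova_by_band <- function(values, group, welch = FALSE) {
  values <- as.matrix(values)
  stopifnot(nrow(values) == length(group))
  tab <- table(group)
  small <- names(tab)[tab < 2]
  if (length(small)) {
    warning("anova_by_band: excluding group(s) with < 2 members: ",
            paste(small, collapse = ", "))
    keep <- !group %in% as.numeric(small)
    values <- values[keep, , drop = FALSE]
    group <- group[keep]
  }
  if (length(unique(group)) < 2)
    stop("anova_by_band: need >= 2 groups with >= 2 members")
  g <- factor(group)
  out <- lapply(colnames(values), function(b) {
    y <- values[, b]
    ok <- !is.na(y)
    fit <- stats::oneway.test(y[ok] ~ g[ok], var.equal = !welch)
    data.frame(band = b, F = unname(fit$statistic), p = fit$p.value,
               df_between = unname(fit$parameter[1]),
               df_within = unname(fit$parameter[2]),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Tukey HSD post-hoc comparisons per band
#'
#' Tukey-Kramer adjusted p-values for every unordered pair of cover
#' groups in every band (harmonic-mean correction handles unbalanced
#' groups), flagged at the 0.05 and 0.1 significance levels. With k
#' groups there are `k (k - 1) / 2` pairs per band.
#'
#' @inheritParams anova_by_band
#' @param season Optional season label added to the output.
#' @return Data frame: `season`, `band`, `group_a`, `group_b`, `diff`,
#'   `p_adj`, `sig_05`, `sig_10`.
#' @export
tukey_by_band <- function(values, group, season = NA_character_) {
  values <- as.matrix(values)
  stopifnot(nrow(values) == length(group))
  tab <- table(group)
  keep <- group %in% as.numeric(names(tab)[tab >= 2])
  if (!all(keep))
    warning("tukey_by_band: excluding group(s) with < 2 members")
  values <- values[keep, , drop = FALSE]
  group <- group[keep]
  g <- factor(group)
  out <- list()
  for (b in colnames(values)) {
    y <- values[, b]
    ok <- !is.na(y)
    fit <- stats::aov(y[ok] ~ g[ok])
    tk <- stats::TukeyHSD(fit)[[1]]
    pairs <- strsplit(rownames(tk), "-", fixed = TRUE)
    out[[length(out) + 1]] <- data.frame(
      season = season, band = b,
      group_a = as.integer(vapply(pairs, `[`, "", 2)),
      group_b = as.integer(vapply(pairs, `[`, "", 1)),
      diff = tk[, "diff"], p_adj = tk[, "p adj"],
      sig_05 = tk[, "p adj"] < 0.05,
      sig_10 = tk[, "p adj"] < 0.1,
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Minimum detectable shrub cover from Tukey comparisons
#'
#' For each season and significance level, finds the lowest-cover group
#' (beyond the 0% group) whose comparison against group 1 is significant
#' in at least one band, together with the supporting bands, plus the
#' per-band tally of separable group pairs (a band's overall importance).
#'
#' @param tukey Long table from [tukey_by_band()] (may span seasons).
#' @param scheme Optional [build_cover_scheme()] result used to label the
#'   group cover ranges.
#' @return List with `minimum` (data frame per season x level:
#'   `min_group`, `cover_range`, `bands`; `min_group = NA` when nothing
#'   is detectable) and `band_importance` (season, band, n_separable).
#' @export
min_detectable_cover <- function(tukey, scheme = NULL) {
  stopifnot(all(c("band", "group_a", "group_b", "p_adj") %in% names(tukey)))
  if (!"season" %in% names(tukey)) tukey$season <- NA_character_
  lab <- function(g) {
    if (is.null(scheme) || is.na(g)) return(NA_character_)
    b <- c(0, scheme$breakpoints, 100)
    if (g == 1) "0%"
    else if (scheme$includes_endmember_group && g == scheme$n_groups) "~100%"
    else sprintf("%g-%g%%", b[g - 1], b[g])
  }
  mins <- list()
  imp <- list()
  for (se in unique(tukey$season)) {
    sub <- tukey[tukey$season %in% se, , drop = FALSE]
    for (lev in c(0.05, 0.1)) {
      vs1 <- sub[(sub$group_a == 1 | sub$group_b == 1) & sub$p_adj < lev, ,
                 drop = FALSE]
      other <- pmax(vs1$group_a, vs1$group_b)
      if (nrow(vs1) == 0) {
        mins[[length(mins) + 1]] <- data.frame(
          season = se, level = lev, min_group = NA_integer_,
          cover_range = "none detectable", bands = "",
          stringsAsFactors = FALSE)
      } else {
        mg <- min(other)
        bands <- sort(unique(vs1$band[other == mg]))
        mins[[length(mins) + 1]] <- data.frame(
          season = se, level = lev, min_group = mg,
          cover_range = lab(mg), bands = paste(bands, collapse = ";"),
          stringsAsFactors = FALSE)
      }
    }
    cnt <- stats::aggregate(list(n_separable = sub$p_adj < 0.05),
                            by = list(band = sub$band), FUN = sum)
    cnt$season <- se
    imp[[length(imp) + 1]] <- cnt[, c("season", "band", "n_separable")]
  }
  list(minimum = do.call(rbind, mins),
       band_importance = do.call(rbind, imp))
}
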