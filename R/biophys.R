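#' Screen biophysical outliers at k standard deviations
#'
#' Single-pass screening of quadrat-level measurements: within each season
#' and variable, the mean and sample SD are computed once over all records
#' (candidates included) and records farther than `k` SDs from the mean
#' are dropped. This removes artefacts such as seasonal quadrat shifting
#' without iterated trimming. Zero-variance variables never trigger
#' removals.
#'
#' @param tab Data frame with columns `quadrat_id`, `season` and the
#'   variables.
#' @param variables Character vector of numeric column names to screen.
#' @param k SD multiplier (default 3).
#' @return List with `table` (screened data frame) and `log` (data frame
#'   of removals: quadrat_id, season, variable, value, z).
#' @export
remove_outliers <- function(tab, variables, k = 3) {
  stopifnot(is.data.frame(tab), all(variables %in% names(tab)),
            all(c("quadrat_id", "season") %in% names(tab)))
  drop <- rep(FALSE, nrow(tab))
  logs <- list()
  for (se in unique(tab$season)) {
    sel <- tab$season == se
    if (sum(sel) < 3) next
    for (v in variables) {
      x <- tab[[v]][sel]
      m <- mean(x, na.rm = TRUE)
      s <- stats::sd(x, na.rm = TRUE)
      if (!is.finite(s) || s == 0) next
      z <- abs(x - m) / s
      bad <- which(z > k & !is.na(z))
      if (length(bad)) {
        idx <- which(sel)[bad]
        drop[idx] <- TRUE
        logs[[length(logs) + 1]] <- data.frame(
          quadrat_id = tab$quadrat_id[idx], season = se, variable = v,
          value = tab[[v]][idx], z = z[bad], stringsAsFactors = FALSE)
      }
    }
  }
  log <- if (length(logs)) do.call(rbind, logs) else
    data.frame(quadrat_id = character(), season = character(),
               variable = character(), value = numeric(), z = numeric())
  list(table = tab[!drop, , drop = FALSE], log = log)
}

#' Seasonal differences of biophysical variables
#'
#' Subtracts each variable between consecutive seasons per quadrat
#' (summer minus spring, fall minus summer) and tallies the fraction of
#' quadrats increasing, stable and decreasing per variable and
#' transition. Quadrats missing a season are skipped and logged.
#'
#' @param tab Data frame with `quadrat_id`, `season` and the variables.
#' @param variables Numeric columns to difference (default: all numeric
#'   except `position_m`/`stratum`).
#' @param seasons Season order (default spring, summer, fall).
#' @return List with `differences` (quadrat x transition x variable long
#'   data frame), `direction` (per variable and transition: fraction
#'   increase / stable / decrease) and `skipped` (quadrat ids).
#' @export
seasonal_difference <- function(tab, variables = NULL,
                                seasons = c("spring", "summer", "fall")) {
  stopifnot(all(c("quadrat_id", "season") %in% names(tab)))
  if (is.null(variables)) {
    num <- vapply(tab, is.numeric, TRUE)
    variables <- setdiff(names(tab)[num], c("position_m", "stratum"))
  }
  seasons <- seasons[seasons %in% unique(tab$season)]
  if (length(seasons) < 2) stop("seasonal_difference: need >= 2 seasons")
  wide <- split(tab, tab$quadrat_id)
  diffs <- list()
  skipped <- character()
  for (q in names(wide)) {
    d <- wide[[q]]
    if (!all(seasons %in% d$season)) { skipped <- c(skipped, q); next }
    d <- d[match(seasons, d$season), ]
    for (tr in seq_len(length(seasons) - 1)) {
      for (v in variables) {
        diffs[[length(diffs) + 1]] <- data.frame(
          quadrat_id = q,
          transition = paste(seasons[tr + 1], seasons[tr], sep = "-"),
          variable = v,
          delta = d[[v]][tr + 1] - d[[v]][tr],
          stringsAsFactors = FALSE)
      }
    }
  }
  differences <- do.call(rbind, diffs)
  agg <- do.call(rbind, lapply(
    split(differences, list(differences$transition, differences$variable),
          drop = TRUE),
    function(g) data.frame(
      transition = g$transition[1], variable = g$variable[1],
      mean_delta = mean(g$delta),
      frac_increase = mean(g$delta > 0),
      frac_stable = mean(g$delta == 0),
      frac_decrease = mean(g$delta < 0),
      stringsAsFactors = FALSE)))
  rownames(agg) <- NULL
  list(differences = differences, direction = agg, skipped = skipped)
}

#' Per-season summary of biophysical variables
#'
#' Mean, sample SD (n-1 denominator), minimum and maximum of each
#' variable by season — the standard seasonal field-campaign summary
#' layout.
#'
#' @param tab Data frame with `season` and the variables.
#' @param variables Numeric columns (default: all numeric except
#'   `position_m`/`stratum`).
#' @return Data frame: season, variable, mean, sd, min, max, n.
#' @export
seasonal_summary <- function(tab, variables = NULL) {
  stopifnot("season" %in% names(tab), nrow(tab) > 0)
  if (is.null(variables)) {
    num <- vapply(tab, is.numeric, TRUE)
    variables <- setdiff(names(tab)[num], c("position_m", "stratum"))
  }
  out <- list()
  for (se in unique(tab$season)) {
    sub <- tab[tab$season == se, , drop = FALSE]
    for (v in variables) {
      x <- sub[[v]][!is.na(sub[[v]])]
      out[[length(out) + 1]] <- data.frame(
        season = se, variable = v, mean = mean(x),
        sd = if (length(x) > 1) stats::sd(x) else 0,
        min = min(x), max = max(x), n = length(x),
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, out)
}

#' Compare line-intercept and quadrat shrub cover
#'
#' Line-intercept sampling measures cover continuously along the whole
#' transect and is treated as the reference; visual quadrat estimation
#' typically underestimates shrub cover. The comparison reports both
#' estimates and their difference (LIT minus quadrat mean).
#'
#' @param lit A [simulate_lit()] summary (or list with `cover_pct`).
#' @param tab Quadrat table with `season` and a shrub-cover column.
#' @param season Season to compare.
#' @param cover_col Quadrat shrub-cover column (default `"vis_shrub"`,
#'   falling back to `"cover_shrub"`).
#' @return Data frame: method, cover_pct, plus a `difference` attribute
#'   row (LIT - quadrat).
#' @export
compare_lit_quadrat <- function(lit, tab, season,
                                cover_col = c("vis_shrub", "cover_shrub")) {
  stopifnot("season" %in% names(tab))
  if (!season %in% tab$season)
    stop("compare_lit_quadrat: season '", season, "' absent from table")
  cover_col <- cover_col[cover_col %in% names(tab)][1]
  if (is.na(cover_col)) stop("compare_lit_quadrat: no shrub cover column")
  qmean <- mean(tab[[cover_col]][tab$season == season], na.rm = TRUE)
  data.frame(
    season = season,
    lit_cover_pct = lit$cover_pct,
    quadrat_cover_pct = qmean,
    difference = lit$cover_pct - qmean,
    stringsAsFactors = FALSE)
}
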