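#' Internal cluster-validity indices
#'
#' The default panel used by the majority-rule optimal-k search:
#' Calinski-Harabasz (maximize), average silhouette width (maximize),
#' Davies-Bouldin (minimize), Krzanowski-Lai (maximize; computed from
#' successive within-cluster sums of squares in
#' [optimal_cluster_count()]) and point-biserial correlation (maximize).
#' All operate on Euclidean distances.
#'
#' @param X Numeric sample-by-feature matrix.
#' @param labels Integer cluster labels.
#' @param index Index name.
#' @param d Optional precomputed `dist` object for `X`.
#' @return Scalar index value.
#' @keywords internal
validity_index <- function(X, labels, index, d = NULL) {
  k <- length(unique(labels))
  n <- nrow(X)
  if (k < 2) return(NA_real_)
  switch(index,
    ch = {
      gm <- colMeans(X)
      cents <- rowsum(X, labels) / as.vector(table(labels))
      ssb <- sum(as.vector(table(labels)) *
                   rowSums(sweep(cents, 2, gm)^2))
      ssw <- 0
      for (g in unique(labels)) {
        Xi <- X[labels == g, , drop = FALSE]
        ssw <- ssw + sum(sweep(Xi, 2, colMeans(Xi))^2)
      }
      (ssb / (k - 1)) / (ssw / (n - k))
    },
    silhouette = {
      if (is.null(d)) d <- stats::dist(X)
      mean(cluster::silhouette(labels, d)[, "sil_width"])
    },
    db = {
      cents <- rowsum(X, labels) / as.vector(table(labels))
      gs <- sort(unique(labels))
      s <- vapply(gs, function(g) {
        Xi <- X[labels == g, , drop = FALSE]
        mean(sqrt(rowSums(sweep(Xi, 2, cents[as.character(g), ])^2)))
      }, 0)
      M <- as.matrix(stats::dist(cents))
      r <- vapply(seq_len(k), function(i) {
        max(vapply(seq_len(k)[-i],
                   function(j) (s[i] + s[j]) / M[i, j], 0))
      }, 0)
      mean(r)
    },
    ptbiserial = {
      if (is.null(d)) d <- stats::dist(X)
      D <- as.matrix(d)
      same <- outer(labels, labels, `==`) & upper.tri(D)
      diff <- outer(labels, labels, `!=`) & upper.tri(D)
      fw <- sum(same) / (sum(same) + sum(diff))
      (mean(D[diff]) - mean(D[same])) * sqrt(fw * (1 - fw)) /
        stats::sd(D[upper.tri(D)])
    },
    stop("validity_index: unknown index '", index, "'"))
}

# within-cluster sum of squares of a labelling
wss_of <- function(X, labels) {
  s <- 0
  for (g in unique(labels)) {
    Xi <- X[labels == g, , drop = FALSE]
    s <- s + sum(sweep(Xi, 2, colMeans(Xi))^2)
  }
  s
}

index_direction <- c(ch = 1, silhouette = 1, db = -1, kl = 1,
                     ptbiserial = 1)

#' Default validity-index panel
#' @return Character vector of index names.
#' @export
default_index_panel <- function() names(index_direction)

#' Majority-rule optimal cluster count
#'
#' Clusters the spectra at every k in `k_range`, scores each solution
#' with every index in the panel, lets each index vote for its best k,
#' and returns the modal vote (ties broken toward the smallest k).
#'
#' @param X Sample-by-wavelength reflectance matrix (masked wavelengths
#'   already dropped, e.g. via [library_matrix()]).
#' @param method `"kmeans"` or `"ward"`.
#' @param k_range Integer vector of candidate k (default 2:15).
#' @param index_panel Index names (default [default_index_panel()]).
#' @param seed Seed for the K-means restarts.
#' @return List with `k` (chosen count), `votes` (named per-index k) and
#'   `scores` (index-by-k matrix).
#' @export
optimal_cluster_count <- function(X, method = c("kmeans", "ward"),
                                  k_range = 2:15,
                                  index_panel = default_index_panel(),
                                  seed = 1L) {
  method <- match.arg(method)
  X <- as.matrix(X)
  n <- nrow(X)
  if (max(k_range) >= n) {
    warning("optimal_cluster_count: k_range truncated to n - 1")
    k_range <- k_range[k_range < n]
  }
  stopifnot(length(k_range) > 0, all(index_panel %in% names(index_direction)))
  d <- stats::dist(X)
  hc <- if (method == "ward") stats::hclust(d, method = "ward.D2") else NULL
  labels_at <- function(k) {
    if (k == 1) return(rep(1L, n))
    if (method == "ward") stats::cutree(hc, k) else {
      set.seed(seed)
      stats::kmeans(X, centers = k, nstart = 10, iter.max = 100)$cluster
    }
  }
  scores <- matrix(NA_real_, length(index_panel), length(k_range),
                   dimnames = list(index_panel, k_range))
  # within-cluster SS on k_range widened by one on each side, for the
  # Krzanowski-Lai successive-difference index
  kw <- max(2L, min(k_range) - 1L):min(n - 1L, max(k_range) + 1L)
  wss <- stats::setNames(rep(NA_real_, length(kw)), kw)
  direct <- setdiff(index_panel, "kl")
  for (k in kw) {
    labels <- labels_at(k)
    wss[as.character(k)] <- wss_of(X, labels)
    j <- match(k, k_range)
    if (!is.na(j))
      for (ix in direct)
        scores[ix, j] <- validity_index(X, labels, ix, d = d)
  }
  if ("kl" %in% index_panel) {
    p <- ncol(X)
    wk <- function(k) {
      if (k == 1) sum(sweep(X, 2, colMeans(X))^2)
      else unname(wss[as.character(k)])
    }
    DIFF <- function(k) (k - 1)^(2 / p) * wk(k - 1) - k^(2 / p) * wk(k)
    for (j in seq_along(k_range)) {
      k <- k_range[j]
      if ((k + 1) <= max(kw)) {
        dn <- DIFF(k + 1)
        scores["kl", j] <- if (is.finite(dn) && dn != 0)
          abs(DIFF(k)) / abs(dn) else NA_real_
      }
    }
  }
  votes <- vapply(index_panel, function(ix) {
    v <- scores[ix, ] * index_direction[[ix]]
    k_range[which.max(v)]
  }, 0L)
  tab <- table(factor(votes, levels = sort(unique(votes))))
  best <- as.integer(names(tab)[tab == max(tab)])
  list(k = min(best), votes = votes, scores = scores)
}

#' Cluster quadrat spectra
#'
#' K-means (deterministic from the seed, 10 restarts keeping the best
#' within-cluster sum of squares) or Ward agglomeration on Euclidean
#' distances cut at k.
#'
#' @param X Sample-by-wavelength matrix.
#' @param k Number of clusters (>= 2, <= n samples).
#' @param method `"kmeans"` or `"ward"`.
#' @param seed K-means restart seed.
#' @return A `cluster_result`: list with `method`, `k`, `labels`.
#' @export
cluster_spectra <- function(X, k, method = c("kmeans", "ward"), seed = 1L) {
  method <- match.arg(method)
  X <- as.matrix(X)
  if (k > nrow(X)) stop("cluster_spectra: k exceeds sample count")
  labels <- if (method == "ward") {
    stats::cutree(stats::hclust(stats::dist(X), method = "ward.D2"), k)
  } else {
    set.seed(seed)
    stats::kmeans(X, centers = k, nstart = 10, iter.max = 100)$cluster
  }
  structure(list(method = method, k = as.integer(k),
                 labels = as.integer(labels)),
            class = "cluster_result")
}

#' Assign quadrats to cover groups by breakpoints
#'
#' Group 1 holds exactly the 0%-cover quadrats; the remaining groups are
#' the half-open intervals `(0, b1], (b1, b2], ..., (b_last, 100]`.
#'
#' @param cover Per-quadrat shrub cover (percent).
#' @param breakpoints Ascending interior breakpoints (percent).
#' @return Integer group ids in `1..(length(breakpoints) + 2)`.
#' @export
assign_cover_groups <- function(cover, breakpoints) {
  stopifnot(all(cover >= 0), all(cover <= 100),
            !is.unsorted(breakpoints, strictly = TRUE) || length(breakpoints) < 2)
  ifelse(cover == 0, 1L,
         2L + vapply(cover, function(x) sum(x > breakpoints), 0L))
}

# breakpoints from one clustering: order clusters by mean cover, merge
# clusters whose cover ranges overlap, then take midpoints between the
# merged clusters' adjacent range edges
breakpoints_from_clustering <- function(labels, cover) {
  gs <- sort(unique(labels))
  rng <- t(vapply(gs, function(g) {
    x <- cover[labels == g]
    c(lo = min(x), hi = max(x), mean = mean(x))
  }, c(0, 0, 0)))
  rng <- rng[order(rng[, "mean"]), , drop = FALSE]
  merged <- list(rng[1, c("lo", "hi")])
  for (i in seq_len(nrow(rng))[-1]) {
    cur <- merged[[length(merged)]]
    if (rng[i, "lo"] <= cur[["hi"]])
      merged[[length(merged)]] <- c(lo = cur[["lo"]],
                                    hi = max(cur[["hi"]], rng[i, "hi"]))
    else merged[[length(merged) + 1]] <- rng[i, c("lo", "hi")]
  }
  if (length(merged) < 2) return(numeric(0))
  m <- do.call(rbind, merged)
  (m[-nrow(m), "hi"] + m[-1, "lo"]) / 2
}

# drop breakpoints that delimit empty groups (the forced 0% rule can
# leave the first half-open interval unpopulated when the lowest cluster
# holds only zero-cover quadrats)
prune_empty_groups <- function(breakpoints, cover) {
  repeat {
    g <- assign_cover_groups(cover, breakpoints)
    counts <- tabulate(g, nbins = length(breakpoints) + 2L)
    empty <- which(counts == 0)
    if (!length(empty) || !length(breakpoints)) return(breakpoints)
    j <- empty[1]
    # group j (j >= 2) is (b[j-2], b[j-1]]; drop its upper boundary,
    # or the last breakpoint when the final interval is empty
    drop_i <- if (j <= length(breakpoints) + 1L) j - 1L else length(breakpoints)
    breakpoints <- breakpoints[-drop_i]
  }
}

#' Build a shrub-cover grouping scheme from spectral clusterings
#'
#' Each candidate clustering of the quadrat spectra yields a candidate
#' breakpoint set (midpoints between the cover ranges of adjacent
#' clusters, after ordering clusters by mean cover and merging clusters
#' with overlapping cover ranges). Quadrats with exactly 0% shrub are
#' always forced into group 1, and the pure-shrub endmember spectra form
#' the final (~100%) group. Among the candidates, the scheme with the
#' most balanced group sizes (minimum variance of quadrat counts) is
#' selected.
#'
#' @param results A `cluster_result` or list of them (e.g. K-means and
#'   Ward solutions).
#' @param shrub_cover Per-quadrat shrub cover percent, aligned with the
#'   clustering labels.
#' @param n_endmembers Number of pure-shrub endmember spectra appended as
#'   the final group (0 to omit).
#' @return A `cover_group_scheme`: `breakpoints`, `group_of` (per
#'   quadrat), `counts` (quadrat counts per group, endmember count in the
#'   last group if appended), `n_groups`, `includes_zero_group`,
#'   `includes_endmember_group`, `candidates`.
#' @export
build_cover_scheme <- function(results, shrub_cover, n_endmembers = 0) {
  if (inherits(results, "cluster_result")) results <- list(results)
  stopifnot(length(results) >= 1)
  if (length(unique(shrub_cover)) == 1) {
    warning("build_cover_scheme: all quadrats share one cover value; degenerate scheme")
    candidates <- list(numeric(0))
  } else {
    candidates <- lapply(results, function(r) {
      stopifnot(length(r$labels) == length(shrub_cover))
      prune_empty_groups(
        breakpoints_from_clustering(r$labels, shrub_cover), shrub_cover)
    })
  }
  score <- vapply(candidates, function(b) {
    g <- assign_cover_groups(shrub_cover, b)
    stats::var(as.vector(table(factor(g, levels = seq_len(max(g))))))
  }, 0)
  score[is.na(score)] <- Inf
  pick <- which.min(score)
  breakpoints <- candidates[[pick]]
  group_of <- assign_cover_groups(shrub_cover, breakpoints)
  n_quad_groups <- length(breakpoints) + 2L
  counts <- as.vector(table(factor(group_of, levels = seq_len(n_quad_groups))))
  has_em <- n_endmembers > 0
  if (has_em) {
    counts <- c(counts, n_endmembers)
  }
  structure(list(
    breakpoints = breakpoints,
    group_of = group_of,
    counts = counts,
    n_groups = n_quad_groups + as.integer(has_em),
    includes_zero_group = TRUE,
    includes_endmember_group = has_em,
    candidates = candidates,
    balance_score = score,
    selected_candidate = pick
  ), class = "cover_group_scheme")
}

#' @export
print.cover_group_scheme <- function(x, ...) {
  lab <- c("0%", paste0("<", c(x$breakpoints, 100), "%"))
  if (x$includes_endmember_group) lab <- c(lab, "~100% (endmembers)")
  cat("<cover_group_scheme>\n")
  for (i in seq_along(lab))
    cat(sprintf("  group %d: %s shrub cover (n = %d)\n",
                i, lab[i], x$counts[i]))
  invisible(x)
}

#' Write a cover scheme as CSV
#'
#' @param scheme A `cover_group_scheme`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_cover_scheme <- function(scheme, path) {
  b <- scheme$breakpoints
  lows <- c(0, 0, b)
  highs <- c(0, b, 100)
  if (scheme$includes_endmember_group) { lows <- c(lows, 100); highs <- c(highs, 100) }
  utils::write.csv(data.frame(group_id = seq_along(scheme$counts),
                              low_pct = lows[seq_along(scheme$counts)],
                              high_pct = highs[seq_along(scheme$counts)],
                              count = scheme$counts),
                   path, row.names = FALSE)
  invisible(path)
}
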