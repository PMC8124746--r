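test_that("well-separated blobs give a unanimous optimal k", {
  # two blobs separated by ~20x the within-blob SD
  X2 <- blob_matrix(list(0.2, 0.3), n_per = 12, sd = 0.005, seed = 31)
  ok2 <- optimal_cluster_count(X2, "kmeans", k_range = 2:8)
  expect_equal(ok2$k, 2L)
  expect_true(all(ok2$votes == 2L))
  X3 <- blob_matrix(list(0.2, 0.3, 0.4), n_per = 10, sd = 0.005, seed = 32)
  ok3 <- optimal_cluster_count(X3, "ward", k_range = 2:8)
  expect_equal(ok3$k, 3L)
  expect_gte(sum(ok3$votes == 3L), 3)  # majority
})

test_that("a singleton index panel returns that index's k", {
  X <- blob_matrix(list(0.2, 0.35), n_per = 10, seed = 33)
  ok <- optimal_cluster_count(X, "kmeans", k_range = 2:6,
                              index_panel = "silhouette")
  expect_equal(unname(ok$k), unname(ok$votes[["silhouette"]]))
})

test_that("k_range is truncated with a warning when samples are scarce", {
  X <- blob_matrix(list(0.2, 0.4), n_per = 4, seed = 34)
  expect_warning(ok <- optimal_cluster_count(X, "kmeans", k_range = 2:15),
                 "truncated")
  expect_lt(max(ok$votes), nrow(X))
})

test_that("both clustering methods recover blob membership exactly", {
  X <- blob_matrix(list(0.2, 0.32), n_per = 15, sd = 0.005, seed = 35)
  truth <- rep(1:2, each = 15)
  for (m in c("kmeans", "ward")) {
    cl <- cluster_spectra(X, 2, m)
    # labels equal truth up to permutation
    expect_equal(length(unique(paste(cl$labels, truth))), 2)
  }
  expect_error(cluster_spectra(X, 31, "ward"), "exceeds")
})

test_that("ward at k = n isolates every sample; duplicates share labels", {
  X <- blob_matrix(list(0.2, 0.4), n_per = 4, seed = 36)
  cl <- cluster_spectra(X, nrow(X), "ward")
  expect_equal(length(unique(cl$labels)), nrow(X))
  Xd <- rbind(X, X)
  cld <- cluster_spectra(Xd, 2, "ward")
  expect_equal(cld$labels[seq_len(nrow(X))],
               cld$labels[nrow(X) + seq_len(nrow(X))])
})

test_that("breakpoint assignment uses half-open intervals with a forced 0 group", {
  g <- assign_cover_groups(c(0, 7, 20, 60, 90), c(10, 35, 50, 75))
  expect_equal(g, c(1L, 2L, 3L, 5L, 6L))
  # boundary values belong to the lower group: (low, high]
  expect_equal(assign_cover_groups(10, c(10, 35)), 2L)
  expect_equal(assign_cover_groups(10.001, c(10, 35)), 3L)
})

test_that("scheme selection prefers balanced group counts", {
  # engineered covers and two clusterings: one splits covers evenly,
  # the other lumps most quadrats together
  cover <- c(rep(0, 10), rep(10, 20), rep(40, 20), rep(80, 10))
  balanced <- structure(list(method = "kmeans", k = 3L,
                             labels = c(rep(1L, 30), rep(2L, 20),
                                        rep(3L, 10))),
                        class = "cluster_result")
  lumped <- structure(list(method = "ward", k = 2L,
                           labels = c(rep(1L, 50), rep(2L, 10))),
                      class = "cluster_result")
  sch <- build_cover_scheme(list(balanced, lumped), cover, n_endmembers = 5)
  expect_equal(sch$selected_candidate, 1L)
  v <- function(cnt) var(cnt)
  expect_lt(v(table(assign_cover_groups(cover, sch$candidates[[1]]))),
            v(table(assign_cover_groups(cover, sch$candidates[[2]]))) + 1e-12)
  # partition: every quadrat in exactly one group, counts sum to n (+ endmembers)
  expect_equal(sum(sch$counts), length(cover) + 5)
  expect_true(all(tabulate(sch$group_of) ==
                    sch$counts[seq_len(max(sch$group_of))]))
})

test_that("cover ordering holds across groups except the forced zero rule", {
  sc <- generate_scene(transect_config(seed = 37, seasons = "spring"))
  lib <- average_replicates(mask_water_regions(sc$library))
  X <- library_matrix(lib)
  cover <- sc$quadrats$vis_shrub[match(lib$meta$quadrat_id,
                                       sc$quadrats$quadrat_id)]
  cl <- cluster_spectra(X, 3, "ward")
  sch <- build_cover_scheme(cl, cover, n_endmembers = 10)
  gs <- sort(unique(sch$group_of))
  for (i in seq_along(gs)[-1]) {
    lo_cur <- min(cover[sch$group_of == gs[i]])
    hi_prev <- max(cover[sch$group_of == gs[i - 1]])
    expect_gte(lo_cur, hi_prev - 1e-9)
  }
})

test_that("degenerate identical covers give a warned single-group scheme", {
  cl <- structure(list(method = "kmeans", k = 2L, labels = rep(1:2, 5)),
                  class = "cluster_result")
  expect_warning(sch <- build_cover_scheme(cl, rep(40, 10)), "degenerate")
  expect_length(sch$breakpoints, 0)
})

test_that("clustering and schemes are reproducible from the seed", {
  X <- blob_matrix(list(0.2, 0.3, 0.4), n_per = 8, seed = 38)
  a <- cluster_spectra(X, 3, "kmeans", seed = 5)
  b <- cluster_spectra(X, 3, "kmeans", seed = 5)
  expect_identical(a$labels, b$labels)
})

test_that("planted strata are recovered by the selected scheme", {
  sc <- generate_scene(transect_config(seed = 5, seasons = "summer",
                                       strata = c(0, 0.15, 0.45, 0.8)))
  lib <- average_replicates(mask_water_regions(sc$library))
  X <- library_matrix(lib)
  q <- sc$quadrats[match(lib$meta$quadrat_id, sc$quadrats$quadrat_id), ]
  results <- lapply(c("kmeans", "ward"), function(m)
    cluster_spectra(X, optimal_cluster_count(X, m)$k, m))
  sch <- build_cover_scheme(results, q$vis_shrub, n_endmembers = 10)
  tab <- table(q$stratum, sch$group_of)
  expect_true(all(apply(tab, 1, max) / rowSums(tab) >= 0.9))
  # strata map to distinct groups
  expect_equal(length(unique(apply(tab, 1, which.max))), 4)
})
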