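pref_tbl <- function(x, ids = NULL) {
  colnames(x) <- c("pt_t", "ro_t", "kl_t", "sa_t")
  tibble::tibble(patient_id = ids %||% sprintf("p%03d", seq_len(nrow(x)))) |>
    dplyr::bind_cols(tibble::as_tibble(x))
}

three_archetypes <- function(n_each = 50, noise = 0.03, seed = 17) {
  withr::with_seed(seed, {
    base <- rbind(
      matrix(rep(c(1, 0, 0, 0), n_each), ncol = 4, byrow = TRUE),
      matrix(rep(c(0, 0, 1, 0), n_each), ncol = 4, byrow = TRUE),
      matrix(rep(c(0, 0, 0, 1), n_each), ncol = 4, byrow = TRUE)
    )
    x <- abs(base + matrix(rnorm(length(base), 0, noise), ncol = 4))
    x <- x / rowSums(x)
    list(features = pref_tbl(x), truth = rep(1:3, each = n_each))
  })
}

test_that("k-means separates well-separated clouds and is deterministic", {
  arch <- three_archetypes()
  fit1 <- fit_kmeans(arch$features, k = 3, seed = 5)
  fit2 <- fit_kmeans(arch$features, k = 3, seed = 5)
  expect_identical(fit1$assignments, fit2$assignments)
  # perfect recovery of the planted archetypes
  tab <- table(fit1$assignments$cluster, arch$truth)
  expect_equal(sum(apply(tab, 1, max)), 150)
  # inertia equals the within-cloud scatter of the recovered partition
  x <- as.matrix(arch$features[, c("pt_t", "ro_t", "kl_t", "sa_t")])
  scatter <- sum(vapply(1:3, function(cl) {
    xi <- x[fit1$assignments$cluster == cl, , drop = FALSE]
    sum(sweep(xi, 2, colMeans(xi))^2)
  }, numeric(1)))
  expect_equal(fit1$inertia, scatter, tolerance = 1e-8)
})

test_that("k-means matches the exhaustive-initialisation Lloyd oracle", {
  withr::with_seed(29, {
    x <- rbind(
      matrix(rnorm(28, mean = 0, sd = 0.05), ncol = 4),
      matrix(rnorm(28, mean = 0.5, sd = 0.05), ncol = 4),
      matrix(rnorm(24, mean = 1, sd = 0.05), ncol = 4)
    )
  })
  feats <- pref_tbl(x)
  fit <- fit_kmeans(feats, k = 3, seed = 3, n_restarts = 20)
  # oracle: Lloyd's from every triplet of data points
  combos <- utils::combn(nrow(x), 3)
  best <- Inf
  for (i in seq_len(ncol(combos))) {
    res <- lloyd_by_hand(x, x[combos[, i], , drop = FALSE])
    best <- min(best, res$inertia)
  }
  expect_lte(fit$inertia, best + 1e-9)
})

test_that("degenerate inputs are handled explicitly", {
  same <- pref_tbl(matrix(rep(c(0.25, 0.25, 0.25, 0.25), 10),
                          ncol = 4, byrow = TRUE))
  expect_warning(fit <- fit_kmeans(same, k = 3), "single effective cluster")
  expect_equal(unique(fit$assignments$cluster), 1L)

  two_vals <- pref_tbl(matrix(rep(c(1, 0, 0, 0, 0, 1, 0, 0), 5),
                              ncol = 4, byrow = TRUE))
  expect_error(fit_kmeans(two_vals, k = 3), "distinct")
  expect_error(fit_kmeans(three_archetypes()$features, k = 200), "exceeds")
})

test_that("silhouette agrees with the hand-computed formula on 6 points", {
  x <- matrix(c(
    0.0, 0.0, 0.0, 1.0,
    0.1, 0.0, 0.0, 0.9,
    0.9, 0.1, 0.0, 0.0,
    1.0, 0.0, 0.0, 0.0,
    0.5, 0.5, 0.0, 0.0,
    0.4, 0.6, 0.0, 0.0
  ), ncol = 4, byrow = TRUE)
  labels <- c(1L, 1L, 2L, 2L, 3L, 3L)
  expect_equal(silhouette_score(x, labels), silhouette_by_hand(x, labels),
               tolerance = 1e-12)
  expect_gte(silhouette_score(x, labels), -1)
  expect_lte(silhouette_score(x, labels), 1)
  expect_error(silhouette_score(x, rep(1L, 6)), "two clusters")
})

test_that("silhouette and sizes are invariant to label permutation", {
  arch <- three_archetypes()
  x <- as.matrix(arch$features[, c("pt_t", "ro_t", "kl_t", "sa_t")])
  labels <- arch$truth
  perm <- c(2L, 3L, 1L)[labels]
  expect_equal(silhouette_score(x, labels), silhouette_score(x, perm))
  expect_equal(sort(tabulate(labels)), sort(tabulate(perm)))
})

test_that("the silhouette scan recovers planted k = 3", {
  arch <- three_archetypes()
  sol <- cluster_preferences(arch$features, k_range = 2:9, seed = 1)
  expect_equal(sol$k, 3L)
  expect_true(all(sol$silhouette_by_k$silhouette >= -1 &
                  sol$silhouette_by_k$silhouette <= 1))
  expect_equal(sum(sol$sizes), 150)
  expect_equal(nrow(tidy(sol)), 150)
  expect_equal(glance(sol)$k, 3L)
  # autoplot builds without error
  expect_no_error(ggplot2::ggplot_build(autoplot(sol)))
})

test_that("excluded patients are dropped from clustering", {
  arch <- three_archetypes(n_each = 10)
  feats <- dplyr::bind_rows(
    dplyr::mutate(arch$features, excluded = FALSE),
    tibble::tibble(patient_id = "pz", pt_t = NA_real_, ro_t = NA_real_,
                   kl_t = NA_real_, sa_t = NA_real_, excluded = TRUE)
  )
  sol <- cluster_preferences(feats, k_range = 2:4, seed = 1)
  expect_false("pz" %in% sol$assignments$patient_id)
  expect_error(cluster_preferences(feats[feats$excluded, ]),
               "available for clustering")
})
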