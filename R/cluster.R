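#' K-means clustering of behavior-preference vectors
#'
#' Lloyd's algorithm in Euclidean preference space, restarted `n_restarts`
#' times from k-means++ seeds drawn among the distinct data points; the
#' solution with the lowest within-cluster sum of squares wins.
#' Deterministic given `seed`. If a restart produces an empty cluster, fresh
#' seeds are drawn for that restart.
#'
#' @param features A preference tibble from [preference_features()] (rows
#'   with `excluded = TRUE` are dropped), or any tibble with a `patient_id`
#'   column plus numeric feature columns `pt_t`, `ro_t`, `kl_t`, `sa_t`.
#' @param k Number of clusters (`2 <= k <=` number of distinct points).
#' @param seed Integer seed controlling initialisation.
#' @param n_restarts Number of k-means++ restarts (default 10).
#' @return An object of class `preference_kmeans`: list with `assignments`
#'   (tibble `patient_id`, `cluster`), `centroids` (tibble with `cluster`
#'   and feature columns), `inertia` (total within-cluster sum of squares),
#'   `sizes`, `k`, `seed`.
#' @export
fit_kmeans <- function(features, k, seed = 1, n_restarts = 10) {
  dat <- prepare_pref_matrix(features)
  x <- dat$x
  if (k < 2) rlang::abort("`k` must be at least 2.")
  if (k > nrow(x)) rlang::abort("`k` exceeds the number of patients.")
  ux <- unique(x)
  if (nrow(ux) == 1L) {
    rlang::warn("All preference vectors are identical: single effective cluster.")
    return(new_preference_kmeans(dat$ids, rep(1L, nrow(x)),
                                 ux, 0, 1L, seed))
  }
  if (k > nrow(ux)) {
    rlang::abort(paste0("`k` = ", k, " exceeds the ", nrow(ux),
                        " distinct preference vectors."))
  }
  fit <- withr::with_seed(seed, {
    best <- NULL
    for (r in seq_len(n_restarts)) {
      km <- NULL
      for (attempt in 1:5) {
        centers <- ux[kmeanspp_seeds(ux, k), , drop = FALSE]
        km <- suppressWarnings(
          tryCatch(stats::kmeans(x, centers = centers, iter.max = 100,
                                 algorithm = "Lloyd"),
                   error = function(e) NULL)
        )
        if (!is.null(km) && all(km$size > 0)) break
      }
      if (is.null(km)) next
      if (is.null(best) || km$tot.withinss < best$tot.withinss) best <- km
    }
    best
  })
  if (is.null(fit)) rlang::abort("k-means failed to converge on any restart.")
  new_preference_kmeans(dat$ids, fit$cluster, fit$centers, fit$tot.withinss,
                        k, seed)
}

# k-means++ seeding: first center uniform, subsequent centers sampled with
# probability proportional to squared distance to the nearest chosen center.
kmeanspp_seeds <- function(x, k) {
  n <- nrow(x)
  ids <- integer(k)
  ids[1] <- sample.int(n, 1L)
  d2 <- rowSums(sweep(x, 2, x[ids[1], ])^2)
  for (j in seq_len(k - 1L) + 1L) {
    if (all(d2 == 0)) {
      ids[j] <- sample.int(n, 1L)
    } else {
      ids[j] <- sample.int(n, 1L, prob = d2)
    }
    d2 <- pmin(d2, rowSums(sweep(x, 2, x[ids[j], ])^2))
  }
  ids
}

prepare_pref_matrix <- function(features) {
  if ("excluded" %in% names(features)) {
    features <- dplyr::filter(features, !.data$excluded)
  }
  cols <- intersect(pref_cols(), names(features))
  if (length(cols) == 0L) {
    cols <- names(features)[vapply(features, is.numeric, logical(1))]
    cols <- setdiff(cols, c("n_total"))
  }
  if (length(cols) == 0L || nrow(features) == 0L) {
    rlang::abort("No feature columns / rows available for clustering.")
  }
  x <- as.matrix(features[, cols])
  if (anyNA(x)) rlang::abort("Feature matrix contains NA values.")
  list(x = x, ids = features$patient_id, cols = cols)
}

new_preference_kmeans <- function(ids, labels, centers, inertia, k, seed) {
  # relabel so cluster 1 is the largest (ties: higher PT-T centroid first)
  sizes <- tabulate(labels, nbins = nrow(centers))
  ord <- order(-sizes, -centers[, 1])
  relabel <- match(seq_along(ord), ord)
  labels <- relabel[labels]
  centers <- centers[ord, , drop = FALSE]
  structure(
    list(
      assignments = tibble::tibble(patient_id = ids, cluster = labels),
      centroids = tibble::as_tibble(centers) |>
        dplyr::mutate(cluster = dplyr::row_number(), .before = 1),
      inertia = inertia,
      sizes = tabulate(labels, nbins = k),
      k = k,
      seed = seed
    ),
    class = "preference_kmeans"
  )
}

#' @export
print.preference_kmeans <- function(x, ...) {
  cat("<preference_kmeans> k = ", x$k, ", sizes: ",
      paste(x$sizes, collapse = "/"), ", inertia = ",
      format(x$inertia, digits = 5), "\n", sep = "")
  invisible(x)
}

#' Mean silhouette width of a clustering
#'
#' For each point, `(b - a) / max(a, b)` where `a` is the mean distance to
#' its own cluster's other members and `b` the mean distance to the nearest
#' other cluster; the score is the mean over points. Euclidean distance.
#'
#' @param features Preference tibble or numeric matrix.
#' @param labels Integer cluster labels (one per retained row).
#' @return Mean silhouette width in `[-1, 1]`.
#' @export
silhouette_score <- function(features, labels) {
  x <- if (is.matrix(features)) features else prepare_pref_matrix(features)$x
  if (length(unique(labels)) < 2L) {
    rlang::abort("Silhouette needs at least two clusters.")
  }
  sil <- cluster::silhouette(as.integer(labels), stats::dist(x))
  mean(sil[, "sil_width"])
}

#' Select the number of behavior-preference clusters by silhouette score
#'
#' Fits k-means for each `k` in `k_range`, computes the mean silhouette
#' width, and returns the solution at the maximum (ties broken toward the
#' smaller `k`).
#'
#' @inheritParams fit_kmeans
#' @param k_range Candidate cluster counts (default `2:9`).
#' @return An object of class `cluster_solution`: list with `k` (chosen),
#'   `silhouette_by_k` (tibble `k`, `silhouette`), `assignments`,
#'   `centroids`, `sizes`, `fits` is not retained beyond the chosen one
#'   (`fit`), and `seed`.
#' @export
#' @examples
#' set.seed(1)
#' f <- tibble::tibble(
#'   patient_id = as.character(1:60),
#'   pt_t = rep(c(0.9, 0.1, 0.1), each = 20) + runif(60, 0, 0.05),
#'   ro_t = 0, kl_t = rep(c(0.1, 0.9, 0.1), each = 20),
#'   sa_t = rep(c(0, 0, 0.8), each = 20)
#' )
#' cluster_preferences(f, k_range = 2:4, seed = 1)$k
cluster_preferences <- function(features, k_range = 2:9, seed = 1,
                                n_restarts = 10) {
  dat <- prepare_pref_matrix(features)
  if (nrow(dat$x) == 0L) rlang::abort("No patients to cluster.")
  k_range <- sort(unique(as.integer(k_range)))
  n_unique <- nrow(unique(dat$x))
  k_range <- k_range[k_range >= 2 & k_range < nrow(dat$x) &
                     k_range <= n_unique]
  if (length(k_range) == 0L) {
    rlang::abort("No feasible k in `k_range` for these data.")
  }
  fits <- purrr::map(k_range, function(k) {
    fit <- fit_kmeans(features, k, seed = seed + k, n_restarts = n_restarts)
    list(fit = fit,
         silhouette = silhouette_score(dat$x, fit$assignments$cluster))
  })
  sil <- tibble::tibble(
    k = k_range,
    silhouette = purrr::map_dbl(fits, "silhouette")
  )
  best <- which.max(sil$silhouette)  # first max: ties go to smaller k
  fit <- fits[[best]]$fit
  structure(
    list(
      k = k_range[best],
      silhouette_by_k = sil,
      assignments = fit$assignments,
      centroids = fit$centroids,
      sizes = fit$sizes,
      fit = fit,
      seed = seed
    ),
    class = "cluster_solution"
  )
}

#' @export
print.cluster_solution <- function(x, ...) {
  cat("<cluster_solution> chose k = ", x$k, " by silhouette (",
      format(max(x$silhouette_by_k$silhouette), digits = 3),
      "); sizes: ", paste(x$sizes, collapse = "/"), "\n", sep = "")
  invisible(x)
}

#' @describeIn cluster_preferences Patient-level assignments as a tibble.
#' @param x A `cluster_solution`.
#' @param ... Unused.
#' @method tidy cluster_solution
#' @export
tidy.cluster_solution <- function(x, ...) x$assignments

#' @describeIn cluster_preferences One-row summary (chosen k, best
#'   silhouette, sizes).
#' @method glance cluster_solution
#' @export
glance.cluster_solution <- function(x, ...) {
  tibble::tibble(
    k = x$k,
    silhouette = max(x$silhouette_by_k$silhouette),
    n_patients = nrow(x$assignments),
    inertia = x$fit$inertia
  )
}

#' @describeIn cluster_preferences Silhouette score against candidate k.
#' @param object A `cluster_solution`.
#' @method autoplot cluster_solution
#' @export
autoplot.cluster_solution <- function(object, ...) {
  ggplot2::ggplot(object$silhouette_by_k,
                  ggplot2::aes(x = .data$k, y = .data$silhouette)) +
    ggplot2::geom_line(colour = "steelblue") +
    ggplot2::geom_point(size = 2) +
    ggplot2::geom_point(data = dplyr::filter(object$silhouette_by_k,
                                             .data$k == object$k),
                        colour = "red", size = 3) +
    ggplot2::scale_x_continuous(breaks = object$silhouette_by_k$k) +
    ggplot2::labs(x = "number of clusters k", y = "mean silhouette score") +
    ggplot2::theme_minimal()
}
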