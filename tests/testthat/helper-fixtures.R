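# Shared fixture builders. All fixtures are generated in code.

epoch <- function(x) as.POSIXct(x, origin = "1970-01-01", tz = "UTC")

# A visit stream for one patient with prescribed idle gaps (seconds between
# one visit's exit and the next visit's enter). dwell defaults to 10 s.
usage_from_gaps <- function(gaps, states = NULL, dwell = 10,
                            patient_id = "p1", t0 = 0) {
  n <- length(gaps) + 1L
  if (is.null(states)) states <- rep("main", n)
  dwell <- rep_len(dwell, n)
  enter <- numeric(n)
  enter[1] <- t0
  for (i in seq_along(gaps)) {
    enter[i + 1] <- enter[i] + dwell[i] + gaps[i]
  }
  tibble::tibble(
    patient_id = patient_id,
    state = states,
    enter_time = epoch(enter),
    exit_time = epoch(enter + dwell),
    dwell = dwell
  )
}

# Visit-level expansion of the published per-state quantity / total-time
# table: each state contributes `quantity` visits of equal dwell, so totals
# and means reproduce the printed arithmetic exactly.
reference_visit_fixture <- function() {
  ref <- reference_state_stats()
  tibble::tibble(
    patient_id = "cohort",
    state = rep(ref$state, ref$quantity),
    dwell = rep(ref$total_time_s / ref$quantity, ref$quantity)
  )
}

# Small deterministic cohort for integration-style tests.
small_cohort <- function(seed = 42) {
  cfg <- synth_config(
    n_patients = c(30, 12, 10),
    sessions_per_patient = list(mu = 20, size = 3)
  )
  simulate_cohort(cfg, seed = seed)
}

# Independent silhouette computation straight from the formula:
# s(i) = (b - a) / max(a, b).
silhouette_by_hand <- function(x, labels) {
  n <- nrow(x)
  d <- as.matrix(stats::dist(x))
  s <- numeric(n)
  for (i in seq_len(n)) {
    own <- which(labels == labels[i] & seq_len(n) != i)
    if (length(own) == 0) { s[i] <- 0; next }
    a <- mean(d[i, own])
    b <- min(vapply(setdiff(unique(labels), labels[i]), function(cl) {
      mean(d[i, labels == cl])
    }, numeric(1)))
    s[i] <- (b - a) / max(a, b)
  }
  mean(s)
}

# Plain Lloyd's algorithm for the exhaustive-initialisation k-means oracle.
lloyd_by_hand <- function(x, centers, iter = 100) {
  for (it in seq_len(iter)) {
    d <- vapply(seq_len(nrow(centers)), function(j) {
      rowSums(sweep(x, 2, centers[j, ])^2)
    }, numeric(nrow(x)))
    lab <- max.col(-d)
    new_centers <- centers
    for (j in seq_len(nrow(centers))) {
      if (any(lab == j)) {
        new_centers[j, ] <- colMeans(x[lab == j, , drop = FALSE])
      }
    }
    if (max(abs(new_centers - centers)) < 1e-12) break
    centers <- new_centers
  }
  d <- vapply(seq_len(nrow(centers)), function(j) {
    rowSums(sweep(x, 2, centers[j, ])^2)
  }, numeric(nrow(x)))
  lab <- max.col(-d)
  inertia <- sum(d[cbind(seq_len(nrow(x)), lab)])
  list(labels = lab, inertia = inertia)
}
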