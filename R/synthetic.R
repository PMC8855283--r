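#' Configuration for the synthetic cohort generator
#'
#' The generator emulates the statistical structure the pipeline assumes:
#' three patient subpopulations of sizes 694/96/73 whose usage sessions are
#' first-order Markov walks from the start pseudo-state to the exit
#' pseudo-state under subpopulation-specific transition matrices; per-state
#' lognormal dwell times seeded from the observed per-state mean dwell
#' times; inter-session idle gaps always above the 600 s session threshold;
#' and demographics and blood pressure drawn from subpopulation-specific
#' distributions (age, gender, education, SBP/DBP/HR means and SDs from the
#' observed cluster profiles).
#'
#' The three subpopulations differ only in the main-page row of the
#' transition matrix: the allocation of the main row's mass across the four
#' trail entry points is calibrated (by a fixed-point iteration on the
#' chain's expected per-state visit counts) so that the expected per-trail
#' visit fractions equal `mixtures`. This keeps the generator a legitimate
#' memoryless Markov process, matching the estimator's own assumption.
#'
#' @param n_patients Integer vector of subpopulation sizes (default
#'   `c(694, 96, 73)`).
#' @param mixtures Matrix with one row per subpopulation and columns
#'   PT-T/RO-T/KL-T/SA-T giving the target per-trail visit fractions; rows
#'   must sum to 1. Defaults to the three observed archetypes (0.81 on PT-T;
#'   0.37/0.53 on PT-T/KL-T; 0.30/0.37 on PT-T/SA-T) with the unreported
#'   remainder spread uniformly over the unlisted trails.
#' @param sessions_per_patient List with `mu` and `size` of the negative
#'   binomial session count per patient (at least 1 session is generated).
#' @param dwell_means Named vector of mean dwell seconds per state (default:
#'   observed per-state means shipped with the package).
#' @param dwell_sdlog Log-scale SD of the lognormal dwell distribution.
#' @param gap_mean Mean of the exponential part of the inter-session gap in
#'   seconds; the gap is `601 +` an exponential draw, so it always exceeds
#'   the 600 s threshold.
#' @param demo_params Per-subpopulation demographic/physiological
#'   parameters; see [default_demo_params()].
#' @param mean_readings Mean number of BP uploads per patient.
#' @param study_start,study_end Bounds of the simulated calendar window.
#' @param space State space (default the 28-state vocabulary).
#' @param trail_map Trail membership used for calibration.
#' @return An object of class `synth_config`.
#' @export
synth_config <- function(n_patients = c(694, 96, 73),
                         mixtures = default_mixtures(),
                         sessions_per_patient = list(mu = 60, size = 3),
                         dwell_means = default_dwell_means(),
                         dwell_sdlog = 1,
                         gap_mean = 7200,
                         demo_params = default_demo_params(),
                         mean_readings = 20,
                         study_start = as.POSIXct("2016-12-28", tz = "UTC"),
                         study_end = as.POSIXct("2020-07-02", tz = "UTC"),
                         space = state_space(),
                         trail_map = default_trail_map()) {
  mixtures <- as.matrix(mixtures)
  if (length(n_patients) != nrow(mixtures) ||
      length(demo_params) != nrow(mixtures)) {
    rlang::abort("n_patients, mixtures, demo_params must agree on the number of subpopulations.")
  }
  if (any(mixtures < 0) || any(abs(rowSums(mixtures) - 1) > 1e-8)) {
    rlang::abort("Each row of `mixtures` must be nonnegative and sum to 1.")
  }
  if (any(n_patients < 1)) rlang::abort("Subpopulation sizes must be >= 1.")
  if (any(dwell_means[space$states] <= 0) || anyNA(dwell_means[space$states])) {
    rlang::abort("`dwell_means` must give a positive mean for every state.")
  }
  cfg <- structure(
    list(
      n_patients = as.integer(n_patients),
      mixtures = mixtures,
      sessions_per_patient = sessions_per_patient,
      dwell_means = dwell_means,
      dwell_sdlog = dwell_sdlog,
      gap_mean = gap_mean,
      demo_params = demo_params,
      mean_readings = mean_readings,
      study_start = study_start,
      study_end = study_end,
      space = space,
      trail_map = trail_map
    ),
    class = "synth_config"
  )
  cfg$matrices <- lapply(seq_len(nrow(mixtures)), function(i) {
    subpop_transition_matrix(cfg, mixtures[i, ])
  })
  cfg
}

#' @export
print.synth_config <- function(x, ...) {
  cat("<synth_config> ", length(x$n_patients), " subpopulations (",
      paste(x$n_patients, collapse = "/"), " patients), ",
      length(x$space$states), " states\n", sep = "")
  invisible(x)
}

#' Default per-trail visit-fraction archetypes of the three subpopulations
#'
#' The listed components are the observed cluster preferences (PT-T 0.81;
#' PT-T 0.37 with KL-T 0.53; PT-T 0.30 with SA-T 0.37); the unreported
#' remainders are synthetic choices, spread uniformly over the unlisted
#' trails.
#'
#' @return A 3 x 4 matrix, rows named by subpopulation archetype.
#' @export
default_mixtures <- function() {
  m <- rbind(
    "PT-T"       = c(0.81, 0.19 / 3, 0.19 / 3, 0.19 / 3),
    "PT-T+KL-T"  = c(0.37, 0.05, 0.53, 0.05),
    "PT-T+SA-T"  = c(0.30, 0.165, 0.165, 0.37)
  )
  colnames(m) <- c("PT-T", "RO-T", "KL-T", "SA-T")
  m
}

#' Observed per-state visit counts and total dwell times
#'
#' The published per-state quantities and total dwell seconds of the
#' 863-patient hypertension deployment the package models, shipped as a
#' plain-text reference table. Used to seed the generator's dwell-time
#' means and as the fixture for the summary-arithmetic checks.
#'
#' @return A tibble `state`, `quantity`, `total_time_s`.
#' @export
reference_state_stats <- function() {
  readr::read_csv(
    system.file("extdata", "reference_state_stats.csv", package = "trailmark"),
    col_types = readr::cols(
      state = readr::col_character(),
      quantity = readr::col_integer(),
      total_time_s = readr::col_double()
    )
  )
}

#' @rdname reference_state_stats
#' @export
default_dwell_means <- function() {
  ref <- reference_state_stats()
  stats::setNames(ref$total_time_s / ref$quantity, ref$state)
}

#' Default per-subpopulation demographic and physiological parameters
#'
#' Seeded from the observed cluster profiles: mean (SD) of age, male
#' proportion, education distribution (below high school / high school /
#' university and above / don't know), and mean (SD) of SBP, DBP and HR.
#' `sd_within` values (within-patient reading noise) are synthetic choices.
#'
#' @return A list with one entry per subpopulation.
#' @export
default_demo_params <- function() {
  list(
    "PT-T" = list(
      age = c(53.20, 9.93), p_male = 0.6758,
      education = c(0.3588, 0.1513, 0.4625, 0.0274),
      sbp = c(132.71, 15.43), dbp = c(86.46, 11.37), hr = c(72.41, 14.23)
    ),
    "PT-T+KL-T" = list(
      age = c(52.23, 9.99), p_male = 0.5000,
      education = c(0.4479, 0.2188, 0.3125, 0.0208),
      sbp = c(137.44, 17.96), dbp = c(90.60, 12.88), hr = c(73.20, 17.13)
    ),
    "PT-T+SA-T" = list(
      age = c(50.86, 10.34), p_male = 0.6712,
      education = c(0.4657, 0.1507, 0.3425, 0.0411),
      sbp = c(130.77, 13.18), dbp = c(84.87, 11.29), hr = c(73.23, 15.83)
    )
  )
}

# ---- transition-matrix construction --------------------------------------

# Shared within-trail dynamics over the full state space. Quoted transition
# probabilities of the deployment are used where reported; remaining mass
# goes back to main and to exit. The main row is set per subpopulation by
# set_main_row().
base_transition_matrix <- function(space) {
  all <- space$all
  P <- matrix(0, length(all), length(all),
              dimnames = list(from = all, to = all))
  set_row <- function(from, ...) {
    probs <- c(...)
    stopifnot(abs(sum(probs) - 1) < 1e-9)
    P[from, names(probs)] <<- probs
  }
  exit <- space$exit_state
  row <- function(...) c(...)
  set_row(space$start_state, row("main" = 0.91, "log-in" = 0.06,
                                 "register" = 0.01,
                                 "person information" = 0.02))
  set_row("task BP", row("task BP" = 0.05, "BP history" = 0.10,
                         "BP guidance" = 0.03, "main" = 0.52,
                         "(exit)" = 0.30))
  set_row("task drug", row("task drug" = 0.05, "drug history" = 0.08,
                           "main" = 0.53, "(exit)" = 0.34))
  set_row("task weight", row("task weight" = 0.05, "weight history" = 0.08,
                             "main" = 0.57, "(exit)" = 0.30))
  set_row("task food", row("task food" = 0.05, "food history" = 0.04,
                           "main" = 0.61, "(exit)" = 0.30))
  set_row("task uncomfortable", row("task uncomfortable" = 0.05,
                                    "main" = 0.65, "(exit)" = 0.30))
  set_row("BP history", row("task BP" = 0.90, "main" = 0.06, "(exit)" = 0.04))
  set_row("drug history", row("task drug" = 0.95, "main" = 0.03,
                              "(exit)" = 0.02))
  set_row("weight history", row("task weight" = 0.95, "main" = 0.03,
                                "(exit)" = 0.02))
  set_row("food history", row("task food" = 0.99, "main" = 0.008,
                              "(exit)" = 0.002))
  set_row("BP guidance", row("task BP" = 0.96, "main" = 0.03,
                             "(exit)" = 0.01))
  set_row("reminder", row("reminder item" = 0.58, "main" = 0.30,
                          "(exit)" = 0.12))
  set_row("reminder item", row("reminder" = 0.43, "task BP" = 0.20,
                               "task drug" = 0.25, "main" = 0.08,
                               "(exit)" = 0.04))
  set_row("health report", row("monthly report" = 0.26, "ranking" = 0.10,
                               "main" = 0.44, "(exit)" = 0.20))
  set_row("monthly report", row("health report" = 0.92, "main" = 0.05,
                                "(exit)" = 0.03))
  set_row("ranking", row("health report" = 0.10, "main" = 0.46,
                         "(exit)" = 0.44))
  set_row("knowledge list", row("knowledge content" = 0.47,
                                "knowledge list by tag" = 0.05,
                                "knowledge collect" = 0.02,
                                "main" = 0.31, "(exit)" = 0.15))
  set_row("knowledge content", row("knowledge list" = 0.31,
                                   "knowledge collect" = 0.03,
                                   "main" = 0.41, "(exit)" = 0.25))
  set_row("knowledge list by tag", row("knowledge content" = 0.98,
                                       "main" = 0.01, "(exit)" = 0.01))
  set_row("knowledge collect", row("knowledge content" = 0.40,
                                   "main" = 0.40, "(exit)" = 0.20))
  set_row("questionnaire", row("questionnaire" = 0.29, "main" = 0.41,
                               "(exit)" = 0.30))
  set_row("appointment", row("show appointment" = 0.41, "main" = 0.39,
                             "(exit)" = 0.20))
  set_row("show appointment", row("appointment" = 0.73, "main" = 0.17,
                                  "(exit)" = 0.10))
  set_row("person information", row("setting" = 0.16, "main" = 0.64,
                                    "(exit)" = 0.20))
  set_row("setting", row("person information" = 1.00))
  set_row("account", row("person information" = 0.95, "main" = 0.03,
                         "(exit)" = 0.02))
  set_row("log-in", row("register" = 0.17, "main" = 0.28, "(exit)" = 0.55))
  set_row("register", row("log-in" = 0.65, "main" = 0.25, "(exit)" = 0.10))
  stopifnot(identical(exit, "(exit)"))
  P
}

# Within-trail allocation of the main row's trail mass (entry pages).
# PT-T entries follow the quoted main-row probabilities (task BP 0.29,
# task drug 0.18, task weight 0.20, task food 0.03, task uncomfortable 0.01)
# plus a small reminder share.
main_entry_dists <- function() {
  norm <- function(x) x / sum(x)
  list(
    "PT-T" = norm(c("task BP" = 0.29, "task drug" = 0.18,
                    "task weight" = 0.20, "task food" = 0.03,
                    "task uncomfortable" = 0.01, "reminder" = 0.03)),
    "RO-T" = norm(c("ranking" = 0.55, "health report" = 0.45)),
    "KL-T" = norm(c("knowledge list" = 0.85, "knowledge list by tag" = 0.15)),
    "SA-T" = norm(c("questionnaire" = 0.50, "appointment" = 0.50))
  )
}

# Fixed (non-trail) part of the main row.
main_fixed_row <- function() {
  c("(exit)" = 0.10, "person information" = 0.006, "setting" = 0.002,
    "account" = 0.002)
}

set_main_row <- function(P, w) {
  entries <- main_entry_dists()
  fixed <- main_fixed_row()
  row <- stats::setNames(numeric(ncol(P)), colnames(P))
  row[names(fixed)] <- fixed
  for (t in names(entries)) {
    row[names(entries[[t]])] <- row[names(entries[[t]])] +
      w[[t]] * entries[[t]]
  }
  P["main", ] <- row
  P
}

# Expected number of visits to each state per session, from the fundamental
# matrix of the absorbing chain (exit absorbing, start the initial state).
expected_visits <- function(P, space) {
  transient <- setdiff(space$all, space$exit_state)
  Q <- P[transient, transient, drop = FALSE]
  e1 <- stats::setNames(numeric(length(transient)), transient)
  e1[space$start_state] <- 1
  v <- solve(t(diag(length(transient)) - Q), e1)
  stats::setNames(as.numeric(v), transient)
}

trail_fractions <- function(P, space, trail_map) {
  v <- expected_visits(P, space)
  trails <- c("PT-T", "RO-T", "KL-T", "SA-T")
  by_trail <- vapply(trails, function(t) {
    sum(v[intersect(trail_map$state[trail_map$trail == t], names(v))])
  }, numeric(1))
  by_trail / sum(by_trail)
}

# Calibrate the main row's trail weights so the chain's expected per-trail
# visit fractions match the target mixture. Damped multiplicative fixed
# point; deterministic.
subpop_transition_matrix <- function(cfg, target, tol = 1e-5,
                                     max_iter = 2000) {
  base <- base_transition_matrix(cfg$space)
  mass <- 1 - sum(main_fixed_row())
  target <- as.numeric(target)
  names(target) <- c("PT-T", "RO-T", "KL-T", "SA-T")
  w <- rep(mass / 4, 4)
  names(w) <- names(target)
  P <- set_main_row(base, w)
  for (it in seq_len(max_iter)) {
    f <- trail_fractions(P, cfg$space, cfg$trail_map)
    if (max(abs(f - target)) < tol) break
    w <- w * (target / pmax(f, 1e-12))^0.6
    w <- w / sum(w) * mass
    P <- set_main_row(base, w)
  }
  if (max(abs(trail_fractions(P, cfg$space, cfg$trail_map) - target)) > 1e-3) {
    rlang::warn("Trail-mixture calibration did not reach 1e-3; using best iterate.")
  }
  P
}

# ---- simulation -----------------------------------------------------------

# Vectorised Markov walks: all sessions advance in lock step; absorbed
# sessions drop out. Returns session index + state index (into space$all)
# in within-session order.
walk_markov <- function(P, n_sessions, max_len = 500) {
  cum <- t(apply(P, 1, cumsum))
  exit_idx <- ncol(P)
  cum[, exit_idx] <- 1  # absorb floating-point shortfall into exit
  cur <- rep(1L, n_sessions)
  active <- seq_len(n_sessions)
  ids <- vector("list", max_len)
  sts <- vector("list", max_len)
  step <- 0L
  while (length(active) > 0L && step < max_len) {
    step <- step + 1L
    nxt <- integer(length(active))
    for (s in unique(cur)) {
      w <- which(cur == s)
      nxt[w] <- findInterval(stats::runif(length(w)), cum[s, ]) + 1L
    }
    keep <- nxt != exit_idx
    ids[[step]] <- active[keep]
    sts[[step]] <- nxt[keep]
    active <- active[keep]
    cur <- nxt[keep]
  }
  sid <- unlist(ids)
  st <- unlist(sts)
  o <- order(sid)  # radix sort is stable: step order preserved in-session
  tibble::tibble(session_idx = sid[o], state_idx = st[o])
}

simulate_subpop <- function(cfg, sub, patient_ids) {
  n_pat <- length(patient_ids)
  P <- cfg$matrices[[sub]]
  par <- cfg$demo_params[[sub]]
  space <- cfg$space

  n_sessions <- pmax(1L, stats::rnbinom(n_pat,
                                        size = cfg$sessions_per_patient$size,
                                        mu = cfg$sessions_per_patient$mu))
  session_patient <- rep(patient_ids, n_sessions)
  walks <- walk_markov(P, sum(n_sessions))
  meanlog <- log(cfg$dwell_means[space$states]) - cfg$dwell_sdlog^2 / 2

  visits <- walks |>
    dplyr::mutate(
      patient_id = session_patient[.data$session_idx],
      state = space$all[.data$state_idx],
      dwell = pmax(1, round(stats::rlnorm(dplyr::n(),
                                          meanlog[.data$state],
                                          cfg$dwell_sdlog)))
    )
  # session start offsets within patient: previous sessions' durations plus
  # idle gaps strictly above the 600 s threshold
  sess <- visits |>
    dplyr::group_by(.data$patient_id, .data$session_idx) |>
    dplyr::summarise(dur = sum(.data$dwell), .groups = "drop_last") |>
    dplyr::mutate(
      gap = c(0, 601 + round(stats::rexp(dplyr::n() - 1L,
                                         1 / cfg$gap_mean))),
      session_start = cumsum(.data$gap +
                               dplyr::lag(.data$dur, default = 0))
    ) |>
    dplyr::ungroup()
  window <- as.numeric(difftime(cfg$study_end, cfg$study_start,
                                units = "secs"))
  patient_start <- stats::setNames(
    floor(stats::runif(n_pat, 0, window * 0.5)), patient_ids)

  usage <- visits |>
    dplyr::left_join(sess[, c("session_idx", "session_start")],
                     by = "session_idx") |>
    dplyr::group_by(.data$session_idx) |>
    dplyr::mutate(offset = cumsum(dplyr::lag(.data$dwell, default = 0))) |>
    dplyr::ungroup() |>
    dplyr::mutate(
      enter_time = cfg$study_start + patient_start[.data$patient_id] +
        .data$session_start + .data$offset,
      exit_time = .data$enter_time + .data$dwell
    ) |>
    dplyr::select("patient_id", "state", "enter_time", "exit_time", "dwell")

  # demographics: age at first use, truncated to the 18-80 inclusion window
  first_use <- usage |>
    dplyr::group_by(.data$patient_id) |>
    dplyr::summarise(first_use = min(.data$enter_time), .groups = "drop")
  age <- pmin(80, pmax(18, stats::rnorm(n_pat, par$age[1], par$age[2])))
  demographics <- tibble::tibble(
    patient_id = patient_ids,
    date_of_birth = as.Date(first_use$first_use[
      match(patient_ids, first_use$patient_id)]) -
      round(age * 365.2425),
    gender = factor(ifelse(stats::runif(n_pat) < par$p_male,
                           "male", "female"),
                    levels = c("male", "female")),
    education = factor(sample(education_levels(), n_pat, replace = TRUE,
                              prob = par$education),
                       levels = education_levels())
  )

  # physiology: patient-level means at the subpopulation distribution,
  # within-patient reading noise on top
  n_read <- 1L + stats::rpois(n_pat, cfg$mean_readings - 1)
  mu_sbp <- stats::rnorm(n_pat, par$sbp[1], par$sbp[2])
  mu_dbp <- stats::rnorm(n_pat, par$dbp[1], par$dbp[2])
  mu_hr <- stats::rnorm(n_pat, par$hr[1], par$hr[2])
  last_use <- usage |>
    dplyr::group_by(.data$patient_id) |>
    dplyr::summarise(last_use = max(.data$exit_time), .groups = "drop")
  physio <- tibble::tibble(
    patient_id = rep(patient_ids, n_read),
    sbp = round(stats::rnorm(sum(n_read), rep(mu_sbp, n_read), 6)),
    dbp = round(stats::rnorm(sum(n_read), rep(mu_dbp, n_read), 5)),
    hr = round(stats::rnorm(sum(n_read), rep(mu_hr, n_read), 6))
  ) |>
    dplyr::mutate(
      dbp = pmax(40, pmin(.data$dbp, .data$sbp - 5)),
      sbp = pmax(.data$sbp, .data$dbp + 5),
      hr = pmax(35, .data$hr)
    )
  span_start <- first_use$first_use[match(physio$patient_id,
                                          first_use$patient_id)]
  span_end <- last_use$last_use[match(physio$patient_id,
                                      last_use$patient_id)]
  physio$upload_time <- span_start + floor(
    stats::runif(nrow(physio)) *
      pmax(1, as.numeric(difftime(span_end, span_start, units = "secs"))))
  physio <- dplyr::arrange(physio, .data$patient_id, .data$upload_time) |>
    dplyr::select("patient_id", "sbp", "dbp", "hr", "upload_time")

  list(usage = usage, demographics = demographics, physio = physio)
}

#' Simulate a full synthetic cohort
#'
#' Generates usage logs, demographics and physiological records for every
#' subpopulation in `config`, together with a ground-truth table of planted
#' subpopulation labels and target trail mixtures for recovery experiments.
#' Deterministic given `seed`.
#'
#' @param config A [synth_config()].
#' @param seed Integer seed.
#' @return A list of tibbles: `usage`, `demographics`, `physio`, `truth`
#'   (patient, subpopulation, planted mixture), plus the `config`.
#' @export
#' @examples
#' cfg <- synth_config(n_patients = c(5, 3, 2),
#'                     sessions_per_patient = list(mu = 5, size = 3))
#' cohort <- simulate_cohort(cfg, seed = 7)
#' nrow(cohort$truth)
simulate_cohort <- function(config = synth_config(), seed = 1) {
  stopifnot(inherits(config, "synth_config"))
  withr::with_seed(seed, {
    n_sub <- length(config$n_patients)
    ids <- split(
      sprintf("p%04d", seq_len(sum(config$n_patients))),
      rep(seq_len(n_sub), config$n_patients)
    )
    parts <- lapply(seq_len(n_sub), function(i) {
      simulate_subpop(config, i, ids[[i]])
    })
    labels <- names(config$demo_params) %||% paste0("sub", seq_len(n_sub))
    truth <- tibble::tibble(
      patient_id = unlist(ids),
      subpopulation = rep(labels, config$n_patients)
    )
    mix <- config$mixtures[rep(seq_len(n_sub), config$n_patients), ,
                           drop = FALSE]
    truth$pt_t <- mix[, 1]; truth$ro_t <- mix[, 2]
    truth$kl_t <- mix[, 3]; truth$sa_t <- mix[, 4]
    list(
      usage = purrr::list_rbind(purrr::map(parts, "usage")),
      demographics = purrr::list_rbind(purrr::map(parts, "demographics")),
      physio = purrr::list_rbind(purrr::map(parts, "physio")),
      truth = truth,
      config = config
    )
  })
}

#' Simulate a single patient
#'
#' Convenience wrapper around the cohort machinery for one patient of one
#' subpopulation; useful for unit tests and inspection.
#'
#' @inheritParams simulate_cohort
#' @param subpopulation Subpopulation index (row of `config$mixtures`).
#' @param patient_id Identifier for the simulated patient.
#' @return A list of tibbles `usage`, `demographics`, `physio`.
#' @export
simulate_patient <- function(config = synth_config(), subpopulation = 1,
                             patient_id = "p0001", seed = 1) {
  stopifnot(inherits(config, "synth_config"),
            subpopulation %in% seq_along(config$n_patients))
  withr::with_seed(seed, simulate_subpop(config, subpopulation, patient_id))
}

#' Write a simulated cohort to CSV files
#'
#' Writes `usage_log.csv`, `demographics.csv`, `physio.csv` and `truth.csv`
#' into `dir`, in the formats the readers in this package expect.
#'
#' @param cohort Output of [simulate_cohort()].
#' @param dir Output directory (created if needed).
#' @return The directory, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_usage_log(cohort$usage, file.path(dir, "usage_log.csv"))
  write_demographics(cohort$demographics, file.path(dir, "demographics.csv"))
  write_physio(cohort$physio, file.path(dir, "physio.csv"))
  readr::write_csv(cohort$truth, file.path(dir, "truth.csv"))
  invisible(dir)
}
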