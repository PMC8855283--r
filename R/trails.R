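#' Per-patient behavior-preference vectors over engagement trails
#'
#' The preference feature of a patient is the number of behavioral states
#' the patient performed in each trail, normalised so the four components
#' (PT-T, RO-T, KL-T, SA-T) sum to 1. By default a "performed state" is a
#' visit event, so revisiting a page counts again (`count = "visits"`);
#' `count = "distinct"` counts distinct pages per trail instead. Visits to
#' `OTHER` states (the navigation hub and account pages) are excluded.
#'
#' Patients with no visit in any trail cannot be normalised: they are kept
#' with `excluded = TRUE` and `NA` preference values, and are dropped from
#' clustering downstream.
#'
#' @param usage A visit-level tibble (raw usage log or sessionized) with
#'   columns `patient_id` and `state`.
#' @param trail_map State-to-trail mapping tibble with columns `state`,
#'   `trail` (default [default_trail_map()]); states absent from the map are
#'   treated as `OTHER`.
#' @param count `"visits"` (default) or `"distinct"`.
#' @return A tibble with one row per patient: preference columns `pt_t`,
#'   `ro_t`, `kl_t`, `sa_t` summing to 1, raw counts `n_pt_t` ... `n_sa_t`,
#'   `n_total` (visits counted), and `excluded`.
#' @export
#' @examples
#' usage <- tibble::tibble(
#'   patient_id = "p1",
#'   state = c(rep("task BP", 6), "ranking", "ranking",
#'             "knowledge list", "knowledge content")
#' )
#' preference_features(usage)  # (0.6, 0.2, 0.2, 0)
preference_features <- function(usage, trail_map = default_trail_map(),
                                count = c("visits", "distinct")) {
  count <- match.arg(count)
  trails <- c("PT-T", "RO-T", "KL-T", "SA-T")
  counted <- usage |>
    dplyr::left_join(trail_map, by = "state") |>
    dplyr::mutate(trail = dplyr::coalesce(.data$trail, "OTHER")) |>
    dplyr::filter(.data$trail %in% trails)
  if (count == "distinct") {
    counted <- dplyr::distinct(counted, .data$patient_id, .data$trail,
                               .data$state)
  }
  wide <- counted |>
    dplyr::count(.data$patient_id,
                 trail = factor(.data$trail, levels = trails),
                 .drop = FALSE) |>
    tidyr::pivot_wider(names_from = "trail", values_from = "n",
                       values_fill = 0L)
  # patients whose every visit is OTHER still get a (zero) row
  wide <- tibble::tibble(patient_id = unique(usage$patient_id)) |>
    dplyr::left_join(wide, by = "patient_id") |>
    dplyr::mutate(dplyr::across(-"patient_id", ~ dplyr::coalesce(.x, 0L)))
  raw <- as.matrix(wide[, trails])
  totals <- rowSums(raw)
  prefs <- raw / ifelse(totals > 0, totals, NA_real_)
  out <- tibble::tibble(
    patient_id = wide$patient_id,
    pt_t = as.numeric(prefs[, "PT-T"]), ro_t = as.numeric(prefs[, "RO-T"]),
    kl_t = as.numeric(prefs[, "KL-T"]), sa_t = as.numeric(prefs[, "SA-T"]),
    n_pt_t = as.integer(raw[, "PT-T"]), n_ro_t = as.integer(raw[, "RO-T"]),
    n_kl_t = as.integer(raw[, "KL-T"]), n_sa_t = as.integer(raw[, "SA-T"]),
    n_total = as.numeric(totals),
    excluded = totals == 0
  )
  if (any(out$excluded)) {
    rlang::warn(paste0(sum(out$excluded), " patient(s) with no trail visits ",
                       "flagged `excluded` (preference undefined)."))
  }
  out
}

pref_cols <- function() c("pt_t", "ro_t", "kl_t", "sa_t")

#' Write / read preference vectors
#'
#' @param preferences A tibble from [preference_features()].
#' @param path CSV path.
#' @export
write_preferences <- function(preferences, path) {
  readr::write_csv(preferences, path)
  invisible(path)
}
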