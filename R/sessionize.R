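#' Split visit streams into sessions by an inactivity gap
#'
#' A session is a contiguous run of page visits by one patient. A new
#' session begins exactly when the idle time between two consecutive visits
#' exceeds `gap` seconds (strictly greater: a gap of exactly `gap` stays in
#' the same session). By default the gap is measured from the exit of the
#' current page to the entry of the next (`from = "exit"`, i.e. idle time);
#' `from = "enter"` measures entry-to-entry instead.
#'
#' Overlapping visits (negative gaps) are tolerated: the gap is clamped to 0
#' with a warning, so they always stay in the same session. Consecutive
#' identical states within a session are kept as separate visits; they become
#' self-transitions in the Markov model (the app-switch-and-return pattern).
#'
#' @param usage A usage-log tibble (see [read_usage_log()]) with columns
#'   `patient_id`, `state`, `enter_time`, `exit_time`; `dwell` is computed if
#'   absent.
#' @param gap Inactivity threshold in seconds (default 600).
#' @param from Where the gap is measured from: `"exit"` (default, idle time)
#'   or `"enter"`.
#' @return A tibble of the input visits (stably sorted by patient and enter
#'   time) with added columns `session` (1-based session index within
#'   patient) and `position` (1-based visit index within session).
#' @export
#' @examples
#' usage <- tibble::tibble(
#'   patient_id = "p1", state = c("main", "task BP", "main"),
#'   enter_time = as.POSIXct(c(0, 20, 1000), origin = "1970-01-01", tz = "UTC"),
#'   exit_time  = as.POSIXct(c(10, 30, 1010), origin = "1970-01-01", tz = "UTC")
#' )
#' sessionize(usage)  # 601+ s idle -> two sessions
sessionize <- function(usage, gap = 600, from = c("exit", "enter")) {
  from <- match.arg(from)
  if (!is.numeric(gap) || length(gap) != 1L || gap <= 0) {
    rlang::abort("`gap` must be a single positive number of seconds.")
  }
  if (nrow(usage) == 0L) {
    return(dplyr::mutate(usage, session = integer(), position = integer()))
  }
  if (!"dwell" %in% names(usage)) {
    usage <- dplyr::mutate(
      usage,
      dwell = as.numeric(difftime(.data$exit_time, .data$enter_time,
                                  units = "secs"))
    )
  }
  anchor <- if (from == "exit") rlang::sym("exit_time") else rlang::sym("enter_time")
  out <- usage |>
    dplyr::arrange(.data$patient_id, .data$enter_time) |>
    dplyr::group_by(.data$patient_id) |>
    dplyr::mutate(
      .gap = as.numeric(difftime(.data$enter_time, dplyr::lag(!!anchor),
                                 units = "secs"))
    ) |>
    dplyr::mutate(
      .neg = !is.na(.data$.gap) & .data$.gap < 0,
      .gap = pmax(.data$.gap, 0),
      session = cumsum(is.na(.data$.gap) | .data$.gap > gap)
    ) |>
    dplyr::group_by(.data$patient_id, .data$session) |>
    dplyr::mutate(position = dplyr::row_number()) |>
    dplyr::ungroup()
  n_neg <- sum(out$.neg)
  if (n_neg > 0) {
    rlang::warn(paste0(n_neg, " negative inter-visit gap(s) (overlapping ",
                       "visits) clamped to 0."))
  }
  dplyr::select(out, -".gap", -".neg")
}

#' Per-patient session summaries
#'
#' @param sessions A sessionized tibble from [sessionize()].
#' @return A tibble with one row per patient: `n_sessions`, `n_visits`,
#'   `visits_per_session`, and `total_dwell` (seconds).
#' @export
session_stats <- function(sessions) {
  sessions |>
    dplyr::group_by(.data$patient_id) |>
    dplyr::summarise(
      n_sessions = dplyr::n_distinct(.data$session),
      n_visits = dplyr::n(),
      visits_per_session = dplyr::n() / dplyr::n_distinct(.data$session),
      total_dwell = sum(.data$dwell),
      .groups = "drop"
    )
}
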