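#' Read a usage log of page visits
#'
#' The usage log is the raw clickstream: one row per page visit with the
#' patient identifier, the page (behavioral state) name, and the times the
#' page was entered and exited, at second resolution. Dwell time is computed
#' as `exit_time - enter_time`.
#'
#' Files are UTF-8 CSV with ISO-8601 timestamps (UTC). Rows are returned
#' sorted by `(patient_id, enter_time)` with a stable sort, so visits sharing
#' a timestamp keep their file order. States outside `vocabulary` are kept
#' (they are routed to the `OTHER` trail downstream) but reported with a
#' warning, and flagged in the `known` column.
#'
#' @param path Path to a CSV file with columns `patient_id`, `state`,
#'   `enter_time`, `exit_time`.
#' @param vocabulary Character vector of expected state names, or a
#'   [state_space()]. Defaults to the 28-state app vocabulary.
#' @return A tibble with columns `patient_id` (character), `state`
#'   (character), `enter_time`, `exit_time` (POSIXct, UTC), `dwell`
#'   (seconds), `known` (logical).
#' @export
#' @examples
#' f <- tempfile(fileext = ".csv")
#' writeLines(c("patient_id,state,enter_time,exit_time",
#'              "p1,main,2019-01-01T08:00:00Z,2019-01-01T08:00:10Z"), f)
#' read_usage_log(f)
read_usage_log <- function(path, vocabulary = app_states()) {
  if (inherits(vocabulary, "state_space")) vocabulary <- vocabulary$states
  x <- readr::read_csv(
    path,
    col_types = readr::cols(
      patient_id = readr::col_character(),
      state = readr::col_character(),
      enter_time = readr::col_datetime(),
      exit_time = readr::col_datetime()
    )
  )
  required <- c("patient_id", "state", "enter_time", "exit_time")
  missing <- setdiff(required, names(x))
  if (length(missing)) {
    rlang::abort(paste0("Usage log is missing column(s): ",
                        paste(missing, collapse = ", ")))
  }
  bad <- which(x$exit_time < x$enter_time)
  if (length(bad)) {
    rlang::abort(paste0(
      "exit_time precedes enter_time in row(s): ",
      paste(utils::head(bad, 10), collapse = ", "),
      if (length(bad) > 10) " ..." else ""
    ))
  }
  x <- x |>
    dplyr::mutate(
      dwell = as.numeric(difftime(.data$exit_time, .data$enter_time,
                                  units = "secs")),
      known = .data$state %in% vocabulary
    ) |>
    dplyr::arrange(.data$patient_id, .data$enter_time)
  n_unknown <- sum(!x$known)
  if (n_unknown > 0) {
    rlang::warn(paste0(
      n_unknown, " visit(s) use state name(s) outside the vocabulary: ",
      paste(utils::head(sort(unique(x$state[!x$known])), 5), collapse = ", ")
    ))
  }
  x
}

#' @rdname read_usage_log
#' @param usage A usage-log tibble as returned by [read_usage_log()] (the
#'   derived `dwell`/`known` columns are dropped on write).
#' @export
write_usage_log <- function(usage, path) {
  usage |>
    dplyr::select("patient_id", "state", "enter_time", "exit_time") |>
    readr::write_csv(path)
  invisible(path)
}

education_levels <- function() {
  c("below high school", "high school", "university and above", "don't know")
}

#' Read patient demographics
#'
#' One row per patient: date of birth, gender (`male`/`female`), and
#' education level (`below high school`, `high school`,
#' `university and above`, `don't know`). Unrecognised education strings are
#' mapped to `don't know`, and unrecognised genders to `NA`, with a warning;
#' rows are never silently dropped. A duplicated `patient_id` is an error.
#'
#' @param path Path to a CSV file with columns `patient_id`,
#'   `date_of_birth`, `gender`, `education`.
#' @return A tibble with typed columns; `gender` and `education` are factors
#'   with the closed category sets.
#' @export
read_demographics <- function(path) {
  x <- readr::read_csv(
    path,
    col_types = readr::cols(
      patient_id = readr::col_character(),
      date_of_birth = readr::col_date(),
      gender = readr::col_character(),
      education = readr::col_character()
    )
  )
  required <- c("patient_id", "date_of_birth", "gender", "education")
  missing <- setdiff(required, names(x))
  if (length(missing)) {
    rlang::abort(paste0("Demographics file is missing column(s): ",
                        paste(missing, collapse = ", ")))
  }
  dup <- unique(x$patient_id[duplicated(x$patient_id)])
  if (length(dup)) {
    rlang::abort(paste0("Duplicate patient_id in demographics: ",
                        paste(utils::head(dup, 5), collapse = ", ")))
  }
  bad_gender <- !is.na(x$gender) & !x$gender %in% c("male", "female")
  if (any(bad_gender)) {
    rlang::warn(paste0(sum(bad_gender),
                       " unrecognised gender value(s) set to NA."))
    x$gender[bad_gender] <- NA_character_
  }
  bad_edu <- !is.na(x$education) & !x$education %in% education_levels()
  if (any(bad_edu)) {
    rlang::warn(paste0(sum(bad_edu),
                       " unrecognised education value(s) mapped to \"don't know\"."))
    x$education[bad_edu] <- "don't know"
  }
  x$education[is.na(x$education)] <- "don't know"
  x |>
    dplyr::mutate(
      gender = factor(.data$gender, levels = c("male", "female")),
      education = factor(.data$education, levels = education_levels())
    )
}

#' @rdname read_demographics
#' @param demographics A demographics tibble.
#' @export
write_demographics <- function(demographics, path) {
  demographics |>
    dplyr::mutate(dplyr::across(dplyr::where(is.factor), as.character)) |>
    readr::write_csv(path)
  invisible(path)
}

#' Read physiological records
#'
#' Patient-uploaded readings: systolic and diastolic blood pressure (mmHg),
#' heart rate (beats/min), and the upload timestamp. Rows violating
#' `sbp > dbp > 0` or `hr > 0` are an error, listing the offending rows.
#'
#' @param path Path to a CSV file with columns `patient_id`, `sbp`, `dbp`,
#'   `hr`, `upload_time`.
#' @return A tibble of typed readings.
#' @export
read_physio <- function(path) {
  x <- readr::read_csv(
    path,
    col_types = readr::cols(
      patient_id = readr::col_character(),
      sbp = readr::col_double(),
      dbp = readr::col_double(),
      hr = readr::col_double(),
      upload_time = readr::col_datetime()
    )
  )
  required <- c("patient_id", "sbp", "dbp", "hr", "upload_time")
  missing <- setdiff(required, names(x))
  if (length(missing)) {
    rlang::abort(paste0("Physio file is missing column(s): ",
                        paste(missing, collapse = ", ")))
  }
  bad <- which(!(x$sbp > x$dbp & x$dbp > 0 & x$hr > 0))
  if (length(bad)) {
    rlang::abort(paste0(
      "Physiological readings violate sbp > dbp > 0, hr > 0 in row(s): ",
      paste(utils::head(bad, 10), collapse = ", "),
      if (length(bad) > 10) " ..." else ""
    ))
  }
  x
}

#' @rdname read_physio
#' @param physio A physio tibble.
#' @export
write_physio <- function(physio, path) {
  readr::write_csv(physio, path)
  invisible(path)
}
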