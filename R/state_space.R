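#' The behavioral-state vocabulary of the hypertension self-management app
#'
#' Each page of the pathway-based mHealth app stands in for one
#' self-management behavior ("behavioral state"): e.g. `task BP` is recording
#' a blood-pressure measurement, `knowledge content` is reading a piece of
#' health-education content. The vocabulary has 28 states organised in the
#' care pathway's modules.
#'
#' @return A character vector of 28 state names, ordered by care-pathway
#'   module (navigation hub first, then self-management tasks, record
#'   histories, reminders, reports, health education, support acquisition,
#'   and account pages).
#' @export
#' @examples
#' app_states()
app_states <- function() {
  c(
    "main",
    "task BP", "task drug", "task weight", "task food", "task uncomfortable",
    "BP history", "drug history", "weight history", "food history",
    "BP guidance",
    "reminder", "reminder item",
    "health report", "monthly report", "ranking",
    "knowledge list", "knowledge content", "knowledge list by tag",
    "knowledge collect",
    "questionnaire", "appointment", "show appointment",
    "person information", "setting", "account", "log-in", "register"
  )
}

#' Define a behavioral state space with start/exit pseudo-states
#'
#' A session is modelled as a walk that begins in a start pseudo-state (the
#' patient opens the app) and ends in an exit pseudo-state (the patient
#' leaves). Both pseudo-states are added to the real page vocabulary so the
#' transition matrix can count entries into the first page and exits from the
#' last one.
#'
#' @param states Character vector of real state names (defaults to the
#'   28-state app vocabulary from [app_states()]).
#' @param start_state,exit_state Names for the pseudo-states. They must not
#'   collide with any real state.
#' @return An object of class `state_space`: a list with elements `states`,
#'   `start_state`, `exit_state`, and `all` (start, states, exit in order).
#' @export
#' @examples
#' sp <- state_space(c("a", "b"))
#' sp$all
state_space <- function(states = app_states(),
                        start_state = "(start)",
                        exit_state = "(exit)") {
  states <- as.character(states)
  if (length(states) < 1L) {
    rlang::abort("`states` must contain at least one state name.")
  }
  if (anyDuplicated(states)) {
    rlang::abort("`states` must be distinct.")
  }
  if (start_state %in% states || exit_state %in% states ||
      start_state == exit_state) {
    rlang::abort("Pseudo-state names must not collide with real states.")
  }
  structure(
    list(
      states = states,
      start_state = start_state,
      exit_state = exit_state,
      all = c(start_state, states, exit_state)
    ),
    class = "state_space"
  )
}

#' @export
print.state_space <- function(x, ...) {
  cat("<state_space> ", length(x$states), " states + pseudo-states '",
      x$start_state, "' / '", x$exit_state, "'\n", sep = "")
  invisible(x)
}

#' Default mapping from behavioral states to engagement trails
#'
#' Four trails group the states by self-management scene:
#' * `PT-T` (perform task): the five self-management tasks, their record
#'   histories, BP guidance, and the reminder pages that funnel patients
#'   into the tasks.
#' * `RO-T` (result oriented): health report, monthly report, ranking.
#' * `KL-T` (knowledge learning): the four health-education pages.
#' * `SA-T` (support acquisition): questionnaire and appointment pages.
#'
#' Navigation and account pages (`main`, `person information`, `setting`,
#' `account`, `log-in`, `register`) are labelled `OTHER` and excluded from
#' preference features: `main` is the forced navigation hub of every session
#' and would swamp the trail signal.
#'
#' @return A tibble with columns `state` and `trail`.
#' @export
#' @examples
#' default_trail_map()
default_trail_map <- function() {
  pt <- c("task BP", "task drug", "task weight", "task food",
          "task uncomfortable", "BP history", "drug history",
          "weight history", "food history", "BP guidance",
          "reminder", "reminder item")
  ro <- c("health report", "monthly report", "ranking")
  kl <- c("knowledge list", "knowledge content", "knowledge list by tag",
          "knowledge collect")
  sa <- c("questionnaire", "appointment", "show appointment")
  other <- c("main", "person information", "setting", "account",
             "log-in", "register")
  tibble::tibble(
    state = c(pt, ro, kl, sa, other),
    trail = c(rep("PT-T", length(pt)), rep("RO-T", length(ro)),
              rep("KL-T", length(kl)), rep("SA-T", length(sa)),
              rep("OTHER", length(other)))
  )
}

#' Default grouping of states into care-pathway modules
#'
#' Used by [module_mean_time()] to aggregate per-state mean dwell times to
#' the app's functional modules. The `management plans` module comprises the
#' five self-management tasks together with their four record histories and
#' BP guidance.
#'
#' @return A named list mapping module name to a character vector of member
#'   states.
#' @export
default_module_map <- function() {
  list(
    "management plans" = c("task BP", "task drug", "task weight", "task food",
                           "task uncomfortable", "BP history", "drug history",
                           "weight history", "food history", "BP guidance"),
    "health education" = c("knowledge list", "knowledge content",
                           "knowledge list by tag", "knowledge collect"),
    "appointment" = c("appointment", "show appointment"),
    "reminder" = c("reminder", "reminder item"),
    "health report" = c("health report", "monthly report", "ranking"),
    "questionnaire" = "questionnaire"
  )
}

#' Read or write a trail map as YAML
#'
#' Trail membership is configuration: the YAML file maps each trail label to
#' a list of state names. Unlisted vocabulary states fall back to `OTHER`.
#'
#' @param path Path to a YAML file.
#' @param states Vocabulary used to complete the map (unlisted states become
#'   `OTHER`).
#' @return `read_trail_map()` returns a tibble with columns `state`, `trail`.
#' @export
read_trail_map <- function(path, states = app_states()) {
  raw <- yaml::read_yaml(path)
  map <- tibble::tibble(
    state = unlist(raw, use.names = FALSE),
    trail = rep(names(raw), lengths(raw))
  )
  if (anyDuplicated(map$state)) {
    rlang::abort("Each state may appear under exactly one trail.")
  }
  missing <- setdiff(states, map$state)
  dplyr::bind_rows(map, tibble::tibble(state = missing, trail = "OTHER"))
}

#' @rdname read_trail_map
#' @param trail_map A tibble with columns `state` and `trail`.
#' @export
write_trail_map <- function(trail_map, path) {
  split_map <- split(trail_map$state, trail_map$trail)
  yaml::write_yaml(split_map, path)
  invisible(path)
}

#' Read a state space from YAML
#'
#' The file holds `states` (list of real state names) and optionally
#' `start_state` / `exit_state`.
#'
#' @param path Path to a YAML file.
#' @return A [state_space()] object.
#' @export
read_state_space <- function(path) {
  raw <- yaml::read_yaml(path)
  state_space(
    states = raw$states,
    start_state = raw$start_state %||% "(start)",
    exit_state = raw$exit_state %||% "(exit)"
  )
}
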