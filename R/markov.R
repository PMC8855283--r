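#' Count behavioral-state transitions over sessions
#'
#' Every session of `m` visits is bracketed by the start and exit
#' pseudo-states and contributes exactly `m + 1` transitions: start to the
#' first page, the `m - 1` between-visit pairs (self-transitions when
#' consecutive visits share a page), and the last page to exit.
#'
#' @param sessions A sessionized tibble from [sessionize()].
#' @param space A [state_space()]; states in the log but not in the space are
#'   an error (route unknown pages through a wider vocabulary instead).
#' @return An integer count matrix `N` over `space$all` (start and exit
#'   pseudo-states included) with `N[i, j]` the number of observed
#'   transitions from state `i` to state `j`.
#' @export
count_transitions <- function(sessions, space = state_space()) {
  stopifnot(inherits(space, "state_space"))
  unknown <- setdiff(unique(sessions$state), space$states)
  if (length(unknown)) {
    rlang::abort(paste0("Sessions contain states outside the state space: ",
                        paste(utils::head(unknown, 5), collapse = ", ")))
  }
  all_states <- space$all
  n <- length(all_states)
  N <- matrix(0L, n, n, dimnames = list(from = all_states, to = all_states))
  if (nrow(sessions) == 0L) return(N)
  edges <- sessions |>
    dplyr::arrange(.data$patient_id, .data$session, .data$position) |>
    dplyr::group_by(.data$patient_id, .data$session) |>
    dplyr::reframe(
      from = c(space$start_state, .data$state),
      to = c(.data$state, space$exit_state)
    ) |>
    dplyr::count(.data$from, .data$to)
  idx <- cbind(match(edges$from, all_states), match(edges$to, all_states))
  N[idx] <- as.integer(edges$n)
  N
}

#' Row-normalise a transition count matrix
#'
#' Converts counts to maximum-likelihood transition probabilities
#' `p[i, j] = N[i, j] / sum_j N[i, j]`. Rows with no outgoing transitions
#' (always the exit pseudo-state, possibly unvisited states) are left as
#' all-zero and treated as absorbing.
#'
#' @param N A nonnegative count matrix with identical row/column names.
#' @return A row-stochastic matrix of the same shape; absorbing rows are
#'   all-zero and listed in the `"absorbing"` attribute.
#' @export
normalize_rows <- function(N) {
  if (any(N < 0)) rlang::abort("Transition counts must be nonnegative.")
  totals <- rowSums(N)
  P <- N / ifelse(totals > 0, totals, 1)
  attr(P, "absorbing") <- rownames(N)[totals == 0]
  P
}

#' Fit the first-order Markov chain of patient behavior
#'
#' Estimates the memoryless (first-order) chain: the probability of the next
#' behavioral state depends only on the current state. Higher orders are not
#' supported and are rejected explicitly rather than approximated.
#'
#' @inheritParams count_transitions
#' @param order Markov order; only `1` is supported.
#' @return An object of class `transition_model`: a list with the count
#'   matrix `counts`, the row-stochastic matrix `probs`, the `space`, and
#'   `n_sessions`.
#' @export
#' @examples
#' sp <- state_space(c("a", "b"))
#' usage <- tibble::tibble(
#'   patient_id = "p1", state = c("a", "b"),
#'   enter_time = as.POSIXct(c(0, 20), origin = "1970-01-01", tz = "UTC"),
#'   exit_time = as.POSIXct(c(10, 30), origin = "1970-01-01", tz = "UTC")
#' )
#' fit_markov(sessionize(usage), sp)
fit_markov <- function(sessions, space = state_space(), order = 1) {
  if (!identical(as.integer(order), 1L)) {
    rlang::abort("Only the first-order (memoryless) chain is supported.")
  }
  N <- count_transitions(sessions, space)
  structure(
    list(
      counts = N,
      probs = normalize_rows(N),
      space = space,
      n_sessions = nrow(dplyr::distinct(sessions, .data$patient_id,
                                        .data$session))
    ),
    class = "transition_model"
  )
}

#' @export
print.transition_model <- function(x, ...) {
  cat("<transition_model> first-order Markov chain over ",
      length(x$space$states), " states (+ start/exit), ",
      sum(x$counts), " transitions from ", x$n_sessions, " sessions\n",
      sep = "")
  invisible(x)
}

#' @describeIn fit_markov One row per observed transition: `from`, `to`,
#'   `count`, `prob`.
#' @param x A `transition_model`.
#' @param ... Unused.
#' @method tidy transition_model
#' @export
tidy.transition_model <- function(x, ...) {
  as.data.frame.table(x$counts, responseName = "count",
                      stringsAsFactors = FALSE) |>
    tibble::as_tibble() |>
    dplyr::mutate(prob = as.vector(x$probs)) |>
    dplyr::filter(.data$count > 0) |>
    dplyr::arrange(.data$from, dplyr::desc(.data$prob))
}

#' @describeIn fit_markov One-row model summary.
#' @method glance transition_model
#' @export
glance.transition_model <- function(x, ...) {
  tibble::tibble(
    n_states = length(x$space$states),
    n_sessions = x$n_sessions,
    n_transitions = sum(x$counts),
    n_edges = sum(x$counts > 0)
  )
}

#' Per-state visit quantity and dwell-time summary
#'
#' For each real behavioral state (pseudo-states excluded): the number of
#' visits (`quantity`), its percentage of all real-state visits
#' (`relative_quantity`), and total and mean dwell time in seconds. Values
#' are kept at full precision; the published-style 2-decimal rounding is a
#' display concern (see `print`/reporting helpers).
#'
#' @param sessions A sessionized tibble (or any visit-level tibble with
#'   `state` and `dwell` columns).
#' @param sort_by Column to sort descending by, `"quantity"` (default) or
#'   `"mean_time"`.
#' @return A tibble with columns `state`, `quantity`, `relative_quantity`
#'   (percent), `total_time`, `mean_time` (seconds).
#' @export
summarize_states <- function(sessions, sort_by = c("quantity", "mean_time")) {
  sort_by <- match.arg(sort_by)
  out <- sessions |>
    dplyr::group_by(.data$state) |>
    dplyr::summarise(
      quantity = dplyr::n(),
      total_time = sum(.data$dwell),
      .groups = "drop"
    ) |>
    dplyr::mutate(
      relative_quantity = 100 * .data$quantity / sum(.data$quantity),
      mean_time = .data$total_time / .data$quantity
    ) |>
    dplyr::select("state", "quantity", "relative_quantity",
                  "total_time", "mean_time")
  dplyr::arrange(out, dplyr::desc(.data[[sort_by]]))
}

#' Mean dwell time aggregated to care-pathway modules
#'
#' A module's value is the sum of its member states' mean dwell times, with
#' member means rounded to 2 decimals before summing, matching how the
#' published per-state means combine into module figures.
#'
#' @param summaries A state summary tibble from [summarize_states()].
#' @param grouping Named list mapping module name to member states
#'   (default [default_module_map()]). Every member must have a summary row.
#' @return A tibble with columns `module` and `mean_time` (seconds).
#' @export
#' @examples
#' s <- tibble::tibble(state = c("appointment", "show appointment"),
#'                     quantity = c(3209, 1606),
#'                     relative_quantity = c(1.08, 0.54),
#'                     total_time = c(19157, 261371),
#'                     mean_time = c(5.97, 162.75))
#' module_mean_time(s, list(appointment = c("appointment", "show appointment")))
module_mean_time <- function(summaries, grouping = default_module_map()) {
  unknown <- setdiff(unlist(grouping), summaries$state)
  if (length(unknown)) {
    rlang::abort(paste0("Grouping refers to state(s) with no summary: ",
                        paste(unknown, collapse = ", ")))
  }
  purrr::imap(grouping, function(members, module) {
    tibble::tibble(
      module = module,
      mean_time = sum(round_half_up(
        summaries$mean_time[match(members, summaries$state)], 2
      ))
    )
  }) |>
    purrr::list_rbind()
}

#' Filter a transition model for display
#'
#' Reproduces the readability cutoffs used for the transition heatmap and
#' trail graph: keep real states whose relative visit quantity is at least
#' `quantity_cutoff` (a fraction, default 1%), and among retained states
#' (plus the pseudo-states) keep edges with transition probability at least
#' `tp_cutoff` (default 0.15). Both thresholds are inclusive.
#'
#' @param model A `transition_model`.
#' @param summaries Per-state summary from [summarize_states()].
#' @param quantity_cutoff Minimum relative quantity as a fraction in `[0, 1]`.
#' @param tp_cutoff Minimum transition probability in `[0, 1]`.
#' @return A list with `states` (retained real states) and `edges` (tibble
#'   `from`, `to`, `prob`, `count`).
#' @export
display_filter <- function(model, summaries, quantity_cutoff = 0.01,
                           tp_cutoff = 0.15) {
  stopifnot(inherits(model, "transition_model"))
  if (quantity_cutoff < 0 || quantity_cutoff > 1 ||
      tp_cutoff < 0 || tp_cutoff > 1) {
    rlang::abort("Cutoffs must lie in [0, 1].")
  }
  keep <- summaries$state[summaries$relative_quantity >= 100 * quantity_cutoff]
  keep <- intersect(model$space$states, keep)
  nodes <- c(model$space$start_state, keep, model$space$exit_state)
  edges <- tidy(model) |>
    dplyr::filter(.data$from %in% nodes, .data$to %in% nodes,
                  .data$prob >= tp_cutoff)
  list(states = keep, edges = edges)
}

#' Classify transitions as self, cycle, or one-way
#'
#' Self-transitions are edges `i -> i` (app-switch-and-return on the same
#' page). Between distinct states, an edge pair is a cycle transition when
#' both directions have probability at least `high`, and one-way when only
#' one direction does.
#'
#' @param model A `transition_model`.
#' @param high Probability threshold for a "high" edge (default 0.15, the
#'   display cutoff).
#' @return A tibble `from`, `to`, `prob`, `reverse_prob`, `type` with `type`
#'   in `self`, `cycle`, `one-way`; only edges with `prob >= high` are
#'   listed (cycles appear once per direction).
#' @export
classify_transitions <- function(model, high = 0.15) {
  stopifnot(inherits(model, "transition_model"))
  P <- model$probs
  real <- model$space$states
  ij <- which(P[real, real, drop = FALSE] >= high, arr.ind = TRUE)
  if (nrow(ij) == 0L) {
    return(tibble::tibble(from = character(), to = character(),
                          prob = double(), reverse_prob = double(),
                          type = character()))
  }
  tibble::tibble(
    from = real[ij[, 1]],
    to = real[ij[, 2]],
    prob = P[real, real][ij],
    reverse_prob = P[real, real][ij[, c(2, 1), drop = FALSE]]
  ) |>
    dplyr::mutate(
      type = dplyr::case_when(
        from == to ~ "self",
        reverse_prob >= high ~ "cycle",
        TRUE ~ "one-way"
      )
    ) |>
    dplyr::arrange(.data$from, .data$to)
}
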