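tiny_space <- state_space(c("A", "B"))

sessions_from_states <- function(state_lists) {
  purrr::imap(state_lists, function(states, i) {
    usage_from_gaps(rep(0, length(states) - 1), states = states,
                    t0 = (i - 1) * 10000)
  }) |>
    purrr::list_rbind() |>
    sessionize()
}

test_that("each session of m visits contributes m + 1 transitions", {
  s <- sessions_from_states(list("A"))
  N <- count_transitions(s, tiny_space)
  expect_equal(N["(start)", "A"], 1L)
  expect_equal(N["A", "(exit)"], 1L)
  expect_equal(sum(N), 2L)

  # manual enumeration over two sessions, incl. a self-transition
  s2 <- sessions_from_states(list(c("A", "B"), c("A", "A")))
  N2 <- count_transitions(s2, tiny_space)
  expect_equal(N2["A", "B"], 1L)
  expect_equal(N2["A", "A"], 1L)
  expect_equal(N2["A", "(exit)"], 1L)
  expect_equal(N2["(start)", "A"], 2L)
  expect_equal(sum(N2), 2L + 1L + 2L + 1L)  # sum over sessions of m + 1
})

test_that("transition conservation holds on a random cohort", {
  co <- small_cohort()
  s <- sessionize(co$usage)
  N <- count_transitions(s)
  n_sessions <- nrow(dplyr::distinct(s, patient_id, session))
  expect_equal(sum(N), nrow(s) + n_sessions)
  expect_equal(sum(N[, "(start)"]), 0L)   # nothing enters the start state
  expect_equal(sum(N["(exit)", ]), 0L)    # nothing leaves the exit state
})

test_that("row normalisation is the MLE and flags absorbing rows", {
  s <- sessions_from_states(list(c("A", "B"), c("A", "A")))
  m <- fit_markov(s, tiny_space)
  expect_equal(m$probs["A", c("A", "B", "(exit)")],
               c(A = 1 / 3, B = 1 / 3, "(exit)" = 1 / 3))
  expect_equal(m$probs["(start)", "A"], 1)
  expect_true("(exit)" %in% attr(m$probs, "absorbing"))
  expect_error(normalize_rows(matrix(-1, 1, 1)), "nonnegative")
})

test_that("non-absorbing rows of P sum to 1 within 1e-12", {
  co <- small_cohort()
  m <- fit_markov(sessionize(co$usage))
  absorbing <- attr(m$probs, "absorbing")
  live <- setdiff(rownames(m$probs), absorbing)
  expect_true(all(abs(rowSums(m$probs[live, ]) - 1) < 1e-12))
})

test_that("only the first-order chain is supported", {
  s <- sessions_from_states(list("A"))
  expect_error(fit_markov(s, tiny_space, order = 2), "first-order")
})

test_that("state summaries reproduce the published table arithmetic", {
  fx <- reference_visit_fixture()
  sm <- summarize_states(fx)
  ref <- reference_state_stats()
  expect_equal(sm$quantity[match(ref$state, sm$state)], ref$quantity)
  get <- function(col, state) sm[[col]][sm$state == state]
  expect_equal(round(get("relative_quantity", "main"), 2), 42.42)
  expect_equal(round(get("relative_quantity", "task BP"), 2), 16.54)
  expect_equal(round(get("mean_time", "task food"), 2), 35.87)
  expect_equal(round(get("mean_time", "knowledge content"), 2), 83.96)
  # relative quantities cover 100% and means recombine into totals
  expect_equal(sum(sm$relative_quantity), 100)
  expect_equal(sm$mean_time * sm$quantity, sm$total_time)
  # descending sort by the requested column
  expect_equal(sm$state[1], "main")
  expect_equal(summarize_states(fx, sort_by = "mean_time")$state[1],
               "show appointment")
})

test_that("single-visit summary is 100% with its own dwell", {
  sm <- summarize_states(tibble::tibble(patient_id = "p", state = "A",
                                        dwell = 10))
  expect_equal(sm$relative_quantity, 100)
  expect_equal(sm$mean_time, 10)
})

test_that("module aggregation sums member mean times", {
  sm <- summarize_states(reference_visit_fixture())
  mods <- module_mean_time(sm)
  get <- function(m) mods$mean_time[mods$module == m]
  expect_equal(get("health education"), 124.06)
  expect_equal(get("appointment"), 168.72)
  expect_equal(get("management plans"), 230.21)
  expect_equal(module_mean_time(sm, list(none = character()))$mean_time, 0)
  expect_error(module_mean_time(sm, list(bad = "no such page")),
               "no summary")
})

test_that("display filter matches a brute-force threshold scan", {
  withr::with_seed(5, {
    sp <- state_space(paste0("s", 1:10))
    sess <- sessions_from_states(
      purrr::map(1:300, ~ sample(sp$states, sample(1:6, 1), replace = TRUE))
    )
    m <- fit_markov(sess, sp)
    sm <- summarize_states(sess)
    fl <- display_filter(m, sm, quantity_cutoff = 0.05, tp_cutoff = 0.2)
    # oracle: exhaustive scan over the matrix
    keep <- sm$state[sm$relative_quantity >= 5]
    nodes <- c("(start)", keep, "(exit)")
    expected <- list()
    for (a in nodes) for (b in nodes) {
      if (m$counts[a, b] > 0 && m$probs[a, b] >= 0.2) {
        expected[[length(expected) + 1]] <- c(a, b)
      }
    }
    expect_setequal(sort(fl$states), sort(keep))
    got <- paste(fl$edges$from, fl$edges$to)
    expect_setequal(got, vapply(expected, paste, collapse = " ",
                                FUN.VALUE = character(1)))
  })
})

test_that("display filter boundaries are inclusive and cutoffs validated", {
  sess <- sessions_from_states(c(
    rep(list(c("A")), 991),           # A: 99.1% of visits
    rep(list(c("B")), 9)              # B: 0.9% -> excluded at 1%
  ))
  m <- fit_markov(sess, tiny_space)
  sm <- summarize_states(sess)
  fl <- display_filter(m, sm)
  expect_false("B" %in% fl$states)
  # start -> A has p = 0.991; exactly-at-threshold edge retained
  fl2 <- display_filter(m, sm, tp_cutoff = 0.991)
  expect_true(any(fl2$edges$from == "(start)" & fl2$edges$to == "A"))
  expect_error(display_filter(m, sm, quantity_cutoff = 1.5), "\\[0, 1\\]")
})

test_that("transition typing matches a brute-force scan", {
  withr::with_seed(9, {
    sp <- state_space(paste0("s", 1:6))
    sess <- sessions_from_states(
      purrr::map(1:200, ~ sample(sp$states, sample(1:5, 1), replace = TRUE))
    )
    m <- fit_markov(sess, sp)
    cl <- classify_transitions(m, high = 0.12)
    P <- m$probs
    for (r in seq_len(nrow(cl))) {
      i <- cl$from[r]; j <- cl$to[r]
      expected <- if (i == j) "self"
        else if (P[i, j] >= 0.12 && P[j, i] >= 0.12) "cycle"
        else "one-way"
      expect_equal(cl$type[r], expected)
    }
    # completeness: every above-threshold real-state pair is listed
    real <- sp$states
    n_above <- sum(P[real, real] >= 0.12)
    expect_equal(nrow(cl), n_above)
  })
})

test_that("tidy and glance expose the model as tibbles", {
  s <- sessions_from_states(list(c("A", "B"), c("A", "A")))
  m <- fit_markov(s, tiny_space)
  td <- tidy(m)
  expect_true(all(td$count > 0))
  expect_equal(sum(td$count), sum(m$counts))
  g <- glance(m)
  expect_equal(g$n_sessions, 2L)
  expect_equal(g$n_transitions, 6L)
})

test_that("heatmap and trail graph build deterministically", {
  co <- small_cohort()
  s <- sessionize(co$usage)
  m <- fit_markov(s)
  sm <- summarize_states(s)
  p1 <- ggplot2::ggplot_build(autoplot(m))
  p2 <- ggplot2::ggplot_build(autoplot(m))
  expect_equal(p1$data, p2$data)
  # blank cells exactly where transitions were never observed
  expect_equal(nrow(p1$data[[1]]), sum(m$counts > 0))
  fl <- display_filter(m, sm)
  g1 <- ggplot2::ggplot_build(plot_trail_graph(fl, sm))
  g2 <- ggplot2::ggplot_build(plot_trail_graph(fl, sm))
  expect_equal(g1$data, g2$data)
})
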