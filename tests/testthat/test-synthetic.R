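test_that("config validation rejects malformed inputs", {
  expect_error(
    synth_config(n_patients = 2, mixtures = rbind(c(0.5, 0.5, 0.5, 0.5)),
                 demo_params = default_demo_params()[1]),
    "sum to 1"
  )
  expect_error(synth_config(n_patients = c(10, 10)), "agree")
  bad_dwell <- default_dwell_means()
  bad_dwell["main"] <- -1
  expect_error(synth_config(dwell_means = bad_dwell), "positive")
})

test_that("planted matrices are row-stochastic and hit the target mixtures", {
  cfg <- synth_config(n_patients = c(2, 2, 2))
  for (i in 1:3) {
    P <- cfg$matrices[[i]]
    live <- rownames(P)[rowSums(P) > 0]
    expect_true(all(abs(rowSums(P[live, ]) - 1) < 1e-9))
    expect_equal(sum(P[, "(start)"]), 0)            # start has no inflow
    expect_equal(sum(P["(exit)", ]), 0)             # exit absorbs
    f <- trailmark:::trail_fractions(P, cfg$space, cfg$trail_map)
    expect_equal(unname(f), unname(cfg$mixtures[i, ]), tolerance = 1e-3)
  }
})

test_that("generated logs satisfy the data-model invariants", {
  co <- small_cohort()
  expect_true(all(co$usage$exit_time >= co$usage$enter_time))
  expect_true(all(co$usage$state %in% app_states()))
  expect_true(all(co$physio$sbp > co$physio$dbp))
  expect_true(all(co$physio$dbp > 0 & co$physio$hr > 0))
  expect_setequal(co$demographics$patient_id, unique(co$usage$patient_id))
  expect_equal(nrow(co$truth), 52)
  # within a patient, visits never overlap and sessions are separated by
  # more than the 600 s threshold
  s <- sessionize(co$usage)
  gaps <- co$usage |>
    dplyr::arrange(patient_id, enter_time) |>
    dplyr::group_by(patient_id) |>
    dplyr::mutate(gap = as.numeric(enter_time - dplyr::lag(exit_time),
                                   units = "secs")) |>
    dplyr::filter(!is.na(gap))
  expect_true(all(gaps$gap == 0 | gaps$gap > 600))
})

test_that("simulation is deterministic given the seed", {
  cfg <- synth_config(n_patients = c(4, 3, 2),
                      sessions_per_patient = list(mu = 6, size = 3))
  a <- simulate_cohort(cfg, seed = 99)
  b <- simulate_cohort(cfg, seed = 99)
  c <- simulate_cohort(cfg, seed = 100)
  expect_identical(a$usage, b$usage)
  expect_identical(a$physio, b$physio)
  expect_false(identical(a$usage, c$usage))
})

test_that("an absorbing main state collapses every session to one visit", {
  cfg <- synth_config(n_patients = c(3, 2, 2),
                      sessions_per_patient = list(mu = 4, size = 3))
  P <- cfg$matrices[[1]]
  P[, ] <- 0
  P["(start)", "main"] <- 1
  P["main", "(exit)"] <- 1
  cfg$matrices[[1]] <- P
  pat <- simulate_patient(cfg, subpopulation = 1, seed = 5)
  expect_true(all(pat$usage$state == "main"))
  s <- sessionize(pat$usage)
  expect_true(all(session_stats(s)$visits_per_session == 1))
})

test_that("per-trail visit fractions converge to the planted mixtures", {
  cfg <- synth_config(
    n_patients = c(40, 2, 2),
    sessions_per_patient = list(mu = 80, size = 5)
  )
  co <- simulate_cohort(cfg, seed = 8)
  pf <- preference_features(co$usage)
  sub1 <- pf[pf$patient_id %in%
               co$truth$patient_id[co$truth$subpopulation == "PT-T"], ]
  observed <- colMeans(sub1[, c("pt_t", "ro_t", "kl_t", "sa_t")])
  expect_equal(unname(observed), unname(cfg$mixtures[1, ]),
               tolerance = 0.05)
})

test_that("cohorts round-trip through write_cohort and the readers", {
  co <- small_cohort()
  dir <- withr::local_tempdir()
  write_cohort(co, dir)
  expect_true(all(file.exists(file.path(
    dir, c("usage_log.csv", "demographics.csv", "physio.csv", "truth.csv")))))
  back <- read_usage_log(file.path(dir, "usage_log.csv"))
  expect_equal(nrow(back), nrow(co$usage))
})
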