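test_that("profiles compute means and ages with a recount oracle", {
  co <- small_cohort()
  pr <- build_profiles(co$demographics, co$physio, co$usage)
  expect_equal(nrow(pr), nrow(co$demographics))
  # recount a patient by hand
  pid <- pr$patient_id[1]
  mine <- co$physio[co$physio$patient_id == pid, ]
  expect_equal(pr$mean_sbp[pr$patient_id == pid], mean(mine$sbp))
  expect_equal(pr$n_readings[pr$patient_id == pid], nrow(mine))
  # planted ages are clamped to the 18-80 inclusion window; recomputation
  # against calendar years may drift by a few days
  expect_true(all(pr$age >= 17.9 & pr$age <= 80.6))

  # a two-reading toy patient and one with no readings
  demo <- tibble::tibble(patient_id = c("a", "b"),
                         date_of_birth = as.Date("1970-01-01"),
                         gender = factor("male", c("male", "female")),
                         education = factor("high school",
                                            c("below high school",
                                              "high school",
                                              "university and above",
                                              "don't know")))
  phys <- tibble::tibble(patient_id = "a", sbp = c(130, 140),
                         dbp = c(80, 90), hr = c(70, 72),
                         upload_time = epoch(c(0, 10)))
  usage <- tibble::tibble(patient_id = c("a", "b"), state = "main",
                          enter_time = epoch(0), exit_time = epoch(10))
  pr2 <- build_profiles(demo, phys, usage)
  expect_equal(pr2$mean_sbp[1], 135)
  expect_true(pr2$missing_physio[2])
  expect_true(is.na(pr2$mean_sbp[2]))
})

test_that("chi-square equals the hand-computed Pearson statistic", {
  m <- rbind(c(30, 10), c(20, 40))
  got <- chisq_association(m)
  # formula oracle: sum over cells of (O - E)^2 / E
  E <- outer(rowSums(m), colSums(m)) / sum(m)
  expect_equal(got$statistic, sum((m - E)^2 / E), tolerance = 1e-12)
  expect_equal(got$df, 1)

  # perfectly proportional table: statistic 0, P = 1
  prop <- rbind(c(10, 20), c(20, 40))
  res <- chisq_association(prop)
  expect_equal(res$statistic, 0)
  expect_equal(res$p.value, 1)

  expect_error(chisq_association(rbind(c(0, 0), c(1, 2))), "all-zero")
  expect_error(chisq_association(matrix(1, 1, 2)), "at least 2")
})

test_that("observed gender contingency gives P rounding to .003", {
  res <- chisq_association(rbind(c(469, 225), c(48, 48), c(49, 24)))
  expect_equal(round(res$p.value, 3), 0.003)
})

test_that("pairwise z-tests match the pooled-variance formula", {
  m <- rbind(g1 = c(30, 70), g2 = c(50, 50))
  got <- pairwise_prop_ztests(m)
  first <- got[got$category == "1", ]
  p1 <- 0.3; p2 <- 0.5; pool <- 80 / 200
  z <- (p1 - p2) / sqrt(pool * (1 - pool) * (1 / 100 + 1 / 100))
  expect_equal(first$z, z, tolerance = 1e-12)
  expect_equal(first$p.value, 2 * pnorm(-abs(z)), tolerance = 1e-12)
  # cross-check: pooled z^2 equals the uncorrected 2x2 chi-square
  expect_equal(z^2, unname(chisq.test(m, correct = FALSE)$statistic),
               tolerance = 1e-12)

  same <- pairwise_prop_ztests(rbind(c(10, 10), c(20, 20)))
  expect_equal(same$z, c(0, 0))
  expect_equal(same$p.value, c(1, 1))
})

test_that("observed male-proportion difference between the large clusters is flagged", {
  gender <- rbind("PT-T" = c(469, 225), "PT-T+KL-T" = c(48, 48),
                  "PT-T+SA-T" = c(49, 24))
  res <- pairwise_prop_ztests(gender)
  male <- res[res$category == "1", ]
  flag <- male$significant[male$cluster_a == "PT-T" &
                           male$cluster_b == "PT-T+KL-T"]
  expect_true(flag)
})

test_that("zero-denominator pairs are skipped with a note", {
  m <- rbind(c(0, 0), c(5, 5))
  res <- pairwise_prop_ztests(m)
  expect_true(all(res$note == "zero denominator"))
  expect_false(any(res$significant))
})

test_that("two-group ANOVA F equals the pooled t statistic squared", {
  withr::with_seed(2, {
    x <- c(rnorm(20), rnorm(25, 1))
    g <- rep(c("a", "b"), c(20, 25))
  })
  res <- anova_bonferroni(x, g)
  tt <- t.test(x ~ g, var.equal = TRUE)
  expect_equal(res$omnibus$statistic, unname(tt$statistic)^2,
               tolerance = 1e-12)
  expect_equal(res$omnibus$p.value, tt$p.value, tolerance = 1e-12)
})

test_that("equal groups give F near 0 and no post-hoc flags", {
  withr::with_seed(3, {
    x <- rep(c(5, 6, 7), times = 3) + rnorm(9, 0, 1e-8)
    g <- rep(c("a", "b", "c"), each = 3)
  })
  res <- anova_bonferroni(x, g)
  expect_lt(res$omnibus$statistic, 1e-6)
  expect_equal(nrow(res$pairwise), 0L)
  expect_error(anova_bonferroni(1:3, c("a", "a", "b")), "at least 2")
})

test_that("planted DBP differences reproduce the observed flag pattern", {
  # subpopulation DBP means 86.46 / 90.60 / 84.87, SDs ~11-13,
  # sizes 694 / 96 / 73: omnibus significant; the middle cluster differs
  # from the large one
  withr::with_seed(14, {
    g <- rep(c("PT-T", "PT-T+KL-T", "PT-T+SA-T"), c(694, 96, 73))
    x <- c(rnorm(694, 86.46, 11.37), rnorm(96, 90.60, 12.88),
           rnorm(73, 84.87, 11.29))
  })
  res <- anova_bonferroni(x, g)
  expect_lte(res$omnibus$p.value, 0.05)
  pair <- res$pairwise[
    (res$pairwise$cluster_a == "PT-T+KL-T" &
       res$pairwise$cluster_b == "PT-T") |
    (res$pairwise$cluster_a == "PT-T" &
       res$pairwise$cluster_b == "PT-T+KL-T"), ]
  expect_true(any(pair$significant))
})

test_that("the cluster report assembles descriptives and tests", {
  co <- small_cohort()
  s <- sessionize(co$usage)
  pf <- preference_features(s)
  sol <- cluster_preferences(pf, k_range = 2:5, seed = 2)
  pr <- build_profiles(co$demographics, co$physio, co$usage)
  rep <- characterize_clusters(pr, sol$assignments)
  # sizes echo the clustering
  expect_equal(sort(rep$sizes$n), sort(sol$sizes))
  # percentage columns sum to 100 within each cluster and variable
  pct <- rep$descriptives |>
    dplyr::filter(!is.na(level)) |>
    dplyr::group_by(variable, cluster) |>
    dplyr::summarise(total = sum(pct), .groups = "drop")
  expect_equal(pct$total, rep(100, nrow(pct)))
  expect_true(all(rep$tests$p.value >= 0 & rep$tests$p.value <= 1))
  # post-hoc rows only for variables whose omnibus is significant
  if (!is.null(rep$pairwise) && nrow(rep$pairwise)) {
    sig_vars <- rep$tests$variable[rep$tests$p.value <= rep$alpha]
    expect_true(all(rep$pairwise$variable %in% sig_vars))
  }
  expect_output(print(rep), "Cluster characterization")
  expect_equal(glance(rep)$n_patients, sum(sol$sizes))
})

test_that("single-cluster input yields descriptives only", {
  co <- small_cohort()
  pr <- build_profiles(co$demographics, co$physio, co$usage)
  one <- tibble::tibble(patient_id = pr$patient_id, cluster = 1L)
  rep <- characterize_clusters(pr, one)
  expect_null(rep$tests)
  expect_gt(nrow(rep$descriptives), 0)
})
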