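#' Build per-patient profiles from demographics, physiology, and usage
#'
#' Age is computed in years at the patient's first usage record (the
#' earliest `enter_time`), which fixes a deterministic reference date.
#' Blood-pressure and heart-rate summaries are unweighted per-patient means
#' over all uploaded readings; patients with no readings are kept with
#' `missing_physio = TRUE` and `NA` means, and are excluded pairwise from
#' the continuous-variable tests downstream.
#'
#' @param demographics Tibble from [read_demographics()].
#' @param physio Tibble from [read_physio()].
#' @param usage Usage-log tibble (for the first-visit reference date).
#' @return A tibble with one row per patient in `demographics`: `age`,
#'   `gender`, `education`, `mean_sbp`, `mean_dbp`, `mean_hr`, `n_readings`,
#'   `missing_physio`.
#' @export
build_profiles <- function(demographics, physio, usage) {
  first_use <- usage |>
    dplyr::group_by(.data$patient_id) |>
    dplyr::summarise(first_use = min(.data$enter_time), .groups = "drop")
  phys <- physio |>
    dplyr::group_by(.data$patient_id) |>
    dplyr::summarise(
      mean_sbp = mean(.data$sbp),
      mean_dbp = mean(.data$dbp),
      mean_hr = mean(.data$hr),
      n_readings = dplyr::n(),
      .groups = "drop"
    )
  demographics |>
    dplyr::left_join(first_use, by = "patient_id") |>
    dplyr::left_join(phys, by = "patient_id") |>
    dplyr::mutate(
      age = lubridate::time_length(
        lubridate::interval(.data$date_of_birth,
                            as.Date(.data$first_use)), "years"),
      n_readings = dplyr::coalesce(.data$n_readings, 0L),
      missing_physio = .data$n_readings == 0L
    ) |>
    dplyr::select("patient_id", "age", "gender", "education",
                  "mean_sbp", "mean_dbp", "mean_hr",
                  "n_readings", "missing_physio")
}

#' Chi-square test of association between clusters and a discrete variable
#'
#' Pearson chi-square (no continuity correction) on a clusters-by-category
#' contingency table, with `(r - 1)(c - 1)` degrees of freedom.
#'
#' @param contingency A nonnegative integer matrix or table, clusters in
#'   rows, categories in columns; at least 2 rows and 2 columns with
#'   positive margins.
#' @return A one-row tibble: `statistic`, `df`, `p.value`, `method`.
#' @export
#' @examples
#' chisq_association(rbind(c(469, 225), c(48, 48), c(49, 24)))
chisq_association <- function(contingency) {
  m <- as.matrix(contingency)
  if (nrow(m) < 2 || ncol(m) < 2) {
    rlang::abort("Contingency table needs at least 2 rows and 2 columns.")
  }
  if (any(m < 0)) rlang::abort("Counts must be nonnegative.")
  if (any(rowSums(m) == 0) || any(colSums(m) == 0)) {
    rlang::abort("Contingency table has an all-zero row or column.")
  }
  ct <- suppressWarnings(stats::chisq.test(m, correct = FALSE))
  tibble::tibble(
    statistic = unname(ct$statistic),
    df = unname(ct$parameter),
    p.value = ct$p.value,
    method = "Pearson chi-square"
  )
}

#' Pairwise two-proportion z-tests between clusters
#'
#' For every pair of clusters and every category, the pooled two-proportion
#' z-test compares the category's proportion between the two clusters:
#' `z = (p1 - p2) / sqrt(p(1 - p)(1/n1 + 1/n2))` with `p` the pooled
#' proportion. P values are two-sided and Bonferroni-adjusted within each
#' category across the cluster pairs. Pairs with a zero denominator are
#' skipped with a note column.
#'
#' @inheritParams chisq_association
#' @param alpha Significance level for the `significant` flag (default .05).
#' @param adjust Multiplicity adjustment method (default `"bonferroni"`).
#' @return A tibble with one row per (category, cluster pair): proportions,
#'   `z`, `p.value`, `p.adjusted`, `significant`.
#' @export
pairwise_prop_ztests <- function(contingency, alpha = 0.05,
                                 adjust = "bonferroni") {
  m <- as.matrix(contingency)
  if (is.null(rownames(m))) rownames(m) <- seq_len(nrow(m))
  if (is.null(colnames(m))) colnames(m) <- seq_len(ncol(m))
  n <- rowSums(m)
  pairs <- utils::combn(nrow(m), 2)
  out <- purrr::map(seq_len(ncol(m)), function(cat) {
    purrr::map(seq_len(ncol(pairs)), function(p) {
      i <- pairs[1, p]; j <- pairs[2, p]
      if (n[i] == 0 || n[j] == 0) {
        return(tibble::tibble(
          category = colnames(m)[cat],
          cluster_a = rownames(m)[i], cluster_b = rownames(m)[j],
          prop_a = NA_real_, prop_b = NA_real_, z = NA_real_,
          p.value = NA_real_, note = "zero denominator"
        ))
      }
      p1 <- unname(m[i, cat] / n[i]); p2 <- unname(m[j, cat] / n[j])
      pool <- unname((m[i, cat] + m[j, cat]) / (n[i] + n[j]))
      se <- sqrt(pool * (1 - pool) * (1 / n[i] + 1 / n[j]))
      z <- unname(if (se == 0) 0 else (p1 - p2) / se)
      tibble::tibble(
        category = colnames(m)[cat],
        cluster_a = rownames(m)[i], cluster_b = rownames(m)[j],
        prop_a = p1, prop_b = p2, z = z,
        p.value = 2 * stats::pnorm(-abs(z)), note = NA_character_
      )
    }) |> purrr::list_rbind()
  }) |> purrr::list_rbind()
  out |>
    dplyr::group_by(.data$category) |>
    dplyr::mutate(p.adjusted = stats::p.adjust(.data$p.value,
                                               method = adjust)) |>
    dplyr::ungroup() |>
    dplyr::mutate(significant = !is.na(.data$p.adjusted) &
                    .data$p.adjusted <= alpha)
}

#' One-way ANOVA with Bonferroni pairwise comparisons
#'
#' Omnibus one-way ANOVA of a continuous variable across clusters. When the
#' omnibus P value is at or below `alpha`, all pairwise mean comparisons are
#' computed as pooled-SD t tests with Bonferroni adjustment (the SPSS-style
#' post hoc); otherwise the pairwise table is returned empty.
#'
#' @param values Numeric vector (NAs dropped pairwise with their group).
#' @param groups Vector of cluster labels, same length as `values`.
#' @param alpha Gate for post-hoc comparisons (default .05).
#' @return A list with `omnibus` (one-row tibble `statistic`, `df1`, `df2`,
#'   `p.value`) and `pairwise` (tibble `cluster_a`, `cluster_b`,
#'   `mean_a`, `mean_b`, `p.adjusted`, `significant`).
#' @export
anova_bonferroni <- function(values, groups, alpha = 0.05) {
  keep <- !is.na(values) & !is.na(groups)
  values <- values[keep]
  groups <- factor(groups[keep])
  tab <- table(groups)
  if (length(tab) < 2 || any(tab < 2)) {
    rlang::abort("ANOVA needs at least 2 groups with at least 2 observations each.")
  }
  fit <- stats::aov(values ~ groups)
  an <- stats::anova(fit)
  omnibus <- tibble::tibble(
    statistic = an[1, "F value"],
    df1 = an[1, "Df"], df2 = an[2, "Df"],
    p.value = an[1, "Pr(>F)"]
  )
  empty_pw <- tibble::tibble(
    cluster_a = character(), cluster_b = character(),
    mean_a = double(), mean_b = double(),
    p.adjusted = double(), significant = logical()
  )
  if (is.na(omnibus$p.value) || omnibus$p.value > alpha) {
    return(list(omnibus = omnibus, pairwise = empty_pw))
  }
  pt <- stats::pairwise.t.test(values, groups, p.adjust.method = "bonferroni",
                               pool.sd = TRUE)
  means <- tapply(values, groups, mean)
  pw <- as.data.frame(as.table(pt$p.value), stringsAsFactors = FALSE)
  names(pw) <- c("cluster_a", "cluster_b", "p.adjusted")
  pw <- pw[!is.na(pw$p.adjusted), , drop = FALSE]
  pairwise <- tibble::as_tibble(pw) |>
    dplyr::mutate(
      mean_a = as.numeric(means[.data$cluster_a]),
      mean_b = as.numeric(means[.data$cluster_b]),
      significant = .data$p.adjusted <= alpha
    ) |>
    dplyr::select("cluster_a", "cluster_b", "mean_a", "mean_b",
                  "p.adjusted", "significant")
  list(omnibus = omnibus, pairwise = pairwise)
}

#' Characterize behavior-preference clusters
#'
#' Produces the descriptive-and-inferential comparison of clusters:
#' counts and percentages with a chi-square test and pairwise pooled
#' z-tests for the discrete variables (gender, education), and mean (SD)
#' with one-way ANOVA plus Bonferroni pairwise comparisons for the
#' continuous variables (age, SBP, DBP, HR). Post-hoc comparisons are only
#' reported when the omnibus test is significant at `alpha`.
#'
#' The education category `"don't know"` is kept in the descriptives but
#' excluded from the chi-square by default (its expected counts are tiny);
#' set `education_exclude = character()` to include it.
#'
#' @param profiles Per-patient profiles from [build_profiles()].
#' @param assignments Tibble `patient_id`, `cluster` (e.g.
#'   `tidy(cluster_solution)`).
#' @param alpha Significance level (default .05).
#' @param education_exclude Education levels dropped from the chi-square
#'   (default `"don't know"`).
#' @return An object of class `cluster_report`: list with `descriptives`
#'   (long tibble), `tests` (per-variable omnibus results), `pairwise`
#'   (post-hoc flags), `sizes`, `alpha`. With a single cluster only the
#'   descriptives are filled.
#' @export
characterize_clusters <- function(profiles, assignments, alpha = 0.05,
                                  education_exclude = "don't know") {
  dat <- dplyr::inner_join(profiles, assignments, by = "patient_id") |>
    dplyr::mutate(cluster = as.character(.data$cluster))
  if (nrow(dat) == 0L) rlang::abort("No clustered patients with profiles.")
  clusters <- sort(unique(dat$cluster))
  sizes <- dat |> dplyr::count(.data$cluster, name = "n")

  discrete_vars <- c("gender", "education")
  continuous_vars <- c(age = "age", SBP = "mean_sbp", DBP = "mean_dbp",
                       HR = "mean_hr")

  desc_disc <- purrr::map(discrete_vars, function(v) {
    dat |>
      dplyr::filter(!is.na(.data[[v]])) |>
      dplyr::count(.data$cluster, level = .data[[v]], .drop = FALSE) |>
      dplyr::group_by(.data$cluster) |>
      dplyr::mutate(pct = 100 * .data$n / sum(.data$n)) |>
      dplyr::ungroup() |>
      dplyr::mutate(variable = v, level = as.character(.data$level))
  }) |> purrr::list_rbind()
  desc_cont <- purrr::map(names(continuous_vars), function(nm) {
    v <- continuous_vars[[nm]]
    dat |>
      dplyr::group_by(.data$cluster) |>
      dplyr::summarise(mean = mean(.data[[v]], na.rm = TRUE),
                       sd = stats::sd(.data[[v]], na.rm = TRUE),
                       n = sum(!is.na(.data[[v]])), .groups = "drop") |>
      dplyr::mutate(variable = nm, level = NA_character_)
  }) |> purrr::list_rbind()
  descriptives <- dplyr::bind_rows(desc_disc, desc_cont)

  tests <- NULL
  pairwise <- NULL
  if (length(clusters) >= 2) {
    disc_res <- purrr::map(discrete_vars, function(v) {
      x <- dat |> dplyr::filter(!is.na(.data[[v]]))
      if (v == "education" && length(education_exclude)) {
        x <- dplyr::filter(x, !.data[[v]] %in% education_exclude)
      }
      tab <- table(x$cluster, droplevels(factor(x[[v]])))
      omni <- chisq_association(tab)
      pw <- pairwise_prop_ztests(tab, alpha = alpha)
      if (omni$p.value > alpha) pw <- pw[0, ]
      list(
        test = dplyr::mutate(omni, variable = v, .before = 1),
        pairwise = dplyr::mutate(pw, variable = v, .before = 1)
      )
    })
    cont_res <- purrr::map(names(continuous_vars), function(nm) {
      v <- continuous_vars[[nm]]
      res <- anova_bonferroni(dat[[v]], dat$cluster, alpha = alpha)
      list(
        test = tibble::tibble(
          variable = nm, statistic = res$omnibus$statistic,
          df = res$omnibus$df1, p.value = res$omnibus$p.value,
          method = "one-way ANOVA"
        ),
        pairwise = dplyr::mutate(res$pairwise, variable = nm, .before = 1)
      )
    })
    all_res <- c(disc_res, cont_res)
    tests <- purrr::list_rbind(purrr::map(all_res, "test"))
    pairwise <- purrr::list_rbind(purrr::map(all_res, "pairwise"))
  }

  structure(
    list(descriptives = descriptives, tests = tests, pairwise = pairwise,
         sizes = sizes, alpha = alpha),
    class = "cluster_report"
  )
}

#' @export
print.cluster_report <- function(x, digits = 2, ...) {
  cat("Cluster characterization (alpha =", x$alpha, ")\n")
  cat("Cluster sizes:",
      paste(x$sizes$cluster, "=", x$sizes$n, collapse = ", "), "\n\n")
  disc <- dplyr::filter(x$descriptives, !is.na(.data$level))
  if (nrow(disc)) {
    wide <- disc |>
      dplyr::mutate(cell = sprintf("%d (%.2f)", .data$n, .data$pct)) |>
      dplyr::select("variable", "level", "cluster", "cell") |>
      tidyr::pivot_wider(names_from = "cluster", values_from = "cell")
    print(as.data.frame(wide), row.names = FALSE)
    cat("\n")
  }
  cont <- dplyr::filter(x$descriptives, is.na(.data$level))
  if (nrow(cont)) {
    wide <- cont |>
      dplyr::mutate(cell = sprintf("%.2f (%.2f)", .data$mean, .data$sd)) |>
      dplyr::select("variable", "cluster", "cell") |>
      tidyr::pivot_wider(names_from = "cluster", values_from = "cell")
    print(as.data.frame(wide), row.names = FALSE)
    cat("\n")
  }
  if (!is.null(x$tests)) {
    cat("Omnibus tests:\n")
    print(as.data.frame(
      dplyr::mutate(x$tests,
                    p.value = signif(.data$p.value, 3),
                    statistic = round(.data$statistic, digits))
    ), row.names = FALSE)
    sig <- dplyr::filter(x$pairwise, .data$significant)
    if (nrow(sig)) {
      cat("\nSignificant pairwise differences (adjusted P <=", x$alpha, "):\n")
      print(as.data.frame(sig), row.names = FALSE)
    }
  }
  invisible(x)
}

#' @describeIn characterize_clusters Omnibus test results as a tibble.
#' @param x A `cluster_report`.
#' @param ... Unused.
#' @method tidy cluster_report
#' @export
tidy.cluster_report <- function(x, ...) {
  if (is.null(x$tests)) return(tibble::tibble())
  x$tests
}

#' @describeIn characterize_clusters One-row summary.
#' @method glance cluster_report
#' @export
glance.cluster_report <- function(x, ...) {
  tibble::tibble(
    n_clusters = nrow(x$sizes),
    n_patients = sum(x$sizes$n),
    n_significant = if (is.null(x$tests)) 0L
                    else sum(x$tests$p.value <= x$alpha)
  )
}
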