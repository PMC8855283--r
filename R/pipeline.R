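#' Run the full engagement-trail analysis pipeline
#'
#' Chains the stages end to end: read (or accept) the three input tables,
#' sessionize the usage log, fit the first-order Markov chain, summarise
#' states, apply the display filter, compute preference vectors, cluster
#' patients with the silhouette scan, and characterize the clusters. All
#' stage outputs are written to `outdir` along with a manifest recording
#' the package version, seed, and parameters. Fully deterministic given the
#' inputs and `seed`.
#'
#' @param usage,demographics,physio Paths to the three CSV inputs, or
#'   already-read tibbles. `demographics`/`physio` may be `NULL`, in which
#'   case the characterization stage is skipped.
#' @param outdir Output directory (created if needed).
#' @param gap Session inactivity threshold in seconds (default 600).
#' @param quantity_cutoff,tp_cutoff Display-filter thresholds (defaults
#'   0.01 and 0.15).
#' @param k_range Candidate cluster counts (default `2:9`).
#' @param seed Seed for clustering initialisation.
#' @param n_restarts K-means restarts.
#' @param trail_map State-to-trail mapping.
#' @param space State space for the Markov model.
#' @param figures Write PNG figures (default TRUE).
#' @return Invisibly, a list with all intermediate results: `sessions`,
#'   `model`, `summaries`, `filtered`, `preferences`, `solution`, `report`
#'   (or `NULL`), and `manifest`.
#' @export
run_pipeline <- function(usage, demographics = NULL, physio = NULL,
                         outdir, gap = 600, quantity_cutoff = 0.01,
                         tp_cutoff = 0.15, k_range = 2:9, seed = 1,
                         n_restarts = 10, trail_map = default_trail_map(),
                         space = state_space(), figures = TRUE) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      rlang::abort(paste0("Pipeline stage '", name, "' failed: ",
                          conditionMessage(e)))
    })
  }
  usage <- stage("read usage", {
    if (is.character(usage)) read_usage_log(usage, space) else usage
  })
  demographics <- stage("read demographics", {
    if (is.character(demographics)) read_demographics(demographics)
    else demographics
  })
  physio <- stage("read physio", {
    if (is.character(physio)) read_physio(physio) else physio
  })

  sessions <- stage("sessionize", sessionize(usage, gap = gap))
  readr::write_csv(
    dplyr::select(sessions, "patient_id", "session", "position", "state",
                  "enter_time", "exit_time", "dwell"),
    file.path(outdir, "sessions.csv"))

  model <- stage("markov", fit_markov(sessions, space))
  write_matrix <- function(m, path) {
    readr::write_tsv(
      tibble::as_tibble(as.data.frame(m), rownames = "state"), path)
  }
  write_matrix(model$counts, file.path(outdir, "transition_counts.tsv"))
  write_matrix(model$probs, file.path(outdir, "transition_probs.tsv"))

  summaries <- stage("summarize", summarize_states(sessions))
  readr::write_tsv(
    dplyr::transmute(summaries, .data$state, .data$quantity,
                     relative_quantity_pct = round_half_up(
                       .data$relative_quantity, 2),
                     total_time_s = .data$total_time,
                     mean_time_s = round_half_up(.data$mean_time, 2)),
    file.path(outdir, "state_summary.tsv"))

  filtered <- stage("display filter",
                    display_filter(model, summaries, quantity_cutoff,
                                   tp_cutoff))
  readr::write_csv(filtered$edges, file.path(outdir, "filtered_edges.csv"))

  preferences <- stage("preferences", preference_features(sessions, trail_map))
  write_preferences(preferences, file.path(outdir, "preferences.csv"))

  solution <- stage("cluster",
                    cluster_preferences(preferences, k_range = k_range,
                                        seed = seed,
                                        n_restarts = n_restarts))
  readr::write_csv(solution$assignments, file.path(outdir, "clusters.csv"))
  readr::write_csv(solution$silhouette_by_k,
                   file.path(outdir, "silhouette.csv"))
  readr::write_csv(solution$centroids, file.path(outdir, "centroids.csv"))

  report <- NULL
  if (!is.null(demographics) && !is.null(physio)) {
    report <- stage("characterize", {
      profiles <- build_profiles(demographics, physio, usage)
      characterize_clusters(profiles, solution$assignments)
    })
    readr::write_csv(report$descriptives,
                     file.path(outdir, "cluster_descriptives.csv"))
    if (!is.null(report$tests)) {
      readr::write_csv(report$tests, file.path(outdir, "cluster_tests.csv"))
      readr::write_csv(report$pairwise,
                       file.path(outdir, "cluster_pairwise.csv"))
    }
  }

  if (isTRUE(figures)) {
    stage("figures", {
      render_heatmap(model, file.path(outdir, "transition_heatmap.png"))
      render_trail_graph(filtered, summaries,
                         file.path(outdir, "trail_graph.png"),
                         trail_map = trail_map)
      ggplot2::ggsave(file.path(outdir, "silhouette.png"),
                      autoplot(solution), width = 5, height = 4, dpi = 150)
    })
  }

  params <- list(gap = gap, quantity_cutoff = quantity_cutoff,
                 tp_cutoff = tp_cutoff, k_range = as.integer(k_range),
                 seed = as.integer(seed), n_restarts = as.integer(n_restarts))
  manifest <- list(
    package = "trailmark",
    version = as.character(utils::packageVersion("trailmark")),
    seed = as.integer(seed),
    params = params,
    config_hash = rlang::hash(params),
    n_patients = dplyr::n_distinct(usage$patient_id),
    n_records = nrow(usage),
    n_sessions = model$n_sessions,
    chosen_k = solution$k
  )
  jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(list(sessions = sessions, model = model, summaries = summaries,
                 filtered = filtered, preferences = preferences,
                 solution = solution, report = report, manifest = manifest))
}
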