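Package: trailmark
Title: Markov-Chain Engagement Trails from mHealth Usage Logs
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for page-visit logs from pathway-based mobile
    health (mHealth) self-management apps, developed around hypertension
    self-management. Splits per-patient visit streams into sessions with an
    inactivity-gap rule, estimates a first-order Markov chain over the app's
    behavioral states (transition counts and row-stochastic probabilities),
    summarises per-state visit quantity and dwell time, maps states to
    engagement trails (perform-task, result-oriented, knowledge-learning,
    support-acquisition) to obtain normalized per-patient behavior-preference
    vectors, clusters patients with k-means selecting the number of clusters
    by silhouette score, and characterizes clusters with chi-square tests,
    pairwise proportion z-tests, and one-way ANOVA with Bonferroni multiple
    comparisons. Includes a synthetic cohort generator (Markov-walk usage
    logs, demographics, blood-pressure records) so the whole pipeline is
    testable without patient data.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    cluster,
    dplyr,
    generics,
    ggplot2,
    igraph,
    jsonlite,
    lubridate,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    mclust,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
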