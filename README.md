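# trailmark

Markov-chain engagement trails from mHealth usage logs.

Patients managing a chronic condition such as hypertension interact with a
pathway-based mobile-health app through many small behaviors — recording a
blood pressure, reading health-education content, checking a ranking,
booking an appointment — each represented by a page of the app (a
*behavioral state*). `trailmark` turns raw page-visit logs into a
longitudinal picture of that behavior, for digital-health researchers who
want to know *what patients actually do* during self-management and which
patient groups prefer which behaviors.

## The model

The pipeline has four statistical stages:

1. **Sessionization.** Each patient's visit stream is split into sessions
   wherever the idle time between consecutive visits exceeds 600 s
   (strictly greater; the boundary stays in-session). Every session is
   bracketed by start and exit pseudo-states `s0` and `s(n+1)`.

2. **First-order Markov chain.** With state space `S = {s1, ..., sn}` (the
   28 app pages) plus the pseudo-states, transitions are counted over all
   sessions and the transition probability is the maximum-likelihood
   estimate

   ```
   p_ij = N_ij / sum_j N_ij
   ```

   where `N_ij` is the number of observed transitions `si -> sj`. Rows of
   the resulting matrix `P` are stochastic; the exit state is absorbing.
   Per-state visit quantities and dwell times, display cutoffs (1% relative
   quantity, 0.15 transition probability), and the self / cycle / one-way
   transition typology are derived from `N` and `P`.

3. **Behavior preferences and clustering.** States map to four engagement
   trails — perform task (PT-T), result oriented (RO-T), knowledge learning
   (KL-T), support acquisition (SA-T) — and each patient's trail-wise visit
   counts, normalised to sum to 1, form a 4-component preference vector.
   K-means (Euclidean distance, k-means++ restarts) clusters the vectors;
   the number of clusters is chosen by the maximum mean silhouette score
   over k = 2..9.

4. **Cluster characterization.** Chi-square tests with pairwise pooled
   two-proportion z-tests for the discrete variables (gender, education)
   and one-way ANOVA with Bonferroni multiple comparisons for the
   continuous ones (age, SBP, DBP, HR), at the .05 level.

A synthetic cohort generator (`simulate_cohort()`) produces usage logs,
demographics, and blood-pressure records from planted per-subpopulation
transition matrices, so every stage is testable without patient data.

## Worked example

```r
library(trailmark)

cfg <- synth_config(n_patients = c(60, 25, 15),
                    sessions_per_patient = list(mu = 20, size = 3))
cohort <- simulate_cohort(cfg, seed = 42)

sessions <- sessionize(cohort$usage, gap = 600)
model <- fit_markov(sessions)
model
#> <transition_model> first-order Markov chain over 28 states (+ start/exit),
#> 12499 transitions from 1997 sessions

summaries <- summarize_states(sessions)
head(summaries, 5)
#> # A tibble: 5 × 5
#>   state          quantity relative_quantity total_time mean_time
#> 1 main               4387             41.8       61310      14.0
#> 2 task BP            1216             11.6       32531      26.8
#> 3 task weight         841              8.01      18614      22.1
#> 4 knowledge list      706              6.72      15732      22.3
#> 5 task drug           669              6.37      16383      24.5

prefs <- preference_features(sessions)
solution <- cluster_preferences(prefs, k_range = 2:9, seed = 1)
solution
#> <cluster_solution> chose k = 3 by silhouette (0.662); sizes: 61/24/15
solution$centroids
#> # A tibble: 3 × 5
#>   cluster  pt_t   ro_t   kl_t   sa_t
#> 1       1 0.816 0.0705 0.0614 0.0524
#> 2       2 0.385 0.0349 0.544  0.0360
#> 3       3 0.258 0.142  0.184  0.417
```

The chain spends ~42% of visits on the `main` navigation hub, and the
silhouette scan recovers the three planted preference patterns: a large
task-focused cluster (PT-T 0.82), a knowledge-learning cluster (KL-T 0.54),
and a support-seeking cluster (SA-T 0.42) — each centroid close to its
planted mixture. `build_profiles()` + `characterize_clusters()` then
compare demographics and blood pressure across the clusters
(`tidy(report)` gives the test table); at this toy size none of the
planted demographic contrasts reach significance, which is the expected
behavior at n = 100.

`autoplot(model)` draws the transition heatmap, `plot_trail_graph()` the
filtered trail graph, `autoplot(solution)` the silhouette-vs-k curve, and
`run_pipeline()` chains everything from CSV inputs to a written artifact
bundle with a manifest.

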