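---
title: "Modelling patient engagement trails from mHealth usage logs"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling patient engagement trails from mHealth usage logs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(trailmark)
```

`trailmark` analyses page-visit logs from a pathway-based mHealth
hypertension self-management app. This vignette explains the models and
procedures behind each stage, the parameters that matter, the choices made
where the design was genuinely open, and what the synthetic-data tests do
and do not establish about real data.

## The data model

Three tables drive the pipeline. The *usage log* has one row per page
visit: patient id, behavioral-state (page) name, and enter/exit timestamps
at second resolution; dwell time is their difference. *Demographics* carry
date of birth, gender, and a four-level education category.
*Physiological records* are patient-uploaded SBP/DBP/HR readings with an
upload timestamp (we assume second resolution throughout, including for
uploads). Files are UTF-8 CSV with ISO-8601 timestamps — unambiguous and
diff-friendly.

The 28-state vocabulary (`app_states()`) covers the app's care-pathway
modules: the navigation hub `main`, five self-management tasks and their
record histories, BP guidance, reminders, reports and ranking, four
health-education pages, questionnaire and appointment pages, and account
pages. Visits to pages outside the vocabulary are retained and flagged,
not rejected — real logs contain pages outside any analysis vocabulary —
and fall into the `OTHER` trail downstream.

Patient age is computed at the patient's first usage record. No reference
date is inherent in the data, so fixing it at first use makes the profile
deterministic and reproducible.

## Sessionization

A session ends when the patient is idle for more than `gap = 600` seconds.
Two details are open to interpretation and are explicit parameters:

* **Where the gap is measured from.** "Interval between consecutive
  states" can mean exit-to-enter (idle time) or enter-to-enter. The
  default is exit-to-enter, because idle time is what actually captures
  *leaving* the app; `from = "enter"` is available.
* **The boundary.** Exactly 600 s stays in the same session; the rule is
  strictly greater-than.

Overlapping visits (negative gaps, possible with coarse clocks) are
clamped to zero with a warning, so they never split a session. Consecutive
identical states are kept as separate visits: they become self-transitions,
which carry meaning (the patient switched to another app and returned to
the same page). Sessionization conserves the input exactly — every visit
appears in exactly one session — and lowering the threshold can only
increase the session count; both properties are tested.

## The first-order Markov chain

Each session is bracketed by start and exit pseudo-states, so a session of
`m` visits contributes exactly `m + 1` transitions. The transition
probability matrix is the row-normalised count matrix; this is the maximum
likelihood estimator for a first-order (memoryless) chain. The chain is
deliberately first-order only: higher orders are rejected with an error
rather than silently approximated, because every downstream quantity
(trail structure, display filtering, the generator) assumes memorylessness.

Numerical conventions:

* The exit row has no outgoing transitions and is kept all-zero, flagged
  absorbing, and excluded from row-sum checks; all other observed rows sum
  to 1 within 1e-12.
* Row normalisation includes transitions to the exit state in the
  denominator, so "probability of leaving the app from state *i*" is a
  regular matrix entry.
* Relative visit quantities are percentages of *real-state* visits;
  pseudo-states are bookkeeping, not behavior, and including them would
  deflate every share.
* Reported percentages and mean times are rounded half-up to 2 decimals
  for display; full precision is kept internally. Module-level mean times
  sum the *2-decimal* member means, matching how per-state means combine
  into published module figures.

The display filter keeps states with at least 1% relative quantity and
edges with transition probability at least 0.15; both thresholds are
inclusive, a choice we fix because "cutoff" does not specify strictness.
Transition typing (self / cycle / one-way) uses the same 0.15 threshold
for a "high" edge by default and is configurable, since those labels are
descriptive rather than inferential.

The `management plans` module grouping deserves a note: its reported mean
time corresponds to the sum of ten state means — the five tasks, their
four record histories, and BP guidance — although it is described as
containing five task parts. The shipped grouping uses the ten-state
membership because it is the one that reproduces the module figure
exactly; it is editable via the `grouping` argument.

## Preference features and clustering

Each state belongs to one of four trails: perform task (PT-T; tasks,
histories, guidance, reminders), result oriented (RO-T; reports and
ranking), knowledge learning (KL-T), and support acquisition (SA-T;
questionnaire and appointments). A patient's preference vector is the
per-trail count of visit events, normalised to sum to 1.

Two open choices, both exposed as arguments:

* **Events, not distinct pages.** "Number of behavioral states performed"
  is read as visit events. Counting distinct pages would saturate at the
  trail size (at most 12) and could not produce the continuous spread of
  preferences that clustering requires; `count = "distinct"` exists for
  comparison.
* **`main` is excluded.** The hub page starts almost every session by
  design, so counting it would swamp the trail signal; it is assigned to
  `OTHER` along with the account pages.

Patients with no trail visits at all have an undefined preference vector;
they are flagged `excluded` and dropped from clustering, never silently
removed.

Clustering is k-means with Euclidean distance, run as Lloyd iterations
from k-means++ seeds with 10 restarts (best within-cluster sum of squares
wins), deterministic given the seed. The restart scheme is a choice — the
method description is silent on initialisation — and k-means++ is the
standard default. If a restart yields an empty cluster, fresh seeds are
drawn for that restart; re-seeding was chosen over farthest-point
reassignment because the Lloyd iterations come from `stats::kmeans`, which
does not expose per-iteration repair, and re-seeding is equally
deterministic. The number of clusters is selected by the maximum mean
silhouette width over k = 2..9, ties toward the smaller k. Cluster labels
are canonicalised by decreasing size so that "cluster 1" is always the
largest.

## Cluster characterization

Discrete variables use Pearson chi-square (no continuity correction) on
the clusters-by-category table, followed — only when the omnibus P is at
or below .05 — by pooled-variance two-proportion z-tests for every cluster
pair and category. The pooled form is a choice; the variant is not
specified in the method description. Bonferroni adjustment is applied per
variable across the cluster pairs (for multi-category variables, within
each category across pairs), which is the narrowest defensible family.
The education category "don't know" is kept in descriptives but excluded
from the chi-square by default because its expected counts are tiny; this
is configurable, and with three clusters either way can move the omnibus
P across the .05 boundary.

Continuous variables (age at first use, per-patient mean SBP/DBP/HR —
unweighted means over all readings, another stated choice) use one-way
ANOVA with Bonferroni-adjusted pooled-SD pairwise t tests as the post hoc,
the SPSS-style battery. Patients without physiological readings are
excluded pairwise from the continuous tests only. The type-I error of
both omnibus tests is verified on null simulations (1,000 replicates) to
sit within two binomial standard errors of the nominal .05.

## The synthetic cohort generator

The generator exists so that every pipeline stage can be validated against
known ground truth; it emulates the *statistical structure* the analysis
assumes, at the scale of the deployment the package models:

* Three subpopulations of 694, 96, and 73 patients (863 total), with
  target trail mixtures (0.81 PT-T; 0.37 PT-T / 0.53 KL-T;
  0.30 PT-T / 0.37 SA-T). The components not reported for each archetype
  are spread uniformly over the unlisted trails and are synthetic choices.
* Sessions are genuine first-order Markov walks from start to exit. All
  subpopulations share a base transition matrix whose within-trail
  dynamics use the reported transition probabilities where available
  (e.g. main to task BP 0.29, knowledge list/content cycle 0.47/0.31,
  questionnaire self-transition 0.29); remaining mass returns to `main`
  or exits. The subpopulations differ only in how the `main` row
  allocates mass across the four trail entry points. That allocation is
  calibrated by a damped fixed-point iteration on the chain's expected
  per-state visit counts (computed exactly from the fundamental matrix of
  the absorbing chain) until the expected per-trail visit fractions match
  the target mixture to 1e-5. This keeps the generator a legitimate
  memoryless process — the same model family the estimator assumes —
  rather than pasting preference vectors on top of arbitrary dynamics.
* Session counts per patient are negative binomial (mean 60, size 3),
  which with the chain's mean session length of about five visits yields
  on the order of 300 visits per patient, matching the deployment's
  ~296k records over 863 patients. Dwell times are lognormal per state
  with means seeded from the observed per-state mean dwell table
  (`reference_state_stats()`) and log-scale SD 1. Neither distribution
  family is reported anywhere; both are stated choices of plausible
  heavy-tailed forms. Dwells are independent of the transition process.
* Inter-session gaps are 601 s plus an exponential draw, so generated
  sessions can never be merged by the 600 s rule; within-session visits
  are back-to-back.
* Demographics and blood pressure are drawn per subpopulation from the
  observed cluster profiles (age, male proportion, education distribution,
  SBP/DBP/HR means and SDs). The reported SDs are treated as
  between-patient SDs of patient-level means, with synthetic
  within-patient reading noise (5-6 mmHg / bpm) on top, and readings are
  clamped to satisfy SBP > DBP > 0 and HR > 0.

What passing tests on this generator show: the estimator recovers a
planted 28-state matrix (max absolute error below 0.05 on rows with at
least 1,000 transitions at 10,000 sessions); the silhouette scan selects
k = 3 and recovers the planted labels with adjusted Rand index above 0.9
across replicate seeds; the test battery holds its nominal size. What
they do *not* show: real patients are not homogeneous within clusters, do
not follow time-homogeneous first-order dynamics (no circadian structure,
no behavior change over years, no dropout), and real dwell times need not
be lognormal. The observed headline probabilities and preference values
from the deployment serve here as generator parameters and qualitative
recovery checks, not as reproducible outputs.

## Problem sizes and runtime choices

The test suite and the acceptance script work at the scales the analyses
prescribe — 10,000 sessions for estimator recovery, the full 863-patient
cohort for 20 replicate clustering runs, 1,000 null replicates for test
calibration — and use small cohorts (tens of patients) elsewhere, which is
ample for exercising the plumbing. The exhaustive-initialisation k-means
oracle runs at 20 points, where all 1,140 triplet initialisations are
enumerable.

## Interfaces

Every stage is a data-frame-in / tibble-out function, so the pipeline
composes with the pipe; `run_pipeline()` chains the stages from CSV paths
(or in-memory tibbles) to a written artifact bundle — sessions, matrices,
summaries, preferences, clusters, characterization tables, figures — plus
a manifest with the package version, seed, parameters, and a config hash.
Fitted objects have `tidy()`, `glance()`, and `autoplot()` methods. Trail
membership and the state vocabulary are editable configuration
(`read_trail_map()`, `read_state_space()`, YAML on disk).

## Known limitations

First-order dynamics only; no semi-Markov modelling of dwell times inside
the chain; no inferential tests on transition probabilities; trail
membership is configuration reconstructed from the trail descriptions, not
learned from data; and the characterization battery is deliberately
limited to the descriptive tests above — no regression adjustment.
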