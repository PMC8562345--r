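# behavdyn

Integrative, multilevel analysis of spatial behavioral dynamics in R.

Operant and Pavlovian preparations traditionally record behavior as discrete
responses — head entries, lever presses — and analyze their rates. Video
tracking adds the dimension those records ignore: the animal's continuous
position in the arena. `behavdyn` is for behavioral scientists who have both
kinds of record (5-Hz x/y tracking plus delivery and head-entry event logs
from open-field sessions under time-based schedules) and want to quantify
the whole behavioral system rather than a single response:

- **First-order kinematics** — traveled distance, maximum velocity,
  distance-to-landmark series (absolute or relative to the farthest corner)
  with trailing moving-average smoothing, and the subject's location at each
  delivery.
- **Occupancy dynamics** on a G x G zone grid — per-session Shannon entropy
  of the occupancy distribution, *H = −Σ p log₂ p* (bits, 0 to log₂ Z);
  between-consecutive-session Jensen–Shannon divergence,
  *JS(p,q) = ½KL(p‖m) + ½KL(q‖m)* with *m = (p+q)/2* (symmetric, in
  [0, 1]); and categorical recurrence summaries (recurrence rate, mean
  same-zone run length, transition count).
- **Discrete-response indices** — coincidence of position with delivery
  availability windows, and per-dispenser head-entry intensity, precision,
  and proportion-contacted, with a within-subject 5th-percentile filter.
- **A machine-learning stage** — per-session feature tables ranked by
  information gain, Gini gain and χ² against the condition label; exact
  t-SNE embedding; K-means clustering with purity and adjusted Rand
  agreement; and a PCA linear projection with per-feature axis vectors.

A stochastic goal-directed agent simulator (`simulate_experiment1()`,
`simulate_experiment2()`) generates complete synthetic session corpora —
schedule-driven approach–withdrawal kinematics, dwell episodes, head-entry
emission, condition contrasts and across-session acquisition — so the whole
pipeline is testable end to end without animal data.

## Worked example

Simulate the schedule experiment (fixed-time vs variable-time 30-s water
delivery; 2 subjects per condition, 20 sessions of 20 min each), assemble
the 7-feature session table, and ask which features carry the schedule:

```r
library(behavdyn)

sessions <- simulate_experiment1(sim_design(seed = 42))
features <- assemble_exp1(sessions)

summary <- summarize_features(features)
subset(summary, feature %in% c("traveled_distance", "entropy",
                               "divergence", "coincidence_index"))
#>  condition           feature  n     mean   median       sd       q1       q3
#>         FT traveled_distance 40 2.13e+04 2.12e+04 182.2084 2.11e+04 2.14e+04
#>         FT           entropy 40 5.99e+00 5.98e+00   0.1342 5.91e+00 6.09e+00
#>         FT        divergence 38 2.13e-01 2.03e-01   0.0454 1.82e-01 2.37e-01
#>         FT coincidence_index 40 5.37e-01 5.38e-01   0.0753 5.00e-01 5.75e-01
#>         VT traveled_distance 40 1.21e+04 1.21e+04 893.3676 1.16e+04 1.26e+04
#>         VT           entropy 40 2.88e+00 2.94e+00   0.3285 2.79e+00 3.08e+00
#>         VT        divergence 38 7.72e-01 8.31e-01   0.1629 7.97e-01 8.46e-01
#>         VT coincidence_index 40 3.41e-01 3.12e-01   0.1656 2.40e-01 3.91e-01
```

Fixed-time sessions travel farther (21.3 m vs 12.1 m per 20 min, in cm
above), spread over more of the arena (entropy 6.0 vs 2.9 bits of a
possible log₂ 100 ≈ 6.64), and keep a stable spatial layout across sessions
(divergence 0.21 vs 0.77); the discrete-response coincidence index also
differs (0.54 vs 0.34) but with overlapping distributions. Variable ranking
makes that asymmetry explicit — the spatial features outrank the
discrete-response index:

```r
ranking <- rank_variables(features)
head(subset(ranking, method == "info_gain"), 7)
#>     method             feature score rank
#>  info_gain             entropy 1.000    1
#>  info_gain   traveled_distance 1.000    2
#>  info_gain        max_velocity 0.851    3
#>  info_gain          divergence 0.730    4
#>  info_gain   coincidence_index 0.527    5
#>  info_gain mean_dist_dispenser 0.226    6
#>  info_gain             session 0.000    7
```

Embedding the standardized table with t-SNE and clustering with K-means
recovers the two schedule conditions as two clean regions:

```r
std <- standardize(features)
emb <- tsne_embed(std, seed = 0)
cl  <- kmeans_cluster(emb$coords, k = 2, seed = 0,
                      labels = features$condition[emb$rows])
cl$purity
#> [1] 1
```

`run_exp1_analysis(sessions, "out/")` orchestrates all of the above and
writes `features.csv`, `summary_stats.csv`, `rankings.csv`,
`embedding.csv`, `projection.csv` and plots (routes with
location-at-delivery overlays, raw and smoothed distance traces, recurrence
plots, per-feature box summaries, t-SNE scatter, PCA biplot) with full seed
provenance in `run.log`. `run_exp2_analysis()` does the same for the
two-dispenser deprivation design (13 features, percentile-filtered
precision, K-means purity against the deprivation label).
`inst/cli/behavdyn.R` is a thin command-line wrapper
(`simulate` / `analyze`) over the same functions.

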