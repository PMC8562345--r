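---
title: "Quantifying spatial behavioral dynamics with behavdyn"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying spatial behavioral dynamics with behavdyn}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Classical operant preparations record behavior as discrete switch closures
(lever presses, head entries) and analyze their rates. Video tracking makes
the complementary dimension observable: the animal's continuous position in
the arena. `behavdyn` quantifies one subject's open-field sessions at four
levels and then asks, with simple machine-learning tools, which of those
quantities carry the signature of the experimental manipulation:

1. **First-order kinematics** — traveled distance, per-frame velocity, and
   distance to named landmarks (dispenser, arena center), absolute or
   relative.
2. **Occupancy dynamics** — the arena is tiled by a G x G grid (default
   10 x 10); the distribution of frames over zones gives a Shannon entropy
   per session, a Jensen-Shannon divergence between consecutive sessions,
   and categorical recurrence structure.
3. **Discrete-response indices** — coincidence of position with delivery
   windows, and head-entry intensity / precision / proportion-contacted per
   dispenser.
4. **Multivariate stage** — per-session feature tables ranked by
   information gain, Gini gain and chi-squared against the condition label,
   embedded in 2-D with t-SNE, clustered with K-means, and projected on the
   first two principal components.

The package also ships a stochastic agent simulator that produces complete
synthetic session corpora with the structure this analysis assumes, so every
stage can be exercised and tested end to end without animal data.

## Measures and their definitions

### Kinematics

Traveled distance is the sum of Euclidean step lengths between consecutive
frames (cm); maximum velocity is the largest step divided by the 0.2-s
sampling period (cm/s). The distance-to-landmark series in *relative* mode
divides by the largest distance from the landmark to any arena corner, so 1
means "as far as the arena allows" and 0 means "at the landmark". Smoothing
is a trailing moving average (default 200 frames = 40 s); the partial
windows at session start are averaged over the frames available, which
keeps the series the same length and avoids inventing data before the
session. Position at a delivery is read from the sample at or before the
event onset; at 5 Hz this at-or-before convention errs by at most 0.2 s and
avoids interpolating through walls.

### Occupancy

Zone ids are row-major over the grid with half-open bins, the last bin on
each axis closed, so the far walls belong to the grid. Entropy is reported
in bits: $H = -\sum_k p_k \log_2 p_k$, ranging from 0 (one zone) to
$\log_2 Z$ (uniform). Between-session dissimilarity is the Jensen-Shannon
divergence, base 2:

$$\mathrm{JS}(p, q) = \tfrac12 \mathrm{KL}(p \| m) + \tfrac12 \mathrm{KL}(q \| m),
\qquad m = \tfrac{p+q}{2},$$

chosen over raw Kullback-Leibler because real sessions always leave zones
unvisited (KL is undefined on zeros), and because JS is symmetric and
bounded in [0, 1], matching the "close to zero / far from zero" reading the
divergence is put to. A smoothed-KL option (`method = "kl"`, additive 1/Z
pseudocounts) is kept for comparison. Recurrence summaries — off-diagonal
recurrence rate, mean constant-zone run length ("permanence"), and the
transition count — are computed by streaming over zone counts and run
lengths; the T x T matrix is materialized only for plotting and is
downsampled to at most 1500 frames per side there. These summaries are this
package's quantification of what recurrence plots show qualitatively.

### Discrete-response indices

The coincidence index is the fraction of deliveries with at least one
sampled frame inside the coincidence radius (default 10 cm) during the
availability window (default 3 s). One in-radius frame suffices by default
(`min_dwell_frames = 1`); at 5 Hz a dwell-time threshold would be hard to
justify, but the knob exists, as does an onset-only reading. Intensity
normalizes a session's head-entry count by the maximum count that subject
produced at that dispenser across the experiment, so 0/0 (a subject that
never entered) is reported as missing, never as 0. Precision is the
fraction of a session's entries that fell inside availability windows;
proportion-contacted is the fraction of deliveries answered by at least one
entry. Deliveries pair only with entries to the same dispenser. The
percentile filter removes values strictly below the 5th percentile
(linear interpolation between order statistics) within each
subject-dispenser series before precision is summarized; removed cells are
masked missing, never zero-filled.

### Feature tables

The schedule experiment's table has 7 features per session: traveled
distance, entropy, divergence, max velocity, coincidence index, mean
relative distance to the dispenser, and session number. The deprivation
experiment's table has 13: relative distances to food and water dispensers
and arena center, entropy, divergence, intensity/precision/proportion per
dispenser, session, and sequence encoded 1/2. Divergence pairs session s
with s-1 within subject, so every subject's first session is masked; rows
with any masked feature are excluded from ranking, embedding and
projection but retained for univariate summaries. "Mean distance to the
dispenser" enters as the relative (dimensionless) mean; the absolute value
in cm is carried alongside in the table for reporting.

### Machine-learning stage

Continuous features are discretized into equal-frequency bins (default
k = 4; when a feature has at most k distinct values each value is its own
category) before scoring. The three scores are the plain contingency-table
quantities: information gain $H(Y) - \sum_v p(v) H(Y|v)$ in bits, Gini gain
with $\mathrm{Gini} = 1 - \sum_c p_c^2$, and Pearson's
$\sum (O - E)^2 / E$. Ties in a ranking are broken by feature name so
output order is deterministic.

t-SNE is implemented exactly (the corpora are tens of sessions, so the
O(n²) gradient is cheap). Defaults: perplexity min(30, 0.95·(n-1)/3), PCA
initialization with a small seeded jitter, 500 iterations with early
exaggeration 12 for the first 100, learning rate max(50, n/12). Because
gradient descent at very small n occasionally sticks in a split layout,
the embedding is run 3 times from different jitters and the run with the
lowest final KL divergence is kept; the whole procedure is a deterministic
function of one integer seed, which is recorded in the result. K-means uses
`stats::kmeans` with 10 restarts; agreement with condition labels is
reported as purity (primary) and the adjusted Rand index (chance-corrected,
computed from the pair-counting formula). The linear projection is PCA of
the standardized complete rows; each feature's axis vector is its loadings
on the first two components, with each component's sign fixed so its
largest-magnitude loading is positive.

## The simulator

`simulate_session()` runs a two-mode stochastic agent at 5 Hz. In
*approach* mode the position contracts toward a goal dispenser at rate
$\lambda$ (1/s); in *explore* mode it drifts toward a home-base point; all
motion carries Gaussian noise $\sigma\sqrt{dt}\,\varepsilon$ with
reflection at the walls. Under a fixed-time schedule the hazard of starting
an approach rises sigmoidally as the schedule clock nears the next delivery
(anticipation), and the same signal sustains waiting at the dispenser, so
an agent that arrives after the delivery has passed disengages quickly
while one that arrives early holds; under variable-time and concurrent
schedules the approach hazard is constant. A contacted delivery triggers an
exponential dwell at the dispenser; head entries are emitted per in-radius
frame with a fixed probability and a 1-s refractory. The approach gain is
multiplied by `acquisition_ramp^(session-1)` to emulate progressively
sharper approach across an experiment; this is a calibration device, not a
learning model. Variable-time intervals are exponential with the scheduled
mean, rejection-resampled into [5, 90] s (the real schedule's interval list
is unknown; results that depend on the interval law should be read with
that in mind).

Child seeds are derived per (subject, session) with a stable multiplicative
scheme, so corpora are byte-reproducible from one master seed and extending
a design never reshuffles earlier sessions.

### Condition calibrations

The defaults encode the study conditions: 100 x 100 cm arena, central water
dispenser, FT 30 s vs VT 30 s, 2 subjects per condition, 20 sessions of
20 min (schedule experiment); 92 x 92 cm arena, food and water dispensers
at opposite wall centers, concurrent FT 30 s FT 30 s, 6 subjects in two
sequence groups, 2 deprivations x 3 sessions of 30 min (deprivation
experiment).

The FT agent anticipates the clock and roams widely between deliveries
(fresh uniform home base each explore bout); the VT agent approaches at a
constant low hazard and otherwise keeps to a single session-specific home
region with gentler motion. Those choices reproduce the qualitative
condition pattern the analysis is meant to detect: more traveled distance,
entropy and velocity and a stable session-to-session occupancy (low
divergence) under FT; less locomotion, lower entropy, and a
session-varying preferred region (high divergence) under VT. The FT
anticipation peak is deliberately modest (0.12/s) so the coincidence index
overlaps between conditions — the between-condition difference in the
discrete-response measure is real but weaker than the spatial measures,
which is exactly the configuration in which variable ranking places the
spatial features above the coincidence index. Food deprivation biases
approach bouts toward the food dispenser (goal weight 0.85) with long
dwells; water deprivation biases them toward water (0.35) with shorter
dwells and a faster bout turnover, producing the back-and-forth alternation
between dispensers and the commodity-directed distance and intensity
contrasts.

### What the simulator does not emulate

No body orientation, rearing/grooming, thigmotaxis, wall-following, or
inter-subject variability beyond seed noise; the home-base mechanism is a
caricature of exploratory structure; and the mean distance to the arena
center does not reliably differ between deprivations in the simulator even
though the original preparation reports it higher under water deprivation.
Passing tests therefore demonstrate that the pipeline detects the encoded
structure, not that real rats behave like the agent.

## Numerical choices and degenerate inputs

Timestamps must advance by dt within 1e-6 s. Missing tracking frames are
forward-filled; runs longer than 25 frames (5 s) invalidate a session;
out-of-bounds coordinates are clamped to the boundary and counted.
Occupancy vectors must sum to 1 within 1e-9. Zero-delivery sessions yield
missing (not zero) coincidence and proportion indices; all-zero entry
series yield missing intensity. Constant features standardize to zero with
a warning. A k-means request with fewer rows than clusters errors;
t-SNE requires at least 4 complete rows and shrinks an over-large
perplexity with a warning.

## Problem sizes used in the test suite

Unit tests run on fixtures of tens to hundreds of frames. The end-to-end
checks simulate the full default designs — 80 sessions of 6001 frames for
the schedule experiment and 36 sessions of 9001 frames for the deprivation
experiment — which takes well under a minute each on one core; the
parameter-recovery sweep uses 5 gain levels x 10 sessions of 20 min. These
sizes were chosen to exercise the complete pipeline at the study's own
dimensions while keeping a full test run to about half a minute.

## Known limitations

- The divergence is Jensen-Shannon by definition here; analyses tuned to a
  different divergence will differ by more than a constant factor.
- The recurrence summaries reduce the plot to three numbers; line-length
  spectra beyond the mean run length (determinism, laminarity) are out of
  scope.
- Sequence enters the deprivation table as a single 1/2 code, not one-hot;
  with more than two sequences the encoding would need revisiting.
- The exact t-SNE is quadratic in rows; it is intended for session tables
  (tens to a few hundred rows), not large point clouds.
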