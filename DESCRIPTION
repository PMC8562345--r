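Package: behavdyn
Title: Integrative Multilevel Analysis of Spatial Behavioral Dynamics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for the integrative, multilevel analysis of behavioral
    systems recorded as 2-D trajectories in open-field arenas under
    time-based (fixed-time and variable-time) stimulus schedules. Provides
    first-order kinematic measures (traveled distance, velocity,
    distance-to-landmark series with moving-average smoothing), non-first
    order occupancy measures on a zone-discretized arena (Shannon entropy,
    between-session Jensen-Shannon divergence, categorical recurrence
    plots), discrete-response indices (coincidence, intensity, precision,
    proportion contacted), per-session feature tables, and a machine
    learning stage (information gain / Gini / chi-squared variable ranking,
    t-SNE embedding, K-means clustering with purity, PCA linear
    projection). Includes a stochastic goal-directed agent simulator that
    generates session corpora with schedule-driven approach-withdrawal
    structure for validating the pipeline end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    grDevices,
    ggplot2
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    mclust,
    optparse,
    withr
Config/testthat/edition: 3
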