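#' Time-based schedule specification
#'
#' Non-contingent delivery schedules: fixed time (FT, deliveries on a strict
#' clock), variable time (VT, random intervals with the same mean), and two
#' concurrent FT streams (one per dispenser).
#'
#' @param type `"FT"`, `"VT"`, or `"CONC_FT_FT"`.
#' @param mean_interval Mean inter-delivery interval in seconds (default 30).
#' @param availability Seconds each delivery remains available (default 3).
#' @param vt_bounds Interval bounds in seconds for VT sampling (default
#'   `c(5, 90)`).
#' @param dispensers Dispenser landmark name(s): one for FT/VT, two for the
#'   concurrent schedule.
#' @return An object of class `schedule_spec`.
#' @export
schedule_spec <- function(type = c("FT", "VT", "CONC_FT_FT"),
                          mean_interval = 30, availability = 3,
                          vt_bounds = c(5, 90),
                          dispensers = if (match.arg(type) == "CONC_FT_FT")
                            c("food", "water") else "dispenser") {
  type <- match.arg(type)
  stopifnot(mean_interval > 0, availability > 0,
            length(vt_bounds) == 2L, vt_bounds[1] < vt_bounds[2])
  n_disp <- if (type == "CONC_FT_FT") 2L else 1L
  if (length(dispensers) != n_disp)
    stop("schedule '", type, "' needs ", n_disp, " dispenser name(s)", call. = FALSE)
  structure(list(type = type, mean_interval = mean_interval,
                 availability = availability, vt_bounds = vt_bounds,
                 dispensers = dispensers),
            class = "schedule_spec")
}

# Truncated-exponential VT interval: constant hazard, rejection-resampled
# into the bounds.
draw_vt_interval <- function(mean_interval, bounds) {
  repeat {
    x <- stats::rexp(1L, rate = 1 / mean_interval)
    if (x >= bounds[1] && x <= bounds[2]) return(x)
  }
}

#' Generate delivery onsets for a schedule
#'
#' FT schedules deliver at `k * mean_interval` up to the session duration;
#' VT intervals are exponential with the stated mean, resampled into
#' `vt_bounds`; the concurrent schedule runs one independent FT stream per
#' dispenser. VT draws consume the R random stream, so seed the RNG before
#' calling for reproducibility.
#'
#' @param spec A [schedule_spec()].
#' @param duration Session duration in seconds.
#' @return Data frame with columns `t` (onset) and `dispenser`, sorted by
#'   onset, with the spec stored in attribute `spec`.
#' @export
make_schedule <- function(spec, duration) {
  stopifnot(inherits(spec, "schedule_spec"), duration > 0)
  one_ft <- function(nm) {
    on <- if (duration < spec$mean_interval) numeric(0)
          else seq(spec$mean_interval, duration, by = spec$mean_interval)
    data.frame(t = on, dispenser = rep(nm, length(on)))
  }
  df <- switch(spec$type,
    FT = one_ft(spec$dispensers[1L]),
    CONC_FT_FT = rbind(one_ft(spec$dispensers[1L]), one_ft(spec$dispensers[2L])),
    VT = {
      on <- numeric(0); t <- 0
      repeat {
        t <- t + draw_vt_interval(spec$mean_interval, spec$vt_bounds)
        if (t > duration) break
        on <- c(on, t)
      }
      data.frame(t = on, dispenser = rep(spec$dispensers[1L], length(on)))
    })
  df <- df[order(df$t), , drop = FALSE]
  rownames(df) <- NULL
  attr(df, "spec") <- spec
  df
}

#' Agent parameters for the session simulator
#'
#' The simulated subject is a two-mode stochastic agent. In *approach* mode
#' it contracts toward a goal dispenser at rate `approach_gain` (1/s); in
#' *explore* mode it drifts toward a home-base point at `explore_gain`. All
#' motion carries Gaussian noise of intensity `noise` (cm/sqrt(s)) with
#' reflection at the walls. Under an FT schedule the per-second hazard of
#' entering approach rises sigmoidally from `approach_hazard` toward
#' `approach_hazard + anticipation_peak` over the last
#' `anticipation_threshold` seconds before the next delivery (clock
#' anticipation); under VT or concurrent schedules it is the constant
#' `approach_hazard`. After contacting a delivery the agent dwells at the
#' dispenser for an exponential time with mean `dwell_mean`; while inside
#' `entry_radius` of a dispenser it emits head entries with probability
#' `entry_prob` per frame (1-s refractory). `acquisition_ramp` multiplies
#' the approach gain geometrically across sessions to emulate progressively
#' sharper approach over an experiment, and `goal_weight_food` sets the
#' probability that an approach bout targets the food dispenser in
#' two-dispenser arenas. `home_redraw` controls the home base: `"bout"`
#' draws a fresh uniform point at each explore bout (wide-ranging roaming);
#' `"session"` fixes one random point for the whole session (a
#' session-specific preferred region).
#'
#' @param approach_gain Approach contraction rate, 1/s.
#' @param noise Diffusion intensity, cm/sqrt(s).
#' @param dwell_mean Mean post-consumption dwell, s.
#' @param anticipation_threshold Seconds before a scheduled delivery at
#'   which anticipation is half-maximal (FT only).
#' @param anticipation_slope Sigmoid width of the anticipation rise, s.
#' @param anticipation_peak Added approach hazard at full anticipation, 1/s.
#' @param approach_hazard Baseline approach hazard, 1/s.
#' @param explore_hazard Hazard of abandoning a dispenser wait, 1/s.
#' @param explore_gain Home-base attraction rate in explore mode, 1/s.
#' @param goal_weight_food Probability an approach bout targets food.
#' @param entry_prob Head-entry probability per in-radius frame.
#' @param acquisition_ramp Per-session multiplier on approach gain.
#' @param home_redraw `"bout"` or `"session"`.
#' @return An object of class `agent_params`.
#' @export
agent_params <- function(approach_gain = 1.2, noise = 6, dwell_mean = 2,
                         anticipation_threshold = 8, anticipation_slope = 1.5,
                         anticipation_peak = 0.8, approach_hazard = 0.01,
                         explore_hazard = 0.3, explore_gain = 0.3,
                         goal_weight_food = 0.5, entry_prob = 0.1,
                         acquisition_ramp = 1.0,
                         home_redraw = c("bout", "session")) {
  home_redraw <- match.arg(home_redraw)
  stopifnot(approach_gain >= 0, noise >= 0, dwell_mean >= 0,
            goal_weight_food >= 0, goal_weight_food <= 1,
            entry_prob >= 0, entry_prob <= 1, acquisition_ramp > 0)
  structure(as.list(environment()), class = "agent_params")
}

#' Simulate one session
#'
#' Runs the two-mode agent over a delivery schedule in an arena, producing a
#' full [session_record()]: the 5-Hz trajectory, the delivery events from
#' the schedule, and the emitted head entries. The simulation consumes the R
#' random stream; call [set.seed()] (or use the experiment-level wrappers,
#' which derive per-session seeds) for reproducibility.
#'
#' @param schedule Delivery schedule from [make_schedule()].
#' @param agent An [agent_params()].
#' @param arena An [arena_spec()] with a landmark for every schedule
#'   dispenser.
#' @param duration Session duration, s.
#' @param dt Sampling period, s (default 0.2).
#' @param subject,condition,sequence,session_number Metadata for the record.
#' @return A [session_record()].
#' @export
simulate_session <- function(schedule, agent, arena, duration, dt = 0.2,
                             subject = "S1", condition = "SIM",
                             sequence = NA, session_number = 1L) {
  stopifnot(inherits(agent, "agent_params"), inherits(arena, "arena_spec"),
            duration > 0, dt > 0)
  spec <- attr(schedule, "spec")
  is_ft_single <- !is.null(spec) && spec$type == "FT"
  interval <- if (!is.null(spec)) spec$mean_interval else 30
  avail <- arena$availability_duration
  disp_names <- if (!is.null(spec)) spec$dispensers else unique(schedule$dispenser)
  m <- length(disp_names)
  dx_ <- vapply(disp_names, function(nm) arena_landmark(arena, nm)[1], 0)
  dy_ <- vapply(disp_names, function(nm) arena_landmark(arena, nm)[2], 0)
  food_idx <- if (m == 2L) match("food", disp_names) else 1L
  if (is.na(food_idx)) food_idx <- 1L

  n <- as.integer(round(duration / dt)) + 1L
  tvec <- (seq_len(n) - 1L) * dt
  lam <- agent$approach_gain * agent$acquisition_ramp^(session_number - 1L)
  sig <- agent$noise * sqrt(dt)
  r2 <- arena$entry_radius^2
  w <- arena$width; h <- arena$height

  # pre-drawn random streams: one draw per frame per purpose keeps the
  # simulation reproducible regardless of branching
  eps_x <- stats::rnorm(n); eps_y <- stats::rnorm(n)
  u_mode <- stats::runif(n); u_entry <- stats::runif(n); u_goal <- stats::runif(n)
  home <- c(stats::runif(1, 0, w), stats::runif(1, 0, h))
  x <- stats::runif(1, 0, w); y <- stats::runif(1, 0, h)

  del_t <- lapply(seq_len(m), function(j) schedule$t[schedule$dispenser == disp_names[j]])
  del_next <- rep(1L, m)  # first not-yet-consumed delivery per dispenser

  X <- numeric(n); Y <- numeric(n)
  X[1L] <- x; Y[1L] <- y
  mode_approach <- FALSE
  tgt <- 1L
  dwell_until <- -Inf
  dwell_goal <- 1L
  last_entry <- rep(-Inf, m)
  ent_t <- numeric(0); ent_d <- integer(0)

  for (i in seq_len(n - 1L)) {
    t <- tvec[i]
    # presence at a dispenser (radius check; dispensers never overlap)
    near <- 0L
    for (j in seq_len(m)) {
      if ((x - dx_[j])^2 + (y - dy_[j])^2 <= r2) { near <- j; break }
    }
    if (near > 0L) {
      if (u_entry[i] < agent$entry_prob && t - last_entry[near] >= 1) {
        ent_t <- c(ent_t, t); ent_d <- c(ent_d, near)
        last_entry[near] <- t
      }
      k <- del_next[near]
      ts <- del_t[[near]]
      while (k <= length(ts) && ts[k] + avail < t) k <- k + 1L
      del_next[near] <- k
      if (k <= length(ts) && ts[k] <= t && t <= ts[k] + avail) {
        del_next[near] <- k + 1L
        dwell_until <- t + stats::rexp(1L, rate = 1 / max(agent$dwell_mean, 1e-9))
        dwell_goal <- near
        mode_approach <- FALSE
        if (agent$home_redraw == "bout")
          home <- c(stats::runif(1, 0, w), stats::runif(1, 0, h))
      }
    }

    # anticipation signal: rises sigmoidally as the FT clock nears the next
    # delivery; it triggers approach and sustains waiting at the dispenser,
    # so the agent disengages quickly once the delivery has passed
    anticip <- if (is_ft_single) {
      stats::plogis(((t %% interval) - (interval - agent$anticipation_threshold)) /
                      agent$anticipation_slope)
    } else 0

    if (t < dwell_until) {
      gain <- 2; gx <- dx_[dwell_goal]; gy <- dy_[dwell_goal]
    } else if (mode_approach) {
      p_leave <- 1 - exp(-agent$explore_hazard * (1 - anticip) * dt)
      if (near == tgt && near > 0L && u_mode[i] < p_leave) {
        mode_approach <- FALSE
        if (agent$home_redraw == "bout")
          home <- c(stats::runif(1, 0, w), stats::runif(1, 0, h))
        gain <- agent$explore_gain; gx <- home[1L]; gy <- home[2L]
      } else {
        gain <- lam; gx <- dx_[tgt]; gy <- dy_[tgt]
      }
    } else {
      hz <- agent$approach_hazard + agent$anticipation_peak * anticip
      if (u_mode[i] < 1 - exp(-hz * dt)) {
        mode_approach <- TRUE
        tgt <- if (m == 2L) {
          if (u_goal[i] < agent$goal_weight_food) food_idx else (3L - food_idx)
        } else 1L
        gain <- lam; gx <- dx_[tgt]; gy <- dy_[tgt]
      } else {
        gain <- agent$explore_gain; gx <- home[1L]; gy <- home[2L]
      }
    }

    x <- x + gain * dt * (gx - x) + sig * eps_x[i]
    y <- y + gain * dt * (gy - y) + sig * eps_y[i]
    if (x < 0) x <- -x; if (x > w) x <- 2 * w - x
    if (y < 0) y <- -y; if (y > h) y <- 2 * h - y
    x <- min(max(x, 0), w); y <- min(max(y, 0), h)
    X[i + 1L] <- x; Y[i + 1L] <- y
  }

  ev_rows <- rbind(
    data.frame(t = schedule$t, kind = "delivery",
               dispenser = schedule$dispenser),
    if (length(ent_t))
      data.frame(t = ent_t, kind = "head_entry", dispenser = disp_names[ent_d])
  )
  session_record(
    subject = subject, condition = condition, sequence = sequence,
    session_number = session_number,
    trajectory = trajectory(tvec, X, Y, dt = dt),
    events = parse_event_table(ev_rows, arena),
    arena = arena
  )
}

#' Experiment design for the simulator
#'
#' @param subjects_per_condition Subjects per condition (default 2).
#' @param sessions_per_subject Sessions per subject (default 20).
#' @param duration Session duration, s (default 1200).
#' @param seed Master seed; per-session child seeds are derived from it with
#'   a stable splitting scheme, so extending a design never reshuffles
#'   earlier sessions.
#' @return An object of class `sim_design`.
#' @export
sim_design <- function(subjects_per_condition = 2L, sessions_per_subject = 20L,
                       duration = 1200, seed = 1L) {
  stopifnot(subjects_per_condition >= 1L, sessions_per_subject >= 1L,
            duration > 0)
  structure(list(subjects_per_condition = as.integer(subjects_per_condition),
                 sessions_per_subject = as.integer(sessions_per_subject),
                 duration = duration, seed = as.integer(seed)),
            class = "sim_design")
}

# Stable (master, subject, session) -> child seed map; integer arithmetic
# kept below 2^31 via modular reduction.
child_seed <- function(master, subject_idx, session) {
  m <- 2147483647
  h <- (as.numeric(master) %% m)
  h <- (h * 48271 + subject_idx * 2654435) %% m
  h <- (h * 48271 + session * 97911) %% m
  as.integer(h %% 2147483646) + 1L
}

with_seed <- function(seed, expr) {
  old_seed <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed,
                                         envir = globalenv()))
  set.seed(seed)
  expr
}

#' Default arenas for the two simulated experiments
#'
#' The single-dispenser arena is 100 x 100 cm with the water dispenser at
#' the center; the two-dispenser arena is 92 x 92 cm with food and water
#' dispensers at the centers of opposing walls.
#'
#' @return An [arena_spec()].
#' @export
exp1_arena <- function() {
  arena_spec(100, 100,
             landmarks = list(dispenser = c(50, 50), center = c(50, 50)))
}

#' @rdname exp1_arena
#' @export
exp2_arena <- function() {
  arena_spec(92, 92,
             landmarks = list(food = c(46, 92), water = c(46, 0),
                              center = c(46, 46)))
}

#' Default agent calibrations
#'
#' `ft_agent()`/`vt_agent()` are the single-dispenser schedule conditions:
#' the FT agent anticipates the 30-s clock and roams widely between
#' deliveries (fresh home base each bout), while the VT agent approaches at
#' a constant low hazard and otherwise keeps to one session-specific
#' region with gentler motion. `fd_agent()`/`wd_agent()` are the
#' two-dispenser deprivation conditions: food deprivation biases approach
#' bouts strongly toward the food dispenser with long dwells; water
#' deprivation biases them toward water with shorter dwells and a higher
#' bout turnover, producing back-and-forth alternation between dispensers.
#'
#' @return An [agent_params()].
#' @export
ft_agent <- function() {
  agent_params(approach_gain = 1.2, noise = 6, dwell_mean = 2,
               anticipation_threshold = 6, anticipation_slope = 1.5,
               anticipation_peak = 0.12, approach_hazard = 0.01,
               explore_hazard = 0.3, explore_gain = 0.3,
               entry_prob = 0.1, acquisition_ramp = 1.03,
               home_redraw = "bout")
}

#' @rdname ft_agent
#' @export
vt_agent <- function() {
  agent_params(approach_gain = 0.8, noise = 3, dwell_mean = 2,
               anticipation_peak = 0, approach_hazard = 0.06,
               explore_hazard = 0.3, explore_gain = 0.4,
               entry_prob = 0.1, acquisition_ramp = 1.03,
               home_redraw = "session")
}

#' @rdname ft_agent
#' @export
fd_agent <- function() {
  agent_params(approach_gain = 1.0, noise = 4, dwell_mean = 8,
               anticipation_peak = 0, approach_hazard = 0.12,
               explore_hazard = 0.5, explore_gain = 0.3,
               goal_weight_food = 0.85, entry_prob = 0.12,
               home_redraw = "bout")
}

#' @rdname ft_agent
#' @export
wd_agent <- function() {
  agent_params(approach_gain = 1.0, noise = 4.5, dwell_mean = 3,
               anticipation_peak = 0, approach_hazard = 0.18,
               explore_hazard = 0.8, explore_gain = 0.3,
               goal_weight_food = 0.35, entry_prob = 0.12,
               home_redraw = "bout")
}

#' Simulate the single-dispenser schedule experiment
#'
#' Two conditions (FT 30 s vs VT 30 s water delivery), by default 2 subjects
#' per condition, 20 sessions of 20 min each, on the 100 x 100 cm arena with
#' the dispenser at the center. Fully reproducible from the design's master
#' seed.
#'
#' @param design A [sim_design()].
#' @param ft_params,vt_params [agent_params()] per condition.
#' @return List of [session_record()]s.
#' @export
simulate_experiment1 <- function(design = sim_design(),
                                 ft_params = ft_agent(),
                                 vt_params = vt_agent()) {
  stopifnot(inherits(design, "sim_design"))
  arena <- exp1_arena()
  out <- list()
  idx <- 0L
  subj_idx <- 0L
  for (cond in c("FT", "VT")) {
    pars <- if (cond == "FT") ft_params else vt_params
    spec <- schedule_spec(cond, dispensers = "dispenser")
    for (s in seq_len(design$subjects_per_condition)) {
      subj_idx <- subj_idx + 1L
      subject <- sprintf("%s%d", cond, s)
      for (k in seq_len(design$sessions_per_subject)) {
        idx <- idx + 1L
        out[[idx]] <- with_seed(child_seed(design$seed, subj_idx, k), {
          sched <- make_schedule(spec, design$duration)
          simulate_session(sched, pars, arena, design$duration,
                           subject = subject, condition = cond,
                           session_number = k)
        })
      }
    }
  }
  out
}

#' Simulate the two-dispenser deprivation experiment
#'
#' Six subjects by default, each run through two deprivation conditions
#' (food deprivation FD, water deprivation WD) of 3 sessions each under a
#' concurrent FT 30 s FT 30 s food/water schedule, 30-min sessions, on the
#' 92 x 92 cm two-dispenser arena. Half the subjects follow sequence 1
#' (WD then FD), half sequence 2 (FD then WD).
#'
#' @param design A [sim_design()]; its `subjects_per_condition` is read as
#'   subjects per sequence group. Default: 3 per group, 3 sessions per
#'   deprivation, 1800-s sessions.
#' @param fd_params,wd_params [agent_params()] per deprivation.
#' @return List of [session_record()]s with condition FD/WD and sequence
#'   1/2 metadata.
#' @export
simulate_experiment2 <- function(design = sim_design(subjects_per_condition = 3L,
                                                     sessions_per_subject = 3L,
                                                     duration = 1800),
                                 fd_params = fd_agent(),
                                 wd_params = wd_agent()) {
  stopifnot(inherits(design, "sim_design"))
  arena <- exp2_arena()
  spec <- schedule_spec("CONC_FT_FT", dispensers = c("food", "water"))
  out <- list()
  idx <- 0L
  subj_idx <- 0L
  for (seq_id in c("1", "2")) {
    deps <- if (seq_id == "1") c("WD", "FD") else c("FD", "WD")
    for (s in seq_len(design$subjects_per_condition)) {
      subj_idx <- subj_idx + 1L
      subject <- sprintf("R%d", subj_idx)
      snum <- 0L
      for (dep in deps) {
        pars <- if (dep == "FD") fd_params else wd_params
        for (k in seq_len(design$sessions_per_subject)) {
          snum <- snum + 1L
          idx <- idx + 1L
          out[[idx]] <- with_seed(child_seed(design$seed, subj_idx, snum), {
            sched <- make_schedule(spec, design$duration)
            simulate_session(sched, pars, arena, design$duration,
                             subject = subject, condition = dep,
                             sequence = seq_id, session_number = snum)
          })
        }
      }
    }
  }
  out
}
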