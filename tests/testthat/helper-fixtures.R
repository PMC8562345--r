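# Fixtures shared across the suite; everything is built in code.

square_arena <- function(width = 100, grid = 10L) {
  arena_spec(width, width,
             landmarks = list(dispenser = c(width / 2, width / 2),
                              center = c(width / 2, width / 2)),
             grid_divisions = grid)
}

two_dispenser_arena <- function(width = 92) {
  arena_spec(width, width,
             landmarks = list(food = c(width / 2, width),
                              water = c(width / 2, 0),
                              center = c(width / 2, width / 2)))
}

# straight trajectory sitting at one point, or along supplied coordinates
make_traj <- function(x, y, dt = 0.2) {
  n <- max(length(x), length(y))
  x <- rep_len(x, n); y <- rep_len(y, n)
  trajectory(t = (seq_len(n) - 1) * dt, x = x, y = y, dt = dt)
}

random_walk_traj <- function(n, arena, seed, dt = 0.2, step_sd = 2) {
  set.seed(seed)
  x <- pmin(pmax(cumsum(c(arena$width / 2, rnorm(n - 1, sd = step_sd))), 0),
            arena$width)
  y <- pmin(pmax(cumsum(c(arena$height / 2, rnorm(n - 1, sd = step_sd))), 0),
            arena$height)
  make_traj(x, y, dt = dt)
}

event_log_df <- function(t, kind, dispenser, arena) {
  parse_event_table(data.frame(t = t, kind = kind, dispenser = dispenser),
                    arena)
}

# tiny but structurally complete schedule-experiment corpus for pipeline
# tests: 1 subject per condition, few short sessions
tiny_exp1_corpus <- function(seed = 7L, sessions = 3L, duration = 240) {
  simulate_experiment1(sim_design(subjects_per_condition = 1L,
                                  sessions_per_subject = sessions,
                                  duration = duration, seed = seed))
}

tiny_exp2_corpus <- function(seed = 7L, sessions = 2L, duration = 300) {
  simulate_experiment2(sim_design(subjects_per_condition = 1L,
                                  sessions_per_subject = sessions,
                                  duration = duration, seed = seed))
}
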