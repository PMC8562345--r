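test_that("fixed-time schedules deliver on the clock", {
  spec <- schedule_spec("FT", dispensers = "dispenser")
  s <- make_schedule(spec, 1200)
  expect_equal(nrow(s), 40L)
  expect_equal(s$t, seq(30, 1200, by = 30))

  expect_equal(nrow(make_schedule(spec, 20)), 0L)

  conc <- make_schedule(schedule_spec("CONC_FT_FT"), 300)
  expect_equal(sum(conc$dispenser == "food"), 10L)
  expect_equal(sum(conc$dispenser == "water"), 10L)
  expect_true(!is.unsorted(conc$t))
})

test_that("variable-time intervals have the scheduled mean within bounds", {
  set.seed(101)
  draws <- replicate(10000, behavdyn:::draw_vt_interval(30, c(5, 90)))
  expect_true(all(draws >= 5 & draws <= 90))
  expect_lt(abs(mean(draws) - 30), 1)

  set.seed(102)
  counts <- replicate(100, nrow(make_schedule(schedule_spec("VT"), 1200)))
  expect_lt(abs(mean(counts) - 40) / 40, 0.10)
})

test_that("sessions are reproducible and respect arena bounds", {
  arena <- exp1_arena()
  spec <- schedule_spec("FT", dispensers = "dispenser")
  sched <- make_schedule(spec, 300)
  run <- function() simulate_session(sched, ft_agent(), arena, 300,
                                     subject = "R1", condition = "FT")
  set.seed(55); s1 <- run()
  set.seed(55); s2 <- run()
  expect_identical(s1$trajectory$x, s2$trajectory$x)
  expect_identical(as.data.frame(s1$events), as.data.frame(s2$events))

  tr <- s1$trajectory
  expect_equal(nrow(tr), 300 / 0.2 + 1)
  expect_true(all(tr$x >= 0 & tr$x <= arena$width))
  expect_true(all(tr$y >= 0 & tr$y <= arena$height))
  expect_true(all(s1$events$t >= 0 & s1$events$t <= 300))
})

test_that("a noiseless always-approaching agent contracts onto the dispenser", {
  arena <- exp1_arena()
  sched <- make_schedule(schedule_spec("FT", dispensers = "dispenser"), 120)
  agent <- agent_params(approach_gain = 1.5, noise = 0, dwell_mean = 0.01,
                        anticipation_peak = 0, approach_hazard = 1e6,
                        explore_hazard = 0, entry_prob = 0)
  set.seed(1)
  s <- simulate_session(sched, agent, arena, 120)
  tr <- s$trajectory
  final <- c(tail(tr$x, 1), tail(tr$y, 1))
  d <- sqrt(sum((final - arena_landmark(arena, "dispenser"))^2))
  expect_lte(d, arena$entry_radius)
})

test_that("the schedule-experiment corpus has the study dimensions", {
  sess <- simulate_experiment1(sim_design(subjects_per_condition = 1L,
                                          sessions_per_subject = 2L,
                                          duration = 60, seed = 3))
  expect_length(sess, 4L)  # 1 subject x 2 conditions x 2 sessions
  expect_equal(nrow(sess[[1]]$trajectory), 60 / 0.2 + 1)
  expect_setequal(unique(vapply(sess, `[[`, "", "condition")), c("FT", "VT"))

  # full default design: 2 subjects x 2 conditions x 20 sessions
  d <- sim_design()
  expect_equal(d$subjects_per_condition * 2L * d$sessions_per_subject, 80L)
  expect_equal(d$duration / 0.2 + 1, 6001)

  # distinct child seeds give distinct trajectories
  expect_false(identical(sess[[1]]$trajectory$x, sess[[2]]$trajectory$x))
  expect_false(identical(sess[[1]]$trajectory$x, sess[[3]]$trajectory$x))

  # byte-identical corpora from the same master seed
  again <- simulate_experiment1(sim_design(subjects_per_condition = 1L,
                                           sessions_per_subject = 2L,
                                           duration = 60, seed = 3))
  expect_identical(lapply(sess, function(s) s$trajectory$x),
                   lapply(again, function(s) s$trajectory$x))
  expect_identical(lapply(sess, function(s) as.data.frame(s$events)),
                   lapply(again, function(s) as.data.frame(s$events)))
})

test_that("the deprivation corpus carries condition and sequence metadata", {
  sess <- simulate_experiment2(sim_design(subjects_per_condition = 1L,
                                          sessions_per_subject = 2L,
                                          duration = 60, seed = 4))
  expect_length(sess, 8L)  # 2 subjects x 2 deprivations x 2 sessions
  conds <- vapply(sess, `[[`, "", "condition")
  seqs <- vapply(sess, function(s) as.character(s$sequence), "")
  expect_setequal(unique(conds), c("FD", "WD"))
  expect_setequal(unique(seqs), c("1", "2"))
  # sequence 1 runs WD first, sequence 2 FD first
  first_sessions <- vapply(sess, `[[`, 0L, "session_number") == 1L
  expect_true(all(conds[first_sessions & seqs == "1"] == "WD"))
  expect_true(all(conds[first_sessions & seqs == "2"] == "FD"))

  # default design: 6 subjects x 2 deprivations x 3 sessions = 36 sessions,
  # 9001 samples per 30-min trajectory
  d <- sim_design(subjects_per_condition = 3L, sessions_per_subject = 3L,
                  duration = 1800)
  expect_equal(2L * d$subjects_per_condition * 2L * d$sessions_per_subject, 36L)
  expect_equal(d$duration / 0.2 + 1, 9001)
})

test_that("extending a design never reshuffles earlier sessions", {
  short <- simulate_experiment1(sim_design(subjects_per_condition = 1L,
                                           sessions_per_subject = 1L,
                                           duration = 60, seed = 9))
  long <- simulate_experiment1(sim_design(subjects_per_condition = 1L,
                                          sessions_per_subject = 2L,
                                          duration = 60, seed = 9))
  expect_identical(short[[1]]$trajectory$x, long[[1]]$trajectory$x)
})

test_that("schedule conditions produce the expected directional contrasts", {
  # scaled-down replicate corpora: direction of the condition means
  reps <- lapply(1:3, function(r)
    simulate_experiment1(sim_design(subjects_per_condition = 1L,
                                    sessions_per_subject = 4L,
                                    duration = 600, seed = 100 + r)))
  diffs <- vapply(reps, function(sess) {
    ft <- assemble_exp1(sess)
    df <- as.data.frame(ft)
    m <- function(f, cond) mean(df[[f]][df$condition == cond], na.rm = TRUE)
    c(dist = m("traveled_distance", "FT") - m("traveled_distance", "VT"),
      ent = m("entropy", "FT") - m("entropy", "VT"),
      div = m("divergence", "VT") - m("divergence", "FT"))
  }, numeric(3))
  expect_true(all(colMeans(t(diffs) > 0) == 1))
})
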