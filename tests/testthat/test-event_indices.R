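test_that("coincidence index counts in-radius presence during windows", {
  a <- square_arena()
  n <- 200  # 40 s at 5 Hz
  deliveries <- event_log_df(c(5, 15, 25, 35), "delivery",
                             "dispenser", a)

  pinned <- make_traj(rep(50, n), rep(50, n))
  expect_equal(coincidence_index(pinned, deliveries, a, "dispenser"), 1.0)

  far <- make_traj(rep(0, n), rep(0, n))
  expect_equal(coincidence_index(far, deliveries, a, "dispenser"), 0.0)

  # at the dispenser only during windows 1 and 3: fraction 0.5, confirmed
  # by brute-force window enumeration
  t <- (seq_len(n) - 1) * 0.2
  x <- ifelse((t >= 5 & t <= 8) | (t >= 25 & t <= 28), 50, 0)
  traj <- make_traj(x, x)
  expect_equal(coincidence_index(traj, deliveries, a, "dispenser"), 0.5)
  brute <- mean(vapply(deliveries$t, function(on) {
    any(t >= on & t <= on + 3 &
          sqrt((x - 50)^2 + (x - 50)^2) <= 10)
  }, NA))
  expect_equal(coincidence_index(traj, deliveries, a, "dispenser"), brute)

  # no deliveries -> undefined, not zero
  none <- event_log_df(numeric(), character(), character(), a)
  expect_true(is.na(coincidence_index(pinned, none, a, "dispenser")))

  # radius >= arena diagonal covers every window
  expect_equal(coincidence_index(far, deliveries, a, "dispenser",
                                 radius = 150), 1.0)

  # onset-only reading is available and no larger than the window reading
  expect_lte(coincidence_index(traj, deliveries, a, "dispenser",
                               at_onset_only = TRUE),
             coincidence_index(traj, deliveries, a, "dispenser"))
})

test_that("intensity index normalizes by the subject-dispenser maximum", {
  expect_equal(intensity_index(c(2, 4, 8)), c(0.25, 0.5, 1.0))
  set.seed(8)
  counts <- rpois(10, 20)
  expect_equal(max(intensity_index(counts)), 1.0)
  expect_warning(res <- intensity_index(c(0, 0, 0)), "undefined")
  expect_true(all(is.na(res)))
})

test_that("precision index is the in-window fraction of entries", {
  a <- square_arena()
  del_t <- c(10, 40, 70)
  # 12 entries, exactly 3 inside [delivery, delivery + 3]
  ent_t <- c(10.5, 41, 72.5, seq(100, 260, length.out = 9))
  ev <- event_log_df(c(del_t, ent_t),
                     c(rep("delivery", 3), rep("head_entry", 12)),
                     "dispenser", a)
  expect_equal(precision_index(ev, "dispenser"), 3 / 12)
  brute <- mean(vapply(ent_t, function(t0) any(t0 >= del_t & t0 <= del_t + 3), NA))
  expect_equal(precision_index(ev, "dispenser"), brute)

  all_in <- event_log_df(c(10, 10.5, 11), c("delivery", rep("head_entry", 2)),
                         "dispenser", a)
  expect_equal(precision_index(all_in, "dispenser"), 1.0)

  no_entries <- event_log_df(10, "delivery", "dispenser", a)
  expect_true(is.na(precision_index(no_entries, "dispenser")))

  # monotone non-decreasing in the window length
  expect_lte(precision_index(ev, "dispenser", window = 1),
             precision_index(ev, "dispenser", window = 3))
  expect_lte(precision_index(ev, "dispenser", window = 3),
             precision_index(ev, "dispenser", window = 10))
})

test_that("proportion contacted pairs deliveries with same-dispenser entries", {
  a <- two_dispenser_arena()
  del_t <- seq(30, 1200, by = 30)  # 40 deliveries
  contacted <- del_t[seq(1, 40, by = 4)] + 1  # 10 contacted
  ev <- event_log_df(c(del_t, contacted, 500.5),
                     c(rep("delivery", 40), rep("head_entry", 10), "head_entry"),
                     c(rep("food", 50), "water"), a)
  expect_equal(proportion_contacted(ev, "food"), 0.25)
  # the cross-dispenser entry never counts
  expect_equal(proportion_contacted(ev, "water"), NA_real_)

  every <- event_log_df(c(10, 11, 40, 41), rep(c("delivery", "head_entry"), 2),
                        "food", a)
  expect_equal(proportion_contacted(every, "food"), 1.0)
  no_ent <- event_log_df(10, "delivery", "food", a)
  expect_equal(proportion_contacted(no_ent, "food"), 0.0)
})

test_that("percentile filter drops strictly-below-threshold values", {
  mask <- percentile_filter(1:20, p = 5)
  expect_identical(which(!mask), 1L)    # threshold 1.95 drops only the 1
  expect_equal(sum(mask), 19L)

  expect_true(all(percentile_filter(rep(3, 10))))
  expect_true(percentile_filter(42))

  # never removes the maximum; retains at least ceil(0.95 n) - 1
  set.seed(10)
  for (i in 1:20) {
    v <- rnorm(sample(3:50, 1))
    m <- percentile_filter(v, p = 5)
    expect_true(m[which.max(v)])
    expect_gte(sum(m), ceiling(0.95 * length(v)) - 1)
  }
})
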