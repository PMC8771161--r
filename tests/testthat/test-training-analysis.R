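test_that("session summary computes the correct-response proportion", {
  # 79 correct of 80 trials
  results <- c(replicate(79, make_result("CORRECT_ALERT"),
                         simplify = FALSE),
               list(make_result("FALSE_ALERT")))
  s <- session_summary(results)
  expect_equal(s$proportion_correct, 0.9875)
  expect_equal(s$n_trials, 80L)

  # all-clears on blanks count as correct
  mix <- c(replicate(36, make_result("CORRECT_ALERT"), simplify = FALSE),
           replicate(4, make_result("ALL_CLEAR_CORRECT"),
                     simplify = FALSE))
  expect_equal(session_summary(mix)$proportion_correct, 1.0)

  all_to <- replicate(10, make_result("TIMEOUT", latency_ms = NA_integer_),
                      simplify = FALSE)
  sto <- session_summary(all_to)
  expect_equal(sto$proportion_correct, 0)
  expect_equal(sto$proportion_timeout, 1)
  expect_true(is.na(sto$mean_latency_ms))

  expect_error(session_summary(list()), "empty")
})

test_that("outcome proportions always partition the session", {
  set.seed(12)
  classes <- c("CORRECT_ALERT", "FALSE_ALERT", "ALL_CLEAR_CORRECT",
               "MISS", "TIMEOUT")
  for (i in 1:20) {
    resp <- sample(classes, sample(5:60, 1), replace = TRUE)
    s <- session_summary(lapply(resp, make_result))
    expect_equal(s$proportion_correct + s$proportion_false_alert +
                   s$proportion_miss + s$proportion_timeout, 1)
  }
})

test_that("daily performance averages the day's sessions unweighted", {
  two <- daily_performance(list(0.90, 0.80), c("d1", "d1"))
  expect_equal(two$proportion_correct, 0.85)
  one <- daily_performance(list(0.925), "d1")
  expect_equal(one$proportion_correct, 0.925)
  three <- daily_performance(list(0.9, 0.8, 0.7), rep("d1", 3))
  expect_equal(three$proportion_correct, 0.8)
  multi <- daily_performance(list(0.9, 0.8, 1.0), c("d1", "d1", "d2"))
  expect_equal(multi$proportion_correct, c(0.85, 1.0))
  expect_equal(multi$date, c("d1", "d2"))
})

test_that("early shaping steps the hold criterion up the ladder", {
  s <- phase_state()   # P1, food, 0.25 s
  s <- advance_training(s, 0.5, independent_ir = TRUE)
  expect_equal(s$hold_criterion_s, 0.5)
  s <- advance_training(s, 0.5, independent_ir = FALSE)
  expect_equal(s$hold_criterion_s, 0.5)   # no independent search, no step
  for (i in 1:5) s <- advance_training(s, 0.5, independent_ir = TRUE)
  expect_equal(s$hold_criterion_s, 2.0)   # capped at 2 s with food
  expect_equal(s$target_channel, "food")
})

test_that("mastering the starter odor switches to the main target at 1 s", {
  s <- phase_state(target_channel = "food", hold_criterion_s = 2.0)
  s2 <- advance_training(s, 0.87)
  expect_equal(s2$target_channel, "main")
  expect_equal(s2$hold_criterion_s, 1.0)
  # sub-criterion day: no switch
  s3 <- advance_training(s, 0.70)
  expect_equal(s3$target_channel, "food")
  expect_equal(s3$hold_criterion_s, 2.0)
})

test_that("the 2-to-4 second climb needs two consecutive sessions to start", {
  s <- phase_state(target_channel = "main", hold_criterion_s = 2.0,
                   consecutive_sessions_at_criterion = 1L)
  s2 <- advance_training(s, 0.90)
  expect_equal(s2$hold_criterion_s, 2.5)
  # thereafter one at-criterion session per step
  s3 <- advance_training(s2, 0.90)
  expect_equal(s3$hold_criterion_s, 3.0)
  # a bad session resets the counter and freezes the criterion
  bad <- advance_training(phase_state(target_channel = "main",
                                      hold_criterion_s = 2.0,
                                      consecutive_sessions_at_criterion = 1L),
                          0.70)
  expect_equal(bad$hold_criterion_s, 2.0)
  expect_equal(bad$consecutive_sessions_at_criterion, 0L)
})

test_that("criterion comparisons use >= 0.85 after 4-decimal rounding", {
  s <- phase_state(target_channel = "main", hold_criterion_s = 3.0)
  expect_equal(advance_training(s, 0.85)$hold_criterion_s, 3.5)
  expect_equal(advance_training(s, 0.84999999)$hold_criterion_s, 3.5)
  expect_equal(advance_training(s, 0.8499)$hold_criterion_s, 3.0)
})

test_that("the criterion never decreases except at the odor transition", {
  set.seed(77)
  s <- phase_state()
  prev <- s$hold_criterion_s
  prev_target <- s$target_channel
  for (i in 1:200) {
    s <- advance_training(s, stats::runif(1),
                          independent_ir = stats::runif(1) < 0.8)
    if (s$target_channel == prev_target)
      expect_gte(s$hold_criterion_s, prev)
    prev <- s$hold_criterion_s
    prev_target <- s$target_channel
  }
})

test_that("a perfect dog completes the progression in the minimal trace", {
  # hand-traced rule sequence: 4 ladder steps to 2 s with food, the
  # switch session, the 1-s transition session, 2 sessions to leave 2 s,
  # 3 more steps to 4 s, one session to exit P1, then 2 sessions in each
  # of P2 and P3 -> trained after 15 sessions
  s <- phase_state()
  n <- 0
  while (!s$trained && n < 50) {
    s <- advance_training(s, 1.0, independent_ir = TRUE)
    n <- n + 1
  }
  expect_true(s$trained)
  expect_equal(n, 15L)

  # the second-cohort protocol skips phase 2: two sessions fewer
  s2 <- phase_state(skip_p2 = TRUE)
  n2 <- 0
  while (!s2$trained && n2 < 50) {
    s2 <- advance_training(s2, 1.0, independent_ir = TRUE)
    n2 <- n2 + 1
  }
  expect_equal(n2, 13L)
  expect_equal(s2$phase, "P3_BLANKS")
})

test_that("operator regression resets the state explicitly", {
  s <- phase_state(phase = "P3_BLANKS", target_channel = "main",
                   hold_criterion_s = 4.0,
                   consecutive_sessions_at_criterion = 1L)
  back <- regress_training(s, to_phase = "P1_ASSIST", to_target = "food",
                           to_criterion = 2.0)
  expect_equal(back$phase, "P1_ASSIST")
  expect_equal(back$target_channel, "food")
  expect_equal(back$consecutive_sessions_at_criterion, 0L)
})

test_that("chance level is one over the number of ports", {
  expect_equal(chance_level(3), 1 / 3)
  expect_equal(chance_level(1), 1.0)
  expect_equal(chance_level(4), 0.25)
  expect_error(chance_level(0))
})
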