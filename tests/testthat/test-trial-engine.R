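test_that("beam events merge into debounced pokes", {
  ev <- beam_events(c(1000, 5200), c(2, 2), c("BREAK", "RESTORE"))
  expect_equal(merge_pokes(ev),
               data.frame(port = 2L, start_ms = 1000L, duration_ms = 4200L))

  # flicker within the debounce gap fuses into one poke spanning the gap
  ev2 <- beam_events(c(1000, 1200, 1250, 1500), rep(0L, 4),
                     c("BREAK", "RESTORE", "BREAK", "RESTORE"))
  expect_equal(merge_pokes(ev2, debounce_gap_ms = 100),
               data.frame(port = 0L, start_ms = 1000L, duration_ms = 500L))
  # the same gap at or above the threshold stays two pokes
  expect_equal(nrow(merge_pokes(ev2, debounce_gap_ms = 50)), 2L)

  expect_equal(nrow(merge_pokes(beam_events())), 0L)

  # unterminated hold is closed at trial end
  ev3 <- beam_events(1000, 1, "BREAK")
  expect_equal(merge_pokes(ev3, trial_end_ms = 3000)$duration_ms, 2000L)

  expect_error(merge_pokes(beam_events(100, 0, "RESTORE")), "malformed")
  expect_error(
    merge_pokes(beam_events(c(100, 200), c(0, 0), c("BREAK", "BREAK"))),
    "alternate")
})

test_that("a criterion hold on the target port scores a rewarded alert", {
  cfg <- p3_config()
  spec <- make_spec(target_port = 2L)
  ev <- events_from_pokes(list(c(0L, 500L, 600L), c(1L, 1400L, 500L),
                               c(2L, 2200L, 4300L)))
  r <- run_trial(spec, ev, cfg)
  expect_equal(r$response, "CORRECT_ALERT")
  expect_true(r$rewarded)
  expect_equal(r$alert_port, 2L)
  expect_equal(r$latency_ms, 500L)
  expect_equal(r$end_ms, 2200L + 4000L)   # fires when the hold reaches 4 s
  expect_equal(r$entries_by_port, c(1L, 1L, 1L))
  # the alert hold is excluded from sniffing time
  expect_equal(sniff_time(r)$cumulative_ms, 600 + 500)
})

test_that("sampling all ports then holding back scores the no-target response", {
  cfg <- p3_config()
  pokes <- list(c(0L, 500L, 800L), c(1L, 1600L, 800L), c(2L, 2700L, 800L))
  blank <- run_trial(make_spec(is_blank = TRUE), events_from_pokes(pokes),
                     cfg)
  expect_equal(blank$response, "ALL_CLEAR_CORRECT")
  expect_false(blank$rewarded)               # all-clears are never fed
  expect_true(is.na(blank$alert_port))
  expect_equal(blank$end_ms, 2700L + 800L + 4000L)
  expect_equal(sniff_time(blank)$cumulative_ms, 2400)

  target <- run_trial(make_spec(target_port = 1L),
                      events_from_pokes(pokes), cfg)
  expect_equal(target$response, "MISS")
  expect_true(is.na(target$alert_port))
})

test_that("a criterion hold on a distractor port terminates phase-2/3 trials", {
  cfg <- session_config(phase = "P2_BLIND", seed = 1)
  spec <- make_spec(target_port = 2L)
  ev <- events_from_pokes(list(c(0L, 500L, 4100L)))
  r <- run_trial(spec, ev, cfg)
  expect_equal(r$response, "FALSE_ALERT")
  expect_false(r$rewarded)
  expect_equal(r$alert_port, 0L)
  expect_equal(r$end_ms, 4500L)
})

test_that("phase 1 logs false holds but keeps the trial alive", {
  cfg <- session_config(phase = "P1_ASSIST", seed = 1)
  spec <- make_spec(target_port = 2L)
  # wrong-port hold first, correct hold later: correct alert wins
  ev <- events_from_pokes(list(c(0L, 500L, 4200L), c(2L, 5000L, 4200L)))
  r <- run_trial(spec, ev, cfg)
  expect_equal(r$response, "CORRECT_ALERT")
  expect_equal(r$n_false_holds_logged, 1L)
  # only false holds: scored as a false alert at handler end
  r2 <- run_trial(spec, events_from_pokes(list(c(1L, 500L, 4200L))), cfg)
  expect_equal(r2$response, "FALSE_ALERT")
  expect_equal(r2$alert_port, 1L)
})

test_that("failing to search all ports within the limit times out", {
  cfg <- p3_config()
  ev <- events_from_pokes(list(c(0L, 1000L, 700L), c(1L, 2500L, 700L)))
  r <- run_trial(make_spec(target_port = 2L), ev, cfg)
  expect_equal(r$response, "TIMEOUT")
  expect_equal(r$end_ms, 45000L)

  # no events at all: timeout with empty counts and undefined latency
  r0 <- run_trial(make_spec(), beam_events(), cfg)
  expect_equal(r0$response, "TIMEOUT")
  expect_equal(r0$entries_by_port, c(0L, 0L, 0L))
  expect_true(is.na(r0$latency_ms))
})

test_that("sniff time sums poke durations minus the alert hold", {
  cfg <- p3_config()
  r <- run_trial(make_spec(target_port = 2L),
                 events_from_pokes(list(c(0L, 300L, 600L),
                                        c(1L, 1100L, 500L),
                                        c(2L, 1800L, 4300L))), cfg)
  st <- sniff_time(r)
  expect_equal(st$cumulative_ms, 1100)
  expect_equal(st$per_port_ms, c(600, 500, 0))
  r0 <- run_trial(make_spec(), beam_events(), cfg)
  expect_equal(sniff_time(r0)$cumulative_ms, 0)
})

test_that("reward and end-of-trial commands appear exactly as required", {
  cfg <- p3_config()
  correct <- run_trial(make_spec(target_port = 0L),
                       events_from_pokes(list(c(0L, 400L, 4200L))), cfg)
  kinds <- correct$hardware_log$kind
  expect_equal(sum(kinds == "FEEDER_PULSE"), 1L)
  expect_equal(sum(kinds == "BEEP"), 1L)
  expect_equal(sum(kinds == "FAN_ON"), 1L)
  expect_equal(sum(kinds == "PANEL_DOWN"), 1L)
  expect_equal(sum(kinds == "VALVE_OPEN"), 3L)
  expect_equal(sum(kinds == "VALVE_CLOSE"), 3L)
  expect_match(correct$hardware_log$payload[kinds == "FAN_ON"], "15s")

  missed <- run_trial(make_spec(target_port = 0L), beam_events(), cfg)
  expect_false(any(missed$hardware_log$kind %in%
                     c("FEEDER_PULSE", "BEEP")))
  expect_equal(sum(missed$hardware_log$kind == "FAN_ON"), 1L)
  # the rendered trace is one command per line
  expect_length(format_hardware_log(correct), nrow(correct$hardware_log))
})

test_that("state machine agrees with a millisecond-stepping rule oracle", {
  configs <- list(
    session_config(phase = "P3_BLANKS", hold_criterion_s = 1,
                   all_clear_window_s = 1.2, timeout_s = 8.123, seed = 1),
    session_config(phase = "P2_BLIND", hold_criterion_s = 1,
                   all_clear_window_s = 1.2, seed = 1),
    session_config(phase = "P1_ASSIST", hold_criterion_s = 1,
                   all_clear_window_s = 1.2, seed = 1))
  set.seed(2024)
  for (case in 1:150) {
    cfg <- configs[[sample(3, 1)]]
    spec <- if (stats::runif(1) < 0.3) make_spec(is_blank = TRUE)
    else make_spec(target_port = sample(0:2, 1))
    pokes <- random_poke_case()
    ev <- events_from_pokes(pokes)
    got <- suppressWarnings(run_trial(spec, ev, cfg, debounce_gap_ms = 0L))
    want <- oracle_classify(spec, ev, cfg)
    expect_equal(got$response, want$response,
                 info = paste("case", case, cfg$phase,
                              paste(unlist(pokes), collapse = ",")))
    expect_equal(got$alert_port, want$alert_port,
                 info = paste("case", case))
  }
})

test_that("every terminating stream maps to exactly one response class", {
  cfg <- p3_config(hold_criterion_s = 1, all_clear_window_s = 1.2,
                   timeout_s = 8.123)
  classes <- c("CORRECT_ALERT", "FALSE_ALERT", "ALL_CLEAR_CORRECT",
               "MISS", "TIMEOUT")
  set.seed(31)
  for (i in 1:120) {
    spec <- if (i %% 4 == 0) make_spec(is_blank = TRUE)
    else make_spec(target_port = sample(0:2, 1))
    r <- suppressWarnings(
      run_trial(spec, events_from_pokes(random_poke_case()), cfg,
                debounce_gap_ms = 0L))
    expect_true(r$response %in% classes)
    expect_length(r$response, 1L)
  }
})

test_that("pokes after the trial resolves are ignored with a warning", {
  cfg <- session_config(phase = "P2_BLIND", seed = 1)
  ev <- events_from_pokes(list(c(0L, 500L, 4100L), c(1L, 9000L, 500L)))
  expect_warning(r <- run_trial(make_spec(target_port = 2L), ev, cfg),
                 "ignored")
  expect_equal(r$response, "FALSE_ALERT")
  expect_equal(r$entries_by_port, c(1L, 0L, 0L))
})

test_that("classification is a pure function of its inputs", {
  cfg <- p3_config()
  spec <- make_spec(target_port = 1L)
  ev <- events_from_pokes(list(c(0L, 500L, 700L), c(1L, 1500L, 4300L)))
  expect_identical(run_trial(spec, ev, cfg), run_trial(spec, ev, cfg))
})
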