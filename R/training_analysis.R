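#' Summarize a session's performance
#'
#' A correct response is an alert to the target port or an all-clear on a
#' blank trial; false alerts include alerts to distractor ports and any
#' alert on a blank trial. The four outcome proportions (correct, false
#' alert, miss, timeout) partition the session. Latency, cumulative sniff
#' time and entry counts are averaged over trials where they are defined
#' (trials with no nose entry contribute no latency).
#'
#' @param results list of `trial_result` (or a `lineup_session`).
#' @return a `session_summary` list: `n_trials`, `proportion_correct`,
#'   `proportion_false_alert`, `proportion_miss`, `proportion_timeout`,
#'   `mean_latency_ms`, `mean_cumulative_sniff_ms`,
#'   `mean_entries_per_trial`.
#' @examples
#' \dontrun{
#' s <- run_simulated_session(agent_params(), session_config(seed = 3))
#' session_summary(s$results)
#' }
#' @export
session_summary <- function(results) {
  if (inherits(results, "lineup_session")) results <- results$results
  if (length(results) == 0L)
    stop("cannot summarize an empty session", call. = FALSE)
  resp <- vapply(results, `[[`, "", "response")
  n <- length(resp)
  correct <- resp %in% c("CORRECT_ALERT", "ALL_CLEAR_CORRECT")
  lat <- vapply(results, `[[`, NA_integer_, "latency_ms")
  sniff <- vapply(results, function(r) sum(r$sniff_ms_by_port), numeric(1))
  entries <- vapply(results, function(r) sum(r$entries_by_port), numeric(1))
  structure(list(
    n_trials = n,
    proportion_correct = mean(correct),
    proportion_false_alert = mean(resp == "FALSE_ALERT"),
    proportion_miss = mean(resp == "MISS"),
    proportion_timeout = mean(resp == "TIMEOUT"),
    mean_latency_ms = if (all(is.na(lat))) NA_real_ else
      mean(lat, na.rm = TRUE),
    mean_cumulative_sniff_ms = mean(sniff),
    mean_entries_per_trial = mean(entries)
  ), class = "session_summary")
}

#' @export
print.session_summary <- function(x, ...) {
  cat(sprintf("Session summary over %d trials:\n", x$n_trials))
  cat(sprintf("  correct %.2f%% | false alert %.2f%% | miss %.2f%% | timeout %.2f%%\n",
              100 * x$proportion_correct, 100 * x$proportion_false_alert,
              100 * x$proportion_miss, 100 * x$proportion_timeout))
  cat(sprintf("  mean latency %.0f ms, mean cumulative sniff %.0f ms, mean entries %.2f\n",
              x$mean_latency_ms, x$mean_cumulative_sniff_ms,
              x$mean_entries_per_trial))
  invisible(x)
}

#' Daily performance from per-session summaries
#'
#' Dogs may receive one or two sessions per day; daily performance is the
#' unweighted mean of that day's session proportions (a single session
#' passes through unchanged; more than two sessions extend the same rule).
#'
#' @param summaries list of `session_summary` (or bare numerics giving
#'   proportion correct).
#' @param dates vector (same length) of dates/labels grouping sessions
#'   into days.
#' @return data frame with `date` and `proportion_correct`, one row per
#'   day, in first-appearance order.
#' @export
daily_performance <- function(summaries, dates) {
  props <- vapply(summaries, function(s)
    if (is.numeric(s)) s else s$proportion_correct, numeric(1))
  stopifnot(length(props) == length(dates))
  dates <- as.character(dates)
  days <- unique(dates)
  data.frame(
    date = days,
    proportion_correct = vapply(days, function(d)
      mean(props[dates == d]), numeric(1)),
    row.names = NULL, stringsAsFactors = FALSE)
}

criterion_ladder <- function() c(0.25, seq(0.5, 4, by = 0.5))

#' Training phase state
#'
#' Tracks where a dog is in the shaping progression: the current phase,
#' whether the target is still the biologically interesting starter odor
#' (`"food"`) or the main target odor (`"main"`), the nose-hold criterion
#' (on the ladder 0.25 s then 0.5-s steps to 4 s), and the count of
#' consecutive sessions at or above the 85% accuracy criterion.
#'
#' @param phase `"P1_ASSIST"`, `"P2_BLIND"` or `"P3_BLANKS"`.
#' @param target_channel `"food"` or `"main"`.
#' @param hold_criterion_s current criterion, a ladder value.
#' @param consecutive_sessions_at_criterion running count of >=85%
#'   sessions.
#' @param skip_p2 advance P1 directly to P3 (the second-cohort protocol).
#' @param trained set once the phase-3 exit criterion is met.
#' @return a `phase_state` list.
#' @export
phase_state <- function(phase = "P1_ASSIST", target_channel = "food",
                        hold_criterion_s = 0.25,
                        consecutive_sessions_at_criterion = 0L,
                        skip_p2 = FALSE, trained = FALSE) {
  stopifnot(phase %in% c("P1_ASSIST", "P2_BLIND", "P3_BLANKS"),
            target_channel %in% c("food", "main"),
            hold_criterion_s %in% criterion_ladder())
  structure(list(phase = phase, target_channel = target_channel,
                 hold_criterion_s = hold_criterion_s,
                 consecutive_sessions_at_criterion =
                   as.integer(consecutive_sessions_at_criterion),
                 assist_mode = phase == "P1_ASSIST",
                 skip_p2 = skip_p2, trained = trained),
            class = "phase_state")
}

#' @export
print.phase_state <- function(x, ...) {
  cat(sprintf("Phase %s | target %s | hold %.2g s | %d consecutive session(s) at criterion%s\n",
              x$phase, x$target_channel, x$hold_criterion_s,
              x$consecutive_sessions_at_criterion,
              if (x$trained) " | TRAINED" else ""))
  invisible(x)
}

at_criterion <- function(performance) round(performance, 4) >= 0.85

#' Advance the training progression after a session or day
#'
#' Applies the shaping rules: (a) during early phase-1 training with the
#' starter odor, the hold criterion steps up the ladder after every
#' session in which the dog independently activated the IR beams, up to
#' 2 s; (b) at 2 s with the starter odor, a daily performance of at least
#' 85% switches the target to the main odor with the criterion dropped to
#' 1 s for the transition session (it returns to 2 s afterwards); (c) with
#' the main odor at 2 s, two consecutive sessions at or above 85% start
#' the climb from 2 to 4 s in 0.5-s steps, one step per subsequent
#' at-criterion session; (d) at 4 s and at criterion, the dog advances
#' phase (P1 to P2, or directly to P3 with `skip_p2`; P2 and P3 each exit
#' after two consecutive at-criterion sessions); (e) any sub-criterion
#' session resets the consecutive counter and changes nothing else —
#' regression to an earlier phase is an operator decision
#' ([regress_training()]), never automatic.
#'
#' "At criterion" means performance >= 0.85 after rounding to 4 decimals.
#' The criterion never decreases except at the single starter-to-main
#' transition.
#'
#' @param state a [phase_state()].
#' @param performance the session (or daily) proportion correct in
#'   `[0, 1]`.
#' @param independent_ir did the dog search and trigger the beams without
#'   handler assistance this session? (gates the early criterion steps).
#' @return the updated `phase_state`.
#' @export
advance_training <- function(state, performance, independent_ir = TRUE) {
  stopifnot(inherits(state, "phase_state"))
  ladder <- criterion_ladder()
  s <- state
  if (s$trained) return(s)

  step_up <- function(cur, cap = 4) {
    nxt <- ladder[ladder > cur & ladder <= cap]
    if (length(nxt)) nxt[1] else cur
  }

  if (s$phase == "P1_ASSIST") {
    if (s$target_channel == "food") {
      if (s$hold_criterion_s < 2) {
        if (independent_ir)
          s$hold_criterion_s <- step_up(s$hold_criterion_s, cap = 2)
      } else if (at_criterion(performance)) {
        # starter odor mastered: switch to the main target, drop to 1 s
        s$target_channel <- "main"
        s$hold_criterion_s <- 1.0
        s$consecutive_sessions_at_criterion <- 0L
      }
      return(s)
    }
    # main odor
    if (s$hold_criterion_s == 1.0) {
      # transition session over: restore the 2-s criterion
      s$hold_criterion_s <- 2.0
      s$consecutive_sessions_at_criterion <-
        if (at_criterion(performance)) 1L else 0L
      return(s)
    }
    if (!at_criterion(performance)) {
      s$consecutive_sessions_at_criterion <- 0L
      return(s)
    }
    if (s$hold_criterion_s == 2.0) {
      s$consecutive_sessions_at_criterion <-
        s$consecutive_sessions_at_criterion + 1L
      if (s$consecutive_sessions_at_criterion >= 2L) {
        s$hold_criterion_s <- 2.5
        s$consecutive_sessions_at_criterion <- 0L
      }
    } else if (s$hold_criterion_s < 4.0) {
      s$hold_criterion_s <- step_up(s$hold_criterion_s)
    } else {
      s$phase <- if (s$skip_p2) "P3_BLANKS" else "P2_BLIND"
      s$assist_mode <- FALSE
      s$consecutive_sessions_at_criterion <- 0L
    }
    return(s)
  }

  # P2 / P3: two consecutive at-criterion sessions advance/finish
  if (!at_criterion(performance)) {
    s$consecutive_sessions_at_criterion <- 0L
    return(s)
  }
  s$consecutive_sessions_at_criterion <-
    s$consecutive_sessions_at_criterion + 1L
  if (s$consecutive_sessions_at_criterion >= 2L) {
    if (s$phase == "P2_BLIND") {
      s$phase <- "P3_BLANKS"
      s$consecutive_sessions_at_criterion <- 0L
    } else {
      s$trained <- TRUE
    }
  }
  s
}

#' Operator-initiated regression to an earlier training level
#'
#' Returning a dog to an earlier phase or to the starter odor is a
#' trainer judgment call (motivation drops, persistent poor performance),
#' so it is an explicit command rather than part of the automatic rules.
#'
#' @param state a [phase_state()].
#' @param to_phase,to_target,to_criterion the level to return to.
#' @return the updated `phase_state`, counter reset.
#' @export
regress_training <- function(state, to_phase = state$phase,
                             to_target = state$target_channel,
                             to_criterion = state$hold_criterion_s) {
  phase_state(phase = to_phase, target_channel = to_target,
              hold_criterion_s = to_criterion,
              consecutive_sessions_at_criterion = 0L,
              skip_p2 = state$skip_p2, trained = FALSE)
}

#' Chance-level proportion correct
#'
#' With one target among `n_ports` equivalent ports, an odor-blind
#' alerting strategy is correct with probability `1/n_ports` (33% on the
#' three-port line-up).
#'
#' @param n_ports number of ports (>= 1).
#' @return `1 / n_ports`.
#' @export
chance_level <- function(n_ports) {
  if (n_ports < 1) stop("n_ports must be >= 1", call. = FALSE)
  1 / n_ports
}

#' Export session summaries as a CSV table
#' @param summaries list of `session_summary`.
#' @param path output file.
#' @param labels optional row labels (e.g. dog or date).
#' @export
write_summary_csv <- function(summaries, path, labels = NULL) {
  df <- do.call(rbind, lapply(summaries, function(s)
    as.data.frame(unclass(s))))
  if (!is.null(labels)) df <- cbind(label = labels, df)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Plot daily training performance
#'
#' Proportion of correct responses by training day with reference lines
#' at chance (1/3, dashed) and the 85% training criterion (solid), in the
#' style of the standard training-progression panels. Optionally add
#' false-alert / miss / timeout series.
#'
#' @param daily data frame from [daily_performance()], or one with extra
#'   proportion columns.
#' @param main plot title.
#' @export
plot_training_progress <- function(daily, main = "Training progression") {
  n <- nrow(daily)
  graphics::plot(seq_len(n), daily$proportion_correct, type = "b",
                 pch = 16, ylim = c(0, 1), xlab = "Training day",
                 ylab = "Proportion correct", main = main)
  graphics::abline(h = chance_level(3), lty = 2)
  graphics::abline(h = 0.85, lty = 1, col = "grey40")
  invisible(daily)
}
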