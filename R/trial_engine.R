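#' Beam event streams
#'
#' A beam event stream is a data frame with columns `t_ms` (integer
#' milliseconds from panel-raise), `port` (0-based port id) and `kind`
#' (`"BREAK"` or `"RESTORE"`). Events on one port must alternate
#' BREAK/RESTORE and `t_ms` must be non-decreasing.
#'
#' @param t_ms event times in ms from trial start.
#' @param port 0-based port ids.
#' @param kind `"BREAK"` or `"RESTORE"` per event.
#' @return a `beam_events` data frame.
#' @export
beam_events <- function(t_ms = integer(0), port = integer(0),
                        kind = character(0)) {
  ev <- data.frame(t_ms = as.integer(t_ms), port = as.integer(port),
                   kind = as.character(kind), stringsAsFactors = FALSE)
  if (nrow(ev) && is.unsorted(ev$t_ms))
    stop("beam events must have non-decreasing t_ms", call. = FALSE)
  bad <- setdiff(unique(ev$kind), c("BREAK", "RESTORE"))
  if (length(bad))
    stop("unknown beam event kind: ", paste(bad, collapse = ", "),
         call. = FALSE)
  class(ev) <- c("beam_events", "data.frame")
  ev
}

#' Read/write beam event streams as CSV
#' @param events a `beam_events` data frame.
#' @param path file path.
#' @export
write_events_csv <- function(events, path) {
  utils::write.csv(as.data.frame(events)[c("t_ms", "port", "kind")], path,
                   row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_events_csv
#' @export
read_events_csv <- function(path) {
  ev <- utils::read.csv(path, stringsAsFactors = FALSE)
  missing <- setdiff(c("t_ms", "port", "kind"), names(ev))
  if (length(missing))
    stop("event file missing column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  beam_events(ev$t_ms, ev$port, ev$kind)
}

#' Merge beam events into nose pokes
#'
#' Pairs BREAK/RESTORE events per port into poke intervals and merges
#' consecutive pokes on the same port separated by less than
#' `debounce_gap_ms` (IR sensors flicker at entry/exit); a merged poke
#' spans first BREAK to last RESTORE, gap included. An unterminated BREAK
#' is closed at `trial_end_ms` (default: the last event time).
#'
#' @param events a `beam_events` stream.
#' @param debounce_gap_ms gaps shorter than this merge into one poke.
#' @param trial_end_ms timestamp used to close an unterminated poke.
#' @return data frame of pokes (`port`, `start_ms`, `duration_ms`) in
#'   start order; zero rows for an empty stream.
#' @examples
#' ev <- beam_events(c(1000, 1200, 1250, 1500), c(2, 2, 2, 2),
#'                   c("BREAK", "RESTORE", "BREAK", "RESTORE"))
#' merge_pokes(ev)   # one poke: port 2, 1000 ms, 500 ms
#' @export
merge_pokes <- function(events, debounce_gap_ms = 100L,
                        trial_end_ms = NULL) {
  if (!nrow(events))
    return(data.frame(port = integer(0), start_ms = integer(0),
                      duration_ms = integer(0)))
  if (is.null(trial_end_ms)) trial_end_ms <- max(events$t_ms)
  pokes <- do.call(rbind, lapply(split(events, events$port), function(pe) {
    kinds <- pe$kind
    breaks <- which(kinds == "BREAK")
    restores <- which(kinds == "RESTORE")
    if (length(restores) && (!length(breaks) || restores[1] < breaks[1]))
      stop("malformed stream: RESTORE without prior BREAK on port ",
           pe$port[1], call. = FALSE)
    if (any(kinds[seq_along(kinds)] != rep_len(c("BREAK", "RESTORE"),
                                               length(kinds))))
      stop("malformed stream: events on port ", pe$port[1],
           " do not alternate BREAK/RESTORE", call. = FALSE)
    starts <- pe$t_ms[breaks]
    ends <- if (length(restores) < length(breaks))
      c(pe$t_ms[restores], max(trial_end_ms, pe$t_ms[length(kinds)]))
    else pe$t_ms[restores]
    # debounce: merge intervals whose gap to the previous end is short
    keep_start <- c(TRUE, (starts[-1] - ends[-length(ends)]) >= debounce_gap_ms)
    grp <- cumsum(keep_start)
    data.frame(port = pe$port[1],
               start_ms = as.integer(tapply(starts, grp, min)),
               duration_ms = as.integer(tapply(ends, grp, max) -
                                        tapply(starts, grp, min)))
  }))
  pokes <- pokes[pokes$duration_ms > 0L, , drop = FALSE]
  pokes <- pokes[order(pokes$start_ms, pokes$port), , drop = FALSE]
  rownames(pokes) <- NULL
  pokes
}

#' Run one trial through the response state machine
#'
#' Classifies a beam event stream against a trial's odor assignment under
#' the phase rules. The first continuous nose hold to reach the criterion
#' duration fires at the instant the criterion is reached: on the target
#' port it scores a correct alert (beep + feeder pulse); on any other port
#' it is a false alert — logged but non-terminal in phase 1 (the handler
#' assists until a correct response), terminal and unrewarded in phases
#' 2–3. Once all three ports have been sampled, a window of
#' `all_clear_window_s` with no beam activity (measured from the last
#' RESTORE, restarted by any BREAK) scores an all-clear: correct on blank
#' trials, a miss when a target was present. If the timeout elapses before
#' all three ports are sampled, the trial times out.
#'
#' @param spec one row of a `session_plan` (a list/data.frame row with
#'   `is_blank`, `target_port`, `channel_port1..3`).
#' @param events a `beam_events` stream for the trial.
#' @param config the session's [session_config()].
#' @param debounce_gap_ms passed to [merge_pokes()].
#' @return a `trial_result`: list with `response` (one of
#'   `"CORRECT_ALERT"`, `"FALSE_ALERT"`, `"ALL_CLEAR_CORRECT"`, `"MISS"`,
#'   `"TIMEOUT"`), `alert_port`, `latency_ms`, `entries_by_port`,
#'   `sniff_ms_by_port` (alert hold excluded), `pokes`, `rewarded`,
#'   `end_ms` and `hardware_log`.
#' @export
run_trial <- function(spec, events, config, debounce_gap_ms = 100L) {
  spec <- as.list(spec)
  criterion_ms <- as.integer(round(config$hold_criterion_s * 1000))
  window_ms <- as.integer(round(config$all_clear_window_s * 1000))
  timeout_ms <- if (is.na(config$timeout_s)) NA_integer_ else
    as.integer(round(config$timeout_s * 1000))
  horizon <- max(if (nrow(events)) max(events$t_ms) else 0L,
                 timeout_ms, na.rm = TRUE)
  pokes <- merge_pokes(events, debounce_gap_ms, trial_end_ms = horizon)
  n_ports <- config$n_ports
  target <- spec$target_port

  # candidate resolution times, earliest wins
  alert_t <- NA_integer_; alert_port <- NA_integer_; p1_false <- NULL
  holds <- which(pokes$duration_ms >= criterion_ms)
  for (i in holds) {
    t_fire <- pokes$start_ms[i] + criterion_ms
    on_target <- !spec$is_blank && pokes$port[i] == target
    if (config$phase == "P1_ASSIST" && !on_target) {
      p1_false <- rbind(p1_false,
                        data.frame(t_ms = t_fire, port = pokes$port[i]))
      next  # assisted phase: false alerts logged, search continues
    }
    alert_t <- t_fire
    alert_port <- pokes$port[i]
    break
  }

  # all-clear: window after last RESTORE once every port has been entered
  clear_t <- NA_integer_
  visited_at <- rep(NA_integer_, n_ports)
  for (i in seq_len(nrow(pokes))) {
    p <- pokes$port[i] + 1L
    if (is.na(visited_at[p])) visited_at[p] <- pokes$start_ms[i]
  }
  if (nrow(pokes) && !anyNA(visited_at)) {
    all_in <- max(visited_at)
    ends <- pokes$start_ms + pokes$duration_ms
    starts_next <- c(pokes$start_ms[-1], NA_integer_)
    for (i in seq_len(nrow(pokes))) {
      if (ends[i] < all_in) next
      if (is.na(starts_next[i]) || starts_next[i] - ends[i] >= window_ms) {
        clear_t <- ends[i] + window_ms
        break
      }
    }
  }

  # timeout: all ports not yet entered when the clock runs out
  to_t <- NA_integer_
  if (!is.na(timeout_ms)) {
    entered_by_timeout <- unique(pokes$port[pokes$start_ms < timeout_ms])
    if (length(entered_by_timeout) < n_ports) to_t <- timeout_ms
  }

  cand <- c(alert = alert_t, clear = clear_t, timeout = to_t)
  if (all(is.na(cand))) {
    # stream ended unresolved (e.g. no events and no timeout configured):
    # the operator ends the trial; score it as a timeout at the horizon
    cand["timeout"] <- horizon
  }
  winner <- names(which.min(cand))
  end_ms <- as.integer(min(cand, na.rm = TRUE))

  if (winner == "alert") {
    response <- if (!spec$is_blank && alert_port == target)
      "CORRECT_ALERT" else "FALSE_ALERT"
  } else if (winner == "clear") {
    response <- if (spec$is_blank) "ALL_CLEAR_CORRECT" else "MISS"
    alert_port <- NA_integer_
  } else {
    response <- "TIMEOUT"
    alert_port <- NA_integer_
  }
  if (is.na(alert_t) && !is.null(p1_false)) {
    # phase-1 session that ended with only false holds
    response <- "FALSE_ALERT"
    alert_port <- p1_false$port[1]
    end_ms <- as.integer(max(end_ms, p1_false$t_ms[1]))
  }
  rewarded <- response == "CORRECT_ALERT"

  dropped <- pokes$start_ms >= end_ms
  if (any(dropped)) {
    warning(sum(dropped), " poke(s) after trial end ignored")
    pokes <- pokes[!dropped, , drop = FALSE]
  }

  entries <- tabulate(pokes$port + 1L, nbins = n_ports)
  sniff <- vapply(seq_len(n_ports) - 1L, function(p)
    sum(pokes$duration_ms[pokes$port == p]), numeric(1))
  if (response %in% c("CORRECT_ALERT", "FALSE_ALERT") && !is.na(alert_port)) {
    ap <- pokes$port == alert_port & pokes$duration_ms >= criterion_ms
    if (any(ap)) {
      i <- which(ap)[1]
      sniff[alert_port + 1L] <- sniff[alert_port + 1L] - pokes$duration_ms[i]
    }
  }

  log <- hardware_log_for_trial(spec, config, response, end_ms)
  structure(list(
    response = response,
    alert_port = if (response %in% c("CORRECT_ALERT", "FALSE_ALERT"))
      alert_port else NA_integer_,
    latency_ms = if (nrow(pokes)) min(pokes$start_ms) else NA_integer_,
    entries_by_port = as.integer(entries),
    sniff_ms_by_port = as.numeric(sniff),
    pokes = pokes,
    rewarded = rewarded,
    end_ms = end_ms,
    n_false_holds_logged = if (is.null(p1_false)) 0L else nrow(p1_false),
    hardware_log = log
  ), class = "trial_result")
}

# ordered command trace: valves open at panel-raise, reward on correct,
# valves closed + panel down + fan at trial end
hardware_log_for_trial <- function(spec, config, response, end_ms) {
  chans <- unlist(spec[paste0("channel_port", 1:3)], use.names = FALSE)
  log <- data.frame(
    t_ms = c(0L, rep(0L, 3)),
    kind = c("PANEL_UP", rep("VALVE_OPEN", 3)),
    payload = c("", paste0("olf", 1:3, ":", chans)),
    stringsAsFactors = FALSE)
  if (response == "CORRECT_ALERT")
    log <- rbind(log, data.frame(t_ms = end_ms,
                                 kind = c("BEEP", "FEEDER_PULSE"),
                                 payload = c("", "")))
  log <- rbind(log, data.frame(
    t_ms = end_ms,
    kind = c(rep("VALVE_CLOSE", 3), "PANEL_DOWN", "FAN_ON"),
    payload = c(paste0("olf", 1:3, ":", chans), "",
                sprintf("%gs", config$iti_fan_s))))
  log
}

#' @export
print.trial_result <- function(x, ...) {
  cat(sprintf("Trial result: %s%s%s\n", x$response,
              if (!is.na(x$alert_port))
                sprintf(" at port %d", x$alert_port + 1L) else "",
              if (x$rewarded) " (rewarded)" else ""))
  cat(sprintf("  latency %s ms, entries %s, sniff %s ms\n",
              ifelse(is.na(x$latency_ms), "-", x$latency_ms),
              paste(x$entries_by_port, collapse = "/"),
              paste(round(x$sniff_ms_by_port), collapse = "/")))
  invisible(x)
}

#' Sniffing time per port and cumulative
#'
#' Sums poke durations per port, excluding the criterion hold that
#' triggered an alert (the alert hold is a response, not search).
#'
#' @param result a `trial_result`.
#' @return list with `per_port_ms` (length-3 numeric) and `cumulative_ms`.
#' @export
sniff_time <- function(result) {
  stopifnot(inherits(result, "trial_result"))
  list(per_port_ms = result$sniff_ms_by_port,
       cumulative_ms = sum(result$sniff_ms_by_port))
}

#' Render a hardware log as a text command trace
#' @param result a `trial_result`.
#' @return character vector, one command per line.
#' @export
format_hardware_log <- function(result) {
  log <- result$hardware_log
  trimws(sprintf("%7d %s %s", log$t_ms, log$kind, log$payload))
}
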