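# shared fixtures: hand-built specs, event streams and results

p3_config <- function(seed = 1L, ...) {
  session_config(seed = seed, phase = "P3_BLANKS", ...)
}

# a target trial spec without going through the scheduler
make_spec <- function(target_port = 2L, is_blank = FALSE,
                      channels = c("gauze", "glove", "smokeless_powder")) {
  if (is_blank) target_port <- NA_integer_
  list(trial_index = 0L, is_blank = is_blank, target_port = target_port,
       channel_port1 = channels[1], channel_port2 = channels[2],
       channel_port3 = channels[3])
}

# events for a sequence of non-overlapping pokes: matrix-ish list of
# (port, start_ms, duration_ms)
events_from_pokes <- function(pokes) {
  ev <- do.call(rbind, lapply(pokes, function(p)
    data.frame(t_ms = c(p[2], p[2] + p[3]), port = p[1],
               kind = c("BREAK", "RESTORE"))))
  ev <- ev[order(ev$t_ms), ]
  beam_events(ev$t_ms, ev$port, ev$kind)
}

# minimal classified result for summary-level tests
make_result <- function(response, latency_ms = 1000L,
                        sniff = c(300, 300, 300),
                        entries = c(1L, 1L, 1L)) {
  structure(list(response = response,
                 alert_port = if (response %in%
                                  c("CORRECT_ALERT", "FALSE_ALERT"))
                   0L else NA_integer_,
                 latency_ms = latency_ms,
                 entries_by_port = entries,
                 sniff_ms_by_port = sniff,
                 pokes = data.frame(port = integer(0), start_ms = integer(0),
                                    duration_ms = integer(0)),
                 rewarded = response == "CORRECT_ALERT",
                 end_ms = 10000L,
                 hardware_log = NULL),
            class = "trial_result")
}

# independent millisecond-stepping classifier: walks the raw event stream
# one ms at a time applying the response rules directly; used as the
# brute-force oracle against the interval-based state machine
oracle_classify <- function(spec, events, config) {
  crit <- round(config$hold_criterion_s * 1000)
  window <- round(config$all_clear_window_s * 1000)
  timeout <- if (is.na(config$timeout_s)) NA else
    round(config$timeout_s * 1000)
  horizon <- max(c(events$t_ms, timeout, 0), na.rm = TRUE) + window + 1
  broken <- rep(FALSE, 3); hold_start <- rep(NA_real_, 3)
  hold_spent <- rep(FALSE, 3)
  visited <- rep(FALSE, 3); last_restore <- NA_real_
  p1_false_port <- NA_integer_
  for (t in 0:horizon) {
    # rules first, using the state just before this instant's events:
    # a hold reaching criterion exactly as the nose leaves still fires
    for (p in which(broken)) {
      if (!hold_spent[p] && t - hold_start[p] >= crit) {
        on_target <- !spec$is_blank && (p - 1) == spec$target_port
        if (on_target)
          return(list(response = "CORRECT_ALERT", alert_port = p - 1L))
        if (config$phase != "P1_ASSIST")
          return(list(response = "FALSE_ALERT", alert_port = p - 1L))
        hold_spent[p] <- TRUE   # assisted phase: log and keep searching
        if (is.na(p1_false_port)) p1_false_port <- p - 1L
      }
    }
    if (all(visited) && !any(broken) && !is.na(last_restore) &&
        t - last_restore >= window) {
      if (config$phase == "P1_ASSIST" && !is.na(p1_false_port))
        return(list(response = "FALSE_ALERT", alert_port = p1_false_port))
      return(list(
        response = if (spec$is_blank) "ALL_CLEAR_CORRECT" else "MISS",
        alert_port = NA_integer_))
    }
    for (j in which(events$t_ms == t)) {
      p <- events$port[j] + 1
      if (events$kind[j] == "BREAK") {
        broken[p] <- TRUE; hold_start[p] <- t; hold_spent[p] <- FALSE
        visited[p] <- TRUE
      } else {
        broken[p] <- FALSE; last_restore <- t
      }
    }
    if (!is.na(timeout) && t == timeout && !all(visited))
      return(list(response = "TIMEOUT", alert_port = NA_integer_))
  }
  if (config$phase == "P1_ASSIST" && !is.na(p1_false_port))
    return(list(response = "FALSE_ALERT", alert_port = p1_false_port))
  list(response = "TIMEOUT", alert_port = NA_integer_)
}

# random well-formed small stream: 1-3 sequential non-overlapping pokes
random_poke_case <- function() {
  k <- sample(1:3, 1)
  durs <- sample(c(200L, 500L, 1000L, 1400L), k, replace = TRUE)
  ports <- sample(0:2, k, replace = TRUE)
  gaps <- sample(c(150L, 400L, 1500L), k, replace = TRUE)
  start <- 300L
  pokes <- vector("list", k)
  for (i in seq_len(k)) {
    pokes[[i]] <- c(ports[i], start, durs[i])
    start <- start + durs[i] + gaps[i]
  }
  pokes
}
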