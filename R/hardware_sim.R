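#' Virtual-dog agent parameters
#'
#' The virtual dog is an event-level behavioral stand-in: it emits beam
#' events directly (no spatial model), visiting the three ports with
#' sampled search latency and sniff durations. On the target port, with
#' probability `p_detect`, it produces a criterion-length hold (an alert);
#' on any port it may false-alert with per-port probability
#' `p_false_alert`. When the odor line is unplugged (control sessions) the
#' agent loses access to target identity and only `p_false_alert` operates,
#' mirroring the physical disconnection.
#'
#' Defaults emulate a trained dog at the end of shaping: search latency
#' around 11 s, sub-half-second sniffs per port, high detection
#' probability with rare false alerts.
#'
#' @param p_detect probability of alerting on the target port when odor is
#'   delivered.
#' @param p_false_alert per-port probability of a criterion hold on a
#'   non-target port.
#' @param latency_mean_s,latency_sd_s search-onset delay (s), truncated
#'   normal at 0.2 s.
#' @param sniff_mean_s,sniff_sd_s non-alert poke duration (s), truncated
#'   at 0.05 s.
#' @param visit_policy `"RANDOM_ORDER"` (shuffled each trial) or
#'   `"LEFT_TO_RIGHT"`.
#' @param hold_overshoot_s how far past the criterion an alert hold lasts.
#' @param alert_mode `"probabilistic"` (the p_detect/p_false_alert model)
#'   or `"uniform_random"`: exactly one criterion hold per trial at a
#'   uniformly chosen port, the chance-level reference agent.
#' @return an `agent_params` list.
#' @examples
#' # chance-level reference dog: one alert per trial at a random port
#' chance_dog <- agent_params(alert_mode = "uniform_random")
#' @export
agent_params <- function(p_detect = 0.95,
                         p_false_alert = 0.02,
                         latency_mean_s = 11,
                         latency_sd_s = 2.5,
                         sniff_mean_s = 0.45,
                         sniff_sd_s = 0.15,
                         visit_policy = c("RANDOM_ORDER", "LEFT_TO_RIGHT"),
                         hold_overshoot_s = 0.3,
                         alert_mode = c("probabilistic", "uniform_random")) {
  visit_policy <- match.arg(visit_policy)
  alert_mode <- match.arg(alert_mode)
  stopifnot(p_detect >= 0, p_detect <= 1,
            p_false_alert >= 0, p_false_alert <= 1,
            latency_mean_s > 0, sniff_mean_s > 0, hold_overshoot_s >= 0)
  structure(list(p_detect = p_detect, p_false_alert = p_false_alert,
                 latency_mean_s = latency_mean_s, latency_sd_s = latency_sd_s,
                 sniff_mean_s = sniff_mean_s, sniff_sd_s = sniff_sd_s,
                 visit_policy = visit_policy,
                 hold_overshoot_s = hold_overshoot_s,
                 alert_mode = alert_mode),
            class = "agent_params")
}

rtrunc_norm <- function(n, mean, sd, lower) {
  pmax(stats::rnorm(n, mean, sd), lower)
}

#' Simulate beam events for one trial
#'
#' Emits the beam event stream the virtual dog would produce for a planned
#' trial. The agent visits the ports per its policy; at each port it
#' either sniffs briefly and moves on, or commits a criterion-length hold
#' (per `p_detect` on the target when `odor_connected`, else
#' `p_false_alert`). After visiting every port without alerting it falls
#' silent, so the engine scores an all-clear or miss. Draws come from the
#' current RNG state; seed beforehand for reproducibility.
#'
#' @param agent an [agent_params()].
#' @param spec one planned trial (row of a `session_plan`).
#' @param config the [session_config()].
#' @param odor_connected `FALSE` reproduces the odor-unplugged control
#'   session: the agent cannot smell the target, so target trials behave
#'   like blanks from its point of view.
#' @return a `beam_events` stream.
#' @export
simulate_trial_events <- function(agent, spec, config,
                                  odor_connected = TRUE) {
  spec <- as.list(spec)
  n_ports <- config$n_ports
  criterion_ms <- round(config$hold_criterion_s * 1000)
  order <- if (agent$visit_policy == "LEFT_TO_RIGHT")
    seq_len(n_ports) - 1L else sample(seq_len(n_ports) - 1L)

  target <- if (!spec$is_blank && odor_connected) spec$target_port else
    NA_integer_
  alert_at <- NA_integer_
  if (agent$alert_mode == "uniform_random") {
    alert_at <- sample(seq_len(n_ports) - 1L, 1L)
  } else {
    for (p in order) {
      commit <- if (!is.na(target) && p == target)
        stats::runif(1) < agent$p_detect
      else
        stats::runif(1) < agent$p_false_alert
      if (commit) { alert_at <- p; break }
    }
  }

  t <- round(1000 * rtrunc_norm(1, agent$latency_mean_s,
                                agent$latency_sd_s, 0.2))
  t_ms <- integer(0); port <- integer(0); kind <- character(0)
  for (p in order) {
    is_alert <- !is.na(alert_at) && p == alert_at
    dur <- if (is_alert)
      criterion_ms + round(1000 * agent$hold_overshoot_s)
    else
      round(1000 * rtrunc_norm(1, agent$sniff_mean_s, agent$sniff_sd_s,
                               0.05))
    t_ms <- c(t_ms, t, t + dur)
    port <- c(port, p, p)
    kind <- c(kind, "BREAK", "RESTORE")
    if (is_alert) break
    # travel time between adjacent ports
    t <- t + dur + round(1000 * stats::runif(1, 0.4, 1.2))
  }
  beam_events(t_ms, port, kind)
}

#' Run a fully simulated line-up session
#'
#' Generates the session plan, lets the virtual dog produce beam events
#' for every trial, classifies each through [run_trial()], and (optionally)
#' writes the session CSV. Deterministic for a fixed `config$seed`: the
#' plan is generated first from the seed and simulation draws continue
#' from the post-plan RNG state.
#'
#' @param agent an [agent_params()].
#' @param config a [session_config()].
#' @param odor_connected `FALSE` runs the odor-unplugged control session.
#' @param dog_name name recorded in the session metadata.
#' @param csv_path if non-`NULL`, the session CSV is written here (a
#'   directory path gets the `<dog>_<timestamp>.csv` naming scheme, see
#'   [write_session_csv()]).
#' @param session_time session start time used in metadata/filenames
#'   (defaults to `Sys.time()`; pass a fixed time for reproducible files).
#' @return a `lineup_session` object: list with `results` (list of
#'   `trial_result`), `plan`, `config`, `agent`, `metadata` and (if
#'   written) `csv_path`.
#' @examples
#' s <- run_simulated_session(agent_params(p_detect = 1, p_false_alert = 0),
#'                            session_config(seed = 42))
#' summary(s)
#' @export
run_simulated_session <- function(agent, config, odor_connected = TRUE,
                                  dog_name = "simdog", csv_path = NULL,
                                  session_time = Sys.time()) {
  validate_session_config(config)
  plan <- generate_session_plan(config, seed = config$seed)
  trial_start <- 0
  results <- vector("list", nrow(plan))
  starts <- numeric(nrow(plan))
  for (i in seq_len(nrow(plan))) {
    spec <- plan[i, ]
    events <- simulate_trial_events(agent, spec, config, odor_connected)
    res <- run_trial(spec, events, config)
    starts[i] <- trial_start
    results[[i]] <- res
    # inter-trial interval: trial duration + fan clearance
    trial_start <- trial_start + res$end_ms + config$iti_fan_s * 1000
  }
  metadata <- list(dog_name = dog_name, seed = config$seed,
                   phase = config$phase,
                   odor_connected = odor_connected,
                   session_time = session_time,
                   trial_start_ms = as.integer(round(starts)))
  out <- structure(list(results = results, plan = plan, config = config,
                        agent = agent, metadata = metadata),
                   class = "lineup_session")
  if (!is.null(csv_path))
    out$csv_path <- write_session_csv(out, csv_path)
  out
}

#' @export
print.lineup_session <- function(x, ...) {
  tab <- table(factor(vapply(x$results, `[[`, "", "response"),
                      levels = response_levels()))
  cat(sprintf("Simulated line-up session: %d trials (dog '%s', phase %s, seed %d)\n",
              length(x$results), x$metadata$dog_name, x$config$phase,
              x$config$seed))
  print(tab)
  invisible(x)
}

#' @export
summary.lineup_session <- function(object, ...) {
  session_summary(object$results)
}

response_levels <- function() {
  c("CORRECT_ALERT", "FALSE_ALERT", "ALL_CLEAR_CORRECT", "MISS", "TIMEOUT")
}
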