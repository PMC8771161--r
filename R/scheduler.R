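#' Session configuration for a line-up session
#'
#' Builds and validates the configuration for one line-up session: trial
#' count, odor channels, blank-trial rate, response criteria and air flows.
#' Defaults reproduce the standard 40-trial phase-3 session: 10% blank
#' trials distributed one per block of 10, a 4-s nose-hold alert criterion,
#' a 45-s search timeout, a 4-s all-clear window, 15 s of exhaust-fan time
#' between trials, and a 1 LPM odor line diluted into a 2 LPM clean line
#' (33% odor dilution).
#'
#' @param n_trials number of trials in the session (default 40).
#' @param target_channel odor channel id carrying the target odorant.
#' @param distractor_channels character vector of distractor channel ids;
#'   must be non-empty and disjoint from `target_channel`.
#' @param blank_rate fraction of trials with no target at any port.
#'   Defaults to 0.10 in phase `"P3_BLANKS"` and 0 in earlier phases.
#' @param blank_block_size blanks are placed per consecutive block of this
#'   many trials; `blank_rate * blank_block_size` must be an integer.
#' @param hold_criterion_s continuous nose-hold duration (seconds) that
#'   counts as an alert.
#' @param timeout_s search time limit in seconds, or `NA` for none.
#'   Defaults to 45 in phase 3, `NA` earlier.
#' @param all_clear_window_s seconds of no beam activity, after all three
#'   ports have been sampled, that score an all-clear.
#' @param iti_fan_s exhaust-fan duration (seconds) between trials.
#' @param odor_flow_lpm,clean_flow_lpm odor-line and clean-line air flows
#'   in liters per minute.
#' @param phase training phase, one of `"P1_ASSIST"`, `"P2_BLIND"`,
#'   `"P3_BLANKS"`.
#' @param seed integer seed recorded in the session and used to generate
#'   the plan.
#' @return an object of class `session_config` (a validated list).
#' @examples
#' cfg <- session_config(seed = 1)
#' cfg$blank_rate     # 0.10 in phase 3
#' dilution_fraction(cfg$odor_flow_lpm, cfg$clean_flow_lpm)
#' @export
session_config <- function(n_trials = 40L,
                           target_channel = "smokeless_powder",
                           distractor_channels = c("empty_vial", "gauze",
                                                   "glove", "mineral_oil",
                                                   "limonene"),
                           blank_rate = NULL,
                           blank_block_size = 10L,
                           hold_criterion_s = 4,
                           timeout_s = NULL,
                           all_clear_window_s = 4,
                           iti_fan_s = 15,
                           odor_flow_lpm = 1,
                           clean_flow_lpm = 2,
                           phase = c("P3_BLANKS", "P1_ASSIST", "P2_BLIND"),
                           seed = 1L) {
  phase <- match.arg(phase)
  if (is.null(blank_rate))
    blank_rate <- if (phase == "P3_BLANKS") 0.10 else 0
  if (is.null(timeout_s))
    timeout_s <- if (phase == "P3_BLANKS") 45 else NA_real_
  cfg <- structure(list(
    n_trials = as.integer(n_trials),
    n_ports = 3L,
    target_channel = target_channel,
    distractor_channels = distractor_channels,
    blank_rate = blank_rate,
    blank_block_size = as.integer(blank_block_size),
    hold_criterion_s = hold_criterion_s,
    timeout_s = timeout_s,
    all_clear_window_s = all_clear_window_s,
    iti_fan_s = iti_fan_s,
    odor_flow_lpm = odor_flow_lpm,
    clean_flow_lpm = clean_flow_lpm,
    phase = phase,
    seed = as.integer(seed)
  ), class = "session_config")
  validate_session_config(cfg)
}

#' @rdname session_config
#' @param x a `session_config`.
#' @export
validate_session_config <- function(x) {
  stopifnot(inherits(x, "session_config"))
  if (x$n_trials < 1L)
    stop("n_trials must be a positive integer", call. = FALSE)
  if (x$n_ports != 3L)
    stop("only 3-port line-ups are supported (n_ports = 3)", call. = FALSE)
  if (length(x$distractor_channels) == 0L)
    stop("distractor_channels must be non-empty", call. = FALSE)
  if (x$target_channel %in% x$distractor_channels)
    stop("target_channel must not appear among distractor_channels",
         call. = FALSE)
  if (x$blank_rate < 0 || x$blank_rate > 1)
    stop("blank_rate must lie in [0, 1]", call. = FALSE)
  per_block <- x$blank_rate * x$blank_block_size
  if (abs(per_block - round(per_block)) > 1e-9)
    stop(sprintf(
      "blank_rate (%g) x blank_block_size (%d) must be an integer",
      x$blank_rate, x$blank_block_size), call. = FALSE)
  if (x$hold_criterion_s <= 0)
    stop("hold_criterion_s must be > 0", call. = FALSE)
  if (!is.na(x$timeout_s) && x$hold_criterion_s > x$timeout_s)
    stop("hold_criterion_s must not exceed timeout_s", call. = FALSE)
  if (x$odor_flow_lpm < 0 || x$clean_flow_lpm < 0)
    stop("flows must be non-negative", call. = FALSE)
  x
}

#' @export
print.session_config <- function(x, ...) {
  cat(sprintf("Line-up session config: %d trials, phase %s, seed %d\n",
              x$n_trials, x$phase, x$seed))
  cat(sprintf("  target '%s' vs %d distractors; blank rate %.0f%% (block %d)\n",
              x$target_channel, length(x$distractor_channels),
              100 * x$blank_rate, x$blank_block_size))
  cat(sprintf("  hold %.2g s, timeout %s, all-clear window %g s\n",
              x$hold_criterion_s,
              if (is.na(x$timeout_s)) "none" else paste0(x$timeout_s, " s"),
              x$all_clear_window_s))
  cat(sprintf("  flows %g + %g LPM (odor fraction %.1f%%)\n",
              x$odor_flow_lpm, x$clean_flow_lpm,
              100 * dilution_fraction(x$odor_flow_lpm, x$clean_flow_lpm)))
  invisible(x)
}

#' Counterbalanced target-port sequence
#'
#' Assigns a target port to each of `n_target_trials` trials so that the
#' per-port counts differ by at most one, then shuffles the order. The
#' balanced multiset is built deterministically and shuffled, so the <=1
#' imbalance holds for every seed. For a standard 40-trial session this
#' yields each port as target 13 or 14 times.
#'
#' @param n_target_trials number of target-present trials (>= 0).
#' @param n_ports number of ports (>= 1).
#' @return integer vector of 0-based port ids, length `n_target_trials`.
#'   Draws from the current RNG state; seed beforehand for reproducibility.
#' @export
counterbalance_ports <- function(n_target_trials, n_ports = 3L) {
  if (n_ports < 1L) stop("n_ports must be >= 1", call. = FALSE)
  if (n_target_trials < 0L) stop("n_target_trials must be >= 0", call. = FALSE)
  if (n_target_trials == 0L) return(integer(0))
  base <- n_target_trials %/% n_ports
  extra <- n_target_trials %% n_ports
  counts <- rep(base, n_ports)
  if (extra > 0L) {
    lucky <- sample.int(n_ports, extra)   # which ports get the extra trial
    counts[lucky] <- counts[lucky] + 1L
  }
  ports <- rep(seq_len(n_ports) - 1L, counts)
  sample(ports)
}

#' Place blank trials within blocks
#'
#' Chooses the indices of blank (no-target) trials so that every
#' consecutive block of `block_size` trials contains exactly
#' `blank_rate * block_size` blanks at random positions within the block.
#' A final partial block receives `round(blank_rate * length)` blanks.
#'
#' @param n_trials session length.
#' @param blank_rate fraction of blank trials.
#' @param block_size block length for blank placement.
#' @return sorted integer vector of 0-based blank trial indices.
#' @export
place_blanks <- function(n_trials, blank_rate, block_size = 10L) {
  per_block <- blank_rate * block_size
  if (abs(per_block - round(per_block)) > 1e-9)
    stop("blank_rate x block_size must be an integer", call. = FALSE)
  per_block <- as.integer(round(per_block))
  if (per_block == 0L) return(integer(0))
  starts <- seq.int(0L, n_trials - 1L, by = block_size)
  idx <- unlist(lapply(starts, function(s) {
    len <- min(block_size, n_trials - s)
    k <- if (len == block_size) per_block else
      as.integer(round(blank_rate * len))
    if (k == 0L) return(integer(0))
    s + sample.int(len, k) - 1L
  }))
  sort(as.integer(idx))
}

#' Odor dilution fraction
#'
#' Fraction of total port airflow contributed by the odor line,
#' `odor / (odor + clean)`. A 1 LPM odor line in a 2 LPM clean line gives
#' 1/3 (the 33% dilution used in training and validation).
#'
#' @param odor_flow_lpm,clean_flow_lpm flows in liters/minute (>= 0, not
#'   both zero).
#' @return a fraction in `[0, 1]`.
#' @export
dilution_fraction <- function(odor_flow_lpm, clean_flow_lpm) {
  if (odor_flow_lpm < 0 || clean_flow_lpm < 0)
    stop("flows must be non-negative", call. = FALSE)
  total <- odor_flow_lpm + clean_flow_lpm
  if (total <= 0) stop("total flow must be positive", call. = FALSE)
  odor_flow_lpm / total
}

#' Generate a randomized, counterbalanced session plan
#'
#' Produces one `trial_spec` row per trial. Randomization follows the
#' line-up procedure: first decide which trials are blank (placed per block
#' of `blank_block_size`), then counterbalance the target port over
#' target-present trials (per-port counts differ by at most 1), then draw
#' the distractor channel for every non-target olfactometer independently
#' and uniformly, with replacement, so the two (or on blanks, three)
#' distractors may coincide within a trial.
#'
#' @param config a [session_config()].
#' @param seed seed used for the plan; defaults to `config$seed`. Pass
#'   `NULL` to draw from the current RNG state instead.
#' @return a `session_plan` data frame with columns `trial_index` (0-based),
#'   `is_blank`, `target_port` (0-based, `NA` on blanks) and
#'   `channel_port1`..`channel_port3`.
#' @examples
#' plan <- generate_session_plan(session_config(seed = 7))
#' table(plan$target_port)   # 12/12/12-ish split over 36 target trials
#' sum(plan$is_blank)        # 4 blanks, one per block of 10
#' @export
generate_session_plan <- function(config, seed = config$seed) {
  validate_session_config(config)
  if (!is.null(seed)) set.seed(seed)
  n <- config$n_trials
  blanks <- place_blanks(n, config$blank_rate, config$blank_block_size)
  is_blank <- (seq_len(n) - 1L) %in% blanks
  target_port <- rep(NA_integer_, n)
  target_port[!is_blank] <- counterbalance_ports(sum(!is_blank),
                                                 config$n_ports)
  channels <- matrix(
    sample(config$distractor_channels, n * config$n_ports, replace = TRUE),
    nrow = n)
  for (i in which(!is_blank))
    channels[i, target_port[i] + 1L] <- config$target_channel
  plan <- data.frame(
    trial_index = seq_len(n) - 1L,
    is_blank = is_blank,
    target_port = target_port,
    channel_port1 = channels[, 1L],
    channel_port2 = channels[, 2L],
    channel_port3 = channels[, 3L],
    stringsAsFactors = FALSE
  )
  class(plan) <- c("session_plan", "data.frame")
  plan
}

#' Export or import a session plan as CSV
#'
#' Ports are written 1-based (`target_port` 1..3, `NA` blank) to match the
#' operator-facing convention; `read_plan_csv` converts back to the 0-based
#' internal representation.
#'
#' @param plan a `session_plan`.
#' @param path file path.
#' @return `write_plan_csv` returns `path` invisibly; `read_plan_csv`
#'   returns a `session_plan`.
#' @export
write_plan_csv <- function(plan, path) {
  out <- as.data.frame(plan)
  out$target_port <- out$target_port + 1L
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}

#' @rdname write_plan_csv
#' @export
read_plan_csv <- function(path) {
  plan <- utils::read.csv(path, stringsAsFactors = FALSE)
  needed <- c("trial_index", "is_blank", "target_port",
              paste0("channel_port", 1:3))
  missing <- setdiff(needed, names(plan))
  if (length(missing))
    stop("plan file missing column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  plan$target_port <- as.integer(plan$target_port) - 1L
  plan$is_blank <- as.logical(plan$is_blank)
  class(plan) <- c("session_plan", "data.frame")
  plan
}
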