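#' Synthesize a PID validation trace
#'
#' Generates the photoionization-detector trace the odor-delivery
#' validation protocol would record: each cycle is `off_s` seconds of
#' clean air followed by `on_s` seconds of valve-on stimulation, repeated
#' `n_cycles` times and sampled at `fs` Hz (the standard protocol is 40
#' cycles of 30 s on / 30 s off at 30 Hz, ~72,000 samples). The sensor
#' responds as a first-order system with time constant `rise_tau_s`
#' (exponential approach to the plateau on valve-on, exponential decay on
#' valve-off), on top of a linear baseline drift and white noise. An
#' optional dropped-packet gap removes a run of samples, emulating a DAQ
#' packet loss.
#'
#' @param n_cycles number of on/off cycles.
#' @param on_s,off_s valve-on and valve-off durations (s) per cycle.
#' @param fs sampling rate (Hz).
#' @param rise_tau_s sensor time constant (s); values below one sample
#'   period give an ideal square wave.
#' @param noise_sd white-noise standard deviation (V).
#' @param drift_slope linear baseline drift (V/s; negative for the
#'   downward drift real sensors show).
#' @param baseline_v,amplitude_v baseline voltage and plateau amplitude
#'   above baseline.
#' @param dropped_gap optional `c(start_s, duration_s)`: samples in
#'   `[start, start + duration)` are removed from the record.
#' @return a `pid_trace` data frame (`t_s`, `voltage`, `stim`) with
#'   attribute `fs`.
#' @examples
#' tr <- synth_pid_trace(n_cycles = 3, on_s = 5, off_s = 5, fs = 30,
#'                       noise_sd = 0)
#' nrow(extract_epochs(tr))   # 3
#' @export
synth_pid_trace <- function(n_cycles = 40, on_s = 30, off_s = 30, fs = 30,
                            rise_tau_s = 0.5, noise_sd = 0.01,
                            drift_slope = 0, baseline_v = 0.2,
                            amplitude_v = 1, dropped_gap = NULL) {
  stopifnot(n_cycles >= 1, on_s > 0, off_s > 0, fs > 0)
  dt <- 1 / fs
  n <- round(n_cycles * (on_s + off_s) * fs)
  t_s <- (seq_len(n) - 1L) * dt
  phase <- t_s %% (on_s + off_s)
  stim <- as.integer(phase >= off_s)   # each cycle: off first, then on
  target <- baseline_v + amplitude_v * stim
  v <- numeric(n)
  v[1] <- baseline_v
  if (rise_tau_s < dt / 20) {
    v <- target
  } else {
    a <- exp(-dt / rise_tau_s)
    for (i in 2:n) v[i] <- target[i] + (v[i - 1] - target[i]) * a
  }
  v <- v + drift_slope * t_s
  if (noise_sd > 0) v <- v + stats::rnorm(n, 0, noise_sd)
  tr <- data.frame(t_s = t_s, voltage = v, stim = stim)
  if (!is.null(dropped_gap)) {
    drop <- tr$t_s >= dropped_gap[1] &
      tr$t_s < dropped_gap[1] + dropped_gap[2]
    tr <- tr[!drop, , drop = FALSE]
    rownames(tr) <- NULL
  }
  structure(tr, fs = fs, class = c("pid_trace", "data.frame"))
}

#' Detect dropped-packet gaps in a trace
#' @param trace a `pid_trace`.
#' @return integer indices i where `t_s[i+1] - t_s[i] > 2/fs`.
#' @export
find_gaps <- function(trace) {
  fs <- attr(trace, "fs") %||% (1 / stats::median(diff(trace$t_s)))
  which(diff(trace$t_s) > 2 / fs)
}

#' Zero-phase low-pass Butterworth filter
#'
#' Filters the voltage channel with an order-2 Butterworth low-pass at
#' `cutoff_scalar` times the Nyquist frequency, applied forward-backward
#' (zero phase), so output length equals input length and a constant
#' signal passes unchanged (unit DC gain).
#'
#' @param trace a `pid_trace`.
#' @param cutoff_scalar cutoff as a fraction of Nyquist, in (0, 1);
#'   default 0.05.
#' @param order filter order (default 2).
#' @return the trace with `voltage` replaced by its filtered version.
#' @export
pid_lowpass <- function(trace, cutoff_scalar = 0.05, order = 2) {
  stopifnot(cutoff_scalar > 0, cutoff_scalar < 1)
  n <- nrow(trace)
  # odd-reflection padding long enough for the filter transient to die out
  pad <- min(n - 1L, max(9L * (order + 1L), ceiling(12 / cutoff_scalar)))
  if (n < 9 * (order + 1))
    stop("trace too short for filter warm-up", call. = FALSE)
  bf <- signal::butter(order, cutoff_scalar, type = "low")
  x <- trace$voltage
  ext <- c(2 * x[1] - x[(pad + 1L):2L], x, 2 * x[n] - x[(n - 1L):(n - pad)])
  y <- as.numeric(signal::filtfilt(bf, ext))
  trace$voltage <- y[(pad + 1L):(pad + n)]
  trace
}

#' Extract stimulation epochs
#'
#' One epoch per contiguous run of `stim == 1`. Because epochs are defined
#' on the sampled stimulation channel, a missing-data gap inside an
#' off-period does not split or add epochs.
#'
#' @param trace a `pid_trace`, or a binary stim vector.
#' @return data frame with `onset` and `offset` sample indices (first and
#'   last on-sample of each epoch); zero rows if stim is all off.
#' @export
extract_epochs <- function(trace) {
  stim <- if (is.data.frame(trace)) trace$stim else trace
  stopifnot(all(stim %in% c(0L, 1L)))
  r <- rle(as.integer(stim))
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  on <- r$values == 1L
  data.frame(onset = starts[on], offset = ends[on])
}

# per-epoch pre-onset baseline mean over the trailing window; gaps are
# simply absent samples and are excluded, never interpolated
epoch_baselines <- function(trace, epochs, baseline_window_s = 30) {
  vapply(seq_len(nrow(epochs)), function(i) {
    t_on <- trace$t_s[epochs$onset[i]]
    pre <- trace$t_s >= t_on - baseline_window_s & trace$t_s < t_on &
      trace$stim == 0L
    if (!any(pre)) {
      warning("empty baseline window before epoch ", i,
              "; using nearest pre-onset samples")
      pre0 <- which(trace$t_s < t_on & trace$stim == 0L)
      if (!length(pre0)) return(NA_real_)
      fs <- attr(trace, "fs") %||% 30
      pre <- utils::tail(pre0, max(1, round(baseline_window_s * fs)))
      return(mean(trace$voltage[pre]))
    }
    mean(trace$voltage[pre])
  }, numeric(1))
}

#' Per-cycle baseline drift correction
#'
#' Counters slow sensor drift by re-referencing every cycle to the first
#' cycle's baseline: for each epoch, the mean voltage over the
#' `baseline_window_s` before valve onset (the between-activation period)
#' is taken as that cycle's baseline, and the offset
#' `baseline[1] - baseline[i]` is added uniformly to all of cycle *i*'s
#' samples — the odor-off and odor-on values alike. A cycle spans from the
#' end of the previous epoch's on-period through the end of its own. With
#' a single epoch the offset is zero by definition and the trace is
#' returned unchanged.
#'
#' @param trace a `pid_trace`.
#' @param epochs from [extract_epochs()]; computed if missing.
#' @param baseline_window_s pre-onset window (s), default 30.
#' @return the trace with drift-corrected `voltage`; per-cycle offsets in
#'   attribute `offsets`.
#' @export
drift_correct <- function(trace, epochs = extract_epochs(trace),
                          baseline_window_s = 30) {
  n_ep <- nrow(epochs)
  if (n_ep == 0L) return(trace)
  base <- epoch_baselines(trace, epochs, baseline_window_s)
  offsets <- base[1] - base
  offsets[is.na(offsets)] <- 0
  # cycle i: samples after epoch i-1's offset up to epoch i's offset;
  # anything after the last epoch keeps the last offset
  cyc <- findInterval(seq_len(nrow(trace)) - 1L, c(0L, epochs$offset[-n_ep]))
  cyc[cyc > n_ep] <- n_ep
  trace$voltage <- trace$voltage + offsets[cyc]
  attr(trace, "offsets") <- offsets
  trace
}

#' Per-epoch odor delivery and clearance metrics
#'
#' For each stimulation epoch: the pre-onset baseline mean, the plateau
#' mean (last `plateau_frac` of the on-period), the rise latency (time
#' from valve onset until the voltage first reaches 90% of the
#' baseline-to-plateau step) and the clearance latency (time from valve
#' offset until it first falls back within 10% of the step above
#' baseline). A first-order sensor with time constant tau gives rise and
#' clearance latencies of `tau * log(10)`. Metrics that cannot be reached
#' within the available samples are `NA` (epoch flagged undefined).
#'
#' @param trace a (typically drift-corrected) `pid_trace`.
#' @param epochs from [extract_epochs()]; computed if missing.
#' @param baseline_window_s pre-onset baseline window (s).
#' @param plateau_frac trailing fraction of the on-period averaged as the
#'   plateau.
#' @param rise_frac,clear_frac thresholds as fractions of the
#'   baseline-to-plateau step.
#' @return data frame of `epoch_summary` rows: `onset_t`, `offset_t`,
#'   `baseline_mean`, `plateau_mean`, `rise_latency_s`,
#'   `clearance_latency_s`.
#' @export
epoch_metrics <- function(trace, epochs = extract_epochs(trace),
                          baseline_window_s = 30, plateau_frac = 0.5,
                          rise_frac = 0.9, clear_frac = 0.1) {
  base <- epoch_baselines(trace, epochs, baseline_window_s)
  n_ep <- nrow(epochs)
  dt <- stats::median(diff(trace$t_s))
  out <- lapply(seq_len(n_ep), function(i) {
    on <- epochs$onset[i]; off <- epochs$offset[i]
    t_on <- trace$t_s[on]
    # valve-off edge: the first sample after the on-run
    t_off <- if (off < nrow(trace)) trace$t_s[off + 1L] else
      trace$t_s[off] + dt
    idx_on <- on:off
    n_on <- length(idx_on)
    plateau_idx <- idx_on[idx_on >= on + floor((1 - plateau_frac) * n_on)]
    plateau <- mean(trace$voltage[plateau_idx])
    step <- plateau - base[i]
    rise <- NA_real_
    if (is.finite(step) && step > 0) {
      hit <- idx_on[trace$voltage[idx_on] >= base[i] + rise_frac * step]
      if (length(hit)) rise <- trace$t_s[hit[1]] - t_on
    }
    clearance <- NA_real_
    post_end <- if (i < n_ep) epochs$onset[i + 1] - 1L else nrow(trace)
    if (post_end > off && is.finite(step) && step > 0) {
      idx_post <- (off + 1L):post_end
      hit <- idx_post[trace$voltage[idx_post] <= base[i] + clear_frac * step]
      if (length(hit)) clearance <- trace$t_s[hit[1]] - t_off
    }
    data.frame(onset_t = t_on, offset_t = t_off, baseline_mean = base[i],
               plateau_mean = plateau, rise_latency_s = rise,
               clearance_latency_s = clearance)
  })
  do.call(rbind, out)
}

#' Read/write PID traces as CSV
#' @param trace a `pid_trace`.
#' @param path file path; columns `t_s`, `voltage`, `stim`.
#' @param fs sampling rate to attach on read (inferred from `t_s` if
#'   omitted).
#' @export
write_pid_csv <- function(trace, path) {
  utils::write.csv(as.data.frame(trace)[c("t_s", "voltage", "stim")], path,
                   row.names = FALSE)
  invisible(path)
}

#' @rdname write_pid_csv
#' @export
read_pid_csv <- function(path, fs = NULL) {
  df <- utils::read.csv(path)
  missing <- setdiff(c("t_s", "voltage", "stim"), names(df))
  if (length(missing))
    stop("PID file missing column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  if (is.null(fs)) fs <- 1 / stats::median(diff(df$t_s))
  structure(df, fs = fs, class = c("pid_trace", "data.frame"))
}

#' Plot a PID trace
#'
#' Full-record view of voltage with the stimulation square wave overlaid,
#' plus an optional zoomed panel over a chosen pair of epochs (the layout
#' of the standard delivery/clearance validation figure).
#'
#' @param x a `pid_trace`.
#' @param epochs from [extract_epochs()]; computed if missing.
#' @param zoom optional length-2 integer: epoch range for a second,
#'   enlarged panel.
#' @param ... passed to `plot`.
#' @export
plot.pid_trace <- function(x, epochs = extract_epochs(x), zoom = NULL, ...) {
  op <- graphics::par(mfrow = c(if (is.null(zoom)) 1 else 2, 1),
                      mar = c(4, 4, 2, 1))
  on.exit(graphics::par(op))
  rng <- range(x$voltage)
  graphics::plot(x$t_s / 60, x$voltage, type = "l", xlab = "Time (min)",
                 ylab = "PID voltage (V)", ...)
  graphics::lines(x$t_s / 60, rng[1] + x$stim * diff(rng), col = "red")
  if (!is.null(zoom) && nrow(epochs)) {
    i <- zoom[1]; j <- min(zoom[2], nrow(epochs))
    sel <- x$t_s >= x$t_s[epochs$onset[i]] - 30 &
      x$t_s <= x$t_s[epochs$offset[j]] + 30
    graphics::plot(x$t_s[sel], x$voltage[sel], type = "l",
                   xlab = "Time (s)", ylab = "PID voltage (V)")
    graphics::lines(x$t_s[sel], rng[1] + x$stim[sel] * diff(rng),
                    col = "red")
  }
  invisible(x)
}
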