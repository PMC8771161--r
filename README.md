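# olflineup

Hardware-agnostic experiment controller and simulator for the automated
three-port **olfactometer line-up** used in detection-dog research.

In a line-up task, a dog searches a row of odor ports for a target odorant
(e.g., smokeless powder) among distractors and reports it with a trained
final response — here, a sustained nose hold in the port, read objectively
by infrared beam sensors. An automated line-up removes the handler from the
trial loop entirely: a program plans each trial, drives the olfactometer
valves, scores the dog's beam-break events, and logs everything to CSV,
guaranteeing double-blind conditions by construction.

`olflineup` re-implements that controller as a pure-software package so
the scheduling, scoring, training-progression and signal-validation logic
can be developed, audited and exercised without a physical apparatus. A
parameterised virtual dog closes the loop for fully simulated sessions,
including the odor-unplugged control test used to verify that performance
is odor-driven.

## What it computes

* **Session plans** — per trial: blank (no-target) flag, target port, and
  the odor channel loaded on each of the three olfactometers. Blanks are
  placed one per block of 10 at a 10% rate; target ports are
  counterbalanced so each port is used within ±1 trial of the others
  (13–14 times in a 40-trial session); distractors are drawn independently
  and uniformly per olfactometer.
* **Trial classification** — beam events are debounced into nose pokes; the
  first continuous hold reaching the criterion (shaped from 0.25 s up to
  4 s) fires an alert at the instant the criterion is met. The taxonomy is
  total and exclusive: `CORRECT_ALERT`, `FALSE_ALERT`,
  `ALL_CLEAR_CORRECT`, `MISS`, `TIMEOUT` (45-s search limit). Latency,
  per-port entries and sniff time (alert hold excluded) are measured per
  trial.
* **Training analytics** — session summaries (proportion correct = alerts
  to the target + all-clears on blanks), unweighted daily averaging, and
  the phase-progression rules (criterion ladder, ≥85% accuracy gates,
  phase 1 → 2 → 3), with chance level at 1/3.
* **PID validation** — synthetic photoionization-detector traces for the
  30 s-on/30 s-off delivery/clearance protocol, zero-phase order-2
  Butterworth low-pass at 0.05 × Nyquist, per-cycle baseline drift
  correction, and per-epoch baseline/plateau/rise/clearance metrics (a
  first-order sensor with time constant τ rises to 90% in τ·ln 10).

## Worked example

```r
library(olflineup)

cfg <- session_config(seed = 42)     # standard 40-trial phase-3 session
cfg
#> Line-up session config: 40 trials, phase P3_BLANKS, seed 42
#>   target 'smokeless_powder' vs 5 distractors; blank rate 10% (block 10)
#>   hold 4 s, timeout 45 s, all-clear window 4 s
#>   flows 1 + 2 LPM (odor fraction 33.3%)

dog <- agent_params(p_detect = 0.95, p_false_alert = 0.02)
s <- run_simulated_session(dog, cfg, dog_name = "Rex")
summary(s)
#> Session summary over 40 trials:
#>   correct 92.50% | false alert 2.50% | miss 5.00% | timeout 0.00%
#>   mean latency 10745 ms, mean cumulative sniff 500 ms, mean entries 2.02
```

The 40 trials comprise 36 target-present trials and 4 blanks. This dog
alerted correctly on 34 targets, cleared 3 of the 4 blanks, false-alerted
once and missed twice: 37/40 = 92.5% correct, comfortably above the 85%
training criterion and far above the 33% chance level. Mean search latency
(~10.7 s) and ~0.5 s of cumulative sniffing per trial match a
well-trained dog's profile.

PID delivery/clearance validation on a synthetic trace (40 cycles,
downward sensor drift, one dropped DAQ packet):

```r
tr <- synth_pid_trace(n_cycles = 40, drift_slope = -2e-5,
                      dropped_gap = c(1020, 1))
ep <- extract_epochs(tr)
m  <- epoch_metrics(drift_correct(pid_lowpass(tr), ep), ep)
#> epochs: 40; median rise 1.10 s; median clearance 1.03 s
```

All 40 stimulation epochs are recovered despite the gap; odor is detected
at the port within ~1 s of valve opening and clears within ~1 s of
closing.

A thin command-line wrapper ships at `inst/cli/lineup`
(`lineup simulate|analyze|pid`, with `--config`, `--seed`, `--dog`,
`--out`).

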