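#' Generate a complete synthetic closed-loop session
#'
#' End-to-end bench session: generates a baseline two-site LFP for
#' z-score statistics, calibrates per-subject coherence thresholds from
#' clean baseline windows, then runs the protocol state machine with a
#' detector that streams freshly generated coupled LFP (alternating
#' high/low coupling states) through [stream_detect()]. Produces the trial
#' table, an event log, the threshold profile and per-trial ground truth.
#'
#' Simulated choice outcomes follow a per-type outcome model (defaults:
#' strong-coherence trials are most accurate, weak-coherence trials
#' least), standing in for the animal so accuracy summaries are testable.
#'
#' @param protocol `"delayed_alternation"` or
#'   `"conditional_discrimination"`, or a `protocol_spec`.
#' @param seed Integer seed; identical seeds give identical bundles.
#' @param n_blocks Number of 10-trial blocks.
#' @param spec_a,spec_b `oscillator_spec`s for the two sites.
#' @param dwell Dwell time (s) of each coupling state in the detector
#'   streams.
#' @param outcome_model Named P(correct) per trial type.
#' @param choice_latency Seconds from door opening to choice-point entry
#'   used when laying out the event log.
#' @return A list of class `session_bundle`: `trials`, `events`,
#'   `thresholds`, `baseline` (list of two `baseline_stats`), `lfp`
#'   (baseline two-site recording), `states` (the baseline state track),
#'   and `protocol`.
#' @export
gen_session <- function(protocol = "delayed_alternation", seed = 1,
                        n_blocks = 4,
                        spec_a = oscillator_spec(sampling_rate = 500),
                        spec_b = oscillator_spec(sampling_rate = 500),
                        dwell = 2,
                        outcome_model = c(high = 0.9, low = 0.6,
                                          yoked_high = 0.75,
                                          yoked_low = 0.75, random = 0.75),
                        choice_latency = 2) {
  if (!inherits(protocol, "protocol_spec")) protocol <- protocol_spec(protocol)
  spec <- window_spec()
  with_seed(seed, {
    # -- baseline recording and threshold calibration ----------------------
    base_states <- alternating_states(n_cycles = 15, dwell_high = dwell,
                                      dwell_low = dwell)
    lfp <- gen_coupled_lfp(spec_a, spec_b, base_states,
                           seed = sample.int(2^30, 1))
    bl_a <- baseline_stats(lfp$a)
    bl_b <- baseline_stats(lfp$b)
    ep <- coherence_epochs(lfp$a, lfp$b, bl_a, bl_b, spec)
    clean <- ep$table$verdict == "clean"
    thresholds <- calibrate_thresholds(ep$table$theta_value[clean],
                                       subject_id = sprintf("sim%03d", seed))
    # -- detector over freshly generated streams ---------------------------
    detector <- function(mode, timeout) {
      n_cyc <- ceiling((timeout + 2 * dwell) / (2 * dwell))
      st <- alternating_states(n_cycles = n_cyc, dwell_high = dwell,
                               dwell_low = dwell,
                               start = sample(c("high", "low"), 1))
      stream <- gen_coupled_lfp(spec_a, spec_b, st,
                                seed = sample.int(2^30, 1))
      stream_detect(stream$a, stream$b, bl_a, bl_b, spec, thresholds,
                    mode = mode, timeout = timeout)
    }
    trials <- run_session(protocol, n_blocks = n_blocks,
                          detector = detector,
                          outcome_model = outcome_model)
    # -- event log ---------------------------------------------------------
    t <- 0
    ev_t <- numeric(); ev_k <- character(); ev_p <- character()
    push <- function(time, kind, payload = "") {
      ev_t[[length(ev_t) + 1L]] <<- time
      ev_k[[length(ev_k) + 1L]] <<- kind
      ev_p[[length(ev_p) + 1L]] <<- payload
    }
    push(0, "session_start")
    iti <- 5
    for (i in seq_len(nrow(trials))) {
      tr <- trials[i, ]
      pl <- sprintf("trial=%d", tr$index)
      push(t, "trial_start", pl)
      t_door <- t + tr$delay
      push(t_door, "door_open", pl)
      t_entry <- t_door + choice_latency
      push(t_entry, "choice_entry", pl)
      push(t_entry + 1.0, "choice_exit", pl)
      if (identical(tr$outcome, "correct")) push(t_entry + 1.5, "reward", pl)
      t <- t_entry + 1.5 + iti
    }
    events <- event_log(ev_t, ev_k, ev_p)
    structure(list(trials = trials, events = events,
                   thresholds = thresholds,
                   baseline = list(a = bl_a, b = bl_b),
                   lfp = lfp, states = base_states, protocol = protocol),
              class = "session_bundle")
  })
}

#' @export
print.session_bundle <- function(x, ...) {
  cat(sprintf("<session_bundle> %s: %d trials, %d events\n",
              x$protocol$name, nrow(x$trials), nrow(x$events)))
  invisible(x)
}
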