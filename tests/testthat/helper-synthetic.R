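# Shared fixtures: all synthetic, generated at test time. A 500 Hz
# sampling rate keeps runtimes short without changing any of the window
# mechanics (window/step/grid are in seconds and Hz).

fs_test <- 500

osc_test <- function(...) oscillator_spec(sampling_rate = fs_test, ...)

# quick coupled pair with a constant state
const_pair <- function(duration, mixing = 1, seed = 1, spec = osc_test()) {
  st <- coherence_state_track("high", duration)
  gen_coupled_lfp(spec, spec, st, seed = seed,
                  high_mixing = mixing, low_mixing = mixing)
}

# threshold profile with chosen levels (bypasses calibration)
fixed_profile <- function(mean, sd) {
  structure(list(mean = mean, sd = sd, high = mean + sd, low = mean - sd,
                 subject_id = "fixture", n_samples = 100L),
            class = "threshold_profile")
}

# detector stub for scheduler tests: triggers with a fresh uniform delay,
# or times out with probability p_timeout
stub_detector <- function(p_timeout = 0) {
  function(mode, timeout) {
    if (stats::runif(1) < p_timeout) {
      list(trigger_time = timeout, cause = "timeout")
    } else {
      list(trigger_time = stats::runif(1, 1, timeout * 0.9),
           cause = "threshold")
    }
  }
}

# circular helpers for oracle checks
circ_mean <- function(th) Arg(mean(exp(1i * th)))
circ_mrl <- function(th) Mod(mean(exp(1i * th)))

# population resultant length of a von Mises distribution, I1(k)/I0(k)
vm_mrl <- function(kappa) {
  besselI(kappa, 1, expon.scaled = TRUE) /
    besselI(kappa, 0, expon.scaled = TRUE)
}
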