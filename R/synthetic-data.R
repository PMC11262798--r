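# Synthetic dual-site LFP / spike / behavior generators. These define the
# bench conditions every other module is exercised under: two noisy theta
# oscillators with a controllable shared component, movement-artifact
# transients, von Mises phase-locked spike trains, and straight vs tortuous
# position paths.

# Run code under a fixed seed, restoring the caller's RNG state afterwards.
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Theta oscillator specification
#'
#' Parameters of one synthetic LFP site. Theta is a stochastic oscillator
#' (sinusoidal carrier with slow frequency wander and bounded amplitude
#' modulation) -- not a pure tone -- so coherence between two sites is
#' genuinely statistical.
#' Amplitudes are RMS microvolts on a nominal scale where theta is a few
#' hundred microvolts and amplifier saturation sits near +/-2000.
#'
#' Default amplitudes were fixed once by a brute-force sweep so that two
#' sites built from the default spec reach a magnitude-squared coherence of
#' about 0.7 at 8 Hz when the shared component is fully mixed in
#' (high-coherence state).
#'
#' @param theta_freq Center theta frequency, Hz.
#' @param theta_amp_shared RMS amplitude (uV) of the shared theta
#'   component at full mixing.
#' @param theta_amp_private RMS amplitude (uV) of the site-private theta
#'   component.
#' @param noise_sd RMS amplitude (uV) of broadband white noise.
#' @param delta_amp RMS amplitude (uV) of site-private 1--4 Hz activity.
#' @param sampling_rate Sampling rate, Hz.
#' @return An object of class `oscillator_spec`.
#' @export
oscillator_spec <- function(theta_freq = 8, theta_amp_shared = 170,
                            theta_amp_private = 90, noise_sd = 60,
                            delta_amp = 40, sampling_rate = 2000) {
  stopifnot(theta_amp_shared >= 0, theta_amp_private >= 0,
            noise_sd >= 0, delta_amp >= 0,
            sampling_rate > 2 * (theta_freq + 4))
  structure(list(theta_freq = theta_freq,
                 theta_amp_shared = theta_amp_shared,
                 theta_amp_private = theta_amp_private,
                 noise_sd = noise_sd, delta_amp = delta_amp,
                 sampling_rate = sampling_rate),
            class = "oscillator_spec")
}

#' Coherence state track
#'
#' Piecewise-constant schedule of high/low coupling states covering the
#' full signal duration with no gaps.
#'
#' @param state_labels Character vector over time, values `"high"` /
#'   `"low"`.
#' @param dwell_times Positive dwell duration (s) of each state, same
#'   length.
#' @return An object of class `coherence_state_track` with a `duration`
#'   field.
#' @export
coherence_state_track <- function(state_labels, dwell_times) {
  state_labels <- match.arg(state_labels, c("high", "low"),
                            several.ok = TRUE)
  stopifnot(length(state_labels) == length(dwell_times),
            all(dwell_times > 0))
  structure(list(state_labels = state_labels,
                 dwell_times = as.numeric(dwell_times),
                 duration = sum(dwell_times)),
            class = "coherence_state_track")
}

#' Alternating high/low state track
#' @param n_cycles Number of high+low cycles.
#' @param dwell_high,dwell_low Dwell times in seconds.
#' @param start Which state comes first.
#' @return A `coherence_state_track`.
#' @export
alternating_states <- function(n_cycles = 10, dwell_high = 2,
                               dwell_low = 2, start = "high") {
  lab <- rep(if (start == "high") c("high", "low") else c("low", "high"),
             n_cycles)
  dw <- rep(if (start == "high") c(dwell_high, dwell_low)
            else c(dwell_low, dwell_high), n_cycles)
  coherence_state_track(lab, dw)
}

# Unit-SD narrowband noise: white noise bandpassed with a 3rd-order
# Butterworth (used for the 1-4 Hz delta component).
narrowband_component <- function(n, fs, band) {
  bf <- signal::butter(3, band / (fs / 2), type = "pass")
  x <- signal::filtfilt(bf, stats::rnorm(n + 4L * fs))
  x <- x[(2L * fs + 1L):(2L * fs + n)]          # drop filter warm-up pad
  x / stats::sd(x)
}

# Unit-SD stochastic theta oscillator: a sinusoidal carrier whose
# instantaneous frequency wanders slowly around f0 (SD freq_sd Hz) and
# whose amplitude is modulated by slow bounded noise. A sustained rhythm
# of this kind matches rodent theta better than Gaussian narrowband
# noise, whose Rayleigh envelope fades to zero far too often; fades would
# make even artifact-free windows lose their theta coherence.
theta_oscillator <- function(n, fs, f0, freq_sd = 0.8, amp_cv = 0.25) {
  slow <- function(cutoff) {
    bf <- signal::butter(2, cutoff / (fs / 2), type = "low")
    z <- signal::filtfilt(bf, stats::rnorm(n + 4L * fs))
    z <- z[(2L * fs + 1L):(2L * fs + n)]
    z / stats::sd(z)
  }
  f_inst <- f0 + freq_sd * slow(1.5)
  phase <- 2 * pi * cumsum(f_inst) / fs + stats::runif(1, 0, 2 * pi)
  amp <- pmax(1 + amp_cv * slow(0.5), 0.15)
  x <- amp * sin(phase)
  x / stats::sd(x)
}

# Mixing envelope from a state track: `high_w` in high states, `low_w` in
# low states, raised-cosine ramps at transitions so state changes do not
# introduce broadband clicks.
state_envelope <- function(states, fs, n, high_w, low_w, ramp = 0.1) {
  w <- numeric(n)
  bounds <- round(cumsum(c(0, states$dwell_times)) * fs)
  for (i in seq_along(states$state_labels)) {
    a <- bounds[i] + 1L; b <- min(bounds[i + 1L], n)
    if (a > n) break
    w[a:b] <- if (states$state_labels[i] == "high") high_w else low_w
  }
  if (n > bounds[length(bounds)]) {
    w[(bounds[length(bounds)] + 1L):n] <- w[bounds[length(bounds)]]
  }
  nr <- round(ramp * fs)
  if (nr > 1L) {
    k <- 0.5 * (1 - cos(pi * seq(0, 1, length.out = nr)))
    k <- k / sum(k)
    w <- stats::filter(c(rep(w[1], nr), w, rep(w[n], nr)), k, sides = 2)
    w <- as.numeric(w)[(nr + 1L):(nr + n)]
  }
  w
}

#' Generate a coupled two-site LFP pair
#'
#' Builds two signals sharing a common narrowband theta component whose
#' mixing weight follows the state track: `high_mixing` (default 1) during
#' high-coherence states and `low_mixing` during low states. Each site adds
#' its own private theta, 1--4 Hz delta, and white noise per its
#' `oscillator_spec`. Theta-band magnitude-squared coherence during high
#' states therefore exceeds that during low states by a margin controlled
#' by the two mixing weights.
#'
#' @param spec_a,spec_b `oscillator_spec`s (equal sampling rates).
#' @param states A `coherence_state_track` (its total dwell sets the
#'   duration).
#' @param seed Integer seed; generation is reproducible.
#' @param high_mixing,low_mixing Shared-component mixing weight in
#'   high/low states. The defaults give high-state 8 Hz coherence near 0.7
#'   and low-state coherence near 0.45 with default specs.
#' @param freq_sd,amp_cv Frequency wander (Hz SD) and amplitude modulation
#'   depth of the theta oscillators.
#' @return A list with elements `a` and `b` (`continuous_signal`s, regions
#'   mPFC and HPC) and `states`.
#' @export
gen_coupled_lfp <- function(spec_a, spec_b, states, seed,
                            high_mixing = 1, low_mixing = 0.55,
                            freq_sd = 0.8, amp_cv = 0.25) {
  if (spec_a$sampling_rate != spec_b$sampling_rate) {
    stop("sampling_rate mismatch between specs")
  }
  if (states$duration <= 0) stop("non-positive duration")
  fs <- spec_a$sampling_rate
  n <- as.integer(round(states$duration * fs))
  with_seed(seed, {
    shared <- theta_oscillator(n, fs, spec_a$theta_freq, freq_sd, amp_cv)
    mk_site <- function(spec, region) {
      # private theta is an independent oscillator realization; a common
      # fixed-phase tone would be spuriously coherent across sites
      priv <- theta_oscillator(n, fs, spec$theta_freq, freq_sd, amp_cv)
      delta <- narrowband_component(n, fs, c(1, 4))
      wn <- stats::rnorm(n)
      w <- state_envelope(states, fs, n, high_mixing, low_mixing)
      samples <- spec$theta_amp_shared * w * shared +
        spec$theta_amp_private * priv +
        spec$delta_amp * delta +
        spec$noise_sd * wn
      continuous_signal(samples, fs, region = region)
    }
    a <- mk_site(spec_a, "mPFC")
    b <- mk_site(spec_b, "HPC")
    list(a = a, b = b, states = states)
  })
}

#' Inject saturation and delta-burst artifacts into a signal
#'
#' Corrupts a copy of the signal with (a) contiguous runs of samples
#' clipped at `+/- saturation_level` SDs of the input signal, covering
#' `saturation_fraction` of all samples, and (b) large slow transients with
#' dominant 1--4 Hz energy at `delta_burst_rate` events per minute.
#' Ground-truth artifact intervals are returned alongside so rejection
#' rules can be scored against truth. To emulate common-mode movement
#' artifacts across a simultaneously recorded pair, call with the same
#' `seed` on both signals.
#'
#' @param signal A `continuous_signal`.
#' @param saturation_fraction Fraction of samples to clip, in [0, 1].
#' @param saturation_level Clip level in SD units of the input (> 0);
#'   the default 10 SD mirrors amplifier saturation near +/-2000 uV on the
#'   nominal scale.
#' @param delta_burst_rate Delta bursts per minute.
#' @param seed Integer seed.
#' @param run_len Length of each saturation run, seconds.
#' @param burst_len Length of each delta burst, seconds.
#' @param burst_amp Burst amplitude in SD units of the input.
#' @return A list with `signal` (corrupted copy) and `intervals`
#'   (data.frame: start, end in seconds, kind in saturation/delta_burst;
#'   zero rows when both rates are 0, in which case `signal` is identical
#'   to the input).
#' @export
inject_artifacts <- function(signal, saturation_fraction = 0,
                             saturation_level = 10, delta_burst_rate = 0,
                             seed = 1, run_len = 0.05, burst_len = 0.6,
                             burst_amp = 6) {
  stopifnot(saturation_fraction >= 0, saturation_fraction <= 1)
  if (saturation_level <= 0) stop("saturation_level must be > 0")
  x <- signal$samples
  fs <- signal$sampling_rate
  n <- length(x)
  s <- stats::sd(x)
  intervals <- data.frame(start = numeric(), end = numeric(),
                          kind = character(), stringsAsFactors = FALSE)
  if (saturation_fraction == 0 && delta_burst_rate == 0) {
    return(list(signal = signal, intervals = intervals))
  }
  with_seed(seed, {
    if (saturation_fraction > 0) {
      nrun <- max(1L, as.integer(round(run_len * fs)))
      n_target <- as.integer(ceiling(saturation_fraction * n))
      k <- max(1L, as.integer(ceiling(n_target / nrun)))
      starts <- sort(sample.int(n - nrun + 1L, k))
      clip <- saturation_level * s
      for (st in starts) {
        idx <- st:(st + nrun - 1L)
        x[idx] <- clip * sample(c(-1, 1), 1)
        intervals <- rbind(intervals, data.frame(
          start = signal$start_time + (st - 1L) / fs,
          end = signal$start_time + (st - 1L + nrun) / fs,
          kind = "saturation", stringsAsFactors = FALSE))
      }
    }
    if (delta_burst_rate > 0) {
      dur_min <- n / fs / 60
      k <- stats::rpois(1, delta_burst_rate * dur_min)
      nb <- as.integer(round(burst_len * fs))
      if (k > 0 && n > nb) {
        starts <- sort(sample.int(n - nb + 1L, k))
        for (st in starts) {
          fb <- stats::runif(1, 1.5, 3.5)
          tt <- (0:(nb - 1L)) / fs
          env <- 0.5 * (1 - cos(2 * pi * seq(0, 1, length.out = nb)))
          idx <- st:(st + nb - 1L)
          x[idx] <- x[idx] + burst_amp * s * env *
            sin(2 * pi * fb * tt + stats::runif(1, 0, 2 * pi))
          intervals <- rbind(intervals, data.frame(
            start = signal$start_time + (st - 1L) / fs,
            end = signal$start_time + (st - 1L + nb) / fs,
            kind = "delta_burst", stringsAsFactors = FALSE))
        }
      }
    }
    out <- continuous_signal(x, fs, region = signal$region,
                             start_time = signal$start_time)
    list(signal = out, intervals = intervals)
  })
}

# von Mises sampler (Best & Fisher 1979 rejection scheme); kappa = 0 is
# uniform on (-pi, pi].
rvonmises <- function(n, mu = 0, kappa = 1) {
  if (kappa == 0) return(stats::runif(n, -pi, pi))
  a <- 1 + sqrt(1 + 4 * kappa^2)
  b <- (a - sqrt(2 * a)) / (2 * kappa)
  r <- (1 + b^2) / (2 * b)
  out <- numeric(n)
  i <- 1L
  while (i <= n) {
    u <- stats::runif(3)
    z <- cos(pi * u[1])
    f <- (1 + r * z) / (r + z)
    c_ <- kappa * (r - f)
    if (c_ * (2 - c_) - u[2] > 0 || log(c_ / u[2]) + 1 - c_ >= 0) {
      out[i] <- mu + sign(u[3] - 0.5) * acos(f)
      i <- i + 1L
    }
  }
  wrap_pi(out)
}

# wrap angles to (-pi, pi]
wrap_pi <- function(theta) {
  w <- (theta + pi) %% (2 * pi) - pi
  w[w == -pi] <- pi
  w
}

#' Generate spikes phase-locked to a band-limited LFP rhythm
#'
#' Draws spike phases from a von Mises law with concentration `kappa` and
#' mean `preferred_phase`, then places each spike at the time where the
#' band-filtered LFP's instantaneous (Hilbert) phase attains the drawn
#' phase, in a uniformly chosen cycle. `kappa = 0` yields uniform phases.
#'
#' @param lfp A `continuous_signal`.
#' @param band Two-element Hz interval (inside Nyquist) defining the
#'   rhythm.
#' @param kappa von Mises concentration, >= 0.
#' @param preferred_phase Mean phase, radians.
#' @param rate Mean firing rate, Hz (> 0); spike count is
#'   `round(rate * duration)`.
#' @param seed Integer seed.
#' @return A `spike_train`.
#' @export
gen_locked_spikes <- function(lfp, band = c(6, 11), kappa = 2,
                              preferred_phase = 0, rate = 10, seed = 1) {
  fs <- lfp$sampling_rate
  if (band[2] >= fs / 2) stop("band outside Nyquist")
  stopifnot(kappa >= 0, rate > 0)
  n <- length(lfp$samples)
  bf <- signal::butter(3, band / (fs / 2), type = "pass")
  filt <- signal::filtfilt(bf, lfp$samples)
  ph <- Arg(analytic_signal(filt))
  phu <- cummax_phase(ph)
  dur <- n / fs
  n_spk <- max(1L, as.integer(round(rate * dur)))
  with_seed(seed, {
    theta <- rvonmises(n_spk, preferred_phase, kappa)
    # admissible cycles: unwrapped phase targets 2*pi*c + theta within range
    lo <- ceiling((phu[1] - min(theta)) / (2 * pi)) + 1
    hi <- floor((phu[n] - max(theta)) / (2 * pi)) - 1
    if (hi < lo) stop("LFP too short for requested spikes")
    cyc <- sample(lo:hi, n_spk, replace = TRUE)
    targets <- 2 * pi * cyc + theta
    idx <- findInterval(targets, phu)
    idx[idx < 1L] <- 1L; idx[idx >= n] <- n - 1L
    # linear interpolation of the crossing time
    d <- phu[idx + 1L] - phu[idx]
    frac <- ifelse(d > 0, (targets - phu[idx]) / d, 0)
    times <- lfp$start_time + (idx - 1L + frac) / fs
    spike_train(times, unit_id = "synthetic", region = lfp$region)
  })
}

# analytic signal via FFT (one-sided spectrum doubling)
analytic_signal <- function(x) {
  n <- length(x)
  X <- stats::fft(x)
  h <- numeric(n)
  if (n %% 2 == 0) {
    h[c(1, n / 2 + 1)] <- 1
    h[2:(n / 2)] <- 2
  } else {
    h[1] <- 1
    h[2:((n + 1) / 2)] <- 2
  }
  stats::fft(X * h, inverse = TRUE) / n
}

# monotone unwrapped phase (cummax of the unwrapped phase, so occasional
# phase regressions in narrowband noise cannot break crossing search)
cummax_phase <- function(ph) cummax(signal::unwrap(ph))

#' Generate a straight or tortuous position trajectory
#'
#' Straight paths keep a constant heading; tortuous paths take repeated
#' large heading changes with intermittent reversals. Steps have constant
#' arc length so the noiseless total path length equals `length` exactly.
#'
#' @param kind `"straight"` or `"tortuous"`.
#' @param length Total path length (cm), > 0.
#' @param n_points Number of track points, >= 3.
#' @param noise_sd Positional jitter SD (cm) added after path
#'   construction.
#' @param seed Integer seed.
#' @param sampling_rate Track sampling rate, Hz (default 30).
#' @return A `behavior_track`.
#' @export
gen_trajectory <- function(kind = c("straight", "tortuous"), length = 100,
                           n_points = 90, noise_sd = 0, seed = 1,
                           sampling_rate = 30) {
  kind <- match.arg(kind)
  if (length <= 0) stop("length must be > 0")
  stopifnot(n_points >= 3)
  step <- length / (n_points - 1)
  with_seed(seed, {
    heading <- if (kind == "straight") {
      rep(stats::runif(1, 0, 2 * pi), n_points - 1)
    } else {
      dh <- stats::rnorm(n_points - 1, 0, 0.45)
      flips <- stats::runif(n_points - 1) < 0.08
      dh[flips] <- dh[flips] + pi
      cumsum(dh)
    }
    x <- c(0, cumsum(step * cos(heading)))
    y <- c(0, cumsum(step * sin(heading)))
    if (noise_sd > 0) {
      x <- x + stats::rnorm(n_points, 0, noise_sd)
      y <- y + stats::rnorm(n_points, 0, noise_sd)
    }
    behavior_track(x, y, t = (0:(n_points - 1)) / sampling_rate)
  })
}
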