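#' Analysis window specification
#'
#' Bundles the streaming-coherence analysis parameters: total window length
#' and step, the frequency grid the coherence spectrum is evaluated on, the
#' theta and delta summary bands, and the Welch internals (segment length
#' and overlap). The defaults are the real-time design constants: 1.25 s
#' windows advanced in 250 ms steps, a 1--20 Hz grid at 0.5 Hz spacing, a
#' 6--11 Hz theta band and a 1--4 Hz delta band. Welch internals are
#' 0.5 s Hann-tapered segments with 50% overlap (K = 4 segments per
#' window), chosen so the 0.5 Hz grid is resolvable while enough segments
#' are averaged for a stable estimate.
#'
#' @param window_len Window length in seconds.
#' @param step Step between successive windows in seconds (0 < step <=
#'   window_len).
#' @param freq_grid Strictly increasing frequency grid in Hz.
#' @param theta_band,delta_band Two-element Hz intervals, inside the grid
#'   range.
#' @param seg_len Welch segment length in seconds.
#' @param seg_overlap Welch fractional segment overlap in [0, 1).
#' @return An object of class `window_spec`.
#' @export
window_spec <- function(window_len = 1.25, step = 0.25,
                        freq_grid = seq(1, 20, by = 0.5),
                        theta_band = c(6, 11), delta_band = c(1, 4),
                        seg_len = 0.5, seg_overlap = 0.5) {
  stopifnot(step > 0, step <= window_len,
            all(diff(freq_grid) > 0),
            length(theta_band) == 2L, length(delta_band) == 2L,
            theta_band[1] >= min(freq_grid), theta_band[2] <= max(freq_grid),
            delta_band[1] >= min(freq_grid), delta_band[2] <= max(freq_grid),
            seg_len > 0, seg_overlap >= 0, seg_overlap < 1)
  structure(list(window_len = window_len, step = step, freq_grid = freq_grid,
                 theta_band = theta_band, delta_band = delta_band,
                 seg_len = seg_len, seg_overlap = seg_overlap),
            class = "window_spec")
}

#' Baseline statistics for real-time z-scoring
#'
#' Mean and SD of the raw voltage computed over a baseline recording
#' (conventionally a 10 min rest session preceding closed-loop testing),
#' used to z-score streaming windows.
#'
#' @param signal A `continuous_signal`, or NULL if `mean`/`sd` are given.
#' @param mean,sd Directly supplied statistics (used when `signal` is
#'   NULL).
#' @return An object of class `baseline_stats` with fields mean, sd,
#'   duration.
#' @export
baseline_stats <- function(signal = NULL, mean = NULL, sd = NULL) {
  if (!is.null(signal)) {
    mean <- base::mean(signal$samples)
    sd <- stats::sd(signal$samples)
    duration <- signal_duration(signal)
  } else {
    duration <- NA_real_
  }
  if (!is.finite(sd) || sd <= 0) stop("baseline sd must be > 0")
  structure(list(mean = mean, sd = sd, duration = duration),
            class = "baseline_stats")
}

#' Remove a cubic trend from a window
#'
#' Subtracts the least-squares third-degree polynomial fit over the window,
#' the real-time detrending step applied to every streaming window before
#' z-scoring and coherence estimation. Uses an orthogonal polynomial basis
#' for numerical stability.
#'
#' @param x Numeric window of at least 8 samples.
#' @return The detrended window (same length).
#' @export
detrend_poly3 <- function(x) {
  n <- length(x)
  if (n < 8L) stop("window shorter than 8 samples")
  basis <- cbind(1, stats::poly(seq_len(n), degree = 3))
  fit <- stats::lm.fit(basis, x)
  as.numeric(fit$residuals)
}

#' Z-score a window against baseline statistics
#'
#' @param x Numeric window.
#' @param baseline A `baseline_stats` object.
#' @return `(x - baseline$mean) / baseline$sd`.
#' @export
zscore_with_baseline <- function(x, baseline) {
  if (baseline$sd <= 0) stop("baseline sd must be > 0")
  (x - baseline$mean) / baseline$sd
}

# Hann taper, symmetric convention.
hann_taper <- function(n) 0.5 * (1 - cos(2 * pi * (0:(n - 1)) / (n - 1)))

# Segment start indices for Welch averaging.
welch_starts <- function(n, nseg, noverlap) {
  hop <- nseg - noverlap
  starts <- seq(1L, n - nseg + 1L, by = hop)
  starts
}

#' Welch magnitude-squared coherence on a fixed frequency grid
#'
#' Segment-averaged cross- and auto-spectra (Hann-tapered segments per the
#' `window_spec` internals) evaluated by direct DFT at exactly the grid
#' frequencies, then `|Pxy|^2 / (Pxx * Pyy)`. Direct evaluation at the
#' requested frequencies reproduces the behaviour of grid-driven coherence
#' estimators without a zero-padding choice.
#'
#' Zero-variance input leaves coherence undefined: the function returns
#' all-NA values with a warning rather than silently reporting 0.
#'
#' @param x,y Equal-length numeric windows.
#' @param spec A `window_spec`.
#' @param sampling_rate Sampling rate in Hz.
#' @return Numeric vector of coherence values in [0, 1] on
#'   `spec$freq_grid` (all NA if either input has zero variance).
#' @export
msc_welch <- function(x, y, spec, sampling_rate) {
  if (length(x) != length(y)) stop("length mismatch between the two windows")
  n <- length(x)
  nseg <- as.integer(round(spec$seg_len * sampling_rate))
  noverlap <- as.integer(round(nseg * spec$seg_overlap))
  if (n < 2L * nseg) stop("window must be at least 2 Welch segments long")
  # near-zero variance (e.g. a fully clipped window after detrending)
  # leaves coherence undefined; numerical jitter must not masquerade as
  # signal
  if (stats::sd(x) < 1e-8 || stats::sd(y) < 1e-8) {
    warning("zero-variance input: coherence undefined")
    return(rep(NA_real_, length(spec$freq_grid)))
  }
  starts <- welch_starts(n, nseg, noverlap)
  w <- hann_taper(nseg)
  # DFT basis at the grid frequencies: (nseg x nf) complex matrix
  tt <- (0:(nseg - 1)) / sampling_rate
  E <- exp(-2i * pi * outer(tt, spec$freq_grid))
  segmat <- function(z) {
    m <- vapply(starts, function(s) z[s:(s + nseg - 1L)] * w,
                numeric(nseg))
    # columns are tapered segments
    m
  }
  Fx <- crossprod(E, segmat(x))   # nf x K, t(E) %*% segs (E holds e^{-i...})
  Fy <- crossprod(E, segmat(y))
  Pxx <- rowMeans(Mod(Fx)^2)
  Pyy <- rowMeans(Mod(Fy)^2)
  Pxy <- rowMeans(Fx * Conj(Fy))
  coh <- Mod(Pxy)^2 / (Pxx * Pyy)
  pmin(pmax(coh, 0), 1)
}

#' Band-mean coherence summaries
#'
#' Arithmetic mean of the coherence spectrum over the grid points falling
#' inside the theta and delta bands, both endpoints inclusive (the default
#' 6--11 Hz band on the 0.5 Hz grid averages 11 points).
#'
#' @param coherence Coherence values on `spec$freq_grid`.
#' @param spec A `window_spec`.
#' @return A list with `theta_value` and `delta_value`.
#' @export
theta_summary <- function(coherence, spec) {
  band_mean <- function(band) {
    sel <- spec$freq_grid >= band[1] & spec$freq_grid <= band[2]
    if (!any(sel)) stop("band contains no grid points")
    mean(coherence[sel])
  }
  list(theta_value = band_mean(spec$theta_band),
       delta_value = band_mean(spec$delta_band))
}

#' Artifact verdict for a z-scored window pair
#'
#' A window pair is `saturated` if, in either signal, more than
#' `max_fraction` of samples exceed `saturation_sd` in absolute z units
#' (strict inequality: exactly 1% passes). Otherwise it is
#' `delta_dominant` if the delta-band coherence exceeds the theta-band
#' coherence. Otherwise it is `clean`. Saturation is checked first because
#' a saturated window's spectra are not interpretable.
#'
#' @param zx,zy Z-scored windows (equal length).
#' @param coherence Coherence spectrum already computed for the pair.
#' @param spec A `window_spec`.
#' @param saturation_sd Z threshold for a saturated sample (default 4).
#' @param max_fraction Maximum tolerated saturated fraction (default 0.01).
#' @return One of `"saturated"`, `"delta_dominant"`, `"clean"`.
#' @export
artifact_verdict <- function(zx, zy, coherence, spec,
                             saturation_sd = 4, max_fraction = 0.01) {
  if (length(zx) != length(zy)) stop("length mismatch between the two windows")
  frac <- function(z) mean(abs(z) > saturation_sd)
  if (frac(zx) > max_fraction || frac(zy) > max_fraction) return("saturated")
  s <- theta_summary(coherence, spec)
  if (is.na(s$theta_value)) return("saturated")
  if (s$delta_value > s$theta_value) return("delta_dominant")
  "clean"
}

#' Sliding-window coherence epochs over a signal pair
#'
#' Applies the full streaming pipeline offline: slide a `window_spec`
#' window over the pair, detrend (cubic), z-score against the per-channel
#' baselines, compute Welch coherence, summarize theta/delta, and attach
#' an artifact verdict. The first window is evaluated only once a full
#' window of data exists.
#'
#' @param x,y `continuous_signal`s, time-aligned, equal rate and length.
#' @param baseline_x,baseline_y `baseline_stats` per channel.
#' @param spec A `window_spec`.
#' @param saturation_sd,max_fraction Artifact-gating parameters.
#' @return A list with `table` (data.frame: t_start, theta_value,
#'   delta_value, verdict) and `coherence` (matrix, one row per window, on
#'   `spec$freq_grid`).
#' @export
coherence_epochs <- function(x, y, baseline_x, baseline_y, spec,
                             saturation_sd = 4, max_fraction = 0.01) {
  stopifnot(x$sampling_rate == y$sampling_rate,
            length(x$samples) == length(y$samples))
  fs <- x$sampling_rate
  nwin <- as.integer(round(spec$window_len * fs))
  nstep <- as.integer(round(spec$step * fs))
  n <- length(x$samples)
  if (n < nwin) stop("stream shorter than one window")
  starts <- seq(1L, n - nwin + 1L, by = nstep)
  nf <- length(spec$freq_grid)
  coh <- matrix(NA_real_, length(starts), nf)
  theta <- delta <- numeric(length(starts))
  verdict <- character(length(starts))
  for (i in seq_along(starts)) {
    idx <- starts[i]:(starts[i] + nwin - 1L)
    wx <- detrend_poly3(x$samples[idx])
    wy <- detrend_poly3(y$samples[idx])
    zx <- zscore_with_baseline(wx, baseline_x)
    zy <- zscore_with_baseline(wy, baseline_y)
    ci <- suppressWarnings(msc_welch(zx, zy, spec, fs))
    coh[i, ] <- ci
    if (anyNA(ci)) {
      theta[i] <- NA_real_; delta[i] <- NA_real_
      verdict[i] <- "saturated"
    } else {
      s <- theta_summary(ci, spec)
      theta[i] <- s$theta_value; delta[i] <- s$delta_value
      verdict[i] <- artifact_verdict(zx, zy, ci, spec,
                                     saturation_sd, max_fraction)
    }
  }
  t_start <- x$start_time + (starts - 1L) / fs
  list(table = data.frame(t_start = t_start, theta_value = theta,
                          delta_value = delta, verdict = verdict,
                          stringsAsFactors = FALSE),
       coherence = coh)
}

#' Per-subject coherence threshold profile
#'
#' Calibrates trigger thresholds from a distribution of clean theta
#' coherence values: the weak-coherence threshold is 1 SD below the mean
#' and the strong-coherence threshold 1 SD above, using the sample SD
#' (n - 1 denominator), so each subject carries a unique numerical pair.
#'
#' @param theta_values Clean theta coherence values in [0, 1], length >= 2.
#' @param subject_id Subject label.
#' @return An object of class `threshold_profile` with fields mean, sd,
#'   high, low, subject_id, n_samples.
#' @export
calibrate_thresholds <- function(theta_values, subject_id = "subject") {
  theta_values <- theta_values[is.finite(theta_values)]
  if (length(theta_values) < 2L) stop("need at least 2 theta values")
  if (any(theta_values < 0 | theta_values > 1)) {
    stop("theta values must lie in [0, 1]")
  }
  m <- mean(theta_values)
  s <- stats::sd(theta_values)
  if (s == 0) stop("degenerate distribution: all theta values equal")
  structure(list(mean = m, sd = s, high = m + s, low = m - s,
                 subject_id = subject_id, n_samples = length(theta_values)),
            class = "threshold_profile")
}

#' @export
print.threshold_profile <- function(x, ...) {
  cat(sprintf(
    "<threshold_profile> %s: mean %.3f, sd %.3f, high %.3f, low %.3f (n=%d)\n",
    x$subject_id, x$mean, x$sd, x$high, x$low, x$n_samples))
  invisible(x)
}

#' Write / read a threshold profile as delimited text
#' @param profile A `threshold_profile`.
#' @param path File path.
#' @return `read_thresholds()` returns a `threshold_profile`.
#' @export
write_thresholds <- function(profile, path) {
  df <- data.frame(field = c("subject_id", "mean", "sd", "high", "low",
                             "n_samples"),
                   value = c(profile$subject_id,
                             sprintf("%.17g", c(profile$mean, profile$sd,
                                                profile$high, profile$low)),
                             profile$n_samples))
  utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_thresholds
#' @export
read_thresholds <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  g <- function(k) df$value[match(k, df$field)]
  structure(list(mean = as.numeric(g("mean")), sd = as.numeric(g("sd")),
                 high = as.numeric(g("high")), low = as.numeric(g("low")),
                 subject_id = g("subject_id"),
                 n_samples = as.integer(g("n_samples"))),
            class = "threshold_profile")
}

#' Streaming threshold detector
#'
#' Slides the analysis window over a time-aligned signal pair in
#' `spec$step` increments, evaluating each window once a full window of
#' data exists. On each *clean* window the theta coherence is compared to
#' the calibrated threshold: in `"high"` mode the detector triggers when
#' `theta_value >= thresholds$high`; in `"low"` mode when
#' `theta_value <= thresholds$low`. Saturated or delta-dominant windows can
#' never trigger. If no clean crossing occurs before `timeout` seconds of
#' stream time, the outcome is a timeout.
#'
#' @param x,y `continuous_signal`s (the streams).
#' @param baseline_x,baseline_y `baseline_stats` per channel.
#' @param spec A `window_spec`.
#' @param thresholds A `threshold_profile`.
#' @param mode `"high"` or `"low"`.
#' @param timeout Timeout in seconds (stream time from the start of the
#'   stream).
#' @return A list with `trigger_time` (seconds from stream start: the end
#'   of the triggering window, or `timeout`), `cause` (`"threshold"` or
#'   `"timeout"`), and `n_windows_evaluated`.
#' @export
stream_detect <- function(x, y, baseline_x, baseline_y, spec, thresholds,
                          mode = c("high", "low"), timeout = 30) {
  mode <- match.arg(mode)
  fs <- x$sampling_rate
  nwin <- as.integer(round(spec$window_len * fs))
  nstep <- as.integer(round(spec$step * fs))
  n <- length(x$samples)
  if (n < nwin) stop("stream shorter than one window")
  starts <- seq(1L, n - nwin + 1L, by = nstep)
  n_eval <- 0L
  for (s in starts) {
    decision_time <- (s - 1L + nwin) / fs   # stream time when window complete
    if (decision_time > timeout) break
    idx <- s:(s + nwin - 1L)
    wx <- detrend_poly3(x$samples[idx])
    wy <- detrend_poly3(y$samples[idx])
    zx <- zscore_with_baseline(wx, baseline_x)
    zy <- zscore_with_baseline(wy, baseline_y)
    ci <- suppressWarnings(msc_welch(zx, zy, spec, fs))
    n_eval <- n_eval + 1L
    if (anyNA(ci)) next
    v <- artifact_verdict(zx, zy, ci, spec)
    if (v != "clean") next
    th <- theta_summary(ci, spec)$theta_value
    hit <- switch(mode,
                  high = th >= thresholds$high,
                  low  = th <= thresholds$low)
    if (hit) {
      return(list(trigger_time = decision_time, cause = "threshold",
                  n_windows_evaluated = n_eval))
    }
  }
  list(trigger_time = timeout, cause = "timeout",
       n_windows_evaluated = n_eval)
}
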