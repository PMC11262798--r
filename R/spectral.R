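# Offline spectral analyses: multitaper power, theta peak frequency,
# event-locked coherograms, normalized difference scores, and the
# coherence autocorrelation-vs-shuffle analysis.

#' Discrete prolate spheroidal (Slepian) tapers
#'
#' Computes the first `k` DPSS tapers with time-bandwidth product `nw` via
#' the symmetric tridiagonal eigenproblem. For long windows (n > 1024) the
#' tapers are computed exactly at n = 1024 and spline-interpolated to n,
#' then re-orthonormalized; the error of this standard shortcut is
#' negligible for spectral averaging.
#'
#' @param n Taper length in samples.
#' @param nw Time-bandwidth product (default 2).
#' @param k Number of tapers (default 3).
#' @return An n x k matrix; columns are unit-norm tapers.
#' @export
dpss_tapers <- function(n, nw = 2, k = 3) {
  exact <- function(m) {
    w <- nw / m
    t <- 0:(m - 1)
    diag_main <- ((m - 1 - 2 * t) / 2)^2 * cos(2 * pi * w)
    diag_off <- (1:(m - 1)) * (m - (1:(m - 1))) / 2
    A <- matrix(0, m, m)
    A[cbind(t + 1, t + 1)] <- diag_main
    A[cbind(1:(m - 1), 2:m)] <- diag_off
    A[cbind(2:m, 1:(m - 1))] <- diag_off
    e <- eigen(A, symmetric = TRUE)
    v <- e$vectors[, seq_len(k), drop = FALSE]
    # sign convention: symmetric tapers have positive mean, antisymmetric
    # tapers a positive initial slope
    for (j in seq_len(k)) {
      s <- sum(v[, j])
      if (abs(s) > 1e-8) { if (s < 0) v[, j] <- -v[, j] }
      else if (v[2, j] - v[1, j] < 0) v[, j] <- -v[, j]
    }
    v
  }
  if (n <= 1024) {
    v <- exact(n)
  } else {
    v0 <- exact(1024)
    x0 <- seq(0, 1, length.out = 1024)
    x1 <- seq(0, 1, length.out = n)
    v <- apply(v0, 2, function(col) stats::spline(x0, col, xout = x1)$y)
    v <- qr.Q(qr(v))             # re-orthonormalize
    for (j in seq_len(k)) if (sum(v[, j]) < 0 &&
                              abs(sum(v[, j])) > 1e-8) v[, j] <- -v[, j]
  }
  sweep(v, 2, sqrt(colSums(v^2)), "/")
}

#' Multitaper power spectral density (log10)
#'
#' Slepian-tapered spectra (3 tapers, time-bandwidth product 2 by
#' default), averaged across tapers, then log10-transformed to flatten the
#' 1/f power law. Frequency resolution is set by the epoch length.
#'
#' @param epoch Numeric sample vector.
#' @param sampling_rate Hz.
#' @param nw Time-bandwidth product.
#' @param k Number of tapers.
#' @param fmax Highest frequency to return (default Nyquist).
#' @return A list of class `spectral_result`: `freqs` (Hz), `power`
#'   (log10 units), `taper_params`.
#' @export
psd_multitaper <- function(epoch, sampling_rate, nw = 2, k = 3,
                           fmax = sampling_rate / 2) {
  n <- length(epoch)
  if (stats::sd(epoch) == 0) stop("flat epoch: power undefined")
  v <- dpss_tapers(n, nw, k)
  spec <- rowMeans(vapply(seq_len(k), function(j) {
    Mod(stats::fft(epoch * v[, j]))^2
  }, numeric(n))) / sampling_rate
  nf <- floor(n / 2) + 1L
  freqs <- (0:(nf - 1)) * sampling_rate / n
  keep <- freqs <= fmax
  structure(list(freqs = freqs[keep], power = log10(spec[seq_len(nf)][keep]),
                 taper_params = c(n_tapers = k, time_bandwidth = nw)),
            class = "spectral_result")
}

#' Theta peak frequency
#'
#' Frequency of maximum power within the band (default 4--12 Hz); ties
#' break toward the lower frequency.
#'
#' @param result A `spectral_result`.
#' @param band Two-element Hz interval.
#' @return Peak frequency in Hz.
#' @export
theta_peak_frequency <- function(result, band = c(4, 12)) {
  sel <- result$freqs >= band[1] & result$freqs <= band[2]
  if (!any(sel)) stop("band does not intersect the frequency axis")
  f <- result$freqs[sel]
  f[which.max(result$power[sel])]
}

#' Event-locked coherogram, averaged across events
#'
#' Extracts epochs around each matching event from both signals
#' (default 2 s before to 0.5 s after), computes moving-window Welch
#' coherence inside each epoch using the `window_spec` mechanics, and
#' averages across events. Times are relative to the event (the left edge
#' of each moving window).
#'
#' @param x,y Time-aligned `continuous_signal`s.
#' @param events An `event_log`.
#' @param kind Event kind to lock to (default `"choice_entry"`).
#' @param window `c(pre, post)` seconds around the event.
#' @param spec A `window_spec` for the moving windows.
#' @return A list of class `coherogram`: `times` (s, relative), `freqs`
#'   (Hz), `values` (time x frequency coherence matrix in [0, 1]),
#'   `n_events`.
#' @export
event_coherogram <- function(x, y, events, kind = "choice_entry",
                             window = c(2.0, 0.5), spec = window_spec()) {
  fs <- x$sampling_rate
  ex <- extract_epochs(x, events, kind, window)
  ey <- extract_epochs(y, events, kind, window)
  if (length(ex$epochs) == 0L) stop("no usable events")
  nwin <- as.integer(round(spec$window_len * fs))
  nstep <- as.integer(round(spec$step * fs))
  n_ep <- length(ex$epochs[[1]])
  if (n_ep < nwin) stop("epoch shorter than one moving window")
  starts <- seq(1L, n_ep - nwin + 1L, by = nstep)
  acc <- matrix(0, length(starts), length(spec$freq_grid))
  for (e in seq_along(ex$epochs)) {
    for (i in seq_along(starts)) {
      idx <- starts[i]:(starts[i] + nwin - 1L)
      acc[i, ] <- acc[i, ] +
        msc_welch(ex$epochs[[e]][idx], ey$epochs[[e]][idx], spec, fs)
    }
  }
  structure(list(times = -window[1] + (starts - 1L) / fs,
                 freqs = spec$freq_grid,
                 values = acc / length(ex$epochs),
                 n_events = length(ex$epochs)),
            class = "coherogram")
}

#' Normalized difference score
#'
#' `(X - Y) / (X + Y)`, elementwise. Antisymmetric in its arguments and
#' bounded in [-1, 1] for nonnegative inputs. Undefined where `X + Y = 0`;
#' those elements are returned as NA with a warning.
#'
#' @param x,y Numeric scalars or arrays of equal length.
#' @return The score(s).
#' @export
norm_diff <- function(x, y) {
  s <- x + y
  bad <- s == 0
  if (any(bad)) warning("norm_diff undefined where X + Y = 0; returning NA")
  out <- (x - y) / s
  out[bad] <- NA_real_
  out
}

#' Coherence autocorrelation against a temporally shuffled null
#'
#' Autocorrelation by lag of a theta-coherence time series (biased
#' estimator, normalized by lag 0), compared to a null band from random
#' temporal permutations of the same values. Because successive moving
#' windows share data (1.25 s windows at 250 ms steps overlap up to four
#' steps), real-vs-null comparisons are reported only from `min_lag`
#' onward (default 5, the first lag with disjoint windows).
#'
#' @param theta_values Numeric coherence series (uniform window step).
#' @param n_shuffles Number of permutations (>= 100).
#' @param min_lag First reported lag.
#' @param max_lag Last lag computed (default `min(40, n - 2)`).
#' @param band Central coverage of the null band (default 0.95).
#' @return A list: `lags`, `autocorr` (real series), `null_lo`, `null_hi`
#'   (per-lag band over shuffles), `reported` (logical, lag >= min_lag).
#' @export
coherence_autocorr <- function(theta_values, n_shuffles = 1000,
                               min_lag = 5, max_lag = NULL, band = 0.95) {
  n <- length(theta_values)
  if (n <= min_lag + 1L) stop("series too short")
  if (n_shuffles < 100) stop("need at least 100 shuffles")
  if (is.null(max_lag)) max_lag <- min(40L, n - 2L)
  ac <- function(z) {
    stats::acf(z, lag.max = max_lag, plot = FALSE,
               demean = TRUE)$acf[, 1, 1]
  }
  real <- ac(theta_values)
  null_mat <- vapply(seq_len(n_shuffles),
                     function(i) ac(sample(theta_values)),
                     numeric(max_lag + 1L))
  alpha <- (1 - band) / 2
  lags <- 0:max_lag
  list(lags = lags, autocorr = real,
       null_lo = apply(null_mat, 1, stats::quantile, probs = alpha),
       null_hi = apply(null_mat, 1, stats::quantile, probs = 1 - alpha),
       reported = lags >= min_lag)
}
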