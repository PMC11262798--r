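# Spike-phase entrainment and spike-field coherence under high/low
# coherence states, with the epoch-cleaning pipeline for spike analyses.

#' Clean LFP epochs for spike analyses and map spikes into the
#' concatenated timeline
#'
#' Session-level cleaning for entrainment analyses: per region, epochs are
#' z-scored against the mean/SD of the concatenated session signal and an
#' epoch is removed if more than `max_fraction` of its samples exceed the
#' per-region SD cutoff in absolute value, or (for mPFC/VMT) if any sample
#' exceeds `abs_limit` microvolts in either direction. An epoch failing in
#' any region is removed from all regions so the sites stay aligned.
#' Surviving epochs are concatenated and spike timestamps are mapped into
#' the concatenated timeline, spikes in removed epochs dropped, and
#' duplicate timestamps removed.
#'
#' @param epoch_mats Named list (by region) of numeric matrices, one
#'   column per epoch, rows = samples; all regions share epoch times.
#' @param t_start Epoch start times in seconds (non-overlapping).
#' @param sampling_rate Hz.
#' @param spikes Optional `spike_train` or list of `spike_train`s to map.
#' @param sd_cutoff Per-region z cutoff: scalar or named vector (default
#'   4).
#' @param abs_limit Absolute voltage limit (default 3500) applied to
#'   regions in `abs_regions`.
#' @param abs_regions Regions screened by the absolute limit.
#' @param max_fraction Maximum tolerated extreme-sample fraction (strict
#'   `>` comparison).
#' @return A list: `kept` (logical per epoch), `concat` (named list of
#'   concatenated sample vectors as `continuous_signal`s starting at 0),
#'   `spikes` (mapped trains, same shape as input), `offsets`
#'   (concatenated-start second of each kept epoch).
#' @export
clean_epochs_for_spikes <- function(epoch_mats, t_start, sampling_rate,
                                    spikes = NULL, sd_cutoff = 4,
                                    abs_limit = 3500,
                                    abs_regions = c("mPFC", "VMT"),
                                    max_fraction = 0.01) {
  stopifnot(length(epoch_mats) >= 1, !is.null(names(epoch_mats)))
  nsamp <- nrow(epoch_mats[[1]])
  K <- ncol(epoch_mats[[1]])
  stopifnot(length(t_start) == K)
  dur <- nsamp / sampling_rate
  ord <- order(t_start)
  if (K > 1 && any(diff(t_start[ord]) < dur)) {
    stop("overlapping epochs: spike mapping would be ambiguous")
  }
  if (length(sd_cutoff) == 1L && is.null(names(sd_cutoff))) {
    sd_cutoff <- stats::setNames(rep(sd_cutoff, length(epoch_mats)),
                                 names(epoch_mats))
  }
  drop <- rep(FALSE, K)
  for (rg in names(epoch_mats)) {
    m <- epoch_mats[[rg]]
    mu <- mean(m); sdv <- stats::sd(as.numeric(m))
    cut <- sd_cutoff[[rg]]
    frac <- colMeans(abs((m - mu) / sdv) > cut)
    drop <- drop | frac > max_fraction
    if (rg %in% abs_regions) {
      drop <- drop | apply(abs(m) > abs_limit, 2, any)
    }
  }
  kept <- !drop
  keep_idx <- which(kept)
  offsets <- (seq_along(keep_idx) - 1L) * dur
  concat <- lapply(names(epoch_mats), function(rg) {
    continuous_signal(as.numeric(epoch_mats[[rg]][, keep_idx]),
                      sampling_rate,
                      region = if (rg %in% c("mPFC", "HPC", "VMT")) rg
                               else "other")
  })
  names(concat) <- names(epoch_mats)
  map_one <- function(sp) {
    ts_new <- numeric(0)
    for (j in seq_along(keep_idx)) {
      e <- keep_idx[j]
      sel <- sp$timestamps >= t_start[e] & sp$timestamps < t_start[e] + dur
      ts_new <- c(ts_new, offsets[j] + sp$timestamps[sel] - t_start[e])
    }
    spike_train(ts_new, unit_id = sp$unit_id, region = sp$region)
  }
  mapped <- NULL
  if (!is.null(spikes)) {
    mapped <- if (inherits(spikes, "spike_train")) map_one(spikes)
              else lapply(spikes, map_one)
  }
  list(kept = kept, concat = concat, spikes = mapped, offsets = offsets)
}

#' Spike phases against the theta-filtered LFP, with a theta/delta gate
#'
#' Filters the LFP to the theta band with a third-order zero-phase
#' (forward-backward) Butterworth filter, takes the analytic-signal
#' (Hilbert) phase at each spike time, and includes a spike only if the
#' instantaneous theta envelope is at least `gate_ratio` times the
#' instantaneous delta envelope at that time.
#'
#' @param lfp A `continuous_signal`.
#' @param spikes A `spike_train` (non-empty; spikes outside the record are
#'   dropped).
#' @param theta_band,delta_band Hz intervals.
#' @param gate_ratio Required theta/delta envelope ratio (default 2).
#' @return A list of class `spike_phase_set`: `phases` (radians in
#'   (-pi, pi]), `n`, `n_total`, `unit_id`.
#' @export
spike_phases <- function(lfp, spikes, theta_band = c(4, 12),
                         delta_band = c(1, 4), gate_ratio = 2) {
  if (length(spikes$timestamps) == 0L) stop("empty spike train")
  fs <- lfp$sampling_rate
  n <- length(lfp$samples)
  band_analytic <- function(band) {
    bf <- signal::butter(3, band / (fs / 2), type = "pass")
    analytic_signal(signal::filtfilt(bf, lfp$samples))
  }
  a_theta <- band_analytic(theta_band)
  a_delta <- band_analytic(delta_band)
  idx <- time_to_index(spikes$timestamps, lfp)
  inside <- idx >= 1L & idx <= n
  idx <- idx[inside]
  gate <- Mod(a_theta[idx]) >= gate_ratio * Mod(a_delta[idx])
  phases <- wrap_pi(Arg(a_theta[idx[gate]]))
  structure(list(phases = phases, n = length(phases),
                 n_total = length(spikes$timestamps),
                 unit_id = spikes$unit_id),
            class = "spike_phase_set")
}

phase_vector <- function(x) {
  if (inherits(x, "spike_phase_set")) x$phases else as.numeric(x)
}

#' Rayleigh test of circular non-uniformity
#'
#' `z = n * Rbar^2` with `Rbar` the mean resultant length; the p-value
#' uses the standard small-sample-corrected approximation. Units with at
#' most `min_n` phases are not tested (returned as excluded, not an
#' error), per the inclusion rule requiring more than 50 phase estimates.
#'
#' @param phases A `spike_phase_set` or numeric phase vector (radians).
#' @param min_n Minimum spike count (strict `>` comparison; default 50).
#' @param alpha Significance level for the `significant` flag.
#' @return A list: `rayleigh_z`, `rayleigh_p`, `mrl` (plain resultant
#'   length), `n_spikes`, `significant`, `excluded`.
#' @export
rayleigh <- function(phases, min_n = 50, alpha = 0.05) {
  th <- phase_vector(phases)
  n <- length(th)
  if (n <= min_n) {
    return(list(rayleigh_z = NA_real_, rayleigh_p = NA_real_,
                mrl = NA_real_, n_spikes = n, significant = NA,
                excluded = TRUE))
  }
  Rbar <- Mod(mean(exp(1i * th)))
  Rn <- n * Rbar
  z <- n * Rbar^2
  p <- exp(sqrt(1 + 4 * n + 4 * (n^2 - Rn^2)) - (1 + 2 * n))
  p <- min(max(p, 0), 1)
  list(rayleigh_z = z, rayleigh_p = p, mrl = Rbar, n_spikes = n,
       significant = p < alpha, excluded = FALSE)
}

#' Bootstrapped mean resultant length
#'
#' Draws `sample_size` phases (without replacement by default) `reps`
#' times and returns the average resultant length over draws, the
#' spike-count-controlled MRL used for entrainment strength.
#'
#' @param phases A `spike_phase_set` or numeric phase vector.
#' @param sample_size Phases per draw (default 50).
#' @param reps Number of draws (default 1000).
#' @param replace Sample with replacement (default FALSE).
#' @param seed Optional seed for reproducibility (uses current RNG state
#'   when NULL).
#' @return Mean resultant length in [0, 1] averaged over draws.
#' @export
bootstrap_mrl <- function(phases, sample_size = 50, reps = 1000,
                          replace = FALSE, seed = NULL) {
  th <- phase_vector(phases)
  n <- length(th)
  if (n < sample_size) stop("fewer phases than sample_size")
  ph <- exp(1i * th)
  draw <- function() {
    Mod(mean(ph[sample.int(n, sample_size, replace = replace)]))
  }
  run <- function() mean(vapply(seq_len(reps), function(i) draw(),
                                numeric(1)))
  if (is.null(seed)) run() else with_seed(seed, run())
}

#' Morlet-wavelet spike-field coherence
#'
#' Convolves the LFP with complex Morlet wavelets (six cycles by default)
#' across 1--20 Hz at 0.5 Hz resolution, reads the wavelet phase at each
#' spike time, and reports per frequency the length of the average unit
#' phasor over spikes, `SFC_f = |sum_k e^{-i theta_k}| / N`. Spikes within
#' half a wavelet length of either record edge are excluded at that
#' frequency. The statistic is phase-only, hence invariant to LFP
#' amplitude scaling and wavelet normalization.
#'
#' @param lfp A `continuous_signal`.
#' @param spikes A `spike_train`.
#' @param freqs Frequency grid, Hz.
#' @param cycles Wavelet width in cycles.
#' @return A list of class `sfc_spectrum`: `freqs`, `sfc` (values in
#'   [0, 1]), `n_spikes` (eligible count per frequency).
#' @export
spike_field_coherence <- function(lfp, spikes, freqs = seq(1, 20, by = 0.5),
                                  cycles = 6) {
  fs <- lfp$sampling_rate
  n <- length(lfp$samples)
  idx <- time_to_index(spikes$timestamps, lfp)
  idx <- idx[idx >= 1L & idx <= n]
  if (length(idx) == 0L) stop("no spikes inside the record")
  sfc <- numeric(length(freqs))
  nspk <- integer(length(freqs))
  for (i in seq_along(freqs)) {
    f <- freqs[i]
    sd_t <- cycles / (2 * pi * f)
    half <- as.integer(ceiling(3.5 * sd_t * fs))
    tt <- (-half:half) / fs
    w <- exp(2i * pi * f * tt) * exp(-tt^2 / (2 * sd_t^2))
    w <- w / sqrt(sum(Mod(w)^2))              # L2 norm (phase unaffected)
    nfft <- stats::nextn(n + length(w) - 1L, 2)
    conv <- stats::fft(stats::fft(c(lfp$samples, rep(0, nfft - n))) *
                       stats::fft(c(w, rep(0, nfft - length(w)))),
                       inverse = TRUE) / nfft
    analytic <- conv[(half + 1L):(half + n)]  # align wavelet center
    ok <- idx > half & idx <= n - half
    if (!any(ok)) {
      sfc[i] <- NA_real_; nspk[i] <- 0L
      next
    }
    th <- Arg(analytic[idx[ok]])
    sfc[i] <- Mod(mean(exp(-1i * th)))
    nspk[i] <- sum(ok)
  }
  if (all(nspk == 0L)) stop("all spikes fall in edge-excluded zones")
  structure(list(freqs = freqs, sfc = sfc, n_spikes = nspk),
            class = "sfc_spectrum")
}

#' Entrainment summary across units and coherence states
#'
#' Computes per-unit spike phases in the high- and low-coherence LFP
#' timelines, applies the inclusion rule (more than `min_n` gated phases
#' in both states), runs the Rayleigh test and bootstrapped MRL per
#' state, and reports per-unit normalized difference scores
#' (high vs low) of MRL and Rayleigh z together with the proportion of
#' significantly entrained units per state.
#'
#' @param units_high,units_low Lists of `spike_train`s (same units, times
#'   mapped into each state's concatenated timeline, e.g. from
#'   [clean_epochs_for_spikes()]).
#' @param lfp_high,lfp_low `continuous_signal`s (state timelines).
#' @param alpha Significance level.
#' @param min_n Inclusion threshold (strict).
#' @param sample_size,reps Bootstrap MRL parameters.
#' @param ... Passed to [spike_phases()].
#' @return A list: `units` (data.frame with per-unit, per-state z, p, MRL
#'   and NormDiff columns), `prop_significant` (named high/low),
#'   `n_included`.
#' @export
state_entrainment_summary <- function(units_high, units_low, lfp_high,
                                      lfp_low, alpha = 0.05, min_n = 50,
                                      sample_size = 50, reps = 1000, ...) {
  stopifnot(length(units_high) == length(units_low))
  rows <- list()
  for (u in seq_along(units_high)) {
    ph_h <- spike_phases(lfp_high, units_high[[u]], ...)
    ph_l <- spike_phases(lfp_low, units_low[[u]], ...)
    if (ph_h$n <= min_n || ph_l$n <= min_n) next
    rh <- rayleigh(ph_h, min_n = min_n, alpha = alpha)
    rl <- rayleigh(ph_l, min_n = min_n, alpha = alpha)
    mh <- bootstrap_mrl(ph_h, sample_size, reps)
    ml <- bootstrap_mrl(ph_l, sample_size, reps)
    rows[[length(rows) + 1L]] <- data.frame(
      unit_id = units_high[[u]]$unit_id,
      n_high = ph_h$n, n_low = ph_l$n,
      z_high = rh$rayleigh_z, z_low = rl$rayleigh_z,
      p_high = rh$rayleigh_p, p_low = rl$rayleigh_p,
      mrl_high = mh, mrl_low = ml,
      normdiff_mrl = norm_diff(mh, ml),
      normdiff_z = norm_diff(rh$rayleigh_z, rl$rayleigh_z),
      sig_high = rh$significant, sig_low = rl$significant,
      stringsAsFactors = FALSE)
  }
  if (length(rows) == 0L) stop("no unit passes the inclusion rule")
  df <- do.call(rbind, rows)
  list(units = df,
       prop_significant = c(high = mean(df$sig_high),
                            low = mean(df$sig_low)),
       n_included = nrow(df))
}
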