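spec <- window_spec()

test_that("cubic detrending removes polynomials and keeps oscillations", {
  n <- 2500
  t <- seq(0, 1.25, length.out = n)
  cubic <- 3 - 2 * t + 0.5 * t^2 + 4 * t^3
  out <- detrend_poly3(cubic)
  expect_lt(max(abs(out)) / max(abs(cubic)), 1e-9)
  expect_lt(max(abs(detrend_poly3(rep(7, n)))), 1e-9)

  # linearity: the cubic is removed exactly, leaving the sinusoid minus
  # its own (small but nonzero) cubic projection
  sine <- sin(2 * pi * 8 * t)
  rec <- detrend_poly3(cubic + sine)
  expect_equal(rec, detrend_poly3(sine), tolerance = 1e-9)
  expect_lt(sqrt(sum((rec - sine)^2) / sum(sine^2)), 0.2)
  expect_gt(cor(rec, sine), 0.98)
  expect_error(detrend_poly3(1:7), "shorter than 8")
})

test_that("baseline z-scoring is the stated arithmetic", {
  bl <- baseline_stats(mean = 0, sd = 2)
  expect_equal(zscore_with_baseline(8, bl), 4)
  bl2 <- baseline_stats(mean = 3, sd = 1.5)
  expect_equal(zscore_with_baseline(rep(3, 10), bl2), rep(0, 10))
  id <- baseline_stats(mean = 0, sd = 1)
  x <- rnorm(100)
  expect_equal(zscore_with_baseline(zscore_with_baseline(x, id), id), x)
  expect_error(baseline_stats(mean = 0, sd = 0), "sd must be > 0")
})

test_that("coherence of identical or rescaled signals is 1 on the grid", {
  set.seed(1)
  x <- rnorm(2500)
  expect_equal(msc_welch(x, x, spec, 2000), rep(1, 39), tolerance = 1e-10)
  expect_equal(msc_welch(x, 3.7 * x, spec, 2000), rep(1, 39),
               tolerance = 1e-10)
})

test_that("coherence is invariant to rescaling/sign and bounded in [0,1]", {
  for (seed in 1:5) {
    set.seed(seed)
    x <- rnorm(2500); y <- rnorm(2500) + 0.5 * x
    c0 <- msc_welch(x, y, spec, 2000)
    expect_true(all(c0 >= 0 & c0 <= 1))
    expect_equal(msc_welch(-2 * x, y, spec, 2000), c0, tolerance = 1e-10)
    expect_equal(msc_welch(x, 0.1 * y, spec, 2000), c0, tolerance = 1e-10)
  }
  expect_warning(out <- msc_welch(rep(1, 2500), rnorm(2500), spec, 2000),
                 "zero-variance")
  expect_true(all(is.na(out)))
})

test_that("independent-noise coherence shows the K-segment Welch bias", {
  # Monte-Carlo: default internals average K = 4 Hann segments; the mean
  # coherence of independent noise should sit near 1/K at resolvable
  # frequencies
  set.seed(2)
  nwin <- 200
  i8 <- which(spec$freq_grid == 8)
  vals <- vapply(seq_len(nwin), function(i) {
    msc_welch(rnorm(2500), rnorm(2500), spec, 2000)[i8]
  }, numeric(1))
  expect_gt(mean(vals), 0.25 * 0.8)
  expect_lt(mean(vals), 0.25 * 1.2)
})

test_that("band summaries average the inclusive in-band grid points", {
  expect_equal(theta_summary(rep(0.6, 39), spec)$theta_value, 0.6)
  # default grid: 11 theta points (6.0..11.0), 7 delta points (1.0..4.0)
  expect_identical(sum(spec$freq_grid >= 6 & spec$freq_grid <= 11), 11L)
  ind8 <- as.numeric(spec$freq_grid == 8)
  expect_equal(theta_summary(ind8, spec)$theta_value, 1 / 11)
  sp_gap <- window_spec(theta_band = c(6.1, 6.2), delta_band = c(1, 4),
                        freq_grid = c(1, 4, 6.05, 6.3))
  expect_error(theta_summary(c(0.1, 0.1, 0.1, 0.1), sp_gap),
               "no grid points")
})

test_that("artifact verdicts follow the saturation-then-delta rule", {
  nz <- 2500
  coh_theta <- ifelse(spec$freq_grid >= 6, 0.8, 0.2)   # theta dominant
  coh_delta <- ifelse(spec$freq_grid <= 4, 0.8, 0.5)   # delta dominant
  mk <- function(n_extreme) {
    z <- rep(0.1, nz); z[seq_len(n_extreme)] <- 5; z
  }
  # 30/2500 = 1.2% > 1% -> saturated, even if coherence looks fine
  expect_identical(artifact_verdict(mk(30), mk(0), coh_theta, spec),
                   "saturated")
  # 25/2500 = exactly 1%: not saturated, falls through to the delta check
  expect_identical(artifact_verdict(mk(25), mk(0), coh_theta, spec),
                   "clean")
  expect_identical(artifact_verdict(mk(25), mk(0), coh_delta, spec),
                   "delta_dominant")
  expect_identical(artifact_verdict(mk(0), mk(0), coh_delta, spec),
                   "delta_dominant")
  expect_error(artifact_verdict(mk(0), rep(0, 10), coh_theta, spec),
               "length mismatch")
})

test_that("threshold calibration matches hand arithmetic and invariants", {
  prof <- calibrate_thresholds(c(0.4, 0.6), "r1")
  expect_equal(prof$mean, 0.5)
  expect_equal(prof$sd, sd(c(0.4, 0.6)))     # n-1 denominator, ~0.1414
  expect_equal(prof$sd, 0.1414, tolerance = 1e-3)
  expect_equal(prof$high - prof$low, 2 * prof$sd)
  expect_true(prof$low < prof$mean && prof$mean < prof$high)
  expect_error(calibrate_thresholds(rep(0.5, 10)), "degenerate")
  expect_error(calibrate_thresholds(0.5), "at least 2")
  expect_error(calibrate_thresholds(c(0.5, 1.2)), "\\[0, 1\\]")

  # profile file round trip
  path <- withr::local_tempfile()
  write_thresholds(prof, path)
  back <- read_thresholds(path)
  expect_equal(back$high, prof$high)
  expect_equal(back$subject_id, "r1")
})

test_that("detector triggers inside the window-mechanics latency bound", {
  # low (uncoupled, noise-dominated) for 5 s, then strongly coupled: the
  # first clean trigger must land between onset and onset + window + step
  sp <- osc_test(theta_amp_private = 0, noise_sd = 30, delta_amp = 10)
  prof <- fixed_profile(0.7, 0.1)
  n_ok <- 0L; n_runs <- 40L
  for (s in seq_len(n_runs)) {
    st <- coherence_state_track(c("low", "high"), c(5, 5))
    lfp <- gen_coupled_lfp(sp, sp, st, seed = s, low_mixing = 0)
    out <- stream_detect(lfp$a, lfp$b, baseline_stats(lfp$a),
                         baseline_stats(lfp$b), spec, prof,
                         mode = "high", timeout = 10)
    ok <- out$cause == "threshold" && out$trigger_time >= 5 &&
      out$trigger_time <= 5 + spec$window_len + spec$step
    n_ok <- n_ok + ok
  }
  expect_gte(n_ok / n_runs, 0.95)
})

test_that("detector times out when the threshold is unreachable and is
           monotone in the threshold", {
  lfp <- const_pair(12, mixing = 1, seed = 5)
  bla <- baseline_stats(lfp$a); blb <- baseline_stats(lfp$b)
  # unreachable threshold -> timeout with cause timeout
  out <- stream_detect(lfp$a, lfp$b, bla, blb, spec,
                       fixed_profile(0.98, 0.01), mode = "high",
                       timeout = 10)
  expect_identical(out$cause, "timeout")
  expect_equal(out$trigger_time, 10)
  # raising the high threshold can never make the trigger earlier
  t_prev <- -Inf
  for (thr in c(0.3, 0.5, 0.7, 0.85)) {
    o <- stream_detect(lfp$a, lfp$b, bla, blb, spec,
                       fixed_profile(thr - 0.1, 0.1), mode = "high",
                       timeout = 10)
    t_now <- o$trigger_time
    expect_gte(t_now, t_prev)
    t_prev <- t_now
  }
  expect_error(
    stream_detect(continuous_signal(rnorm(100), fs_test),
                  continuous_signal(rnorm(100), fs_test),
                  bla, blb, spec, fixed_profile(0.5, 0.1), "high", 10),
    "shorter than one window")
})

test_that("saturated windows can never trigger; the next clean crossing
           does", {
  # strongly coupled stream whose first 3 s are saturated on one site
  sp <- osc_test(theta_amp_private = 0, noise_sd = 30, delta_amp = 10)
  lfp <- const_pair(10, mixing = 1, seed = 9, spec = sp)
  x <- lfp$a
  x$samples[1:(3 * fs_test)] <- 10 * sd(x$samples)
  out <- stream_detect(x, lfp$b, baseline_stats(lfp$a),
                       baseline_stats(lfp$b), spec,
                       fixed_profile(0.7, 0.1), mode = "high", timeout = 10)
  expect_identical(out$cause, "threshold")
  expect_gte(out$trigger_time, 3)
})
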