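spec <- window_spec()

test_that("all generators are deterministic given a seed", {
  st <- alternating_states(2, 1.5, 1.5)
  a1 <- gen_coupled_lfp(osc_test(), osc_test(), st, seed = 4)
  a2 <- gen_coupled_lfp(osc_test(), osc_test(), st, seed = 4)
  expect_identical(a1$a$samples, a2$a$samples)
  expect_identical(a1$b$samples, a2$b$samples)
  art1 <- inject_artifacts(a1$a, 0.02, 10, 2, seed = 3)
  art2 <- inject_artifacts(a1$a, 0.02, 10, 2, seed = 3)
  expect_identical(art1$signal$samples, art2$signal$samples)
  expect_identical(art1$intervals, art2$intervals)
  s1 <- gen_locked_spikes(a1$a, kappa = 2, rate = 8, seed = 6)
  s2 <- gen_locked_spikes(a1$a, kappa = 2, rate = 8, seed = 6)
  expect_identical(s1$timestamps, s2$timestamps)
  t1 <- gen_trajectory("tortuous", 120, 60, 0.3, seed = 8)
  t2 <- gen_trajectory("tortuous", 120, 60, 0.3, seed = 8)
  expect_identical(t1$x, t2$x)
})

test_that("zero coupling leaves theta coherence at the independent-noise
           level, identical drive gives coherence 1", {
  # shared amplitude 0 in both states vs literally independent generations
  sp0 <- osc_test(theta_amp_shared = 0)
  st <- coherence_state_track("high", 40)
  lfp <- gen_coupled_lfp(sp0, sp0, st, seed = 10)
  ep <- coherence_epochs(lfp$a, lfp$b, baseline_stats(lfp$a),
                         baseline_stats(lfp$b), spec)
  ind_a <- gen_coupled_lfp(sp0, sp0, st, seed = 11)$a
  ind_b <- gen_coupled_lfp(sp0, sp0, st, seed = 12)$b
  ep_ind <- coherence_epochs(ind_a, ind_b, baseline_stats(ind_a),
                             baseline_stats(ind_b), spec)
  # same generative law, matched spectra: no detectable difference
  p <- wilcox.test(ep$table$theta_value, ep_ind$table$theta_value)$p.value
  expect_gt(p, 0.01)

  # no private component, no noise, same shared drive -> coherence 1
  spc <- osc_test(theta_amp_private = 0, noise_sd = 0, delta_amp = 0)
  pure <- gen_coupled_lfp(spc, spc, st, seed = 13)
  coh <- msc_welch(pure$a$samples[1:625], pure$b$samples[1:625], spec,
                   fs_test)
  expect_equal(coh, rep(1, 39), tolerance = 1e-8)
})

test_that("frozen default mixing hits 8 Hz coherence 0.7 +/- 0.05 in the
           high state", {
  c8 <- vapply(1:3, function(s) {
    lfp <- const_pair(60, mixing = 1, seed = s)
    ep <- coherence_epochs(lfp$a, lfp$b, baseline_stats(lfp$a),
                           baseline_stats(lfp$b), spec)
    stopifnot(nrow(ep$table) >= 100)
    mean(ep$coherence[, spec$freq_grid == 8])
  }, numeric(1))
  expect_gt(mean(c8), 0.65)
  expect_lt(mean(c8), 0.75)
})

test_that("high states dominate low states in theta coherence for any
           mixing margin of at least 0.3", {
  for (low_mix in c(0, 0.4)) {   # margins 1.0 and 0.6
    st <- alternating_states(8, 4, 4)
    lfp <- gen_coupled_lfp(osc_test(), osc_test(), st, seed = 14,
                           low_mixing = low_mix)
    ep <- coherence_epochs(lfp$a, lfp$b, baseline_stats(lfp$a),
                           baseline_stats(lfp$b), spec)
    # label windows fully inside one state
    lab <- rep(NA_character_, nrow(ep$table))
    bounds <- cumsum(c(0, st$dwell_times))
    for (i in seq_along(st$state_labels)) {
      inside <- ep$table$t_start >= bounds[i] &
        ep$table$t_start + spec$window_len <= bounds[i + 1]
      lab[inside] <- st$state_labels[i]
    }
    hi <- ep$table$theta_value[lab == "high" & !is.na(lab)]
    lo <- ep$table$theta_value[lab == "low" & !is.na(lab)]
    expect_gt(mean(hi) - mean(lo), 0)
    expect_lt(wilcox.test(hi, lo, alternative = "greater")$p.value, 0.01)
  }
})

test_that("artifact injection returns truth intervals and the identity
           holds at zero rates", {
  lfp <- const_pair(20, seed = 15)$a
  clean <- inject_artifacts(lfp, 0, delta_burst_rate = 0, seed = 1)
  expect_identical(clean$signal$samples, lfp$samples)
  expect_identical(nrow(clean$intervals), 0L)
  expect_error(inject_artifacts(lfp, 0.1, saturation_level = -1),
               "saturation_level")

  art <- inject_artifacts(lfp, 0.02, delta_burst_rate = 3, seed = 2)
  expect_true(all(art$intervals$end > art$intervals$start))
  expect_setequal(unique(art$intervals$kind),
                  c("saturation", "delta_burst"))
  # clipped runs sit at +/- 10 SD of the input
  sat <- art$intervals[art$intervals$kind == "saturation", ][1, ]
  idx <- (round(sat$start * fs_test) + 1):(round(sat$end * fs_test))
  expect_true(all(abs(art$signal$samples[idx]) > 9 * sd(lfp$samples)))
})

test_that("saturation above 1 percent of a window trips the downstream
           check", {
  lfp <- const_pair(20, seed = 16)
  bla <- baseline_stats(lfp$a); blb <- baseline_stats(lfp$b)
  art <- inject_artifacts(lfp$a, saturation_fraction = 0.02, seed = 3)
  ep <- coherence_epochs(art$signal, lfp$b, bla, blb, spec)
  covered <- vapply(ep$table$t_start, function(t0) {
    any(art$intervals$start >= t0 &
          art$intervals$end <= t0 + spec$window_len)
  }, logical(1))
  expect_true(any(covered))
  expect_true(all(ep$table$verdict[covered] == "saturated"))
})

test_that("a common-mode delta burst spanning a window is rejected
           downstream", {
  lfp <- const_pair(60, seed = 17)
  bla <- baseline_stats(lfp$a); blb <- baseline_stats(lfp$b)
  theta_rms <- sqrt(170^2 + 90^2)
  art_a <- inject_artifacts(lfp$a, delta_burst_rate = 6, seed = 9,
                            burst_len = 1.5,
                            burst_amp = 3 * theta_rms / sd(lfp$a$samples))
  art_b <- inject_artifacts(lfp$b, delta_burst_rate = 6, seed = 9,
                            burst_len = 1.5,
                            burst_amp = 3 * theta_rms / sd(lfp$b$samples))
  ep <- coherence_epochs(art_a$signal, art_b$signal, bla, blb, spec)
  covered <- vapply(ep$table$t_start, function(t0) {
    any(art_a$intervals$start <= t0 &
          art_a$intervals$end >= t0 + spec$window_len)
  }, logical(1))
  expect_true(any(covered))
  expect_true(all(ep$table$verdict[covered] != "clean"))
})

test_that("locked spikes follow the requested von Mises law", {
  lfp <- const_pair(100, seed = 18)$b
  # kappa 5: strong locking, mean recovered, MRL near I1(5)/I0(5)
  spk <- gen_locked_spikes(lfp, band = c(6, 11), kappa = 5,
                           preferred_phase = pi, rate = 6, seed = 1)
  ph <- spike_phases(lfp, spk, theta_band = c(6, 11))
  expect_gt(ph$n, 400)
  d <- abs(Arg(exp(1i * (circ_mean(ph$phases) - pi))))
  expect_lt(d, 0.15)
  expect_gt(circ_mrl(ph$phases), 0.8)

  # kappa 0: uniform -> Rayleigh non-significant in >= 90% of runs
  nonsig <- 0L
  for (s in 1:60) {
    spk0 <- gen_locked_spikes(lfp, kappa = 0, rate = 3, seed = s)
    ph0 <- spike_phases(lfp, spk0, theta_band = c(6, 11))
    r <- rayleigh(ph0)
    nonsig <- nonsig + (r$rayleigh_p > 0.05)
  }
  expect_gte(nonsig / 60, 0.9)
  expect_error(gen_locked_spikes(lfp, band = c(6, 400), kappa = 1),
               "Nyquist")
})

test_that("generated phase histograms match the von Mises density", {
  lfp <- const_pair(160, seed = 19)$b
  kappa <- 2
  spk <- gen_locked_spikes(lfp, band = c(6, 11), kappa = kappa,
                           preferred_phase = 0.5, rate = 13, seed = 2)
  ph <- spike_phases(lfp, spk, theta_band = c(6, 11))$phases
  expect_gt(length(ph), 1800)
  breaks <- seq(-pi, pi, length.out = 19)
  obs <- table(cut(ph, breaks))
  dens <- function(x) exp(kappa * cos(x - 0.5)) /
    (2 * pi * besselI(kappa, 0))
  p_bin <- vapply(seq_len(18), function(i) {
    integrate(dens, breaks[i], breaks[i + 1])$value
  }, numeric(1))
  gof <- chisq.test(as.numeric(obs), p = p_bin / sum(p_bin))
  expect_gt(gof$p.value, 0.01)
})

test_that("trajectories have the requested geometry", {
  straight <- gen_trajectory("straight", 100, 90, 0, seed = 1)
  expect_equal(distance_traveled(straight), 100)
  expect_lt(idphi(straight)$idphi, 1e-8)
  tort <- gen_trajectory("tortuous", 100, 90, 0, seed = 1)
  expect_equal(distance_traveled(tort), 100)  # constant step construction
  expect_gt(idphi(tort)$idphi, idphi(straight)$idphi)
  expect_error(gen_trajectory("straight", -5), "length")
})

test_that("synthetic sessions are reproducible and protocol-complete", {
  b1 <- gen_session("delayed_alternation", seed = 3, n_blocks = 4)
  b2 <- gen_session("delayed_alternation", seed = 3, n_blocks = 4)
  expect_identical(b1$trials, b2$trials)
  expect_identical(b1$events, b2$events)
  expect_identical(b1$lfp$a$samples, b2$lfp$a$samples)
  # a 40-trial session holds 4 complete 10-trial blocks
  expect_identical(nrow(b1$trials), 40L)
  expect_identical(sum(b1$events$kind == "trial_start"), 40L)
  expect_identical(as.integer(table(b1$trials$block)), rep(10L, 4))
  expect_error(gen_session("water_maze"), "arg")
})

test_that("with no reachable high state all experimental trials time out", {
  # detector streams with zero coupling never reach a +1 SD threshold
  # calibrated on coupled data
  sp <- osc_test(theta_amp_private = 0, noise_sd = 30, delta_amp = 10)
  lfp <- const_pair(40, mixing = 1, seed = 20)
  bla <- baseline_stats(lfp$a); blb <- baseline_stats(lfp$b)
  ep <- coherence_epochs(lfp$a, lfp$b, bla, blb, spec)
  prof <- calibrate_thresholds(
    ep$table$theta_value[ep$table$verdict == "clean"], "t")
  detector <- function(mode, timeout) {
    st <- coherence_state_track("low", timeout + 2)
    uncoupled <- gen_coupled_lfp(sp, sp, st, seed = sample.int(2^30, 1),
                                 low_mixing = 0)
    stream_detect(uncoupled$a, uncoupled$b, bla, blb, spec, prof,
                  mode = mode, timeout = timeout)
  }
  tr <- run_session(protocol_spec("delayed_alternation"), n_blocks = 2,
                    detector = detector, seed = 21)
  high <- tr[tr$type == "high", ]
  expect_true(all(high$trigger_cause == "timeout"))
  expect_false(any(tr$type %in% "yoked_high"))   # all substituted
})
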