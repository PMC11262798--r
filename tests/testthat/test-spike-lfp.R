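test_that("epoch cleaning removes extreme epochs and maps spikes", {
  fs <- 500
  set.seed(1)
  nsamp <- fs              # 1 s epochs
  K <- 8
  mk <- function() matrix(rnorm(nsamp * K, sd = 300), nsamp, K)
  eps <- list(mPFC = mk(), HPC = mk())
  t_start <- seq(0, by = 2, length.out = K)
  # epoch 3: one mPFC sample beyond the 3500 uV absolute limit
  eps$mPFC[10, 3] <- 4000
  # epoch 5: 2% of HPC samples far beyond the z cutoff
  eps$HPC[1:10, 5] <- 6000
  spk <- spike_train(c(0.5, 4.2, 8.5, 8.5001, 14.9), unit_id = "u1")
  out <- clean_epochs_for_spikes(eps, t_start, fs, spikes = spk)
  expect_identical(which(!out$kept), c(3L, 5L))
  # conservation: concatenated length equals the sum of kept epochs
  expect_equal(length(out$concat$mPFC$samples), nsamp * 6)
  # spike at 4.2 s fell in removed epoch 3 ([4, 5)): absent
  # spikes at 0.5 -> 0.5; 8.5/8.5001 in epoch 5 removed; 14.9 in epoch 8
  expect_equal(out$spikes$timestamps, c(0.5, 5 + 0.9), tolerance = 1e-9)
  expect_error(
    clean_epochs_for_spikes(eps, rep(0, K), fs),
    "overlapping")
})

test_that("HPC epochs are not screened by the mPFC/VMT absolute limit", {
  fs <- 500
  set.seed(2)
  eps <- list(HPC = matrix(rnorm(fs * 4, sd = 300), fs, 4))
  eps$HPC[5, 2] <- 4000   # above 3500, but HPC is exempt from that rule
  out <- clean_epochs_for_spikes(eps, seq(0, 6, by = 2), fs)
  expect_true(out$kept[2])
})

test_that("spike phases read the Hilbert phase of the theta-filtered LFP
           and obey the theta/delta gate", {
  fs <- 512                                # 8 Hz = exactly 64 samples/cycle
  tt <- seq(0, 20 - 1 / fs, by = 1 / fs)
  lfp <- continuous_signal(100 * sin(2 * pi * 8 * tt), fs)
  # spikes exactly at the oscillation peaks (sample-aligned)
  peaks <- (0.25 + 8:150) / 8
  ps <- spike_phases(lfp, spike_train(peaks), theta_band = c(4, 12))
  expect_gt(ps$n, 100)
  expect_lt(max(abs(Arg(exp(1i * (ps$phases - circ_mean(ps$phases)))))),
            0.1)
  # spikes one period apart have equal phase to high precision
  mid <- spike_train(10 + c(0, 1 / 8, 2 / 8, 3 / 8))
  pm <- spike_phases(lfp, mid, theta_band = c(4, 12))$phases
  expect_lt(max(abs(Arg(exp(1i * (pm - pm[1]))))), 1e-6)

  # delta-dominated segment: no spike passes the gate
  lfp2 <- continuous_signal(600 * sin(2 * pi * 2 * tt) +
                              100 * sin(2 * pi * 8 * tt), fs)
  ps2 <- spike_phases(lfp2, spike_train(seq(1, 19, by = 0.1)))
  expect_identical(ps2$n, 0L)
  expect_error(spike_phases(lfp, spike_train(numeric())), "empty spike")
})

test_that("the Rayleigh test behaves under null, alternative and
           degenerate concentration", {
  # all phases identical: Rbar = 1, z = n
  r1 <- rayleigh(rep(1.3, 100))
  expect_equal(r1$mrl, 1)
  expect_equal(r1$rayleigh_z, 100)
  # inclusion rule is strict: 50 phases are not enough
  expect_true(rayleigh(runif(50, -pi, pi))$excluded)
  expect_false(rayleigh(runif(51, -pi, pi))$excluded)

  set.seed(3)
  null_ok <- 0; alt_ok <- 0
  for (i in 1:100) {
    null_ok <- null_ok + (rayleigh(runif(200, -pi, pi))$rayleigh_p > 0.05)
    alt_ok <- alt_ok +
      (rayleigh(thetabmi:::rvonmises(200, 0, 1))$rayleigh_p < 0.001)
  }
  expect_gte(null_ok / 100, 0.90)
  expect_gte(alt_ok / 100, 0.95)
})

test_that("bootstrapped MRL recovers closed-form expectations", {
  expect_equal(bootstrap_mrl(rep(0.7, 200), seed = 1), 1)
  set.seed(4)
  # uniform null: E[Rbar | n] = sqrt(pi)/2 / sqrt(n) ~ 0.125 at n = 50
  u <- runif(5000, -pi, pi)
  expect_equal(bootstrap_mrl(u, seed = 2), sqrt(pi) / 2 / sqrt(50),
               tolerance = 0.02)
  # von Mises kappa = 2: population resultant I1(2)/I0(2) ~ 0.698
  vm <- thetabmi:::rvonmises(5000, 1, 2)
  expect_equal(bootstrap_mrl(vm, seed = 3), vm_mrl(2), tolerance = 0.03)
  # rotation invariance: adding a constant phase changes nothing
  expect_equal(bootstrap_mrl(vm + 0.9, seed = 5),
               bootstrap_mrl(vm, seed = 5), tolerance = 1e-12)
  expect_error(bootstrap_mrl(runif(30)), "fewer phases")
})

test_that("spike-field coherence peaks at the locking frequency and is
           amplitude invariant", {
  fs <- 500
  tt <- seq(0, 60 - 1 / fs, by = 1 / fs)
  lfp <- continuous_signal(sin(2 * pi * 8 * tt), fs)
  locked <- spike_train(seq(5, 55, by = 1 / 8))   # one spike per cycle
  s <- spike_field_coherence(lfp, locked)
  i8 <- which(s$freqs == 8); i15 <- which(s$freqs == 15)
  expect_gt(s$sfc[i8], 0.95)
  expect_gt(s$sfc[i8], s$sfc[i15])
  expect_true(all(s$sfc >= 0 & s$sfc <= 1, na.rm = TRUE))
  # phase-only: invariant to LFP amplitude rescaling
  lfp2 <- continuous_signal(37 * lfp$samples, fs)
  s2 <- spike_field_coherence(lfp2, locked)
  expect_equal(s2$sfc, s$sfc, tolerance = 1e-12)

  # independent Poisson spikes: resultant near the 1/sqrt(N) null floor
  set.seed(5)
  noise_lfp <- const_pair(80, seed = 6)$a
  pois <- spike_train(sort(runif(1000, 5, 75)))
  s0 <- spike_field_coherence(noise_lfp, pois)
  expect_lt(max(s0$sfc, na.rm = TRUE), 0.1)
  expect_error(
    spike_field_coherence(lfp, spike_train(0.01), freqs = 1),
    "edge-excluded")
})

test_that("SFC at the locking frequency increases with concentration", {
  lfp <- const_pair(120, seed = 7)$b
  prev <- -Inf
  for (kappa in c(0, 1, 5)) {
    spk <- gen_locked_spikes(lfp, band = c(6, 11), kappa = kappa,
                             preferred_phase = 0, rate = 8, seed = 8)
    s <- spike_field_coherence(lfp, spk)
    cur <- s$sfc[s$freqs == 8]
    expect_gt(cur, prev)
    prev <- cur
  }
})

test_that("the state entrainment summary applies inclusion and finds the
           locked subpopulation", {
  fs <- 500
  lfp_high <- const_pair(120, seed = 9)$b
  lfp_low <- const_pair(120, seed = 10)$b
  n_units <- 20
  units_high <- vector("list", n_units)
  units_low <- vector("list", n_units)
  for (u in seq_len(n_units)) {
    kappa_high <- if (u <= 2) 3 else 0      # 10% locked only in high state
    units_high[[u]] <- gen_locked_spikes(lfp_high, band = c(6, 11),
                                         kappa = kappa_high, rate = 4,
                                         seed = 20 + u)
    units_low[[u]] <- gen_locked_spikes(lfp_low, band = c(6, 11),
                                        kappa = 0, rate = 4,
                                        seed = 50 + u)
  }
  out <- state_entrainment_summary(units_high, units_low, lfp_high,
                                   lfp_low, reps = 200,
                                   theta_band = c(6, 11))
  expect_identical(out$n_included, 20L)
  expect_gte(out$prop_significant[["high"]], 0.10)
  expect_lte(out$prop_significant[["high"]], 0.30)
  expect_lte(out$prop_significant[["low"]], 0.20)
  # units are returned in input order: the two locked ones come first
  expect_gt(mean(out$units$normdiff_z[1:2]), 0)

  # a unit with too few high-state phases is excluded entirely
  few <- spike_train(seq(10, 15, length.out = 40))
  out2 <- state_entrainment_summary(c(units_high[1:3], list(few)),
                                    c(units_low[1:3], list(units_low[[4]])),
                                    lfp_high, lfp_low, reps = 100,
                                    theta_band = c(6, 11))
  expect_identical(out2$n_included, 3L)
})
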