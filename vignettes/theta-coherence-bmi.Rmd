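---
title: "Closed-loop theta-coherence interfacing: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Closed-loop theta-coherence interfacing: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(thetabmi)
```

## The problem

Prefrontal–hippocampal theta coherence (6–11 Hz synchrony between the two
local field potentials) waxes and wanes on a timescale of seconds. A
closed-loop experiment exploits this: theta coherence is estimated in a
sliding window over the streaming LFPs, and when it crosses a per-subject
threshold, a trial of a memory task is started — so that choices are made
predominantly during strong (or weak) synchrony. Delay-matched ("yoked")
control trials replay the same delay durations detached from brain state,
which is what licenses a causal reading of any accuracy difference.

`thetabmi` implements the full loop — streaming coherence with artifact
gating, per-subject threshold calibration, block-wise trial scheduling
with yoked controls — plus the offline analyses used around such an
experiment (multitaper power, event-locked coherograms, spectral Granger
causality, spike-phase entrainment, spike-field coherence, IdPhi
behavioral complexity) and a synthetic-data module that makes every part
testable without recordings.

## The streaming estimator

Each analysis window is 1.25 s long and advances in 250 ms steps
(`window_spec()`). A window is

1. detrended by subtracting its least-squares third-degree polynomial,
2. z-scored against per-channel baseline statistics taken from a separate
   rest recording (nominally 10 min),
3. transformed to magnitude-squared coherence
   $C_{xy}(f) = |P_{xy}(f)|^2 / (P_{xx}(f)\,P_{yy}(f))$
   by Welch segment averaging, evaluated on the 1–20 Hz grid at 0.5 Hz
   spacing,
4. summarized as *theta coherence* — the arithmetic mean of the 11 grid
   points in [6, 11] Hz (both endpoints included) — and *delta coherence*
   (the 7 points in [1, 4] Hz), and
5. gated: the window is `saturated` if more than 1% of either channel's
   samples exceed 4 baseline SDs in magnitude (strict inequality — exactly
   1% passes), else `delta_dominant` if delta coherence exceeds theta
   coherence, else `clean`. Saturation is checked first because a
   saturated window's spectra are meaningless.

**Welch internals.** Only the total window (1.25 s) and the frequency grid
are pinned down by the design; the segmentation inside the window is an
implementation choice. We use 0.5 s Hann-tapered segments with 50%
overlap — K = 4 segments per window — which resolves the 0.5 Hz grid while
averaging enough segments for a usable estimate; the cross- and
auto-spectra are evaluated by direct DFT at exactly the grid frequencies,
so no zero-padding convention is involved. Both `seg_len` and
`seg_overlap` are `window_spec()` fields. Two consequences worth knowing:

* **Bias floor.** Independent signals do not give zero coherence: the
  K-segment estimator has expectation near 1/K (≈ 0.25 here) at
  frequencies the segments resolve, and higher below ~3 Hz, where a 0.5 s
  segment holds less than two cycles and the overlapping segments are
  strongly correlated. The acceptance script measures this floor.
* **Per-window dispersion.** A single window has few spectral degrees of
  freedom, so theta and delta summaries each carry an SD of roughly 0.1.
  The delta-dominance gate compares two such estimates inside one window;
  even on stationary, artifact-free, strongly theta-coherent input it
  therefore flags a few percent of windows (the acceptance script reports
  the measured rate as `clean_window_false_rejection_rate`, typically
  0.08–0.11). This is a property of the *rule*, not a bug in the
  implementation: any per-window delta-vs-theta comparison at these window
  lengths behaves this way; on real rigs such windows are simply skipped
  and cost only a short delay before triggering. The saturation rule, by
  contrast, is deterministic and produces no false flags.

**Detrending.** Subtracting a cubic from a 1.25 s window necessarily
removes the projection of everything in the window onto the cubic space —
including about 14% of the energy of a pure 8 Hz sinusoid. Coherence is
insensitive to this common attenuation; tests assert the linearity of the
operation rather than a physically impossible "exact recovery".

## Thresholds and the detector

Per-subject thresholds come from a calibration distribution of clean
theta-coherence values: `high = mean + 1·SD`, `low = mean − 1·SD`, with
the sample SD (n − 1). The detector (`stream_detect()`) evaluates a window
only once it is completely filled, compares clean windows' theta values to
the threshold (≥ high in high mode, ≤ low in low mode), and reports the
first crossing or a timeout (30 s in delayed alternation, 20 s in
conditional discrimination). Non-clean windows can never trigger. Raising
the high threshold can only delay a trigger (a tested invariant), and the
trigger latency after a genuine state onset is bounded by
`window_len + step` once estimates separate cleanly.

## The scheduler

Delayed alternation runs 10-trial blocks containing 1 high, 1 low, 1
yoked-high, 1 yoked-low and 6 random-delay trials (the only integer
solution to 20% experimental / 20% yoked / 60% random in blocks of ten);
conditional discrimination blocks contain 4 high, 4 yoked-high and 2
random trials. Block orders are drawn uniformly from the admissible set
(every yoked trial after its partner; pairing is by order of occurrence
within the block). Yoked trials replay their partner's delay exactly; if a
detector trial times out, its pending yoked partner is converted to a
random delay for the remainder of the block, with a `was_yoked` provenance
flag kept for accounting. Under conditional discrimination every trial
additionally waits at least a uniform 3.5–5 s. Session screens: CD
sessions need performance strictly above 70%, alternation strictly below
70% and at least three experimental trials; DA sessions are screened at
performance ≥ 70%.

Two open points were settled as follows: a timed-out trial's substitution
keeps the block at 10 trials (mutate-in-place), and the CD minimum wait is
drawn uniformly, since no distribution is stated.

## The synthetic-data module

`gen_coupled_lfp()` builds each site as

> amplitude-weighted shared theta oscillator × state envelope
> + private theta oscillator + private 1–4 Hz activity + white noise,

on a nominal microvolt scale (theta ≈ 200 µV RMS, saturation ≈ ±2000 µV).
The theta components are *stochastic oscillators*: a sinusoidal carrier
whose instantaneous frequency wanders slowly around 8 Hz (SD 0.8 Hz) and
whose amplitude is modulated by slow bounded noise (CV 0.25). Two
alternatives were rejected for cause. Narrowband-filtered Gaussian noise
has a Rayleigh envelope that fades to near zero every few tens of seconds
— unlike sustained rodent theta — and those fades delete the theta
coherence of artifact-free windows. A fixed-phase sinusoidal drive shared
between "private" components is worse: two constant-phase tones at a
common frequency are perfectly coherent, so even uncoupled sites would
show strong 8 Hz coherence. A related, genuine property of the model (and
of real dual-site theta) survives: two *independent* theta oscillators
still show elevated within-window coherence, because their relative phase
barely drifts inside 1.25 s; only broadband-dominated signals fall to the
1/K floor.

The default amplitudes were frozen once by a brute-force sweep so that
fully mixed sites (high state) reach a magnitude-squared coherence of
about 0.7 at 8 Hz; the default low-state mixing weight (0.55) leaves about
0.5. Artifact injection (`inject_artifacts()`) clips contiguous runs at
±10 input SDs (the nominal ±2000 µV) and adds 1.5–3.5 Hz hand-shaped
bursts, returning ground-truth intervals so gating can be scored against
truth; movement artifacts are made common-mode by reusing one seed across
the two sites. Phase-locked spikes are placed by drawing von Mises phases
(Best–Fisher sampler) and inverting the band-filtered LFP's unwrapped
Hilbert phase, so the delivered phase law is exact up to phase-estimation
error.

What the generator does **not** emulate: 1/f broadband structure, sharp-
wave ripples, volume conduction, electrode drift, non-stationary firing
rates, or any behavioral covariation between brain state and movement.
Passing tests therefore validate the *machinery* — estimators, gates,
scheduling, statistics — under controlled conditions, not the biological
claims one would test on recordings.

## Offline analyses

* **Multitaper power** (`psd_multitaper()`): three Slepian tapers with
  time–bandwidth product 2, taper-averaged, log10-transformed. DPSS tapers
  are computed from the symmetric tridiagonal eigenproblem; above 1024
  samples they are spline-interpolated from the 1024-point solution and
  re-orthonormalized (error negligible for spectral averaging). Theta peak
  frequency is the 4–12 Hz argmax, ties broken toward the lower frequency.
  Offline theta-power comparisons conventionally use a narrower 6–9 Hz
  band; the real-time summary band stays 6–11 Hz. Both are arguments, not
  constants.
* **Event coherograms** (`event_coherogram()`): epochs from 2 s before to
  0.5 s after each event, moving-window coherence with the streaming
  defaults, averaged across events.
* **Coherence autocorrelation** (`coherence_autocorr()`): biased
  autocorrelation (normalized by lag 0, guaranteeing |r| ≤ 1) of the
  theta-value series against a null band from random temporal
  permutations. Because 1.25 s windows at 250 ms steps share data out to
  four steps, comparisons are reported from lag 5 onward — the first lag
  with disjoint windows.
* **Granger prediction** (`bivariate_gc()`, `multivariate_gc()`):
  time-domain influence is log(Var[e]/Var[ε]) from univariate-vs-bivariate
  OLS autoregressions; the spectral decomposition follows Geweke, from the
  VAR transfer function and residual covariance, and its frequency average
  reproduces the time-domain value (a tested identity). Model order is the
  rounded median of per-signal BIC argmins up to 20 lags (rounding half
  away from zero). The three-site pairwise-conditional measure fits the
  full trivariate VAR, derives the model-implied autocovariance sequence
  through the companion-form Lyapunov equation, obtains each reduced
  (target + conditioning) model from that sequence by solving the block
  Yule–Walker equations — so full and reduced models describe the same
  process — and applies Geweke's conditional formula with a Cholesky
  normalization ordered target-first. Epoch lists are fitted by pooling
  per-epoch normal equations, never regressing across an epoch boundary.
  Desk-scale defaults (autocovariance to lag 200, reduced order 20) are
  arguments. The estimation mode is ordinary least squares throughout —
  the reference estimator with known identities.
* **Spike analyses**: epoch cleaning z-scores each region against its
  concatenated session signal, drops epochs with > 1% extreme samples (at
  a per-region SD cutoff, default 4) or any mPFC/VMT sample beyond
  3500 µV, concatenates survivors and maps spike timestamps into the new
  timeline with duplicates removed. Spike phases come from a third-order
  zero-phase Butterworth (4–12 Hz) and the analytic signal; zero-phase
  filtering is chosen so phases are not lag-shifted. A spike counts only
  if the instantaneous theta envelope is at least twice the delta envelope
  (Hilbert envelopes; a windowed-RMS variant would also be defensible but
  envelopes match the per-spike gating most directly). Entrainment uses
  the Rayleigh test (small-sample-corrected p) and a spike-count-
  controlled MRL: the resultant length of 50 phases, resampled 1000 times
  without replacement (with-replacement is a flag), averaged. Units enter
  only with strictly more than 50 gated phases in both coherence states.
  Spike-field coherence convolves six-cycle L2-normalized Morlet wavelets
  across 1–20 Hz (0.5 Hz steps) and takes the per-frequency resultant of
  the spike-time phasors; spikes within half a wavelet of an edge are
  ineligible at that frequency. The statistic is phase-only, so wavelet
  normalization cannot affect it (asserted by test).
* **Behavior**: positions are smoothed with a Gaussian-weighted window
  (default 0.2 s — unstated upstream, exposed as an argument); velocities
  use discrete time-adaptive windowing (the largest symmetric window whose
  straight-line fit stays within tolerance, defaults 1 position unit and
  3–15 samples); Phi is the four-quadrant `atan2(dY, dX)` (a
  principal-branch arctangent of a ratio would be ill-defined), unwrapped;
  dPhi reuses the adaptive windowing on unwrapped Phi; IdPhi is the
  trapezoidal time-integral of |dPhi|. Distance traveled sums successive
  Euclidean steps (optionally over the final 1.25 s before the trigger)
  and is min–max normalized per session, with the degenerate all-equal
  case reported as 0 with a warning rather than NaN. Scores are in native
  tracking units unless the track carries a scale.
* **Statistics**: Bonferroni multiplies by an explicitly supplied family
  size (capped at 1); Benjamini–Hochberg delegates to
  `stats::p.adjust(method = "BH")`; normalized difference scores
  (X − Y)/(X + Y) are tested against a zero null with a two-sided
  one-sample t-test.

## Numerical choices and degenerate inputs

* Time is seconds in doubles throughout; epochs are half-open
  sample-index intervals `[start, end)`; event-time-to-index conversion
  floors (rounds toward −∞).
* `msc_welch()` refuses windows whose detrended samples have SD below
  1e−8: a fully clipped window detrends to ~1e−13 numerical jitter whose
  "coherence" would be arbitrary. Such windows are flagged, not scored.
* Threshold calibration errors on degenerate (zero-variance) inputs;
  distance normalization and IdPhi warn-and-zero on their degenerate
  cases; the Rayleigh test returns an "excluded" record rather than
  erroring when a unit has too few spikes.
* VAR fits verify the companion spectral radius before any spectral GC is
  computed and report the radius when they refuse; the autocovariance
  block-Toeplitz matrix must pass a Cholesky factorization.

## Problem sizes

Tests and the acceptance script synthesize LFP at 500 Hz (the window
mechanics are expressed in seconds and Hz, so nothing changes except
cost), use 1,000-window batches for estimator calibration, 100 seeds of
length-20,000 series for Granger direction recovery, 5,000-phase sets for
entrainment closed forms, and 500 simulated units for the Rayleigh null.
These sizes give Monte-Carlo error comfortably inside every stated
tolerance while the whole suite runs in about a minute.

## Known limitations

* The generator's defaults describe one operating point (strong theta on
  a quiet background); estimator behavior at much lower SNR is exercised
  only qualitatively (zero-coupling and noise-floor checks).
* The delta-dominance gate's false-flag rate on clean windows (~9%) is
  intrinsic to per-window band comparisons at 1.25 s; see above.
* Conditional Granger causality assumes the trivariate VAR is stable and
  adequately ordered; no state-space or permutation-significance variants
  are provided.
* The real-time path is a faithful offline re-implementation of the
  streaming arithmetic; acquisition-hardware latency is out of scope.
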