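---
title: "Motor-imagery decoding and pain-diary outcomes: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Motor-imagery decoding and pain-diary outcomes: methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mibci)
```

`mibci` implements the computational core of a motor-imagery
brain-computer-interface (BCI) training system and the longitudinal
statistics used to evaluate its effect on chronic neuropathic (phantom-limb
type) pain. This vignette explains the models and procedures, the tunable
parameters, and the design decisions taken where a published description
leaves the arithmetic open. Nothing here states an empirical result that the
test suite or `scripts/acceptance.R` does not itself compute.

## The decoding problem

A participant alternates between three mental states — *relax*, *left-hand*
motor imagery, *right-hand* motor imagery. Kinesthetic imagery suppresses
the sensorimotor mu (8–12 Hz) and beta (13–30 Hz) rhythms over the
contralateral hemisphere (event-related desynchronization, ERD). The decoder
must classify short EEG windows into the three states, first offline during
calibration, then online at a fixed update rate to drive visual feedback.

The pipeline is the field's classic stack: FIR band-pass (8–30 Hz) →
fixed post-cue epochs → 2-s sliding windows → outlier-window screening →
Common Spatial Patterns (CSP) → log-variance features → Linear Discriminant
Analysis (LDA) → run-wise cross-validated accuracy → a 70% competence gate.

## Synthetic sessions: what the generator emulates

`generate_mi_session()` produces annotated multichannel recordings with a
known ERD ground truth, so every downstream stage is testable without any
recorded data.

* **Background**: independent 1/f (pink) noise per channel, unit variance,
  with the 1/f scaling floored below 0.5 Hz so infra-slow drift does not
  dominate. Pink noise is the standard first-order description of broadband
  EEG background.
* **Rhythms**: two sources at the C3 and C4 positions, each a 10 Hz mu
  oscillation plus a half-power 20 Hz beta. Each source is a train of 1-s
  sinusoidal bursts with independent random phases, crossfaded with
  square-root-Hann windows at 50% overlap so expected power is constant
  while phase decorrelates on the burst timescale. This matters: a
  session-long coherent sinusoid lets CSP learn phase-specific cancellation
  filters that are perfect within a session and useless on the next one —
  narrowband burst activity is both more realistic and the honest test of a
  power-based decoder.
* **Spatial mixing**: a Gaussian kernel over great-circle electrode
  distance (width 0.35 rad) projects each source to the scalp, giving
  focal smooth topographies without a biophysical forward model. Electrode
  positions come from an idealized azimuthal-equidistant 10-10 layout
  (18° of polar angle per 10% of the nasion–inion arc).
* **ERD**: during left-hand imagery the C4-side source amplitude is scaled
  by `sqrt(1 - erd_depth)` (power by `1 - erd_depth`) from 0.5 s to 6.5 s
  after the cue with 0.2-s ramps; right-hand imagery suppresses the C3
  side; relax suppresses nothing. The default `erd_depth = 0.4` and
  `snr = 4` (mu power : total broadband noise power at the source channel)
  describe a competent but not exceptional imager.
* **Sampling rate**: nothing in the emulated protocol fixes it; the
  generator defaults to 256 Hz, a common clinical-amplifier rate, and it is
  configurable.

The generator does **not** emulate eye-blink/EMG artifacts (beyond what the
rejection tests inject explicitly), electrode drift, volume-conduction
anisotropy, or non-stationarity across a session. Passing tests therefore
show the pipeline's correctness and its behavior under controlled
signal-to-noise conditions — not robustness to every artifact of real
recordings.

## Preprocessing

* **Filter**: Hamming windowed-sinc FIR, order `ceiling(3.3 * fs / 2)`
  (transition ≈ 2 Hz; no order is prescribed by the protocol, so it follows
  from the transition width). Calibration filtering is zero-lag: one
  forward pass with the group delay compensated and reflection padding at
  the edges.
* **Epochs and windows**: the decoding epoch is `[cue+1 s, cue+6 s)`
  (half-open), cut into 2-s windows with 50% overlap, so each trial yields
  windows starting at cue+1, 2, 3, 4 s. Trials that do not fit are skipped
  with a warning rather than failing the session.
* **Outlier screening**: the published system excludes windows by
  class-wise statistics with the exact statistic left to a future
  publication; the stand-in here is deliberately simple and documented as
  such: per class and channel, a robust z-score (median/MAD, falling back
  to the SD when the MAD is zero) of the window log-variance; a window is
  rejected when its maximum |z| across channels exceeds `z_max = 3.5`.
  Screening is applied only at calibration time, never in the closed loop.

## The decoder

**CSP.** For each class a one-vs-rest generalized eigenproblem of (class
covariance, class + rest covariance) is solved by whitening; eigenvalues in
[0, 1] measure discriminability (0.5 = none). Covariances are means of
per-window sample covariances with automatic diagonal shrinkage when
ill-conditioned (condition number above 1e8). Filters are ranked per class
by eigenvalue extremeness `2|λ − 1/2|` and retained round-robin across
classes up to six components (near-duplicate directions skipped). Patterns
are taken from the inverse of each decomposition's full filter matrix
(equivalently `C w` for whitening solutions): each column is the scalp
topography of the source its filter extracts. A minimum-norm pseudo-inverse
of the retained rectangular filter matrix was rejected because, with three
interleaved decompositions, it redistributes shared source topography across
components and stops localizing.

**Features and LDA.** `log(var(w'x))` per component; pooled-covariance LDA
with closed-form softmax posteriors, empirical priors, shrinkage on an
ill-conditioned pooled covariance, and a deterministic tie-break (lowest
class index) on exact posterior ties.

**Cross-validation.** The fold unit is the run/series, never the window:
overlapping windows of a trial would otherwise leak between folds. `k`
defaults to the number of runs (9 for a competence test, 6 for a daily
calibration). CSP and LDA are refit within every training fold. Accuracy is
the fraction of correct window decisions; a trial-level variant (majority
vote per trial) is available because published accuracies do not always say
which level they report — window-level is the primary definition here.

**Competence gate.** Mean cross-validated accuracy ≥ 0.70 passes
("reaching" a threshold reads as inclusive); at most three attempts are
allowed and a fourth is refused as a protocol error.

## Closed-loop streaming

`stream_decode()` emits one decision per 62.5 ms from a 2-s sliding window —
16 decisions per second of signal, the first at `t = 2 s`. A published
overlap of 15/16 for a 2-s window would imply a 125-ms step, contradicting
the same description's update interval of 62.5 ms; the 62.5 ms step is
adopted (it is stated twice and defines the user-visible rate, making the
effective overlap 31/32), and the step is configurable.

Causality is a contract: the decision at time `t` uses only samples in
`(t − 2, t]`, verified in the tests by zeroing future samples. The default
filtering mode runs one forward-only (causal) FIR pass over the stream, as
an online system filtering samples as they arrive would. The streaming
kernel uses a wider transition (8 Hz) than the calibration kernel: a causal
FIR delays its output by half its length, and the calibration-grade kernel
(~1.65 s at 256 Hz) would add ~0.8 s to every decision while leaving almost
no transient-free samples inside a 2-s window. A per-window filtering mode
is provided for comparison, and an optional majority-of-last-N smoother
exists but is off by default — the core loop emits raw decisions.

## ERD/ERS maps

`compute_erd_map()` quantifies the phenomenon the decoder exploits: per
trial, an epoch from −1 s to 6 s around the cue; per channel, a DPSS
multitaper spectrogram (0.5-s windows, 50% overlap, time–bandwidth 2,
3 tapers — parameters chosen to resolve ~2 Hz structure across a 7-s epoch);
trial-averaged power, then percent change against the mean power in the
−1–0 s baseline. Averaging precedes normalization. Rows with zero baseline
power are masked rather than infinite, and the baseline-interval mean of
every row is exactly zero by construction. The frequency axis is restricted
to 4–40 Hz. DPSS tapers are computed from the symmetric tridiagonal
eigenproblem whose eigenvectors are the Slepian sequences (no suitable R
package ships them; the implementation is validated against an independent
reference in the tests).

With three tapers and `n` trials the per-cell percent-change estimator has
standard deviation around `100 * sqrt(1/(3n) + 1/(9n))` %, so even a
100-trial null map has cells in the ±20–30% range; map-level statements
should use band/interval means (`tf_band_mean()`), which is what the tests
assert (a 40% injected mu suppression is recovered as −40 ± 8 at C4).

## Training protocol analytics

Exercises are ordered state sequences with required holds and an allotted
time. Validation is dwell-based: each decision whose label matches the
current segment contributes one decision period (62.5 ms) of credit, nothing
resets on flicker — robust at a 16 Hz decision rate — and a consecutive-hold
mode exists behind a flag. The composite difficulty score is
`n_states × sum(holds) / allotted_time`; the published ingredients (state
count, completion-time proportion) name no arithmetic, so this product is
this package's convention: dimensionless, monotone in both ingredients,
invariant to relabeling.

The demo course generator ramps difficulty by one extra state every 3
sessions and 25% more temporal tightness every 2 sessions, with the allotted
time floored at `sum(holds) + 2 s per segment`: below that floor an exercise
is uncompletable *by construction* — every state change costs roughly 1–1.5 s
of closed-loop latency (filter delay plus 2-s window turnover) — which would
conflate "difficult" with "impossible". The scripted subject in
`simulate_training_course()` performs each state for its proportional share
of the allotted time after a 2-s pre-roll (the decoder is already running
when a real exercise starts).

## Pain-diary outcomes

**Pain volume.** The daily paroxysmal burden is
`sum(intensity × duration)` over the day's episodes (NRS·hours; zero for
episode-free days). Durations are taken in hours — the published unit is not
explicit, and hours are the only unit consistent with diary self-reports of
hour-scale pain attacks.

**Period tables.** `summarize_periods()` gives 0.25/0.5/0.75 quantiles
(type-7) of daily values per patient and pooled, plus the percent variation
of each period median from the baseline (`m-1`) median, displayed
half-up-rounded to 2 decimals and undefined (NA) for zero baselines. The
packaged transcriptions of the published tables are parsed by a normalizer
that converts comma decimals and flags number-format ambiguity: when any row
of a patient violates `q25 ≤ median ≤ q75` under plain decimal reading, the
dots in that patient's rows cannot be distinguished from thousands
separators, and all of that patient's rows are excluded from parity checks.
Printed variation cells mix truncation and rounding at the second decimal,
so parity is asserted to one unit of the last printed digit (±0.01).

**Mixed models.** Daily values are modelled with a subject random intercept
(baseline heterogeneity in pain perception), REML estimation, Wald z tests
with ±1.96·SE confidence intervals, and a likelihood-ratio test of the
global period effect computed from ML refits — an LRT of fixed effects
between REML fits is not valid, and the implementation refits with ML for
exactly that comparison. The phase model uses three levels (`m-1`,
`w1w2`, `w3w4`); the weekly model five (`m-1`, `w1`–`w4`). The paroxysmal
response is the daily percent variation from the subject's own baseline
median (scale-free across subjects); the continuous-pain response is the
raw daily average NRS. Per-patient rows are per-subject ordinary least
squares with Wald t tests — one subject admits no random intercept — and a
single-subject input is redirected there with a warning. Long-term
follow-up periods (weekly rather than daily self-assessment) are summarized
descriptively and never modelled.

**Diary generator.** Volumes are lognormal around
`baseline_median × period_multiplier × exp(b_i)` with `b_i ~ N(0,
subject_sd²)` and day-to-day dispersion `sdlog = 0.8`, chosen once from the
within-patient interquartile spans of observed right-skewed daily volumes;
episode counts are Poisson (12/day by default, matching cohorts reporting
11–20 daily pain crises), and a day's volume is split across episodes with
Dirichlet(1) weights and integer intensities. The default period
multipliers (0.65, 0.45, 0.36, 0.14 for w1–w4) encode the ~35/55/64/86%
median reductions the intervention period is expected to show. Under
lognormal noise the *mean* percent variation in a period with multiplier
`m` is `100 (m·exp(sdlog²/2) − 1)` while the *median* variation is
`100 (m − 1)`; the tests use whichever functional their estimator targets.
At this dispersion the w2/w3 multipliers (0.45 vs 0.36) differ by well
under one standard error of their contrast at 6 subjects × 7 days, so the
full weekly ordering reproduces in a majority — not the near-totality — of
simulated cohorts, and the tests assert exactly that plus the w4 contrast
being the deepest.

## Numerical choices and degenerate inputs

* Shrinkage: covariances are shrunk toward `mean(diag) · I`, escalating the
  weight tenfold from 1e-6 until the condition number drops below 1e8.
* Constant windows floor their log-variance at `log(1e-12)` with a warning.
* Zero-MAD channels fall back to the SD; zero-SD channels reject nothing.
* Constant-response mixed models report a zero LRT statistic (p = 1)
  directly: the deviance difference between two exact fits is numerical
  noise.
* EDF serialization is 16-bit with per-channel physical scaling; round
  trips are exact to one quantization step, and writes are
  byte-deterministic.
* All randomness flows through one integer seed per generator
  configuration; identical seeds give bit-identical outputs.

## Problem sizes used by the tests

The suite runs entirely on synthetic data: one full 9-series calibration
session (162 trials, 19 channels, 256 Hz) shared across the decoder, ERD
and acceptance tests; 2–3-series sessions elsewhere; 200 simulated
6-subject diary cohorts for the confidence-interval coverage check; and a
3-session training course for the end-to-end protocol demo, with the
10-session course exercised by `scripts/` and the examples. These sizes
keep the full suite in the low minutes on a laptop while leaving every
statistical assertion comfortably powered.

## Known limitations

* The outlier-screening statistic is a documented stand-in, pluggable but
  not a reconstruction of the unpublished original.
* The difficulty-score arithmetic and the exercise-validation dwell rule
  are this package's conventions for published ingredients without
  published formulas.
* The generator's spatial model is idealized; CSP patterns on real data
  will be less focal, and competence-gate results here say nothing about
  BCI-illiteracy rates in real cohorts.
* Streaming latency figures (filter delay, window turnover) describe this
  implementation, not any deployed amplifier/VR stack.
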