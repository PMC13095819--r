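# mibci

Motor-imagery EEG decoding, closed-loop classification, and pain-diary
outcome analysis.

`mibci` is for researchers and engineers building or evaluating
sensorimotor brain-computer-interface (BCI) neurofeedback systems — in
particular BCI-driven motor-imagery training for chronic neuropathic
(phantom-limb type) pain — and for the biostatistics that such trials
produce. It provides, as one tested R package:

* **Synthetic data with known ground truth** — three-class motor-imagery
  EEG sessions with contralateral mu/beta event-related desynchronization
  (ERD) over sensorimotor electrodes, and per-subject pain diaries with
  period effects and subject random intercepts. Every downstream stage is
  testable without recorded patient data.
* **Open-loop calibration** — zero-lag FIR band-pass (8–30 Hz), 1–6 s
  post-cue epochs, 2-s windows at 50% overlap, robust outlier-window
  rejection, Common Spatial Patterns + Linear Discriminant Analysis,
  run-wise k-fold cross-validation, and the 70% competence gate.
* **Closed-loop streaming** — causal decoding of a continuous recording at
  the protocol's update rate (2-s window every 62.5 ms; 16 decisions/s).
* **ERD/ERS mapping** — DPSS multitaper time-frequency maps as percent
  change from a −1–0 s pre-cue baseline.
* **Training-protocol analytics** — balanced competence-test schedules,
  dwell-based exercise validation, a composite difficulty score, and
  session success rates.
* **Pain outcomes** — the paroxysmal *pain volume* statistic
  (Σ episode intensity × duration, NRS·hours), per-period quantile/variation
  tables, and random-intercept linear mixed models with phase and weekly
  contrasts (REML estimates, Wald z tests, ML likelihood-ratio tests).
* **EDF I/O** — native EDF+ reading/writing with annotation (TAL) support.

## The models in brief

**CSP.** For class covariance Σ_c and rest covariance Σ_r, CSP solves the
generalized eigenproblem Σ_c w = λ (Σ_c + Σ_r) w; eigenvalues λ ∈ [0, 1]
measure the variance fraction a filter captures for the class (λ = ½ means
no discrimination). Filters are ranked by |λ − ½| and retained round-robin
across the three one-vs-rest problems to 6 components; features are
log(var(wᵀx)) per 2-s window; a pooled-covariance LDA with softmax
posteriors classifies. Accuracy is assessed by grouped cross-validation
with runs as folds (windows of one run never split across folds), and a
subject passes the competence gate when mean accuracy ≥ 0.70.

**ERD/ERS.** For trial-averaged multitaper power P(ch, f, t) and baseline
mean B(ch, f) over −1–0 s, the map is 100 · (P − B) / B. Imagery shows as a
negative (desynchronized) deflection in the mu band over the contralateral
sensorimotor channel.

**Pain models.** Daily outcome y_id (percent variation of pain volume from
the subject's baseline median, or raw average NRS) follows
y_id = β₀ + β_period + b_i + ε_id with subject intercepts
b_i ~ N(0, τ²), fit by REML; the global period effect is tested by an LRT
of ML refits.

## Worked example

Calibrate a decoder on a simulated competence-test session and map the ERD
that makes it work:

```r
library(mibci)

cfg     <- synth_eeg_config(erd_depth = 0.4, snr = 4, seed = 1)
session <- generate_mi_session(cfg)          # 9 series x 18 trials, 19 ch
cal     <- calibrate_decoder(session$recording)
cal$cv
#> <cv_report> 9-fold (window level): mean accuracy 0.913 [folds: 0.93 0.90 0.92 0.90 0.97 0.94 0.93 0.88 0.84]
cal$gate
#> <gate_decision> attempt 1: accuracy 0.913 >= threshold 0.70 -> PASS
cal$model
#> <decoder_model> classes: relax/left_hand/right_hand | 6 CSP components | training accuracy 0.926

map <- compute_erd_map(session$recording, task = "left_hand")
sprintf("mu ERD 1-6 s: C3 %.1f%%  Cz %.1f%%  C4 %.1f%%",
        tf_band_mean(map, "C3"), tf_band_mean(map, "Cz"), tf_band_mean(map, "C4"))
#> "mu ERD 1-6 s: C3 -1.8%  Cz -13.5%  C4 -40.0%"
```

The decoder clears the inclusion gate with 91.3% run-wise cross-validated
accuracy, and the map recovers the simulated ground truth: left-hand
imagery suppresses mu power by 40% at C4 (contralateral) and barely at C3.

Pain diaries work the same way:

```r
diary <- generate_pain_diaries(pain_sim_config(seed = 1))
summarize_periods(diary, "volume", grouping = "pooled")
#>   patient period    q25 median    q75 variation_pct
#> 1     All    m-1 204.00 348.14 575.02            NA
#> 2     All     w1 100.06 185.49 364.17        -46.72
#> 3     All     w2  81.63 159.09 249.46        -54.30
#> 4     All     w3  98.47 148.46 193.36        -57.36
#> 5     All     w4  19.13  41.54  65.07        -88.07

fit_phase_lmm(diary)   # percent variation of daily pain volume
#> <lmm_result> random-intercept model (REML), n = 348, subject var 6.843
#>   term estimate   se      z         p   ci_lo  ci_hi
#> 1 w1w2   -57.42 11.3 -5.083 3.724e-07  -79.57 -35.28
#> 2 w3w4   -97.70 11.3 -8.648 5.263e-18 -119.84 -75.55
#> LRT vs no-period model: chi^2(2) = 73.197, p = 1.275e-16
```

Median paroxysmal pain volume falls progressively across the intervention
weeks (−46.7% at w1 down to −88.1% at w4 versus baseline in this
simulation), and the mixed model attributes large, significant reductions
to both the training and post-training phases.

A command-line wrapper over the same functions is installed at
`inst/scripts/mibci` (subcommands `simulate-eeg`, `simulate-diary`,
`calibrate`, `stream`, `erdmap`, `protocol-run`, `pain-summarize`,
`pain-model`).

## Package layout

* `R/` — montage & synthetic EEG, pain-diary simulator, preprocessing,
  CSP/LDA decoder, streaming, ERD maps, protocol scoring, pain statistics,
  EDF and JSON I/O.
* `inst/extdata/` — transcriptions of the published period-summary tables
  used by the table-parity tests (with a comma-decimal/ambiguity
  normalizer).
* `vignettes/decoding-and-outcomes.Rmd` — the methods vignette: models,
  assumptions, parameter defaults, numerical choices, and limitations.
* `tests/testthat/` — unit, property and acceptance tests, all on
  synthetic data generated at test time.
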