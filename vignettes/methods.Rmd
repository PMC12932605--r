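---
title: "Estimating structure-specific musculoskeletal loads from IMU data: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating structure-specific musculoskeletal loads from IMU data: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Running-related overuse injuries develop when the cumulative load on a
specific tissue — the Achilles tendon, the patellar tendon, the articular
surfaces of the ankle or knee — outpaces its capacity to adapt. Laboratory
pipelines estimate these structure-specific loads (SSL) from optical motion
capture and force-plate data via musculoskeletal modeling, but that
instrumentation is confined to the lab. `runload` implements the alternative:
estimating the stance-phase SSL of a running step, expressed in multiples of
body weight (BW), from two body-worn inertial measurement units (IMUs) — one
on the right foot, one on the pelvis — together with a handful of subject and
shoe descriptors.

The pipeline covers the full chain: IMU signal processing and gait-event
detection, reference-side step segmentation from the vertical ground reaction
force (vGRF), step exclusion rules, time normalization, a tabular
biomechanical feature battery, a family of regression models (bidirectional
LSTM networks, a feed-forward network, an L1 linear baseline and a mean
regressor), subject-level cross-validation, and Monte Carlo dropout
uncertainty. Because no public dataset accompanies the protocol, the package
also ships a synthetic-cohort generator emulating a laboratory treadmill
protocol; every stage of the pipeline is tested against that
generator's analytic ground truth.

## Signal processing

**Angular velocity.** Orientation streams arrive as unit quaternions at
240 Hz. The body-frame angular velocity is the forward difference
$\omega(t) = \tfrac{2}{\Delta t}\,\mathrm{vec}\!\left(q(t)^{-1} \otimes q(t+\Delta t)\right)$
with $q^{-1}$ the conjugate. Two numerical details matter. First, the
relative quaternion is sign-canonicalized (scalar part made non-negative)
before taking the vector part, so the quaternion double cover — $q$ and $-q$
encode the same orientation — cannot inject spurious $2\pi/\Delta t$ spikes.
Second, the estimator has an $O((\omega\Delta t)^2)$ truncation bias
($\approx 2\cdot 10^{-5}$ rad/s at $\omega = \pi$, 240 Hz); tests therefore
compare against the estimator's closed form exactly and against a
rotation-matrix finite-difference oracle at slow rotation where both biases
are below $10^{-6}$.

**Filtering.** Accelerations are low-passed with a fifth-order Butterworth at
40 Hz, load signals at 20 Hz, both applied forward-backward (zero-phase,
`signal::filtfilt`). Zero-phase application is a deliberate choice: event
*timing* drives step matching, and a causal filter would lag every event by
several samples.

**Gait events.** Initial contact (IC) is an upward crossing of +0.18 g on the
(gravity-free) vertical foot acceleration, toe-off (TO) a downward crossing
of −0.25 g. The additional morphological constraints — "a decrease before IC
and TO, an increase after IC" — are operationalized as: the minimum over the
10 samples before the IC crossing must reach −0.05 g (the pre-contact
unweighting dip), the signal 5 samples after IC must exceed its crossing
value, and the signal 5 samples before TO must exceed its trough-side value.
A *strict* sample-by-sample monotonicity window is not usable here: after
zero-phase 40 Hz filtering a threshold crossing always sits on a rising edge
several samples wide. When no TO is found before the next IC candidate the TO
threshold is relaxed in +0.05 g steps up to −0.05 g; ICs without a TO are
dropped. The detector is validated against a literal brute-force scan of the
same rules and, on synthetic cohorts, against the generator's stored truth
(≥99 % of clean steps within 25 ms).

**Acceleration convention.** The generator emits free (gravity-subtracted)
acceleration in the sensor frame with the vertical axis in channel 3. The
g-relative thresholds presuppose a signal oscillating around zero during
flight; a gravity-inclusive convention would shift both thresholds by 1 g.
User-supplied data must follow the same convention.

## Step processing and characteristics

Stances are segmented from the vGRF as maximal runs ≥ 50 N (half-open
`[IC, TO)`, runs under 10 ms discarded as chatter). GRF-detected steps are
matched greedily to acceleration-detected steps by nearest IC within 50 ms;
unmatched steps are excluded. Steps are then filtered by rules evaluated in a
fixed order, with the first failing rule reported: stance duration outside
[0.15, 0.5] s, step duration outside [0.21, 0.6] s, signal dropout (≥ 20
consecutive identical samples in a raw acceleration channel), and SSL outside
the expected range (peak outside (0.5, 15] BW or any value below −0.01 BW).
The 0.5–15 BW bracket is the package's own default — wide enough to bracket
physiologic running loads for all four structures — and is configurable.

**Step duration** is defined as half the interval between consecutive
right-foot ICs. At running cadence an ipsilateral IC-to-IC interval is a full
stride (≈ 0.65–0.75 s), so a "step" bounded by the 0.21–0.6 s
acceptance band can only be the ipsilateral-to-contralateral interval; with
right-side streams only, the package estimates it as stride/2 under a
left/right symmetry assumption.

All stance-phase signals are linearly interpolated onto 100 points. The three
characteristics of a time-normalized curve with stance duration $t_c$ are:

* **Peak**: the curve maximum (BW); ties resolve to the earliest frame.
* **Impulse**: the rectangular frame sum divided by the effective rate
  $100/t_c$, i.e. BW·s. Rectangular (not trapezoidal) summation matches the
  BW·frame bookkeeping of the definition; on the generator's raised-cosine
  template the closed-form integral is $\mathrm{peak}/2 \cdot t_c$, and the
  rectangular error at 100 frames is below 2 %.
* **Average loading rate**: $(y_{f_u} - y_{f_l}) / ((f_u - f_l)/(100/t_c))$
  in BW/s, with percentile frames $f_p = \mathrm{round}(p \cdot L)$ rounded
  half away from zero over interval $L$ — IC-to-peak (20 %/80 %) for
  Achilles, patellar and ankle; IC-to-TO (10 %/40 %) for the knee. A peak at
  frame 0 makes the interval degenerate; such steps are flagged and excluded
  from loading-rate metrics, and counted.

## Feature battery

Each accepted step yields 6 subject features (mass, sex coded male = 1, age,
height, shoe length, sole thickness) plus the biomechanical block: stance and
step duration; per acceleration channel the stance-phase impulse, maximum,
mean, RMS, sample entropy and skewness (Fisher $g_1$, bias-uncorrected); per
angular-velocity channel the signed maximum and mean. That is 50
biomechanical features for two sensors, 26 for one (56/32 in total).
Statistics are computed on the filtered stance segments at native rate — not
on the 100-point matrices — because the impulse carries physical units.
Sample entropy uses the de facto standard $m = 2$, $r = 0.2\,\mathrm{sd}$;
the package's vectorized implementation is cross-checked against
`pracma::sample_entropy` and a brute-force template-counting oracle. On a
zero-variance segment sample entropy is undefined; the feature is recorded as
0 and the step flagged, keeping the feature matrix complete.

## Models

Five estimators share one contract — input a step, output a 100-value
non-negative stance-phase load curve — so the evaluation harness is
model-agnostic. One model is trained per structure.

* **hybrid-LSTM**: the 12×100 (or 6×100) standardized IMU matrix passes
  through two bidirectional LSTM layers of 20 units per direction; the
  recurrent summary is concatenated with the 56 (or 32) tabular features,
  batch-normalized, then dropout (0.2) → dense 20 ReLU → dropout (0.2) →
  linear dense 100.
* **TS-LSTM**: identical but without the concatenation (time series only).
* **F-NN**: tabular only; dense 20 ReLU → dropout → dense 20 ReLU → dropout
  → linear dense 100.
* **linear L1**: a lasso per output timestamp (`glmnet`), penalty selected
  from the 7-point log grid $10^{-4} \dots 10^{2}$ by validation MSE.
* **mean regressor**: the pointwise training-mean curve, a constant
  prediction.

Networks train with Adam (initial learning rate $10^{-4}$, staircase decay
×0.90 every 10,000 optimizer steps, batch 64), MSE loss, early stopping on
validation loss with patience 30 and best-weight restoration, at most 500
epochs by default.

Design choices where the architecture description is silent:

* **Recurrent summary.** Whether the second bidirectional layer feeds its
  final hidden states or a sequence summary to the dense head is not
  specified. The package's default mean-pools the 40-dimensional output
  sequence over the 100 timestamps; `recurrent_pool = "final"` selects the
  final-states variant. Mean pooling gives every timestep a direct gradient
  path to the loss instead of routing everything through a 100-step
  recurrence, and converges roughly twice as fast at equal capacity — which
  matters at the small learning rate the protocol fixes.
* **Initialization.** Input kernels are Glorot-uniform, recurrent kernels
  orthogonal per gate (the convention of the toolchain this model family is
  usually trained with), LSTM forget-gate biases 1. The output layer is
  initialized to the mean regressor: weights zero, bias equal to the
  training-mean target curve. Targets are trained in BW, unstandardized, so
  they sit far from zero; with a generic random output layer the small fixed
  learning rate spends most of a desk-scale epoch budget first reaching the
  target scale and then unlearning seed-dependent prediction noise, whereas
  the mean-regressor start makes epoch 0 exact and seed-robust, and the
  network learns only deviations from the mean curve.
* **Precision.** The training engine (hand-written in RcppArmadillo, as no
  deep-learning runtime is part of the package's dependency set) runs in
  float32 — the standard precision for this model family — with a
  range-reduced polynomial `exp` for the gate nonlinearities. A
  double-precision instantiation backs the finite-difference gradient checks
  in the test suite, which verify every architecture's analytic gradients to
  ~10⁻⁶ relative error.
* **Batch normalization** uses batch statistics during training and running
  averages (momentum 0.99, ε = 10⁻³) at inference.

## Evaluation

Cross-validation is at the subject level: subjects are shuffled and dealt
round-robin into 5 folds; within each fold the non-test subjects split
5/6 train, 1/6 validation, also by subject. Scalers (z-scores per tabular
feature and per IMU channel, statistics pooled over training steps ×
timestamps) are fitted on the training split only. Disjointness of the three
subject sets is asserted at run time, not assumed.

Curve metrics pool over steps × 100 timestamps: MSE in BW²; MAPE in % over
entries whose true value is at least 0.1 BW (the truth approaches zero at IC
and TO, where a naive MAPE diverges — the floor is configurable); and
$R^2 = 1 - \mathrm{SS}_{res}/\mathrm{SS}_{tot}$ with the total sum of squares
centered per timestamp. Per-timestamp centering makes the constant mean-curve
prediction score ≈ 0, so $R^2$ measures step-to-step explanatory power rather
than the trivial reproduction of the average stance shape. Macro-averaging is
the unweighted mean over folds. Characteristics of predicted curves are
computed with the same operations as the truth, including the predicted
curve's own peak frame for the loading-rate interval.

Monte Carlo dropout keeps the dropout layers active at inference: 100
stochastic forward passes per step give a per-timestamp standard deviation
and, by computing peak/impulse/loading rate from each pass, per-characteristic
standard deviations. Channel ablation retrains a spec from scratch with one
input channel removed and reports the held-out metric change.

## The synthetic cohort generator

The generator stands in for the laboratory data collection and
musculoskeletal modeling chain; its defaults encode the emulated collection
protocol:

* Anthropometrics drawn per sex from normal distributions with the emulated
  cohort's summary statistics (e.g. male mass 79.8 ± 9.5 kg, height
  186.3 ± 7.4 cm), truncated to physiologic ranges; sex ratio 36:7.
* Protocol speed grid 2.22–3.33 m/s (within a typical 2.2–3.9 m/s racing
  and training envelope); stride and stance durations decrease linearly in speed
  (stride ≈ 0.80 − 0.045 v s, stance ≈ 0.40 − 0.05 v s) with ~1 %
  log-normal step-to-step jitter.
* The true load of each structure is a piecewise raised-cosine over stance:
  zero at IC and TO, peak $A$ at stance fraction $\tau_p$, with closed-form
  impulse $A/2 \cdot t_c$ for exact oracles. Peak amplitudes follow
  $A = A_0 (1 + \beta(v - 2.78)) (m/75)^{\gamma} L \varepsilon$ with
  structure bases 6.5/5.0/10.5/8.0 BW (Achilles, patellar, ankle, knee),
  speed slopes β ≈ 0.14–0.18 per m/s, a weak mass exponent γ = 0.05, a
  per-step latent load factor $L = 1 + c(s_{amp} - 1)$,
  $s_{amp} \sim N(1, 0.05^2)$, and residual log-normal noise
  $\varepsilon$ (σ = 2.5 %). Point noise on the load signals is
  multiplicative (σ = 3 % of the instantaneous load, scaled by
  `noise_scale`), mimicking per-timepoint static-optimization chatter and
  vanishing with the load at the stance edges. These values were chosen once
  as physiologic for running at these speeds.
* The same latent $s_{amp}$ (and a correlated impact factor $s_{imp}$)
  scales the foot impact spike, the pelvis oscillation amplitude, and the
  foot rotation amplitude, with coupling strength `coupling` — this shared
  dependence is what makes the IMU→SSL regression identifiable. Speed shapes
  both timing and amplitudes; mass weakly modulates the pelvis channel.
* The foot vertical channel carries the detector's required morphology
  (pre-contact dip to −0.5 g, one-to-two-sample rise through +0.18 g at IC,
  toe-off trough to −0.65 g); the vGRF is an impact-plus-active-peak stance
  profile with exact flight zeros, and true IC/TO are stored at its 50 N
  crossings, mirroring the reference segmentation rule.
* `noise_scale` multiplies all measurement noise (IMU, vGRF, SSL, quaternion
  jitter) and the anthropometric spread; 0 yields noiseless population-mean
  data where the pipeline must reproduce template parameters exactly.
  `corrupt_fraction` tags steps for artifact injection: signal dropout
  (zeroed window), stance-duration inflation (a >50 N decaying tail after
  TO), or out-of-range amplitude (×4), exercising each exclusion rule with
  known labels.

What the generator does *not* emulate: soft-tissue artifact, sensor drift
and magnetometer disturbance, left/right asymmetry, fatigue-related temporal
drift, inter-muscular load sharing, and the error structure of
musculoskeletal-model outputs (static-optimization chatter is only
approximated by white noise before the 20 Hz filter). Passing tests on
synthetic cohorts therefore demonstrate that the pipeline's *mechanics* are
correct and that the models can recover a known IMU-coupled load structure —
not that the trained models transfer to any real runner.

## Desk-scale experiment sizes

The built-in acceptance experiment uses 10 subjects × 3 speeds × 30 steps
(~900 accepted steps), half the default noise, a single held-out subject
fold, and networks capped at 200 epochs (patience 30). These sizes are the
package's chosen defaults for a self-contained, single-CPU run; the full
protocol values (500 epochs, 5-fold macro-averaging) remain the model-spec
defaults and are what a user with a real cohort would run via
`evaluate_models()`.

## Known limitations

* The generator's waveforms are piecewise-analytic caricatures; models
  trained on them say nothing about real gait signals.
* Orientation streams are noise-perturbed analytic rotations; no drift or
  sensor-fusion error model.
* The L1 baseline is fitted by coordinate descent (`glmnet`) rather than the
  networks' Adam loop; the estimator is the same, the optimizer is not.
* Left-foot models, marker-based side determination and the musculoskeletal
  modeling chain itself are out of scope; the generator emits the four
  structure loads directly.
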