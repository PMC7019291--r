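---
title: "Detecting mild dehydration from autonomic responses to cognitive stress"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting mild dehydration from autonomic responses to cognitive stress}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hydrans)
```

## The problem

Mild dehydration — a body-mass loss of roughly 1–2% from fluid
restriction — measurably alters autonomic nervous system (ANS) function,
but no noninvasive field test exists for it. `hydrans` implements a
complete analysis pipeline for one candidate approach: record
electrodermal activity (EDA) and photoplethysmography (PPG) with
wearable-style sensors while a subject sits at rest for four minutes and
then performs a four-minute Stroop colour–word task (cognitive stress),
extract nine indices of autonomic control from the two signals, and
classify the subject's hydration state ("wet" = euhydrated, "dry" =
mildly dehydrated) from those indices.

The cohort design the package emulates is 17 subjects, each measured four
times across three days: baseline (M1), after a day of euhydration (M2),
after a day of total fluid restriction (M3, the "dry" condition), and
after ad-libitum rehydration (M4). That yields 51 wet samples and 17 dry
samples, a 3:1 imbalance that shapes the whole classification design.

Because the human recordings behind this design are not publicly
deposited, the package includes a first-class synthetic cohort generator
with ground-truth logs, so that every stage — event detection, spectral
estimation, time–frequency decomposition, cross-validated classification
— can be validated against analytic oracles rather than against opaque
reference outputs.

## The nine indices

Per stage (rest and test separately):

| Index | Source | Definition |
|---|---|---|
| SCL (µS) | EDA | mean of the tonic component |
| NS.SCRs (/min) | EDA | rate of skin conductance responses with amplitude > 0.05 µS |
| EDASymp (µS²) | EDA | spectral power in 0.045–0.25 Hz |
| EDASympn (n.u.) | EDA | EDASymp / total spectral power |
| TVSymp | EDA | mean normalized instantaneous amplitude of the 0.08–0.24 Hz VFCDM components |
| PRVLF (ms²) | PPG | pulse-interval power in 0.045–0.15 Hz |
| PRVLFn (n.u.) | PPG | PRVLF / total power |
| PRVHF (ms²) | PPG | pulse-interval power in 0.15–0.4 Hz |
| PRVHFn (n.u.) | PPG | PRVHF / total power |

The analysis windows are the first two minutes of EDA and four minutes of
PPG per stage, both sampled at 32 Hz at acquisition.

### EDA decomposition

`decompose_eda()` separates skin conductance into a slow tonic component
and sparse phasic responses by nonnegative sparse deconvolution: it
solves

$$\min_{d \ge 0,\,c}\; \lVert y - K d - B c \rVert^2 + \lambda \lVert d \rVert_1$$

where $K$ convolves a Bateman (bi-exponential) kernel with the sudomotor
driver $d$ and $B$ is a cubic B-spline tonic basis with 10 s knots. The
problem is solved at a 4 Hz working rate with a coordinate-descent lasso
(warm-started over a short penalty path), with the tonic coefficients
unpenalized and the driver bounded below at zero.

Numerical choices that matter:

* **Kernel constants** default to rise 0.7 s / decay 2.0 s, a standard
  SCR shape; the same kernel is used by the synthetic generator, and the
  tests confirm planted events of 0.1–0.5 µS are recovered within 20%
  amplitude and 1 s timing.
* **Penalty** $\lambda$ scales with the signal's peak absolute deviation
  (2.5% of it, divided by the sample count) and is floored so that flat
  records stay identifiable: a constant input yields driver exactly zero
  and tonic equal to the input. The floor corresponds to a detection
  limit well below the 0.05 µS counting threshold, so threshold-level
  events are never lost to regularization.
* **SCR amplitude** is measured as the peak of the reconstructed phasic
  component due to each driver run alone, which matches planted
  amplitudes for kernel-shaped events and is immune to tonic drift
  (NS.SCRs is invariant to adding a pure ramp; the tests assert this).
  The 0.05 µS threshold comparison is strict (`>`).

### Spectral estimates

All spectra use Blackman-windowed averaged periodograms with 50% segment
overlap (`welch_psd()`), 256-point segments at 4 Hz for pulse-interval
spectra and 128-point segments at 2 Hz for EDA (both spanning 64 s, which
resolves the 0.045 Hz band edge). The density is compensated by the
window mean-square so a sinusoid of amplitude $a$ integrates to exactly
$a^2/2$ over its band; this calibration is what lets the synthetic
generator's targets be inverted analytically (`calibrate_params()`:
`lf_amp = sqrt(2 * PRVLF)` and so on) and is asserted to 5% in the tests.
Band integration is trapezoidal, with the LF band half-open at 0.15 Hz so
LF and HF never double-count the shared edge. Total power bands start at
0.003 Hz to exclude DC leakage; the choice of lower bound is exposed as
an argument.

Internal resampling to the 2 Hz and 4 Hz working rates uses two different
schemes deliberately: the spectral paths use a linear-phase FIR
anti-alias filter with the group delay removed (flat passband, so band
powers are unbiased by resampler droop), while the deconvolution path
uses block averaging (exactly preserves constants, so degenerate inputs
stay exactly flat).

### Pulse detection and PRV

`detect_pulses()` band-passes the PPG at 0.5–8 Hz, finds local maxima
over an adaptive amplitude threshold with a 0.3 s refractory interval,
and refines each peak time by parabolic interpolation. The sub-sample
refinement matters: at 32 Hz, raw sample-grid peak times carry ±16 ms of
quantization jitter, which would alias roughly 60 ms² of broadband power
into the PRV bands — comparable to the physiological HF power itself.
With refinement, synthetic pulse times are recovered to ~0.3 ms and band
powers to ~1%.

Since the recordings cannot be visually screened the way bench studies
screen them, an automatic beat-quality rule replaces the human: any
interval outside 0.33–2.0 s, or differing more than 40% from its
predecessor, fails the recording.

The interval series (ms, anchored at each interval's ending pulse) is
cubic-spline resampled to 4 Hz; the spline reproduces constants and
polynomial trends exactly.

### VFCDM and TVSymp

`vfcdm_decompose()` implements variable-frequency complex demodulation at
a 2 Hz working rate: eight components tile contiguous 0.08 Hz bands, so
components 2 and 3 cover 0.08–0.24 Hz, the band carrying sympathetically
mediated EDA oscillations. Stage 1 demodulates at fixed band centers
(64-tap Hamming FIR low-pass at half the bandwidth, applied single-pass
with the group delay removed — a two-pass zero-phase filter would square
the band-edge gain and break the bank's amplitude tiling, which is
instead normalized analytically from the filter design). Stage 2 tracks
each component's instantaneous frequency from its demodulated phase
(smoothed over ~4 s, clamped to the component's band) and re-demodulates
the component along that trajectory, sharpening the amplitude estimate;
the refinement residual is folded back through the fixed bank so the
components always sum to the band-limited input (reconstruction error
~0.2% RMS on band-limited noise, asserted ≤ 10%).

`compute_tvsymp()` takes the instantaneous amplitude (analytic-signal
modulus) of components 2+3 and normalizes by a standard deviation to make
the index dimensionless, trimming one filter length at each end. The
normalization window is a genuine design choice: normalizing each stage
by its own SD forces every stage toward a similar mean amplitude,
erasing the rest/test contrast, whereas normalizing both stages by the SD
of the concatenated rest+test band signal (`normalization =
"per_session"`, the default) reproduces the characteristic pattern of
rest values below 1 and test values above 1. Both options are
implemented; `tvsymp_pair()` applies the default. TVSymp is invariant
under positive rescaling of the input by construction.

## Group statistics

`stats_report()` screens each index for normality with a one-sample
Kolmogorov–Smirnov test of the standardized values (standardizing with
estimated parameters makes the screen anti-conservative — the Lilliefors
issue — but this is the conventional screen and is implemented as such),
then compares rest against test with a paired t-test for normal indices
and a two-sided Wilcoxon rank sum test otherwise. The rank-sum test is
applied unpaired even though the samples are paired, matching the
reporting convention this pipeline reproduces; the t-test's pairing is
switchable. p < 0.05 is flagged significant with no multiple-testing
correction. Simulation tests pin the realized type-I error to 0.05 ± 0.02
and the power at n = 17 against a 1.5 SD shift to ≥ 0.8.

## The classification study

`loso_evaluate()` implements leave-one-subject-out cross-validation: all
four of a subject's samples are held out together, so no subject
contributes to both training and validation. Within each fold:

1. each feature column is scaled by its Euclidean norm computed on the
   training rows only (the same divisor is applied to the held-out rows —
   fitting the scaling globally is available as an option but leaks
   validation information, so per-fold is the default);
2. the dry class is up-sampled by replication to match the wet count
   (exact triplication in the 48:16 study structure, equivalent to a 3×
   class weight);
3. one of nine classifier families is fit with fixed hyperparameters:
   LDA; QDA with a small covariance shrinkage (1e-6 · trace/d, needed
   because replicated dry rows make 16-sample covariances singular);
   unregularized logistic regression with a tiny-ridge fallback under
   perfect separation; cubic-kernel SVM (C = 1, kernel (1 + u·v)³);
   Gaussian SVMs with kernel scale 0.66 ("fine") and 2.6 ("medium") —
   the scale parametrization exp(−‖u−v‖²/σ²) is used because a *fine*
   kernel must be the more flexible one, and these values match the
   conventional fine/medium scale defaults for this feature count;
   1-nearest-neighbor; a CART decision tree (Gini, minimum leaf 1); and
   a random-subspace ensemble of 30 1-NN learners on ⌈d/2⌉ features each
   with majority vote (SE-KNN).

Predictions are pooled over all folds into a single confusion table
(per-fold metric averaging is ill-defined with one dry sample per fold),
and `compute_metrics()` reports accuracy, error rate, sensitivity
(dry recall), FPR, specificity (wet recall) and precision. The FPR
denominator is the actual-wet count, i.e. FPR = 1 − specificity, the
definition consistent with the worked examples the tests reproduce.

`exhaustive_sweep()` evaluates every non-empty subset of the nine indices
(511 of the 2⁹ = 512 subsets) for each family and data view (rest only,
test only, test − rest increments, both stages), sorting by accuracy with
ties broken toward fewer features.

## The synthetic cohort: what it does and does not emulate

`generate_cohort()` draws per-subject, per-cell index targets from
moment-matched log-normal distributions (log-normal because several
indices are strongly right-skewed and must stay positive) around cell
means/SDs fixed, by default, to the published cohort statistics of the
study design (`default_cohort_targets()`). A per-subject, per-index
random effect is drawn once and shared across all of that subject's
measurements, giving the repeated-measures structure that
leave-one-subject-out validation exists to respect. Targets map to
signal parameters analytically (`calibrate_params()`); sampling defaults
are 0.85 s mean inter-pulse interval (~70 bpm), Bateman 0.7 s/2.0 s SCR
kernel, Poisson SCR timing with a 1 s refractory interval whose mean gap
is exact, and an EDA oscillation at 0.1 Hz carrying the EDASymp target.

Honest limitations:

* The generator plants five of the nine indices directly (SCL, NS.SCRs,
  EDASymp, PRVLF, PRVHF); the normalized indices and TVSymp emerge from
  the signal structure rather than being controlled.
* The EDA oscillation interacts with the deconvolution: its rising
  half-cycles are partly attributed to the phasic driver, which inflates
  NS.SCRs by up to the oscillation frequency (6 cycles/min) and biases
  extracted SCL low by up to the oscillation amplitude. With the default
  (published) targets this is a visible bias; cohort-level SCL still
  tracks its target within 15% when oscillation amplitudes are modest.
* Heavily skewed cells (e.g. a dry-condition PRVLF of 170 ± 650 ms²) are
  matched in mean/SD only; full distributions are not attempted.
* No respiration, motion artifact, or sensor-contact physics: passing
  tests demonstrate the *pipeline's* correctness on signals with known
  structure, not field robustness of the dehydration test itself.

## Problem sizes and determinism

The validation suite runs the full 17-subject cohort (68 sessions, 136
stage-recordings) through feature extraction once, then sweeps all 511
subsets for three classifier families (KNN, LDA, cubic SVM) on the
test-stage view — the families span the margin/instance/discriminant
trichotomy while keeping the sweep to about a minute; the full
nine-family, four-view sweep is available through `run_pipeline()`.
Chance-level controls use 100 label permutations with LDA: with balanced
(up-sampled) training and no signal, a margin classifier predicts each
class about half the time, giving 0.5 expected accuracy against the 3:1
truth. A duplication-up-sampled 1-NN rule is *not* rebalanced by
up-sampling (duplicates cannot become anyone's new nearest neighbor), so
its permuted-label accuracy sits at p² + (1−p)² ≈ 0.625 — a useful
reminder that "chance level" is classifier-dependent.

Everything is deterministic given seeds: generators take explicit seeds,
LOSO fold seeds derive from the evaluation seed, and rerunning the
pipeline with the same configuration reproduces every output file
byte-for-byte (wall-clock timing in the run manifest aside).

## A worked run

```{r example, eval = FALSE}
spec <- cohort_effect_spec(n_subjects = 17, seed = 1)
cfg <- pipeline_config(spec, out_dir = "cohort_run", seed = 1,
                       views = c("rest_only", "test_only"),
                       families = c("KNN", "LDA", "CubicSVM"))
res <- run_pipeline(cfg)
res$best[, c("view", "family", "subset", "accuracy")]
```

The output directory then holds the per-stage feature tables, the
rest-vs-test stats report (per index and measurement, with the test used
and significance flags), the full sweep as JSON lines, the best model per
view, and a run manifest recording the seed and configuration.
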