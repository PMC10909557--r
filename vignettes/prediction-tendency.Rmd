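---
title: "Quantifying individual prediction tendency by time-resolved decoding"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying individual prediction tendency by time-resolved decoding}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Listeners and observers differ in how strongly they anticipate upcoming
sensory input. `predtend` implements a complete, simulation-backed pipeline
for quantifying this *individual prediction tendency*: the degree to which
a subject's neural activity pre-activates the stimulus that the statistical
structure of a sequence makes likely, before that stimulus appears.

The paradigm is an entropy-modulated sequence of four stimuli (for
instance four pure-tone frequencies, or four grating orientations)
presented passively at a fixed 3 Hz rate, 100 ms per stimulus. Transition
probabilities alternate between two regimes every 700 trials:

* **ordered** (low entropy): the cyclic *forward* transition 1→2, 2→3,
  3→4, 4→1 occurs with probability 0.75 and a *self-repetition* with
  probability 0.25; nothing else can occur;
* **random** (high entropy): all sixteen transitions are equally likely
  (0.25 each).

Repetitions are equally probable in both regimes, which is what makes a
matched comparison possible later. A block holds 2800 trials (four
segments); two blocks per modality give 5600 trials. A pseudorandom 10% of
trials per stimulus-by-regime stratum (about 70 trials each) is omitted --
positions where expectation can exist without bottom-up input.

## From decision values to a tendency score

Sensor data are band-passed 0.1--30 Hz, downsampled to 100 Hz and cut into
epochs from -0.4 to 0.8 s around onset. The first 20 trials after every
regime change are excluded: a Bayesian observer needs roughly that long to
re-learn the transition structure, which the package reproduces with a
Dirichlet-multinomial count learner (`ideal_observer()`) -- a deliberately
simple stand-in for a hierarchical filter that motivates the same cut-off
qualitatively.

A multiclass linear discriminant analyser with shrinkage
(`train_lda()`) is trained at every time sample between -0.3 and 0.3 s,
**exclusively on ordered forward trials**, so that whatever anticipatory
pattern exists in the ordered regime is part of what the classifier
learns. It is then tested on *self-repetition trials preceded by a forward
transition* (repetition at t-1→t, forward at t-2→t-1), in both regimes.
Because a test trial's identity fixes its entire two-trial history, and
the two conditions are matched within stimulus strata
(`select_test_trials()`), the preceding bottom-up input is identical across
conditions; training and test sets are disjoint by construction (forward
versus repetition trials).

For each test trial the four decision values d1--d4 are re-labelled by the
transition they would constitute given the previous stimulus
(`transition_evidence()`): with stimulus 1 at t-1, d2 is *forward*
evidence and d1 *repetition* evidence. The tendency curve is the mean
forward evidence, ordered minus random, per time sample
(`tendency_curve()`), and the **prediction tendency score** is its signed
sum over the prestimulus window -0.3--0 s (`tendency_score()`): one scalar
per subject and modality. Scores may be negative and are kept signed.

Two analysis choices are deliberately configurable because the method's
verbal description admits both readings: the curve statistic is plain
forward evidence by default, with a within-trial forward-minus-repetition
contrast behind `contrast = "forward_minus_repetition"`; and the decoding
window is -0.3 to 0.3 s, the epoch-supported portion (a wider window is
configurable but cannot exceed the 1.2 s epoch).

## Group statistics and reliability

* `cluster_permutation_test()`: one-sample cluster-based sign-flip
  permutation test of the subject-by-time curve matrix against zero.
  Clusters are contiguous runs of |t| above the per-tail
  `qt(1 - 0.025, n - 1)` threshold; the null distribution of the maximum
  absolute cluster mass is built from seeded sign flips (10,000 by
  default, or exhaustive enumeration for small cohorts), and p-values use
  the add-one convention (1 + exceedances)/(1 + permutations) so no
  cluster gets p = 0. Positive and negative clusters are tracked
  separately and no further multiplicity correction is applied.
* Cross-modal reliability treats the two modality scores as a two-item
  scale: Pearson r, covariance-based Cronbach's alpha
  (`cronbach_alpha()`, for two items equal to
  4 cov/(s1² + s2² + 2 cov)) and the Spearman-Brown step-up
  rho = 2r/(1 + r) (`spearman_brown()`).
* `split_half_reliability()` halves each subject's matched test trials
  (seeded, stratified by condition and stimulus), re-scores each half
  against the shared classifier, and steps up the across-subject
  half-half correlation. Splitting test trials only -- rather than
  retraining per half -- is a documented choice: it isolates the
  variability of the tendency estimate itself.
* `time_by_time_reliability()` computes the Spearman-Brown-transformed
  across-subject correlation for every pair of prestimulus samples of the
  two modalities' curves.

## What the synthetic data emulate

No public recordings accompany the paradigm, so the package ships a
generator that plays the role of the experiment:

* `simulate_full_sequence()` draws the Markov stimulus sequence with the
  paradigm constants; omissions are *exactly* stratified
  (round(0.1 x stratum) per stimulus-by-regime cell) so counts are
  testable; the chain continues across segment boundaries, with the
  20-trial burn-in absorbing the regime switch.
* `make_forward_model()` draws four unit-norm random sensor patterns with
  pairwise correlations bounded at 0.3 (the bound relaxes automatically
  when channel counts make it infeasible).
* `simulate_subject()` superimposes, on white Gaussian channel noise
  (optionally 1/f), an evoked response per non-omitted trial and -- in
  ordered segments only -- a prestimulus pre-activation of the forward
  successor of the *previous* stimulus, scaled by the subject's
  ground-truth amplitude `beta` and carried by a linear ramp over
  [-0.3, 0) s. Omitted trials keep their prediction but produce no evoked
  response. At 3 Hz, adjacent epochs overlap, so the previous trial's
  evoked tail leaks into the prestimulus window by design -- this is
  precisely the confound the t-1/t-2 matching must neutralise, and the
  simulation reproduces it.
* `simulate_cohort()` draws per-subject (auditory, visual) amplitudes from
  a bivariate Gaussian with configurable correlation rho, truncated at 0
  by default (negative ground-truth tendencies can be allowed).

Three generator choices are modelling decisions, not measured facts, and
are flagged as such:

* **Evoked kernel.** A gamma-shaped causal bump
  k(t) = (t/l)^a exp((l - t)/θ), a = (l/w)², θ = w²/l, peaking at
  l = 0.17 s with width w = 0.1 s and effective support [0, ~0.7] s --
  matching the window over which stimulus identity remains decodable in
  such data. The gamma form was preferred over a windowed half-sine
  because its integral has a closed form (incomplete gamma), giving the
  test suite an exact quadrature oracle.
* **Prediction time course.** Nothing constrains the temporal shape of
  pre-activation; a linear ramp over [-0.3, 0) s is assumed.
* **Signal-to-noise.** With unit evoked amplitude, `noise_sd = 2` and
  amplitudes beta ~ N(0.5, 0.25²) truncated at 0, single-trial 4-class
  accuracy is well above the 0.25 chance level post-stimulus while far
  from ceiling, in the range typical of sensor-level decoding of such
  paradigms. These defaults were fixed once, from a calibration pass at
  the reduced geometry, and are not tuned per analysis; the test suite
  checks chance level under label permutation and parameter recovery at
  exactly these defaults.

Passing tests on these data show that the *estimator chain* is correct and
well-calibrated; they cannot show robustness to artifacts, correlated
sensor noise, source mixing or non-stationarity, which the generator does
not emulate (and for which preprocessing steps like SSS or ICA would
exist; they are omitted here because the synthetic data contain nothing to
remove).

## Numerical choices

* Time conventions: sample 1 of a recording sits at t = 0; epochs use the
  half-open window [tmin, tmax) with onset at t = 0, so -0.4--0.8 s at
  100 Hz is exactly 120 samples and the decode window -0.3--0.3 s
  (endpoints inclusive) is 61 samples; the prestimulus sum runs over
  [-0.3, 0), 30 samples.
* Filtering is a windowed-sinc (Hamming) linear-phase FIR of order
  ~3 x srate applied by FFT convolution with group-delay compensation
  (zero phase without the double-pass); resampling uses the Fourier
  method (spectrum truncation), valid because the band-pass precedes it;
  both pad to 5-smooth FFT lengths, the resampler with reflected samples.
* LDA shrinkage uses the analytic Ledoit-Wolf intensity toward a scaled
  identity by default (`lambda = "auto"`), logged per time point;
  `lambda = 1` degenerates to nearest-class-mean scoring and
  `lambda = 0` on singular covariances fails with guidance rather than
  silently regularising.
* Zero-variance time samples in the cluster test contribute t = 0 rather
  than NaN; ties in class assignment resolve to the first class.
* Every stochastic step (sequence, noise, subselection, splits, sign
  flips) takes an explicit seed derived from one master seed
  (`derive_seed()`), making whole runs bit-reproducible.

## Problem sizes

The package-level simulation studies run at desk scale by choice:
`run_experiment()` defaults to 35 subjects, 32 channels and one
2800-trial block per modality at 300 Hz native rate; the parameter
recovery study (`study_beta_recovery()`) uses 16 channels at 150 Hz with
the full 2800-trial block; the replicate cross-modal study
(`study_rho_recovery()`) uses 700-trial blocks with `noise_sd = 0.5` so
that per-subject measurement reliability matches the full design's --
the study probes the cohort-level correlation estimator, and at matched
reliability the compact design answers the same question. The cluster
calibration (`study_cluster_type1()`) uses 400 null cohorts of 20
subjects by 30 samples at 1000 permutations. The full two-block,
306-channel geometry is available via `cohort_design()`.

## Known limitations

* The simulator's prediction signal reuses the evoked spatial patterns;
  if real pre-activations engage different generators, the decoder's
  sensitivity would differ from what parameter recovery suggests.
* The ideal-observer burn-in device reproduces the *rationale* for the
  20-trial exclusion, not any specific hierarchical-filter fit.
* Split-half reliability shares the trained classifier between halves;
  an alternative (independent training per half) would mix training
  variability into the reliability estimate.
* Cronbach's alpha on two items is reported for completeness alongside
  the Spearman-Brown coefficient; with k = 2 the two differ only through
  unequal item variances.

## A worked example

```{r, eval = FALSE}
library(predtend)

cfg <- run_config(
  n_subjects = 10, rho = 0.5,
  design = cohort_design(n_blocks = 1, segment_length = 350,
                         n_channels = 16, srate = 150),
  cluster = cluster_config(n_permutations = 1000),
  seed = 1)
run <- run_experiment(cfg)
print(run)
run$reliability$cross_modal
run$cluster$aud$clusters
```
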