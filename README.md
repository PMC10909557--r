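# predtend

Individual *prediction tendency* -- the degree to which a person's neural
activity pre-activates a stimulus that the statistics of a sequence make
likely, before it appears -- quantified by time-resolved multivariate
decoding. `predtend` is aimed at cognitive-neuroscience researchers who
work with passive entropy-modulated stimulation paradigms (M/EEG), and at
methodologists who want a fully simulated, testable version of that
analysis chain.

The package provides, end to end:

1. **Paradigm simulation** -- first-order Markov stimulus sequences over
   four stimuli with two transition regimes (*ordered*: forward
   transition 1→2, 2→3, 3→4, 4→1 at P = 0.75, self-repetition at 0.25;
   *random*: all transitions at 0.25), alternating every 700 trials;
   exact 10% stratified stimulus omissions; 20-trial burn-in after each
   regime change, motivated by a Dirichlet-multinomial ideal observer.
2. **Synthetic recordings** -- multi-channel sensor data with
   stimulus-specific evoked topographies and a controllable prestimulus
   pre-activation of the expected stimulus, whose per-subject amplitude
   is the ground-truth tendency.
3. **Preprocessing** -- zero-phase FIR band-pass (0.1--30 Hz), Fourier
   resampling to 100 Hz, epoching -0.4--0.8 s.
4. **Decoding** -- shrinkage multiclass LDA trained per time sample on
   ordered forward trials and tested on history-matched self-repetition
   trials; decision values d1--d4 are re-labelled as transition evidence
   given the previous stimulus. The per-subject score is

   score = sum over t in [-0.3, 0) of
           [ mean forward dval (ordered) - mean forward dval (random) ](t)

5. **Statistics** -- cluster-based sign-flip permutation tests (10,000
   permutations, cluster and Monte-Carlo alpha 0.025), Pearson
   correlation, Cronbach's alpha, Spearman-Brown rho = 2r/(1+r),
   split-half and time-by-time cross-modal reliability.

## A worked example

```r
library(predtend)

cfg <- run_config(
  n_subjects = 12, rho = 0.5,
  design = cohort_design(n_blocks = 1, n_channels = 16, srate = 150,
                         noise_sd = 1),
  cluster = cluster_config(n_permutations = 1000),
  seed = 1)
run <- run_experiment(cfg)
print(run)
```

```
predtend run: 12 subjects, 16 channels, 1 block(s)
cross-modal r = 0.390 (alpha 0.498, rho 0.561)
[aud] Cluster permutation test: 12 subjects, 61 samples, |t| > 2.201
  start end       mass sign           p time_start time_end
1     8   8  -2.838984   -1 0.500499500      -0.23    -0.23
2    18  18   2.314791    1 0.726273726      -0.13    -0.13
3    20  30  45.639526    1 0.014985015      -0.11    -0.01
4    41  61 137.944629    1 0.000999001       0.10     0.30
[vis] Cluster permutation test: 12 subjects, 61 samples, |t| > 2.201
  start end      mass sign           p time_start time_end
1     1   1  2.397503    1 0.656343656      -0.30    -0.30
2    17  17  2.235004    1 0.722277722      -0.14    -0.14
3    20  22  8.449772    1 0.077922078      -0.11    -0.09
4    25  30 16.103785    1 0.036963037      -0.06    -0.01
5    41  61 99.114210    1 0.000999001       0.10     0.30
```

Read: with a simulated 12-subject cohort whose true auditory and visual
tendency amplitudes correlate at rho = 0.5, the recovered scores
correlate at r = 0.39 (small-n estimates scatter widely; alpha and the
Spearman-Brown rho are the two-item internal-consistency versions of the
same number). Each modality shows a significant *prestimulus* cluster of
ordered > random forward evidence ending just before onset (auditory
-0.11 to -0.01 s, p = .015; visual -0.06 to -0.01 s, p = .037) -- the
signature of anticipatory pre-activation -- plus a strong post-stimulus
cluster driven by the 75%-likely forward stimulus actually appearing.
Isolated one-sample clusters with p > .5 are noise. Per-subject scores
sit in `run$scores`, reliability summaries in `run$reliability`, and
setting `out_dir` in `run_config()` writes a three-row reliability table
(TSV), per-subject scores (TSV) and a JSON results bundle.

## Layout

* `R/sequence.R` -- transition models, sequence generation, omissions,
  burn-in, ideal observer
* `R/simulate.R` -- forward models, evoked/prediction kernels, subject and
  cohort simulation
* `R/preprocess.R` -- band-pass, resampling, epoching
* `R/decode.R` -- trial selection/matching, shrinkage LDA, transition
  evidence, tendency curves/scores, temporal generalization
* `R/stats.R` -- cluster permutation test, reliability statistics
* `R/pipeline.R`, `R/studies.R` -- end-to-end runs, YAML config, report
  writers, simulation studies
* `vignettes/prediction-tendency.Rmd` -- the methods vignette
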