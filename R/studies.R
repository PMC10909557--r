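# simulate -> preprocess -> decode for one subject and one sequence
run_one_subject <- function(seqs, design, beta, seed, analysis_rate = 100,
                            window = c(-0.3, 0.3), prestim = c(-0.3, 0),
                            contrast = "forward", lambda = "auto") {
  fm <- make_forward_model(design$n_channels, seed = derive_seed(seed, 1),
                           max_abs_cor = design$max_abs_cor)
  p <- subject_params(beta = beta,
                      evoked_amplitude = design$evoked_amplitude,
                      evoked_latency = design$evoked_latency,
                      evoked_width = design$evoked_width,
                      noise_sd = design$noise_sd,
                      seed = derive_seed(seed, 2))
  rec <- simulate_subject(seqs, fm, p,
                          timing = sequence_timing(design$stimulation_rate),
                          srate = design$srate)
  rec <- bandpass_filter(rec)
  if (analysis_rate < rec$srate) rec <- resample_recording(rec, analysis_rate)
  ep <- epoch_recording(rec, seqs)
  decode_subject(ep, window, prestim, contrast, lambda,
                 seed = derive_seed(seed, 3))
}

#' Desk-scale geometry for the simulation studies
#'
#' The compact geometry used by the parameter-recovery and calibration
#' studies: 16 channels, 150 Hz native rate, one block of 4 segments. The
#' per-segment trial count and the noise level are the study-specific
#' knobs.
#'
#' @param segment_length Trials per segment (default 700).
#' @param noise_sd Channel noise SD (default 2, the cohort default).
#' @param n_channels Sensors (default 16).
#' @param srate Native rate in Hz (default 150).
#' @param ... Further overrides passed to [cohort_design()].
#' @return A design list.
#' @export
study_design <- function(segment_length = 700, noise_sd = 2,
                         n_channels = 16, srate = 150, ...) {
  cohort_design(n_blocks = 1, segment_length = segment_length,
                n_channels = n_channels, srate = srate,
                noise_sd = noise_sd, ...)
}

#' Parameter recovery: ground-truth beta versus recovered tendency score
#'
#' Simulates a cohort at the default SNR, runs the full single-modality
#' pipeline per subject, and correlates the recovered prediction-tendency
#' scores with the ground-truth pre-activation amplitudes.
#'
#' @param n_subjects Cohort size (default 35).
#' @param design Simulation geometry (default [study_design()]).
#' @param seed Integer seed.
#' @param beta_mean,beta_sd Amplitude distribution (defaults 0.5, 0.25,
#'   truncated at 0).
#' @return List with `r` (Pearson correlation), `scores` (data frame with
#'   beta and score per subject), `n_test` (matched trials per subject).
#' @export
study_beta_recovery <- function(n_subjects = 35, design = study_design(),
                                seed = 1, beta_mean = 0.5, beta_sd = 0.25) {
  betas <- draw_subject_params(n_subjects, rho = 0, beta_mean, beta_sd,
                               truncate = TRUE,
                               seed = derive_seed(seed, 11))$beta_aud
  res <- lapply(seq_len(n_subjects), function(i) {
    seqs <- simulate_full_sequence(
      n_blocks = design$n_blocks,
      segments_per_block = design$segments_per_block,
      segment_length = design$segment_length,
      omission_rate = design$omission_rate,
      n_burn_in = design$n_burn_in,
      seed = derive_seed(seed, 100 + i))
    run_one_subject(seqs, design, betas[i], derive_seed(seed, 200 + i))
  })
  scores <- vapply(res, `[[`, numeric(1), "score")
  list(r = stats::cor(betas, scores),
       scores = data.frame(subject = seq_len(n_subjects), beta = betas,
                           score = scores),
       n_test = vapply(res, function(d) min(d$n_test), numeric(1)))
}

#' Cross-modal correlation recovery over replicate cohorts
#'
#' For each replicate, simulates a two-modality cohort whose ground-truth
#' pre-activation amplitudes have correlation `rho`, runs the pipeline for
#' both modalities, and estimates the cross-modal Pearson correlation of
#' the recovered scores. The compact replicate geometry uses a reduced
#' noise level so that per-subject measurement reliability matches the
#' full design's; otherwise attenuation from score noise, not the
#' estimator, would dominate.
#'
#' @param rho True amplitude correlation.
#' @param n_replicates Number of replicate cohorts (default 20).
#' @param n_subjects Cohort size (default 35).
#' @param design Geometry (default
#'   `study_design(segment_length = 175, noise_sd = 0.5)`).
#' @param seed Integer seed.
#' @return List with `estimates` (per replicate), `mean_estimate`, `rho`.
#' @export
study_rho_recovery <- function(rho, n_replicates = 20, n_subjects = 35,
                               design = study_design(segment_length = 175,
                                                     noise_sd = 0.5),
                               seed = 1) {
  est <- vapply(seq_len(n_replicates), function(rep) {
    rseed <- derive_seed(seed, 3000 + rep)
    cohort <- simulate_cohort(n_subjects, rho, design, seed = rseed)
    sc <- vapply(seq_len(n_subjects), function(i) {
      vapply(c("aud", "vis"), function(m) {
        run_one_subject(cohort$sequences[[i]][[m]], design,
                        cohort$params[[paste0("beta_", m)]][i],
                        derive_seed(rseed, i * 2 + match(m, c("aud", "vis"))))$score
      }, numeric(1))
    }, numeric(2))
    stats::cor(sc[1, ], sc[2, ])
  }, numeric(1))
  list(estimates = est, mean_estimate = mean(est), rho = rho)
}

#' Empirical chance level of the decoder
#'
#' Simulates one subject, permutes the training labels (several seeded
#' shuffles) and returns the time-averaged 4-class assignment accuracy on
#' the matched test trials, which should sit at the 0.25 chance level.
#'
#' @param design Geometry (default `study_design(segment_length = 350)`).
#' @param n_shuffles Number of label permutations to average (default 3).
#' @param seed Integer seed.
#' @return List with `accuracy` (mean over shuffles, trials and time) and
#'   `per_shuffle`.
#' @export
study_null_decoding <- function(design = study_design(segment_length = 350),
                                n_shuffles = 3, seed = 1) {
  seqs <- simulate_full_sequence(
    n_blocks = design$n_blocks,
    segments_per_block = design$segments_per_block,
    segment_length = design$segment_length,
    omission_rate = design$omission_rate,
    n_burn_in = design$n_burn_in,
    seed = derive_seed(seed, 21))
  fm <- make_forward_model(design$n_channels, seed = derive_seed(seed, 22),
                           max_abs_cor = design$max_abs_cor)
  p <- subject_params(beta = 0.5, evoked_amplitude = design$evoked_amplitude,
                      noise_sd = design$noise_sd,
                      seed = derive_seed(seed, 23))
  rec <- simulate_subject(seqs, fm, p,
                          timing = sequence_timing(design$stimulation_rate),
                          srate = design$srate)
  rec <- resample_recording(bandpass_filter(rec), 100)
  ep <- epoch_recording(rec, seqs)
  train_idx <- select_training_trials(ep$metadata)
  test <- select_test_trials(ep$metadata, seed = derive_seed(seed, 24))
  per <- vapply(seq_len(n_shuffles), function(k) {
    acc <- decode_accuracy(ep, train_idx, c(test$ordered, test$random),
                           shuffle = TRUE, seed = derive_seed(seed, 30 + k))
    mean(acc$accuracy)
  }, numeric(1))
  list(accuracy = mean(per), per_shuffle = per)
}

#' Type-I error calibration of the cluster permutation test
#'
#' Applies the cluster-based sign-flip test to `n_runs` null cohorts
#' (i.i.d. standard Gaussian subject-by-time matrices) and reports the
#' fraction of runs with any cluster p-value below `critical_alpha`.
#'
#' @param n_runs Number of null cohorts (default 400).
#' @param n_subjects Subjects per cohort (default 20).
#' @param n_times Time samples (default 30).
#' @param n_permutations Permutations per test (default 1000).
#' @param seed Integer seed.
#' @return List with `rate`, `significant` (logical per run), `alpha`.
#' @export
study_cluster_type1 <- function(n_runs = 400, n_subjects = 20, n_times = 30,
                                n_permutations = 1000, seed = 1) {
  cfg <- cluster_config(n_permutations = n_permutations)
  sig <- vapply(seq_len(n_runs), function(run) {
    set.seed(derive_seed(seed, 40000 + run))
    x <- matrix(stats::rnorm(n_subjects * n_times), n_subjects, n_times)
    cfg$seed <- derive_seed(seed, 50000 + run)
    res <- cluster_permutation_test(x, cfg)
    any(res$clusters$p < cfg$critical_alpha)
  }, logical(1))
  list(rate = mean(sig), significant = sig, alpha = cfg$critical_alpha)
}
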