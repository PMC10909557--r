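# epoch metadata with the prev/prev2 columns epoch_recording() produces
toy_meta <- function(stim, entropy, omitted = FALSE, burn_in = FALSE) {
  n <- length(stim)
  omitted <- rep_len(omitted, n)
  data.frame(trial = seq_len(n), block = 1L, segment = 1L,
             entropy = rep_len(entropy, n), stimulus = as.integer(stim),
             omitted = omitted, burn_in = rep_len(burn_in, n),
             prev_stimulus = c(NA, stim[-n]),
             prev_omitted = c(NA, omitted[-n]),
             prev2_stimulus = if (n >= 2) c(NA, NA, stim[seq_len(n - 2)])
                              else NA,
             prev2_omitted = if (n >= 2) c(NA, NA, omitted[seq_len(n - 2)])
                             else NA)
}

# bare continuous recording around a data matrix
toy_recording <- function(data, srate, events = NULL) {
  if (is.null(events)) {
    events <- data.frame(trial = 1L, sample = 1L, time = 0,
                         stimulus = 1L, omitted = FALSE)
  }
  structure(list(data = data, srate = srate, events = events),
            class = "sensor_recording")
}

# one small decodable subject, preprocessed to 100 Hz epochs (memoised)
.sim_cache <- new.env(parent = emptyenv())
small_epochs <- function() {
  if (is.null(.sim_cache$ep)) {
    s <- simulate_full_sequence(n_blocks = 1, segments_per_block = 4,
                                segment_length = 150, n_burn_in = 10,
                                seed = 31)
    fm <- make_forward_model(8, seed = 32)
    p <- subject_params(beta = 0.6, noise_sd = 1, seed = 33)
    rec <- simulate_subject(s, fm, p, srate = 150)
    rec <- resample_recording(bandpass_filter(rec), 100)
    .sim_cache$ep <- epoch_recording(rec, s)
    .sim_cache$seq <- s
    .sim_cache$fm <- fm
  }
  .sim_cache$ep
}

# full single-subject pipeline used by reliability tests
pipeline_subject <- function(design, beta, seed, lambda = "auto") {
  s <- simulate_full_sequence(n_blocks = design$n_blocks,
                              segments_per_block = design$segments_per_block,
                              segment_length = design$segment_length,
                              omission_rate = design$omission_rate,
                              n_burn_in = design$n_burn_in,
                              seed = derive_seed(seed, 1))
  fm <- make_forward_model(design$n_channels, seed = derive_seed(seed, 2),
                           max_abs_cor = design$max_abs_cor)
  p <- subject_params(beta = beta,
                      evoked_amplitude = design$evoked_amplitude,
                      noise_sd = design$noise_sd,
                      seed = derive_seed(seed, 3))
  rec <- simulate_subject(s, fm, p, srate = design$srate)
  rec <- resample_recording(bandpass_filter(rec), 100)
  ep <- epoch_recording(rec, s)
  decode_subject(ep, lambda = lambda, seed = derive_seed(seed, 4))
}
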