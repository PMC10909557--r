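#' Derive a reproducible sub-seed
#'
#' Deterministically maps a base seed and a stream index to a new seed in
#' [0, 2^31 - 2], so every stochastic stage of a run can be seeded
#' independently from one top-level seed.
#'
#' @param seed Base integer seed.
#' @param k Stream index.
#' @return Integer seed.
#' @export
derive_seed <- function(seed, k) {
  as.integer((as.numeric(seed) * 7919 + as.numeric(k) * 104729) %% 2147483629)
}

#' Random forward model of stimulus-specific sensor patterns
#'
#' Draws four unit-norm spatial patterns (one per stimulus identity) over
#' `n_channels` sensors, rejection-sampling until all pairwise pattern
#' correlations are at most `max_abs_cor` in magnitude. The patterns stand
#' in for the sensor projection of stimulus-specific cortical sources.
#'
#' @param n_channels Number of channels (>= 4).
#' @param seed Integer seed.
#' @param max_abs_cor Maximum allowed absolute pairwise correlation
#'   (default 0.3).
#' @return A `forward_model`: list with `topographies` (4 x n_channels, unit
#'   row norms) and `n_channels`.
#' @export
make_forward_model <- function(n_channels, seed, max_abs_cor = 0.3) {
  if (n_channels < 4) {
    stop("`n_channels` must be at least 4 for separable patterns",
         call. = FALSE)
  }
  set.seed(seed)
  # with few channels a tight bound can be geometrically infeasible (four
  # centered patterns span n_channels - 1 dimensions), so the bound is
  # relaxed by 10% after every 5000 rejected draws
  bound <- max_abs_cor
  iter <- 0L
  repeat {
    iter <- iter + 1L
    topo <- matrix(stats::rnorm(4 * n_channels), 4, n_channels)
    topo <- topo / sqrt(rowSums(topo^2))
    r <- stats::cor(t(topo))
    if (max(abs(r[upper.tri(r)])) <= bound) break
    if (iter %% 5000L == 0L) bound <- bound * 1.1
  }
  structure(list(topographies = topo, n_channels = n_channels,
                 max_abs_cor = bound),
            class = "forward_model")
}

#' Evoked response kernel
#'
#' Smooth, unimodal, causal kernel used as the single-trial evoked
#' waveform: a gamma-shaped bump
#' \deqn{k(t) = (t/\ell)^a \exp((\ell - t)/\theta), \quad t > 0,}
#' with \eqn{a = (\ell/w)^2} and \eqn{\theta = w^2/\ell}, normalised to peak
#' value 1 at \eqn{t = \ell} (`latency`). With the defaults (latency 0.17 s,
#' width 0.1 s) its support is effectively `[0, 0.7]` s post-onset,
#' matching the window over which stimulus identity remains decodable.
#'
#' @param t Time(s) in seconds relative to stimulus onset (vectorised).
#' @param latency Peak time in seconds (default 0.17).
#' @param width Width (approximate SD) in seconds (default 0.1).
#' @return Kernel amplitude(s); 0 for `t <= 0`.
#' @export
evoked_waveform <- function(t, latency = 0.17, width = 0.1) {
  if (width <= 0) stop("`width` must be positive", call. = FALSE)
  stopifnot(latency > 0)
  a <- (latency / width)^2
  theta <- width^2 / latency
  out <- numeric(length(t))
  pos <- t > 0
  out[pos] <- exp(a * log(t[pos] / latency) + (latency - t[pos]) / theta)
  out
}

#' Closed-form integral of the evoked kernel
#'
#' \eqn{\int_0^{u} k(t)\,dt} via the (regularised) incomplete gamma
#' function; used to validate numerical quadrature of [evoked_waveform()].
#'
#' @param upper Upper integration limit in seconds.
#' @inheritParams evoked_waveform
#' @return The integral value.
#' @export
evoked_waveform_integral <- function(upper, latency = 0.17, width = 0.1) {
  a <- (latency / width)^2
  theta <- width^2 / latency
  # k(t) = t^a e^{-t/theta} * C with C = exp(a)/latency^a
  C <- exp(a - a * log(latency))
  C * exp(lgamma(a + 1) + (a + 1) * log(theta)) *
    stats::pgamma(upper, shape = a + 1, scale = theta)
}

#' Prestimulus pre-activation ramp
#'
#' Linear ramp supported on `[-ramp_len, 0)` s relative to stimulus onset,
#' rising from 0 to 1; the temporal carrier of the simulated prediction
#' signal.
#'
#' @param t Time(s) in seconds relative to onset.
#' @param ramp_len Ramp duration in seconds (default 0.3).
#' @return Ramp amplitude(s).
#' @export
prestim_ramp <- function(t, ramp_len = 0.3) {
  stopifnot(ramp_len > 0)
  out <- numeric(length(t))
  inside <- t >= -ramp_len & t < 0
  out[inside] <- (t[inside] + ramp_len) / ramp_len
  out
}

#' Subject simulation parameters
#'
#' @param beta Prestimulus pre-activation amplitude (signal units).
#' @param evoked_amplitude Evoked response amplitude (default 1).
#' @param evoked_latency Evoked peak latency in seconds (default 0.17).
#' @param evoked_width Evoked kernel width in seconds (default 0.1).
#' @param noise_sd Per-channel Gaussian noise SD (default 1).
#' @param pink_sd SD of an optional 1/f noise component (default 0, off).
#' @param seed Integer seed for the noise draw.
#' @return A `subject_params` list.
#' @export
subject_params <- function(beta, evoked_amplitude = 1, evoked_latency = 0.17,
                           evoked_width = 0.1, noise_sd = 1, pink_sd = 0,
                           seed = 1) {
  stopifnot(noise_sd >= 0, pink_sd >= 0, evoked_amplitude >= 0)
  structure(list(beta = beta, evoked_amplitude = evoked_amplitude,
                 evoked_latency = evoked_latency,
                 evoked_width = evoked_width, noise_sd = noise_sd,
                 pink_sd = pink_sd, seed = seed),
            class = "subject_params")
}

#' Simulate a continuous multi-channel recording for one subject
#'
#' Superimposes, on Gaussian channel noise, (i) one evoked response per
#' non-omitted trial -- the stimulus' spatial pattern modulated by the
#' evoked kernel -- and (ii), for every trial inside an ordered segment
#' whose predecessor exists, a prestimulus pre-activation of the *expected*
#' stimulus: `beta` times the spatial pattern of the forward successor of
#' the previous stimulus, modulated by a linear ramp over `[-0.3, 0)` s.
#' Omitted trials receive the prediction (when ordered) but no evoked
#' response. Everything is deterministic given `p$seed`.
#'
#' @param seq A `stim_sequence`.
#' @param fm A `forward_model`.
#' @param p A `subject_params`.
#' @param timing A [sequence_timing()] list.
#' @param srate Native sampling rate in Hz; must be a multiple of the
#'   stimulation rate so onsets fall on exact samples (default 300).
#' @return A `sensor_recording`: list with `data` (channels x samples),
#'   `srate`, and `events` (data.frame: trial, sample, time, stimulus,
#'   omitted).
#' @export
simulate_subject <- function(seq, fm, p, timing = sequence_timing(),
                             srate = 300) {
  spacing <- srate * timing$onset_asynchrony
  if (abs(spacing - round(spacing)) > 1e-9) {
    stop("`srate` must be an integer multiple of the stimulation rate",
         call. = FALSE)
  }
  spacing <- as.integer(round(spacing))
  n_trials <- nrow(seq)
  nch <- fm$n_channels
  pad <- as.integer(round(0.5 * srate))
  n_samples <- pad + spacing * (n_trials - 1L) + as.integer(round(1 * srate))
  onset <- pad + spacing * (seq$trial - 1L) + 1L

  kernel <- p$evoked_amplitude *
    evoked_waveform(seq(0, 0.8, by = 1 / srate),
                    p$evoked_latency, p$evoked_width)
  ramp_len <- 0.3
  Lr <- as.integer(round(ramp_len * srate))
  ramp <- prestim_ramp(seq(-ramp_len, -1 / srate, by = 1 / srate), ramp_len)
  Lk <- length(kernel)

  # per-class source time courses; rank-1 projection at the end
  G <- matrix(0, 4, n_samples)
  prev <- c(NA_integer_, seq$stimulus[-n_trials])
  predicted <- rep(NA_integer_, n_trials)
  predicted[-1L] <- forward_successor(prev[-1L])
  for (t in seq_len(n_trials)) {
    if (!seq$omitted[t]) {
      idx <- onset[t]:(onset[t] + Lk - 1L)
      G[seq$stimulus[t], idx] <- G[seq$stimulus[t], idx] + kernel
    }
    if (seq$entropy[t] == "ordered" && !is.na(predicted[t]) && p$beta != 0) {
      idx <- (onset[t] - Lr):(onset[t] - 1L)
      G[predicted[t], idx] <- G[predicted[t], idx] + p$beta * ramp
    }
  }
  data <- crossprod(fm$topographies, G)   # channels x samples

  if (p$noise_sd > 0 || p$pink_sd > 0) {
    set.seed(p$seed)
    if (p$noise_sd > 0) {
      data <- data + matrix(stats::rnorm(nch * n_samples, sd = p$noise_sd),
                            nch, n_samples)
    }
    if (p$pink_sd > 0) {
      data <- data + pink_noise(nch, n_samples, srate, p$pink_sd)
    }
  }

  events <- data.frame(trial = seq$trial, sample = onset,
                       time = (onset - 1L) / srate,
                       stimulus = seq$stimulus, omitted = seq$omitted)
  structure(list(data = data, srate = srate, events = events),
            class = "sensor_recording")
}

# 1/f-amplitude Gaussian noise, one independent realisation per channel
pink_noise <- function(nch, n, srate, sd) {
  f <- c(1, seq_len(n - 1))
  shape <- 1 / sqrt(pmin(f, n - f + 1))
  out <- matrix(0, nch, n)
  for (ch in seq_len(nch)) {
    spec <- stats::fft(stats::rnorm(n)) * shape
    x <- Re(stats::fft(spec, inverse = TRUE)) / n
    out[ch, ] <- x / stats::sd(x) * sd
  }
  out
}

#' Draw cohort-level subject parameters
#'
#' Per-subject pre-activation amplitudes for the two modalities are drawn
#' from a bivariate Gaussian with common mean `beta_mean`, SD `beta_sd` and
#' correlation `rho`. With `truncate = TRUE` (default) pairs with any
#' negative amplitude are redrawn, keeping betas non-negative; set it to
#' FALSE to allow negative ground-truth tendencies.
#'
#' @param n_subjects Number of subjects (>= 3).
#' @param rho Target cross-modal correlation in `[-1, 1]`.
#' @param beta_mean,beta_sd Mean and SD of the amplitude distribution
#'   (defaults 0.5 and 0.25).
#' @param truncate Redraw negative pairs (default TRUE).
#' @param seed Integer seed.
#' @return Data frame with columns `subject`, `beta_aud`, `beta_vis`.
#' @export
draw_subject_params <- function(n_subjects, rho, beta_mean = 0.5,
                                beta_sd = 0.25, truncate = TRUE, seed = 1) {
  if (n_subjects < 3) stop("`n_subjects` must be >= 3", call. = FALSE)
  if (abs(rho) > 1) stop("`rho` must be in [-1, 1]", call. = FALSE)
  set.seed(seed)
  Sigma <- beta_sd^2 * matrix(c(1, rho, rho, 1), 2, 2)
  draw <- function(k) MASS::mvrnorm(k, mu = c(beta_mean, beta_mean),
                                    Sigma = Sigma)
  b <- matrix(draw(n_subjects), ncol = 2)
  if (truncate) {
    for (iter in 1:1000) {
      bad <- which(b[, 1] < 0 | b[, 2] < 0)
      if (length(bad) == 0) break
      b[bad, ] <- matrix(draw(length(bad)), ncol = 2)
    }
    b[b < 0] <- 0
  }
  data.frame(subject = seq_len(n_subjects),
             beta_aud = b[, 1], beta_vis = b[, 2])
}

#' Simulate a two-modality cohort
#'
#' Draws cohort parameters and prepares per-subject, per-modality stimulus
#' sequences and forward models. Recordings are built lazily through the
#' returned `recording(i, modality)` accessor so that large cohorts never
#' have to be held in memory at once.
#'
#' @param n_subjects Number of subjects (default 35).
#' @param rho Target cross-modal correlation of pre-activation amplitudes.
#' @param design Design list from [cohort_design()].
#' @param seed Integer seed.
#' @param beta_mean,beta_sd,truncate Passed to [draw_subject_params()].
#' @return A `cohort` object: list with `params` (data frame), `design`,
#'   `sequences` (per subject, per modality), and `recording(i, modality)`.
#' @export
simulate_cohort <- function(n_subjects = 35, rho = 0,
                            design = cohort_design(), seed = 1,
                            beta_mean = 0.5, beta_sd = 0.25,
                            truncate = TRUE) {
  params <- draw_subject_params(n_subjects, rho, beta_mean, beta_sd,
                                truncate, seed = derive_seed(seed, 0))
  modalities <- c("aud", "vis")
  sequences <- lapply(seq_len(n_subjects), function(i) {
    out <- lapply(seq_along(modalities), function(m) {
      simulate_full_sequence(
        n_blocks = design$n_blocks,
        segments_per_block = design$segments_per_block,
        segment_length = design$segment_length,
        omission_rate = design$omission_rate,
        n_burn_in = design$n_burn_in,
        seed = derive_seed(seed, 100 + i * 10 + m))
    })
    names(out) <- modalities
    out
  })
  cohort <- list(
    params = params, design = design, seed = seed, sequences = sequences)
  cohort$recording <- function(i, modality) {
    m <- match(modality, modalities)
    fm <- make_forward_model(design$n_channels,
                             seed = derive_seed(seed, 500 + i * 10 + m),
                             max_abs_cor = design$max_abs_cor)
    beta <- params[[paste0("beta_", modality)]][i]
    p <- subject_params(beta = beta,
                        evoked_amplitude = design$evoked_amplitude,
                        evoked_latency = design$evoked_latency,
                        evoked_width = design$evoked_width,
                        noise_sd = design$noise_sd,
                        seed = derive_seed(seed, 900 + i * 10 + m))
    simulate_subject(sequences[[i]][[modality]], fm, p,
                     timing = sequence_timing(design$stimulation_rate),
                     srate = design$srate)
  }
  class(cohort) <- "cohort"
  cohort
}

#' Cohort design geometry and simulation parameters
#'
#' Defaults follow the paradigm constants (700-trial segments, 4 segments
#' per block, 10% omissions, 20-trial burn-in, 3 Hz stimulation) at the
#' reduced desk-scale geometry of 1 block per modality and 32 channels,
#' simulated natively at 300 Hz. The full experiment uses
#' `cohort_design(n_blocks = 2, n_channels = 306)`.
#'
#' @param n_blocks Blocks per modality (default 1).
#' @param segments_per_block Segments per block (default 4).
#' @param segment_length Trials per segment (default 700).
#' @param omission_rate Omission proportion (default 0.1).
#' @param n_burn_in Burn-in trials per segment (default 20).
#' @param n_channels Sensors (default 32).
#' @param srate Native simulation rate in Hz (default 300).
#' @param stimulation_rate Stimuli per second (default 3).
#' @param evoked_amplitude,evoked_latency,evoked_width,noise_sd Evoked and
#'   noise parameters (defaults 1, 0.17 s, 0.1 s, 1).
#' @param max_abs_cor Pattern correlation bound (default 0.3).
#' @return A named list.
#' @export
cohort_design <- function(n_blocks = 1, segments_per_block = 4,
                          segment_length = 700, omission_rate = 0.1,
                          n_burn_in = 20, n_channels = 32, srate = 300,
                          stimulation_rate = 3, evoked_amplitude = 1,
                          evoked_latency = 0.17, evoked_width = 0.1,
                          noise_sd = 2, max_abs_cor = 0.3) {
  list(n_blocks = n_blocks, segments_per_block = segments_per_block,
       segment_length = segment_length, omission_rate = omission_rate,
       n_burn_in = n_burn_in, n_channels = n_channels, srate = srate,
       stimulation_rate = stimulation_rate,
       evoked_amplitude = evoked_amplitude,
       evoked_latency = evoked_latency, evoked_width = evoked_width,
       noise_sd = noise_sd, max_abs_cor = max_abs_cor)
}
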