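#' Transition matrix for an entropy regime
#'
#' Builds the 4x4 row-stochastic matrix of next-stimulus probabilities for
#' one of the two entropy regimes of the paradigm. In the \code{"ordered"}
#' (low-entropy) regime the cyclic forward transition (1-2, 2-3, 3-4, 4-1)
#' has probability 0.75 and a self-repetition 0.25; all other transitions
#' are impossible. In the \code{"random"} (high-entropy) regime every
#' transition has probability 0.25.
#'
#' @param entropy `"ordered"` or `"random"`.
#' @return An object of class `transition_model`: a list with elements
#'   `entropy` and `probs` (4x4 matrix, rows = current stimulus, columns =
#'   next stimulus, each row summing to 1).
#' @examples
#' build_transition_matrix("ordered")$probs
#' @export
build_transition_matrix <- function(entropy) {
  if (!is.character(entropy) || length(entropy) != 1 ||
      !entropy %in% c("ordered", "random")) {
    stop("`entropy` must be \"ordered\" or \"random\"", call. = FALSE)
  }
  probs <- matrix(0, 4, 4, dimnames = list(current = 1:4, nxt = 1:4))
  if (entropy == "ordered") {
    for (s in 1:4) {
      probs[s, forward_successor(s)] <- 0.75
      probs[s, s] <- 0.25
    }
  } else {
    probs[] <- 0.25
  }
  structure(list(entropy = entropy, probs = probs),
            class = "transition_model")
}

#' Cyclic forward successor of a stimulus
#'
#' The "forward" mapping of the four stimulus identities: 1-2, 2-3, 3-4,
#' 4-1.
#'
#' @param s Vector of stimulus ids in 1..4.
#' @return Successor id(s), same length as `s`.
#' @export
forward_successor <- function(s) {
  if (length(s) == 0 || anyNA(s) || !all(s %in% 1:4)) {
    stop("stimulus ids must be in 1..4", call. = FALSE)
  }
  (s %% 4L) + 1L
}

#' Classify the transition between two consecutive stimuli
#'
#' Labels the pair (previous, current) as `forward` (current is the cyclic
#' successor of previous), `repetition` (equal), `backward` (previous is the
#' successor of current) or `other`. Exactly one label applies to each of
#' the 16 pairs.
#'
#' @param prev,curr Stimulus ids in 1..4 (vectorised, recycled to common
#'   length).
#' @return Character vector of transition labels.
#' @export
classify_transition <- function(prev, curr) {
  if (!all(prev %in% 1:4) || !all(curr %in% 1:4)) {
    stop("stimulus ids must be in 1..4", call. = FALSE)
  }
  n <- max(length(prev), length(curr))
  prev <- rep_len(as.integer(prev), n)
  curr <- rep_len(as.integer(curr), n)
  out <- rep("other", n)
  out[curr == prev] <- "repetition"
  out[curr == forward_successor(prev)] <- "forward"
  out[prev == forward_successor(curr) & curr != prev] <- "backward"
  out
}

#' Balanced pseudorandom entropy schedule
#'
#' Assigns entropy labels to the segments of each block: within every block
#' half the segments are `ordered` and half `random`, in a seeded random
#' order (the regime changes "pseudorandomly" from segment to segment but
#' balance is enforced per block).
#'
#' @param n_blocks Number of blocks.
#' @param segments_per_block Segments per block; must be even.
#' @param seed Integer seed.
#' @return Character vector of length `n_blocks * segments_per_block`.
#' @export
generate_entropy_schedule <- function(n_blocks, segments_per_block, seed) {
  if (segments_per_block %% 2 != 0) {
    stop("`segments_per_block` must be even to balance entropy labels",
         call. = FALSE)
  }
  stopifnot(n_blocks >= 1)
  pool <- rep(c("ordered", "random"), each = segments_per_block / 2)
  set.seed(seed)
  unlist(lapply(seq_len(n_blocks), function(b) sample(pool)))
}

#' Generate a stimulus sequence from an entropy schedule
#'
#' Draws a first-order Markov sequence of stimulus ids 1..4. Each trial's
#' stimulus is drawn from the transition row of the active segment's
#' entropy regime, conditioned on the previous trial's stimulus. The chain
#' continues across segment boundaries (no restart at an entropy change);
#' the very first trial of the experiment is uniform over 1..4.
#'
#' @param schedule Character vector of per-segment entropy labels, e.g. from
#'   [generate_entropy_schedule()].
#' @param segment_length Trials per segment.
#' @param seed Integer seed.
#' @param segments_per_block Used only to assign block indices; defaults to
#'   all segments in one block when it does not divide the schedule.
#' @return A `stim_sequence`: a data.frame with columns `trial`, `block`,
#'   `segment`, `entropy`, `stimulus`, `omitted`, `burn_in`.
#' @export
generate_sequence <- function(schedule, segment_length, seed,
                              segments_per_block = length(schedule)) {
  if (length(schedule) == 0) stop("empty schedule", call. = FALSE)
  stopifnot(segment_length >= 1,
            all(schedule %in% c("ordered", "random")))
  models <- list(ordered = build_transition_matrix("ordered")$probs,
                 random  = build_transition_matrix("random")$probs)
  n_seg <- length(schedule)
  n <- n_seg * segment_length
  entropy <- rep(schedule, each = segment_length)
  segment <- rep(seq_len(n_seg), each = segment_length)
  block <- (segment - 1L) %/% segments_per_block + 1L
  set.seed(seed)
  stimulus <- integer(n)
  stimulus[1] <- sample.int(4L, 1L)
  # pre-draw uniforms; inverse-CDF step keeps the loop cheap
  u <- stats::runif(n)
  for (t in 2:n) {
    p <- models[[entropy[t]]][stimulus[t - 1L], ]
    stimulus[t] <- findInterval(u[t], cumsum(p), left.open = TRUE) + 1L
  }
  out <- data.frame(trial = seq_len(n), block = block, segment = segment,
                    entropy = entropy, stimulus = stimulus,
                    omitted = FALSE, burn_in = FALSE,
                    stringsAsFactors = FALSE)
  class(out) <- c("stim_sequence", "data.frame")
  out
}

#' Flag omission trials by exact stratified sampling
#'
#' Within each (stimulus x entropy) stratum, exactly
#' `round(rate * stratum size)` trials are flagged as omitted, at seeded
#' pseudorandom positions. Stimulus ids of omitted trials are retained for
#' bookkeeping; the simulator generates no evoked response for them.
#'
#' @param seq A `stim_sequence`.
#' @param rate Omission proportion in `[0, 1)`.
#' @param seed Integer seed.
#' @return The sequence with its `omitted` column set.
#' @export
apply_omissions <- function(seq, rate, seed) {
  if (!is.numeric(rate) || rate < 0 || rate >= 1) {
    stop("`rate` must be in [0, 1)", call. = FALSE)
  }
  seq$omitted <- FALSE
  if (rate == 0) return(seq)
  set.seed(seed)
  for (s in 1:4) {
    for (e in c("ordered", "random")) {
      idx <- which(seq$stimulus == s & seq$entropy == e)
      k <- round(rate * length(idx))
      if (k > 0) seq$omitted[sample(idx, k)] <- TRUE
    }
  }
  seq
}

#' Flag burn-in trials after each entropy onset
#'
#' Marks the first `n_exclude` trials of every segment. These trials are
#' excluded from decoding because an ideal observer needs roughly that many
#' trials to infer the new transition regime (see [ideal_observer()]).
#'
#' @param seq A `stim_sequence`.
#' @param n_exclude Trials to exclude per segment (default 20).
#' @return The sequence with its `burn_in` column set.
#' @export
mark_burn_in <- function(seq, n_exclude = 20) {
  seg_len <- min(table(seq$segment))
  if (n_exclude >= seg_len) {
    stop("`n_exclude` must be smaller than the segment length",
         call. = FALSE)
  }
  seq$burn_in <- stats::ave(seq$trial, seq$segment,
                            FUN = seq_along) <= n_exclude
  seq
}

#' Dirichlet-multinomial ideal observer of the transition structure
#'
#' A count-based learner that tracks, for each current stimulus, a symmetric
#' Dirichlet posterior over the next stimulus, and reports the posterior
#' predictive probability of the cyclic forward successor before each trial
#' is observed. The first trial at which that probability exceeds 0.5 is the
#' convergence trial; its typical magnitude in an ordered (75/25) segment
#' motivates the 20-trial burn-in exclusion.
#'
#' This is a deliberately simple rational-learner device (not a hierarchical
#' filter): one Dirichlet(\eqn{\alpha}) per conditioning stimulus, updated
#' by observed transition counts.
#'
#' @param seq A `stim_sequence` (typically a single ordered segment).
#' @param prior_strength Symmetric Dirichlet pseudo-count \eqn{\alpha}
#'   (default 1).
#' @return A list with `predictive` (per-trial posterior predictive
#'   probability of the forward successor, NA for trial 1) and
#'   `convergence_trial` (first trial index with predictive > 0.5, NA if
#'   never reached).
#' @export
ideal_observer <- function(seq, prior_strength = 1) {
  stim <- if (is.data.frame(seq)) seq$stimulus else as.integer(seq)
  n <- length(stim)
  if (n == 0) stop("empty sequence", call. = FALSE)
  stopifnot(prior_strength > 0)
  counts <- matrix(0, 4, 4)
  predictive <- rep(NA_real_, n)
  for (t in 2:n) {
    prev <- stim[t - 1L]
    fwd <- forward_successor(prev)
    predictive[t] <- (counts[prev, fwd] + prior_strength) /
      (sum(counts[prev, ]) + 4 * prior_strength)
    counts[prev, stim[t]] <- counts[prev, stim[t]] + 1
  }
  conv <- which(predictive > 0.5)[1]
  list(predictive = predictive,
       convergence_trial = if (length(conv) && !is.na(conv)) conv else NA_integer_)
}

#' Timing constants of the stimulation paradigm
#'
#' @param stimulation_rate Stimuli per second (default 3 Hz).
#' @param stimulus_duration Stimulus duration in seconds (default 0.1).
#' @return A list with `stimulation_rate`, `stimulus_duration` and
#'   `onset_asynchrony` (= 1/rate).
#' @export
sequence_timing <- function(stimulation_rate = 3, stimulus_duration = 0.1) {
  stopifnot(stimulation_rate > 0, stimulus_duration > 0,
            stimulus_duration <= 1 / stimulation_rate)
  list(stimulation_rate = stimulation_rate,
       stimulus_duration = stimulus_duration,
       onset_asynchrony = 1 / stimulation_rate)
}

#' Write / read a stimulus sequence as TSV
#'
#' One row per trial with columns trial, block, segment, entropy, stimulus,
#' omitted, burn_in.
#'
#' @param seq A `stim_sequence`.
#' @param path File path.
#' @return `write_sequence_tsv` returns `path` invisibly;
#'   `read_sequence_tsv` returns a `stim_sequence`.
#' @export
write_sequence_tsv <- function(seq, path) {
  utils::write.table(as.data.frame(seq), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_sequence_tsv
#' @export
read_sequence_tsv <- function(path) {
  out <- utils::read.delim(path, stringsAsFactors = FALSE)
  out$omitted <- as.logical(out$omitted)
  out$burn_in <- as.logical(out$burn_in)
  class(out) <- c("stim_sequence", "data.frame")
  out
}

#' Build the full experimental sequence for one modality
#'
#' Convenience wrapper composing schedule generation, Markov sampling,
#' omission flagging and burn-in marking with the paradigm defaults
#' (2 blocks of 4 segments x 700 trials, 10% omissions, 20-trial burn-in).
#'
#' @param n_blocks Blocks per modality (default 2).
#' @param segments_per_block Segments per block (default 4).
#' @param segment_length Trials per segment (default 700).
#' @param omission_rate Proportion of omitted trials (default 0.1).
#' @param n_burn_in Burn-in trials per segment (default 20).
#' @param seed Integer seed.
#' @return A `stim_sequence`.
#' @export
simulate_full_sequence <- function(n_blocks = 2, segments_per_block = 4,
                                   segment_length = 700,
                                   omission_rate = 0.1, n_burn_in = 20,
                                   seed = 1) {
  sched <- generate_entropy_schedule(n_blocks, segments_per_block, seed)
  s <- generate_sequence(sched, segment_length, seed = seed + 1L,
                         segments_per_block = segments_per_block)
  s <- apply_omissions(s, omission_rate, seed = seed + 2L)
  mark_burn_in(s, n_burn_in)
}
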