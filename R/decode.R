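#' Select classifier training trials
#'
#' Training uses exclusively ordered forward trials: trials inside an
#' ordered segment whose transition from the previous trial is `forward`,
#' with both the trial and its predecessor presented (non-omitted) and the
#' trial outside the burn-in window.
#'
#' @param meta Epoch metadata (from [epoch_recording()]).
#' @return Integer vector of epoch row indices.
#' @export
select_training_trials <- function(meta) {
  ok <- !is.na(meta$prev_stimulus)
  trans <- rep(NA_character_, nrow(meta))
  trans[ok] <- classify_transition(meta$prev_stimulus[ok], meta$stimulus[ok])
  idx <- which(ok & meta$entropy == "ordered" & trans == "forward" &
                 !meta$omitted & !meta$prev_omitted & !meta$burn_in)
  if (length(idx) == 0) {
    stop(sprintf(paste0(
      "no training trials: %d ordered, %d forward, %d non-omitted, ",
      "%d non-burn-in"),
      sum(meta$entropy == "ordered"), sum(trans == "forward", na.rm = TRUE),
      sum(!meta$omitted), sum(!meta$burn_in)), call. = FALSE)
  }
  idx
}

#' Select matched test trials
#'
#' Test trials are self-repetitions preceded by a forward transition: the
#' stimulus at t equals t-1 (repetition) and t-1 is the forward successor
#' of t-2, with t, t-1 and t-2 all presented and t outside burn-in. This
#' fixes the full two-trial stimulus history of every test trial given its
#' identity, so matching the two entropy conditions on stimulus identity
#' equates the preceding bottom-up input exactly. Within each stimulus
#' stratum the larger condition is randomly subselected (seeded) to the
#' smaller one's size.
#'
#' @param meta Epoch metadata.
#' @param seed Integer seed for the subselection.
#' @return List with integer index vectors `ordered` and `random` of equal
#'   length, and `counts` (per-condition totals before matching).
#' @export
select_test_trials <- function(meta, seed = 1) {
  ok <- !is.na(meta$prev2_stimulus)
  t1 <- rep(NA_character_, nrow(meta))
  t2 <- t1
  t1[ok] <- classify_transition(meta$prev_stimulus[ok], meta$stimulus[ok])
  t2[ok] <- classify_transition(meta$prev2_stimulus[ok],
                                meta$prev_stimulus[ok])
  qual <- ok & t1 == "repetition" & t2 == "forward" &
    !meta$omitted & !meta$prev_omitted & !meta$prev2_omitted & !meta$burn_in
  qual[is.na(qual)] <- FALSE
  sel <- list(ordered = which(qual & meta$entropy == "ordered"),
              random = which(qual & meta$entropy == "random"))
  if (any(lengths(sel) == 0)) {
    stop(sprintf("empty test condition (ordered: %d, random: %d)",
                 length(sel$ordered), length(sel$random)), call. = FALSE)
  }
  counts <- lengths(sel)
  set.seed(seed)
  out <- list(ordered = integer(0), random = integer(0))
  for (s in 1:4) {
    io <- sel$ordered[meta$stimulus[sel$ordered] == s]
    ir <- sel$random[meta$stimulus[sel$random] == s]
    k <- min(length(io), length(ir))
    if (k == 0) next
    if (length(io) > k) io <- sample(io, k)
    if (length(ir) > k) ir <- sample(ir, k)
    out$ordered <- c(out$ordered, io)
    out$random <- c(out$random, ir)
  }
  if (any(lengths(out) == 0)) {
    stop("no stimulus stratum present in both conditions", call. = FALSE)
  }
  out$counts <- counts
  out
}

# 2-D (trials x channels) slice of the epoch array at one time sample
epoch_slice <- function(data, idx, t) {
  matrix(data[idx, , t], nrow = length(idx), ncol = dim(data)[2])
}

#' Train a multiclass shrinkage LDA
#'
#' Fits class-wise linear discriminant functions from class means and a
#' pooled within-class covariance shrunk toward a scaled identity,
#' \eqn{S_\lambda = (1-\lambda) S + \lambda \nu I} with
#' \eqn{\nu = \mathrm{tr}(S)/p}. The shrinkage intensity \eqn{\lambda} is
#' estimated analytically (Ledoit-Wolf) by default. Decision values for a
#' feature vector x are \eqn{d_c = w_c^\top x + b_c} with
#' \eqn{w_c = S_\lambda^{-1} m_c} and
#' \eqn{b_c = -\tfrac12 m_c^\top S_\lambda^{-1} m_c} (equal priors).
#'
#' @param X Trials x channels matrix.
#' @param labels Class labels (stimulus ids).
#' @param lambda `"auto"` for analytic shrinkage or a fixed value in
#'   `[0, 1]`.
#' @return A `lda_model`: list with `W` (channels x classes), `b`,
#'   `classes`, `lambda`.
#' @export
train_lda <- function(X, labels, lambda = "auto") {
  X <- as.matrix(X)
  classes <- sort(unique(labels))
  if (length(classes) < 2) stop("need at least 2 classes", call. = FALSE)
  if (min(table(labels)) < 2) {
    stop("need at least 2 trials per class", call. = FALSE)
  }
  p <- ncol(X)
  n <- nrow(X)
  M <- t(vapply(classes, function(cl) colMeans(X[labels == cl, , drop = FALSE]),
                numeric(p)))
  Xc <- X - M[match(labels, classes), , drop = FALSE]
  S <- crossprod(Xc) / n
  nu <- mean(diag(S))
  if (identical(lambda, "auto")) {
    num <- (sum(rowSums(Xc^2)^2) / n - sum(S^2) * n) / n^2
    den <- sum((S - diag(nu, p))^2)
    lambda <- if (den <= .Machine$double.eps) 1 else max(0, min(1, num / den))
  }
  stopifnot(is.numeric(lambda), lambda >= 0, lambda <= 1)
  Sl <- (1 - lambda) * S + diag(lambda * nu, p)
  W <- tryCatch(solve(Sl, t(M)),
                error = function(e) stop(
                  "singular covariance; use shrinkage (lambda > 0)",
                  call. = FALSE))
  b <- -0.5 * colSums(t(M) * W)
  structure(list(W = W, b = b, classes = classes, lambda = lambda),
            class = "lda_model")
}

#' Decision values of a fitted LDA
#'
#' @param model An `lda_model`.
#' @param X Trials x channels matrix.
#' @return Trials x classes matrix of decision values.
#' @export
lda_dvals <- function(model, X) {
  if (ncol(X) != nrow(model$W)) {
    stop("channel count does not match the fitted model", call. = FALSE)
  }
  sweep(as.matrix(X) %*% model$W, 2, model$b, "+")
}

#' Time-resolved (diagonal) decoding
#'
#' Trains an LDA at every time sample of the decoding window on the
#' training trials and evaluates decision values d1--d4 for the test trials
#' at the same sample.
#'
#' @param epochs A `sensor_epochs`.
#' @param train_idx,test_idx Disjoint epoch row indices.
#' @param window Decoding window in seconds, endpoints inclusive (default
#'   `c(-0.3, 0.3)`; 61 samples at 100 Hz).
#' @param lambda Shrinkage (see [train_lda()]).
#' @return List with `times`, `dvals` (test-trials x 4 x time),
#'   `pred` (test-trials x time predicted class ids), `train_idx`,
#'   `test_idx`, `lambda_used` (per-time vector).
#' @export
time_resolved_decode <- function(epochs, train_idx, test_idx,
                                 window = c(-0.3, 0.3), lambda = "auto") {
  if (length(intersect(train_idx, test_idx)) > 0) {
    stop("training and test trials must be disjoint", call. = FALSE)
  }
  eps <- 1e-9
  ti <- which(epochs$times >= window[1] - eps & epochs$times <= window[2] + eps)
  if (length(ti) == 0) stop("window outside the epoch grid", call. = FALSE)
  labels <- epochs$metadata$stimulus[train_idx]
  nt <- length(test_idx)
  dv <- array(NA_real_, c(nt, 4, length(ti)))
  pred <- matrix(NA_integer_, nt, length(ti))
  lam <- numeric(length(ti))
  for (k in seq_along(ti)) {
    m <- train_lda(epoch_slice(epochs$data, train_idx, ti[k]), labels,
                   lambda)
    d <- lda_dvals(m, epoch_slice(epochs$data, test_idx, ti[k]))
    full <- matrix(NA_real_, nt, 4)
    full[, m$classes] <- d
    dv[, , k] <- full
    pred[, k] <- m$classes[max.col(d, ties.method = "first")]
    lam[k] <- m$lambda
  }
  list(times = epochs$times[ti], dvals = dv, pred = pred,
       train_idx = train_idx, test_idx = test_idx, lambda_used = lam)
}

#' Decoding accuracy of the diagonal decoder
#'
#' Mean proportion of test trials whose highest decision value belongs to
#' the true stimulus, per time sample. With `shuffle = TRUE` the training
#' labels are permuted (seeded) first, yielding the empirical chance level
#' (0.25 for four balanced classes).
#'
#' @inheritParams time_resolved_decode
#' @param shuffle Permute training labels (default FALSE).
#' @param seed Seed for the shuffle.
#' @return List with `times` and `accuracy` (per time sample).
#' @export
decode_accuracy <- function(epochs, train_idx, test_idx,
                            window = c(-0.3, 0.3), lambda = "auto",
                            shuffle = FALSE, seed = 1) {
  ep <- epochs
  if (shuffle) {
    set.seed(seed)
    perm <- sample(length(train_idx))
    ep$metadata$stimulus[train_idx] <- ep$metadata$stimulus[train_idx][perm]
  }
  res <- time_resolved_decode(ep, train_idx, test_idx, window, lambda)
  truth <- epochs$metadata$stimulus[test_idx]
  list(times = res$times,
       accuracy = colMeans(res$pred == truth))
}

#' Relabel decision values as transition evidence
#'
#' For each test trial, the decision value of class c is relabelled by the
#' transition type that c would constitute given the trial's previous
#' stimulus (e.g. with previous stimulus 1, d2 becomes `forward` evidence
#' and d1 `repetition` evidence). The relabelling is a bijection per trial.
#'
#' @param dvals Test-trials x 4 x time array of decision values.
#' @param prev Previous stimulus id per test trial.
#' @return Test-trials x 4 x time array with transition labels
#'   (`forward`, `repetition`, `backward`, `other`) on the second axis.
#' @export
transition_evidence <- function(dvals, prev) {
  if (anyNA(prev)) stop("previous stimulus missing", call. = FALSE)
  if (length(prev) != dim(dvals)[1]) {
    stop("`prev` must have one entry per test trial", call. = FALSE)
  }
  labs <- c("forward", "repetition", "backward", "other")
  out <- array(NA_real_, dim(dvals),
               dimnames = list(NULL, labs, NULL))
  for (i in seq_len(dim(dvals)[1])) {
    tr <- classify_transition(rep(prev[i], 4), 1:4)
    out[i, match(tr, labs), ] <- dvals[i, , ]
  }
  out
}

#' Group evidence into a tendency curve
#'
#' The per-time-point prediction-tendency statistic: mean forward-transition
#' evidence across test trials, ordered minus random. The
#' `"forward_minus_repetition"` contrast subtracts each trial's repetition
#' evidence from its forward evidence before averaging.
#'
#' @param ev_ordered,ev_random Transition-evidence arrays (trials x 4 x
#'   time) for matched ordered and random test trials.
#' @param times Time axis of the evidence arrays.
#' @param contrast `"forward"` (default) or `"forward_minus_repetition"`.
#' @return A `tendency_curve`: list with `times` and `values`.
#' @export
tendency_curve <- function(ev_ordered, ev_random, times,
                           contrast = c("forward",
                                        "forward_minus_repetition")) {
  contrast <- match.arg(contrast)
  if (dim(ev_ordered)[1] == 0 || dim(ev_random)[1] == 0) {
    stop("empty condition", call. = FALSE)
  }
  slc <- function(ev, lab) {
    matrix(ev[, lab, ], nrow = dim(ev)[1], ncol = dim(ev)[3])
  }
  stat <- function(ev) {
    if (contrast == "forward") {
      colMeans(slc(ev, "forward"))
    } else {
      colMeans(slc(ev, "forward") - slc(ev, "repetition"))
    }
  }
  structure(list(times = times, values = stat(ev_ordered) - stat(ev_random),
                 contrast = contrast),
            class = "tendency_curve")
}

#' Prediction tendency score
#'
#' The per-subject, per-modality scalar: the signed sum of the tendency
#' curve over the prestimulus samples (default `[-0.3, 0)` s).
#'
#' @param curve A `tendency_curve`.
#' @param prestim Prestimulus window `c(start, end)`; samples with
#'   `start <= t < end` are summed.
#' @return Scalar score.
#' @export
tendency_score <- function(curve, prestim = c(-0.3, 0)) {
  eps <- 1e-9
  sel <- curve$times >= prestim[1] - eps & curve$times < prestim[2] - eps
  if (!any(sel)) stop("empty prestimulus grid", call. = FALSE)
  sum(curve$values[sel])
}

#' Temporal generalization of the decoder
#'
#' Trains at every sample of `train_window` and tests at every sample of
#' `test_window`, returning train-time x test-time matrices of mean
#' forward-transition evidence and of classification accuracy.
#'
#' @inheritParams time_resolved_decode
#' @param prev Previous stimulus per test trial (for the forward
#'   relabelling).
#' @param train_window,test_window Windows in seconds.
#' @return List with `times_train`, `times_test`, `forward` and `accuracy`
#'   matrices.
#' @export
temporal_generalization <- function(epochs, train_idx, test_idx, prev,
                                    train_window = c(0, 0.3),
                                    test_window = c(-0.3, 0.3),
                                    lambda = "auto") {
  if (length(intersect(train_idx, test_idx)) > 0) {
    stop("training and test trials must be disjoint", call. = FALSE)
  }
  eps <- 1e-9
  tr <- which(epochs$times >= train_window[1] - eps &
                epochs$times <= train_window[2] + eps)
  te <- which(epochs$times >= test_window[1] - eps &
                epochs$times <= test_window[2] + eps)
  if (!length(tr) || !length(te)) {
    stop("window outside the epoch grid", call. = FALSE)
  }
  labels <- epochs$metadata$stimulus[train_idx]
  truth <- epochs$metadata$stimulus[test_idx]
  fwd_class <- forward_successor(prev)
  fmat <- matrix(NA_real_, length(tr), length(te))
  amat <- fmat
  for (a in seq_along(tr)) {
    m <- train_lda(epoch_slice(epochs$data, train_idx, tr[a]), labels,
                   lambda)
    for (b in seq_along(te)) {
      d <- lda_dvals(m, epoch_slice(epochs$data, test_idx, te[b]))
      full <- matrix(NA_real_, length(test_idx), 4)
      full[, m$classes] <- d
      fmat[a, b] <- mean(full[cbind(seq_along(fwd_class), fwd_class)])
      amat[a, b] <- mean(m$classes[max.col(d, ties.method = "first")] == truth)
    }
  }
  list(times_train = epochs$times[tr], times_test = epochs$times[te],
       forward = fmat, accuracy = amat)
}

#' Full decoding pipeline for one subject and modality
#'
#' Composes trial selection, diagonal decoding over the analysis window,
#' the transition-evidence transform, the tendency curve and the summed
#' prestimulus score. Returns the per-trial evidence arrays so reliability
#' analyses can re-split the test trials without re-decoding.
#'
#' @param epochs A `sensor_epochs`.
#' @param window Decoding window (default `c(-0.3, 0.3)` s).
#' @param prestim Prestimulus summation window (default `c(-0.3, 0)` s).
#' @param contrast Curve contrast (see [tendency_curve()]).
#' @param lambda Shrinkage.
#' @param seed Seed for the test-trial subselection.
#' @return A `subject_decoding`: list with `curve`, `score`, `evidence`
#'   (per condition), `test_stimulus` (per condition), `n_test`, `times`,
#'   `seed`.
#' @export
decode_subject <- function(epochs, window = c(-0.3, 0.3),
                           prestim = c(-0.3, 0), contrast = "forward",
                           lambda = "auto", seed = 1) {
  meta <- epochs$metadata
  train_idx <- select_training_trials(meta)
  test <- select_test_trials(meta, seed = seed)
  res <- time_resolved_decode(epochs, train_idx,
                              c(test$ordered, test$random), window, lambda)
  n_o <- length(test$ordered)
  idx_o <- seq_len(n_o)
  idx_r <- n_o + seq_len(length(test$random))
  ev <- transition_evidence(res$dvals,
                            meta$prev_stimulus[c(test$ordered, test$random)])
  ev_o <- ev[idx_o, , , drop = FALSE]
  ev_r <- ev[idx_r, , , drop = FALSE]
  curve <- tendency_curve(ev_o, ev_r, res$times, contrast)
  structure(list(
    curve = curve,
    score = tendency_score(curve, prestim),
    evidence = list(ordered = ev_o, random = ev_r),
    test_stimulus = list(ordered = meta$stimulus[test$ordered],
                         random = meta$stimulus[test$random]),
    n_test = c(ordered = n_o, random = length(test$random)),
    n_train = length(train_idx),
    times = res$times, prestim = prestim, contrast = contrast,
    seed = seed), class = "subject_decoding")
}
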