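test_that("training selection keeps only ordered forward trials", {
  meta <- toy_meta(c(1, 2, 3, 3), "ordered")
  expect_equal(select_training_trials(meta), c(2L, 3L))
  expect_error(select_training_trials(toy_meta(c(1, 2, 3, 4), "random")),
               "no training trials")
  # omitted predecessors disqualify
  meta2 <- toy_meta(c(1, 2, 3, 4), "ordered",
                    omitted = c(FALSE, TRUE, FALSE, FALSE))
  expect_equal(select_training_trials(meta2), 4L)
})

test_that("test selection demands forward-then-repetition histories and
           matches conditions within stimulus strata", {
  meta <- toy_meta(c(1, 2, 2, 1, 2, 2),
                   c(rep("ordered", 3), rep("random", 3)))
  sel <- select_test_trials(meta, seed = 1)
  expect_equal(sel$ordered, 3L)
  expect_equal(sel$random, 6L)
  expect_error(select_test_trials(toy_meta(c(1, 1, 1), "ordered")),
               "empty test condition")

  ep <- small_epochs()
  sel2 <- select_test_trials(ep$metadata, seed = 5)
  expect_equal(length(sel2$ordered), length(sel2$random))
  expect_equal(table(ep$metadata$stimulus[sel2$ordered]),
               table(ep$metadata$stimulus[sel2$random]))
  # matched histories: repetition at t-1, forward at t-2 in both conditions
  for (cond in c("ordered", "random")) {
    m <- ep$metadata[sel2[[cond]], ]
    expect_true(all(m$prev_stimulus == m$stimulus))
    expect_true(all(forward_successor(m$prev2_stimulus) == m$prev_stimulus))
  }
})

test_that("training-set size tracks the analytic expectation", {
  ep <- small_epochs()
  meta <- ep$metadata
  n_eligible <- sum(meta$entropy == "ordered" & !meta$burn_in &
                      !meta$omitted & !meta$prev_omitted &
                      !is.na(meta$prev_stimulus))
  n_train <- length(select_training_trials(meta))
  expect_lt(abs(n_train / n_eligible - 0.75), 0.08)
})

test_that("shrinkage LDA matches the closed-form two-Gaussian discriminant", {
  set.seed(42)
  n <- 200
  Sig <- matrix(c(1, 0.4, 0.4, 0.8), 2)
  X <- rbind(MASS::mvrnorm(n, c(1, 0), Sig), MASS::mvrnorm(n, c(-1, 0.5), Sig))
  y <- rep(1:2, each = n)
  m <- train_lda(X, y, lambda = 0)
  m1 <- colMeans(X[y == 1, ]); m2 <- colMeans(X[y == 2, ])
  Xc <- X - rbind(matrix(m1, n, 2, byrow = TRUE),
                  matrix(m2, n, 2, byrow = TRUE))
  S <- crossprod(Xc) / (2 * n)
  w <- solve(S, m1 - m2)
  b <- -0.5 * (sum(m1 * solve(S, m1)) - sum(m2 * solve(S, m2)))
  d <- lda_dvals(m, X)
  expect_lt(max(abs((d[, 1] - d[, 2]) - (X %*% w + b))), 1e-8)
  # independent reference classifier agrees on every prediction
  ref <- MASS::lda(X, grouping = y)
  expect_equal(max.col(d), as.integer(predict(ref, X)$class))
})

test_that("full shrinkage reduces LDA to nearest-class-mean scoring", {
  set.seed(7)
  X <- matrix(rnorm(120 * 6), 120)
  y <- rep(1:4, each = 30)
  m <- train_lda(X, y, lambda = 1)
  M <- t(vapply(1:4, function(cl) colMeans(X[y == cl, ]), numeric(6)))
  nu <- mean(diag(crossprod(X - M[y, ]) / 120))
  expect_equal(lda_dvals(m, X),
               (X %*% t(M) - rep(0.5 * rowSums(M^2), each = 120)) / nu,
               tolerance = 1e-10, ignore_attr = TRUE)
})

test_that("LDA is equivariant to channel order and scale-stable", {
  set.seed(8)
  X <- matrix(rnorm(80 * 5), 80)
  y <- rep(1:4, each = 20)
  perm <- c(3, 1, 5, 2, 4)
  d1 <- lda_dvals(train_lda(X, y), X)
  d2 <- lda_dvals(train_lda(X[, perm], y), X[, perm])
  expect_equal(d1, d2, tolerance = 1e-10)
  d3 <- lda_dvals(train_lda(3 * X, y), 3 * X)
  expect_equal(max.col(d1), max.col(d3))
})

test_that("singular covariance without shrinkage is rejected", {
  X <- cbind(rnorm(40), 0)                # zero-variance channel
  y <- rep(1:2, each = 20)
  expect_error(train_lda(X, y, lambda = 0), "shrinkage")
  expect_silent(train_lda(X, y, lambda = 0.5))
  expect_error(train_lda(X[1:3, ], c(1, 1, 2)), "2 trials per class")
})

test_that("diagonal decoding covers 61 samples and is test-side
           independent", {
  ep <- small_epochs()
  tr <- select_training_trials(ep$metadata)
  te <- select_test_trials(ep$metadata, seed = 3)
  test_idx <- c(te$ordered, te$random)
  res <- time_resolved_decode(ep, tr, test_idx, window = c(-0.3, 0.3))
  expect_length(res$times, 61)
  expect_equal(res$times[c(1, 61)], c(-0.3, 0.3))
  res_drop <- time_resolved_decode(ep, tr, test_idx[-2], c(-0.3, 0.3))
  expect_equal(res$dvals[3, , ], res_drop$dvals[2, , ])
  expect_error(time_resolved_decode(ep, tr, c(tr[1], test_idx), c(-0.3, 0.3)),
               "disjoint")
  expect_error(time_resolved_decode(ep, tr, test_idx, c(5, 6)), "window")
})

test_that("transition relabelling permutes decision values per trial", {
  dv <- array(seq_len(2 * 4 * 3), c(2, 4, 3))
  ev <- transition_evidence(dv, prev = c(1, 4))
  expect_equal(ev[1, "forward", ], dv[1, 2, ])     # prev 1: d2 is forward
  expect_equal(ev[1, "repetition", ], dv[1, 1, ])
  expect_equal(ev[2, "forward", ], dv[2, 1, ])     # prev 4: d1 is forward
  expect_equal(ev[2, "backward", ], dv[2, 3, ])
  expect_equal(apply(ev, c(1, 3), sum), apply(dv, c(1, 3), sum),
               ignore_attr = TRUE)
  expect_error(transition_evidence(dv, c(1, NA)), "missing")
  expect_error(transition_evidence(dv, 1), "per test trial")
})

test_that("tendency curves vanish under identical evidence and track beta
           monotonically", {
  ev <- array(rnorm(5 * 4 * 7), c(5, 4, 7),
              dimnames = list(NULL,
                              c("forward", "repetition", "backward",
                                "other"), NULL))
  cv <- tendency_curve(ev, ev, times = seq(-0.3, 0.3, length.out = 7))
  expect_equal(cv$values, rep(0, 7))
  cv2 <- tendency_curve(ev, ev, times = seq(-0.3, 0.3, length.out = 7),
                        contrast = "forward_minus_repetition")
  expect_equal(cv2$values, rep(0, 7))

  s <- mark_burn_in(
    generate_sequence(rep(c("ordered", "random"), 2), 150, seed = 51), 10)
  s <- apply_omissions(s, 0.1, seed = 52)
  fm <- make_forward_model(8, seed = 53)
  scores <- vapply(c(0.2, 0.5, 0.8), function(beta) {
    rec <- simulate_subject(s, fm,
                            subject_params(beta, noise_sd = 0, seed = 1),
                            srate = 150)
    ep <- epoch_recording(resample_recording(bandpass_filter(rec), 100), s)
    decode_subject(ep, lambda = 0.05, seed = 54)$score
  }, numeric(1))
  expect_true(all(diff(scores) > 0))
  expect_gt(scores[1], 0)
})

test_that("the tendency score sums the prestimulus curve", {
  times <- seq(-0.3, 0.3, by = 0.01)
  flat <- structure(list(times = times, values = rep(0.2, length(times)),
                         contrast = "forward"), class = "tendency_curve")
  expect_equal(tendency_score(flat), 30 * 0.2)
  zero <- structure(list(times = times, values = numeric(length(times)),
                         contrast = "forward"), class = "tendency_curve")
  expect_equal(tendency_score(zero), 0)
  expect_error(tendency_score(flat, prestim = c(0.5, 0.6)), "empty")
})

test_that("temporal generalization agrees with diagonal decoding on the
           diagonal", {
  ep <- small_epochs()
  tr <- select_training_trials(ep$metadata)
  te <- select_test_trials(ep$metadata, seed = 9)
  test_idx <- c(te$ordered, te$random)
  prev <- ep$metadata$prev_stimulus[test_idx]
  tg <- temporal_generalization(ep, tr, test_idx, prev,
                                train_window = c(0, 0.1),
                                test_window = c(0, 0.1), lambda = 0.1)
  res <- time_resolved_decode(ep, tr, test_idx, window = c(0, 0.1),
                              lambda = 0.1)
  ev <- transition_evidence(res$dvals, prev)
  fwd <- colMeans(matrix(ev[, "forward", ], nrow = length(test_idx)))
  expect_equal(diag(tg$forward), fwd, tolerance = 1e-10)
})
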