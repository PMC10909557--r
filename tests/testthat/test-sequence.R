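test_that("transition matrices implement the two entropy regimes", {
  om <- build_transition_matrix("ordered")$probs
  expect_equal(om[1, 2], 0.75)
  expect_equal(om[4, 1], 0.75)
  expect_equal(om[2, 2], 0.25)
  expect_equal(om[1, 3], 0)
  rnd <- build_transition_matrix("random")$probs
  expect_true(all(rnd == 0.25))
  expect_equal(unname(rowSums(om)), rep(1, 4), tolerance = 1e-12)
  expect_equal(unname(rowSums(rnd)), rep(1, 4), tolerance = 1e-12)
  expect_error(build_transition_matrix("medium"), "ordered")
})

test_that("forward successor is the cyclic next stimulus", {
  expect_equal(forward_successor(1), 2L)
  expect_equal(forward_successor(4), 1L)
  s <- 1:4
  for (k in 1:4) s <- forward_successor(s)
  expect_equal(s, 1:4)
  expect_error(forward_successor(0))
  expect_error(forward_successor(5))
})

test_that("all 16 transition pairs carry the hand-enumerated label", {
  expected <- matrix(c(
    "repetition", "forward",    "other",      "backward",
    "backward",   "repetition", "forward",    "other",
    "other",      "backward",   "repetition", "forward",
    "forward",    "other",      "backward",   "repetition"),
    nrow = 4, byrow = TRUE)
  for (p in 1:4) {
    for (cu in 1:4) {
      expect_equal(classify_transition(p, cu), expected[p, cu])
    }
  }
  expect_error(classify_transition(0, 1))
})

test_that("entropy schedules are balanced, seeded permutations", {
  sch <- generate_entropy_schedule(2, 4, seed = 7)
  expect_length(sch, 8)
  expect_equal(sum(sch == "ordered"), 4)
  expect_identical(sch, generate_entropy_schedule(2, 4, seed = 7))
  one <- generate_entropy_schedule(1, 2, seed = 3)
  expect_setequal(one, c("ordered", "random"))
  expect_error(generate_entropy_schedule(2, 3, seed = 1), "even")
})

test_that("generated sequences follow the transition probabilities", {
  s <- generate_sequence(rep("ordered", 4), 25000, seed = 11)
  tr <- classify_transition(s$stimulus[-nrow(s)], s$stimulus[-1])
  n <- nrow(s) - 1
  expect_lt(abs(mean(tr == "forward") - 0.75),
            3 * sqrt(0.75 * 0.25 / n))
  expect_lt(abs(mean(tr == "repetition") - 0.25),
            3 * sqrt(0.75 * 0.25 / n))
  s2 <- generate_sequence(rep("random", 2), 10000, seed = 12)
  expect_true(all(abs(table(s2$stimulus) / nrow(s2) - 0.25) < 0.02))
  expect_identical(generate_sequence(c("ordered", "random"), 50, seed = 3),
                   generate_sequence(c("ordered", "random"), 50, seed = 3))
  expect_error(generate_sequence(character(0), 10, seed = 1), "empty")
})

test_that("the full design geometry is reproduced", {
  s <- simulate_full_sequence(seed = 4)
  expect_equal(nrow(s), 5600)
  expect_equal(as.vector(table(s$block)), c(2800, 2800))
  expect_equal(as.vector(table(s$segment)), rep(700, 8))
  for (b in 1:2) {
    expect_equal(sum(tapply(s$entropy[s$block == b],
                            s$segment[s$block == b],
                            `[`, 1) == "ordered"), 2)
  }
})

test_that("omission flags are exact per stimulus-by-entropy stratum", {
  s <- simulate_full_sequence(seed = 5)
  for (st in 1:4) {
    for (e in c("ordered", "random")) {
      in_stratum <- s$stimulus == st & s$entropy == e
      expect_equal(sum(s$omitted[in_stratum]), round(0.1 * sum(in_stratum)))
      expect_lt(abs(sum(s$omitted[in_stratum]) - 70), 10)
    }
  }
  toy <- data.frame(trial = 1:40, stimulus = rep(1L, 40),
                    entropy = "ordered", omitted = FALSE)
  expect_equal(sum(apply_omissions(toy, 0.1, seed = 1)$omitted), 4)
  expect_equal(sum(apply_omissions(toy, 0, seed = 1)$omitted), 0)
  expect_error(apply_omissions(toy, 1, seed = 1))
  expect_error(apply_omissions(toy, -0.1, seed = 1))
})

test_that("burn-in marking matches closed-form counts", {
  s <- simulate_full_sequence(seed = 6)
  expect_equal(as.vector(table(s$entropy[!s$burn_in])), c(2720, 2720))
  toy <- generate_sequence(c("ordered", "random"), 50, seed = 2)
  toy <- mark_burn_in(toy, 5)
  expect_equal(sum(!toy$burn_in & toy$entropy == "ordered"), 45)
  expect_equal(sum(!toy$burn_in & toy$entropy == "random"), 45)
  expect_equal(sum(mark_burn_in(toy, 0)$burn_in), 0)
  expect_error(mark_burn_in(toy, 50))
})

test_that("the Dirichlet ideal observer follows the closed-form update", {
  stim <- rep(1:4, 6)                     # deterministic forward cycle
  io <- ideal_observer(stim, prior_strength = 1)
  n_obs <- floor((seq_along(stim) - 2) / 4)
  expect_equal(io$predictive[-1], ((n_obs + 1) / (n_obs + 4))[-1])
  # predictive first exceeds 0.5 on the third observation of a context
  expect_equal(io$convergence_trial, 14L)
  flat <- ideal_observer(stim, prior_strength = 1e9)
  expect_true(all(abs(flat$predictive[-1] - 0.25) < 1e-6))
  expect_true(is.na(flat$convergence_trial))
  expect_error(ideal_observer(integer(0)), "empty")
})

test_that("ordered segments are learned within tens of trials", {
  conv <- vapply(1:200, function(r) {
    s <- generate_sequence("ordered", 100, seed = 1000 + r)
    ct <- ideal_observer(s)$convergence_trial
    if (is.na(ct)) 100L else as.integer(ct)
  }, integer(1))
  expect_gt(stats::median(conv), 2)
  expect_lt(stats::median(conv), 60)
})

test_that("sequences survive a TSV round trip", {
  s <- simulate_full_sequence(n_blocks = 1, segments_per_block = 2,
                              segment_length = 30, seed = 8)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_sequence_tsv(s, path)
  expect_equal(read_sequence_tsv(path), s, ignore_attr = TRUE)
})
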