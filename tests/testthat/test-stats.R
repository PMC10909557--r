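test_that("cluster test finds nothing in flat data and exactly the
           injected window in a positive control", {
  flat <- matrix(0, 10, 25)
  res <- cluster_permutation_test(flat, cluster_config(n_permutations = 200))
  expect_equal(nrow(res$clusters), 0)

  set.seed(11)
  x <- matrix(rnorm(20 * 40, 0, 0.1), 20, 40)
  x[, 10:20] <- x[, 10:20] + 1
  res2 <- cluster_permutation_test(x,
                                   cluster_config(n_permutations = 1000,
                                                  seed = 2))
  big <- res2$clusters[res2$clusters$p < 0.025, ]
  expect_equal(nrow(big), 1)
  expect_equal(c(big$start, big$end), c(10, 20))
  expect_equal(big$sign, 1)
  expect_error(cluster_permutation_test(x[1:2, ]), "3 subjects")
})

test_that("cluster p-values are seeded-reproducible and use the
           add-one convention", {
  set.seed(3)
  x <- matrix(rnorm(8 * 15), 8, 15) + 0.6
  cfg <- cluster_config(n_permutations = 500, seed = 42)
  r1 <- cluster_permutation_test(x, cfg)
  r2 <- cluster_permutation_test(x, cfg)
  expect_identical(r1$clusters, r2$clusters)
  expect_true(all(r1$clusters$p >= 1 / 501))
})

test_that("cluster masses and p-values match brute-force sign-flip
           enumeration for six subjects", {
  set.seed(21)
  x <- matrix(rnorm(6 * 12, 0, 1), 6, 12)
  x[, 4:7] <- x[, 4:7] + 1.6
  res <- cluster_permutation_test(x, cluster_config(n_permutations = "all"))

  # independent oracle: direct t tests, run-scan, all 2^6 sign patterns
  thr <- qt(0.975, 5)
  tvec <- function(m) apply(m, 2, function(v) unname(t.test(v)$statistic))
  all_masses <- function(tv) {
    out <- list()
    cur <- 0; s <- 0; start <- NA
    for (j in seq_along(tv)) {
      lab <- if (tv[j] > thr) 1 else if (tv[j] < -thr) -1 else 0
      if (lab != 0 && lab == s) cur <- cur + tv[j]
      else {
        if (s != 0) out[[length(out) + 1]] <- c(start, j - 1, cur)
        s <- lab; cur <- if (lab != 0) tv[j] else 0
        start <- if (lab != 0) j else NA
      }
    }
    if (s != 0) out[[length(out) + 1]] <- c(start, length(tv), cur)
    out
  }
  obs <- all_masses(tvec(x))
  signs <- as.matrix(expand.grid(rep(list(c(-1, 1)), 6)))
  null_max <- apply(signs, 1, function(sg) {
    m <- all_masses(tvec(x * sg))
    if (length(m)) max(abs(vapply(m, `[`, numeric(1), 3))) else 0
  })
  expect_equal(sort(res$null_max), sort(null_max), tolerance = 1e-10)
  expect_equal(nrow(res$clusters), length(obs))
  for (k in seq_along(obs)) {
    expect_equal(unlist(res$clusters[k, c("start", "end", "mass")]),
                 obs[[k]], tolerance = 1e-10, ignore_attr = TRUE)
    expect_equal(res$clusters$p[k],
                 (1 + sum(null_max >= abs(obs[[k]][3]))) / (1 + 64))
  }
})

test_that("pearson correlation matches direct arithmetic", {
  x <- c(1.2, 0.7, 3.1, 2.2, 1.9)
  y <- c(0.4, 1.1, 2.6, 2.9, 1.0)
  pc <- pearson_correlation(x, y)
  r_direct <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  expect_equal(pc$r, r_direct, tolerance = 1e-12)
  expect_equal(pearson_correlation(x, x)$r, 1)
  expect_equal(pearson_correlation(x, -x)$r, -1)
  expect_error(pearson_correlation(x, rep(1, 5)), "variance")
  expect_error(pearson_correlation(x, y[1:3]), "equal length")
})

test_that("Cronbach's alpha obeys the two-item identity and reference
           moments", {
  set.seed(31)
  items <- matrix(rnorm(40), 20, 2)
  a <- cronbach_alpha(items)
  cv <- cov(items)[1, 2]
  expect_equal(a, 4 * cv / (var(items[, 1]) + var(items[, 2]) + 2 * cv),
               tolerance = 1e-12)
  expect_equal(cronbach_alpha(cbind(items[, 1], items[, 1])), 1)

  # two items with reference cross-modal moments (SDs .164/.127, r .18)
  z1 <- scale(rnorm(200))[, 1]
  z2 <- scale(residuals(lm(rnorm(200) ~ z1)))[, 1]
  z1 <- z1 / sd(z1); z2 <- z2 / sd(z2)
  it <- cbind(0.164 * z1, 0.127 * (0.18 * z1 + sqrt(1 - 0.18^2) * z2))
  expect_equal(cor(it)[1, 2], 0.18, tolerance = 1e-10)
  expect_equal(cronbach_alpha(it), 0.298, tolerance = 0.005)

  # independent items at large n
  set.seed(32)
  big <- matrix(rnorm(2e4), ncol = 2)
  expect_lt(abs(cronbach_alpha(big)), 3 / sqrt(1e4))
  expect_error(cronbach_alpha(matrix(1, 5, 2)), "variance")
})

test_that("Spearman-Brown step-up has the right fixed points and values", {
  expect_equal(spearman_brown(0), 0)
  expect_equal(spearman_brown(1), 1)
  expect_equal(round(spearman_brown(0.74), 3), 0.851)
  expect_equal(spearman_brown(0.18), 0.305, tolerance = 5e-4)
  rr <- seq(-0.9, 1, by = 0.1)
  expect_true(all(diff(spearman_brown(rr)) > 0))
  expect_error(spearman_brown(-1), "undefined")
})

test_that("split-half reliability approaches 1 in near-noiseless cohorts
           and is stepped up by Spearman-Brown", {
  design <- study_design(segment_length = 350, noise_sd = 0.05,
                         n_channels = 8)
  betas <- seq(0.2, 1, length.out = 6)
  dec <- lapply(seq_along(betas), function(i)
    pipeline_subject(design, betas[i], seed = 6000 + i * 13))
  sh <- split_half_reliability(dec, seed = 5)
  expect_gt(sh$r, 0.9)
  expect_gt(sh$rho, sh$r)
  expect_equal(sh$rho, 2 * sh$r / (1 + sh$r))
  expect_error(split_half_reliability(dec, min_trials = 10000),
               "fewer than")
})

test_that("time-by-time reliability is 1 on the diagonal for identical
           curves", {
  times <- seq(-0.3, 0.3, by = 0.01)
  set.seed(41)
  curves <- matrix(rnorm(12 * length(times)), 12)
  tb <- time_by_time_reliability(curves, curves, times)
  expect_equal(unname(diag(tb$rho)), rep(1, 30), tolerance = 1e-10)
  expect_equal(dim(tb$rho), c(30, 30))
  expect_error(time_by_time_reliability(curves, curves[1:5, ], times),
               "subject axes")
})

test_that("the paired difference test matches the hand formula", {
  a <- c(0.3, -0.1, 0.2, 0.05, -0.25)
  b <- rep(0, 5)
  res <- paired_difference_test(a, b)
  t_hand <- mean(a) / (sd(a) / sqrt(5))
  expect_equal(res$t, t_hand, tolerance = 1e-10)
  expect_equal(res$ci,
               mean(a) + qt(c(0.025, 0.975), 4) * sd(a) / sqrt(5),
               tolerance = 1e-10)
  same <- paired_difference_test(a, a)
  expect_equal(same$t, 0)
  expect_equal(same$ci, c(0, 0))
  expect_error(paired_difference_test(a, b[1:2]))
})
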