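#' Configuration for the cluster-based permutation test
#'
#' @param n_permutations Number of random sign-flip permutations
#'   (default 10000; >= 100, or `"all"` for exhaustive enumeration when
#'   the cohort has at most 20 subjects).
#' @param cluster_alpha Per-tail cluster-forming alpha (default 0.025).
#' @param critical_alpha Monte-Carlo significance level for cluster
#'   p-values (default 0.025).
#' @param seed Integer seed for the sign flips.
#' @return A `cluster_config` list.
#' @export
cluster_config <- function(n_permutations = 10000, cluster_alpha = 0.025,
                           critical_alpha = 0.025, seed = 1) {
  if (!identical(n_permutations, "all")) {
    stopifnot(n_permutations >= 100)
  }
  stopifnot(cluster_alpha > 0, cluster_alpha < 0.5,
            critical_alpha > 0, critical_alpha < 0.5)
  list(n_permutations = n_permutations, cluster_alpha = cluster_alpha,
       critical_alpha = critical_alpha, seed = seed)
}

# one-sample t statistics per column given column sums and fixed column
# sums of squares (sign flips leave the sums of squares unchanged)
.t_from_sums <- function(colsum, ssq, n) {
  m <- colsum / n
  v <- (ssq - n * m^2) / (n - 1)
  tv <- m / sqrt(v / n)
  tv[!is.finite(tv)] <- 0   # zero-variance columns carry no evidence
  tv
}

# maximal contiguous runs of `above`; returns data.frame(start, end, mass)
.clusters_from_t <- function(tval, above) {
  r <- rle(above)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- which(r$values)
  if (!length(keep)) {
    return(data.frame(start = integer(0), end = integer(0),
                      mass = numeric(0)))
  }
  data.frame(start = starts[keep], end = ends[keep],
             mass = vapply(keep, function(k)
               sum(tval[starts[k]:ends[k]]), numeric(1)))
}

# max |cluster mass| of one t series under the two-tailed threshold
.max_cluster_mass <- function(tval, thr) {
  mpos <- .clusters_from_t(tval, tval > thr)$mass
  mneg <- .clusters_from_t(tval, tval < -thr)$mass
  m <- c(mpos, -mneg)
  if (length(m)) max(m) else 0
}

# row-wise max |cluster mass| for a permutations x time matrix of t values:
# a running-sum scan over columns, vectorised across permutations
.max_cluster_mass_rows <- function(tmat, thr) {
  nr <- nrow(tmat)
  run_pos <- numeric(nr)
  run_neg <- numeric(nr)
  best <- numeric(nr)
  for (j in seq_len(ncol(tmat))) {
    tj <- tmat[, j]
    run_pos <- ifelse(tj > thr, run_pos + tj, 0)
    run_neg <- ifelse(tj < -thr, run_neg - tj, 0)
    best <- pmax(best, run_pos, run_neg)
  }
  best
}

#' One-sample cluster-based sign-flip permutation test
#'
#' Tests a subjects x time matrix of paired differences against zero while
#' controlling for multiple comparisons across time. Per time sample a
#' one-sample t statistic is computed; clusters are maximal contiguous runs
#' of samples whose |t| exceeds the two-sided cluster-forming threshold
#' (the `1 - cluster_alpha` t quantile per tail); a cluster's mass is its
#' summed t values. The null distribution of the maximum absolute cluster
#' mass is built by randomly sign-flipping whole subject curves, and each
#' observed cluster receives the Monte-Carlo p-value
#' `(1 + #\{null >= |mass|\}) / (1 + n_permutations)`.
#'
#' @param data Subjects x time matrix of differences (e.g. ordered -
#'   random tendency curves).
#' @param cfg A [cluster_config()].
#' @param times Optional time axis (per column) used to report cluster
#'   intervals in seconds.
#' @return A `cluster_result`: list with `t` (per-sample t), `clusters`
#'   (data.frame: start, end, time_start, time_end, mass, sign, p),
#'   `threshold`, `null_max`, `cfg`.
#' @export
cluster_permutation_test <- function(data, cfg = cluster_config(),
                                     times = NULL) {
  data <- as.matrix(data)
  n <- nrow(data)
  if (n < 3) stop("need at least 3 subjects", call. = FALSE)
  nt <- ncol(data)
  ssq <- colSums(data^2)
  tobs <- .t_from_sums(colSums(data), ssq, n)
  thr <- stats::qt(1 - cfg$cluster_alpha, df = n - 1)
  pos <- .clusters_from_t(tobs, tobs > thr)
  neg <- .clusters_from_t(tobs, tobs < -thr)
  obs <- rbind(cbind(pos, sign = if (nrow(pos)) 1 else numeric(0)),
               cbind(neg, sign = if (nrow(neg)) -1 else numeric(0)))

  if (identical(cfg$n_permutations, "all")) {
    if (n > 20) stop("exhaustive enumeration needs n <= 20", call. = FALSE)
    signs <- as.matrix(expand.grid(rep(list(c(-1, 1)), n)))
    nperm <- nrow(signs)
  } else {
    nperm <- cfg$n_permutations
    set.seed(cfg$seed)
    signs <- matrix(sample(c(-1, 1), nperm * n, replace = TRUE), nperm, n)
  }
  colsums <- signs %*% data                 # nperm x nt
  M <- colsums / n
  V <- sweep(-n * M^2, 2, ssq, "+") / (n - 1)
  Tmat <- M / sqrt(V / n)
  Tmat[!is.finite(Tmat)] <- 0
  null_max <- .max_cluster_mass_rows(Tmat, thr)
  if (nrow(obs)) {
    obs$p <- vapply(abs(obs$mass), function(m)
      (1 + sum(null_max >= m)) / (1 + nperm), numeric(1))
    if (!is.null(times)) {
      obs$time_start <- times[obs$start]
      obs$time_end <- times[obs$end]
    }
    obs <- obs[order(obs$start), , drop = FALSE]
    rownames(obs) <- NULL
  } else {
    obs$p <- numeric(0)
  }
  structure(list(t = tobs, clusters = obs, threshold = thr,
                 null_max = null_max, cfg = cfg, n_subjects = n,
                 times = times),
            class = "cluster_result")
}

#' Pearson correlation with two-sided p-value
#'
#' Thin wrapper around [stats::cor.test()] that validates the inputs the
#' way the reliability analyses need.
#'
#' @param x,y Numeric vectors of equal length >= 3 with non-zero variance.
#' @return List with `r`, `p`, `n`.
#' @export
pearson_correlation <- function(x, y) {
  if (length(x) != length(y) || length(x) < 3) {
    stop("need two vectors of equal length >= 3", call. = FALSE)
  }
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop("zero variance", call. = FALSE)
  }
  ct <- stats::cor.test(x, y, method = "pearson")
  list(r = unname(ct$estimate), p = ct$p.value, n = length(x))
}

#' Cronbach's alpha
#'
#' Covariance-based internal consistency of a k-item scale:
#' \eqn{\alpha = k/(k-1)\,(1 - \sum_i s_i^2 / s_{sum}^2)}. For two items
#' this reduces to \eqn{4\,\mathrm{cov}/(s_1^2 + s_2^2 + 2\,\mathrm{cov})}.
#'
#' @param items Subjects x k matrix (k >= 2 columns, >= 3 rows).
#' @return Scalar alpha.
#' @export
cronbach_alpha <- function(items) {
  items <- as.matrix(items)
  k <- ncol(items)
  if (k < 2 || nrow(items) < 3) {
    stop("need >= 2 items and >= 3 subjects", call. = FALSE)
  }
  total_var <- stats::var(rowSums(items))
  if (total_var == 0) stop("zero total variance", call. = FALSE)
  k / (k - 1) * (1 - sum(apply(items, 2, stats::var)) / total_var)
}

#' Spearman-Brown step-up reliability
#'
#' The predicted full-length reliability of a two-part measure given the
#' correlation r between its parts: \eqn{\rho = 2r/(1+r)}.
#'
#' @param r Correlation in `(-1, 1]`.
#' @return rho.
#' @export
spearman_brown <- function(r) {
  if (any(r <= -1)) stop("undefined for r = -1", call. = FALSE)
  2 * r / (1 + r)
}

#' Split-half reliability of the prediction tendency score
#'
#' For each subject, the matched test trials of each condition are split
#' (seeded, stratified by condition and stimulus identity) into two halves;
#' the tendency score is computed per half from the stored per-trial
#' evidence (the classifier is shared between halves), and the across-
#' subject Pearson correlation between half scores is stepped up with the
#' Spearman-Brown formula.
#'
#' @param decodings List of `subject_decoding` objects (one per subject).
#' @param seed Integer seed for the splits.
#' @param min_trials Minimum matched test trials per condition
#'   (default 20).
#' @return List with `r`, `rho`, `alpha` (two-half Cronbach alpha),
#'   `half_scores` (subjects x 2).
#' @export
split_half_reliability <- function(decodings, seed = 1, min_trials = 20) {
  n_test <- vapply(decodings, function(d) min(d$n_test), numeric(1))
  if (any(n_test < min_trials)) {
    stop(sprintf("subjects with fewer than %d matched test trials",
                 min_trials), call. = FALSE)
  }
  set.seed(seed)
  halves <- t(vapply(decodings, function(d) {
    idx <- lapply(c("ordered", "random"), function(cond) {
      stim <- d$test_stimulus[[cond]]
      h1 <- unlist(lapply(1:4, function(s) {
        i <- which(stim == s)
        if (length(i) < 2) return(integer(0))
        sample(i, floor(length(i) / 2))
      }))
      list(h1 = h1, h2 = setdiff(seq_along(stim), h1))
    })
    names(idx) <- c("ordered", "random")
    score_half <- function(h) {
      cv <- tendency_curve(
        d$evidence$ordered[idx$ordered[[h]], , , drop = FALSE],
        d$evidence$random[idx$random[[h]], , , drop = FALSE],
        d$times, d$contrast)
      tendency_score(cv, d$prestim)
    }
    c(score_half("h1"), score_half("h2"))
  }, numeric(2)))
  pc <- pearson_correlation(halves[, 1], halves[, 2])
  list(r = pc$r, p = pc$p, rho = spearman_brown(pc$r),
       alpha = cronbach_alpha(halves), half_scores = halves)
}

#' Time-by-time cross-modal reliability matrix
#'
#' For every pair of prestimulus samples (i in modality A, j in modality
#' B), the across-subject Pearson correlation of tendency-curve values is
#' computed and stepped up with the Spearman-Brown formula, mapping when
#' prediction signals in one modality generalize to the other.
#'
#' @param curves_a,curves_b Subjects x time matrices of tendency-curve
#'   values (same subject order).
#' @param times Time axis of the curve columns.
#' @param prestim Prestimulus window (default `c(-0.3, 0)` s).
#' @return List with `rho` (time x time matrix), `r`, `times`.
#' @export
time_by_time_reliability <- function(curves_a, curves_b, times,
                                     prestim = c(-0.3, 0)) {
  if (nrow(curves_a) != nrow(curves_b)) {
    stop("subject axes differ", call. = FALSE)
  }
  eps <- 1e-9
  sel <- which(times >= prestim[1] - eps & times < prestim[2] - eps)
  r <- stats::cor(curves_a[, sel, drop = FALSE],
                  curves_b[, sel, drop = FALSE])
  list(r = r, rho = spearman_brown(pmax(r, -1 + 1e-12)),
       times = times[sel])
}

#' Paired difference t-test with confidence interval
#'
#' One-sample t-test of the per-subject score differences (e.g. auditory
#' minus visual) against zero, with the 95% confidence interval of the
#' mean difference.
#'
#' @param scores_a,scores_b Paired score vectors.
#' @return List with `t`, `p`, `ci` (length 2), `mean_diff`, `df`.
#' @export
paired_difference_test <- function(scores_a, scores_b) {
  if (length(scores_a) != length(scores_b) || length(scores_a) < 3) {
    stop("need paired vectors of length >= 3", call. = FALSE)
  }
  d <- scores_a - scores_b
  if (stats::sd(d) == 0) {
    # degenerate case: identical pairs; t defined as 0 with a point CI
    return(list(t = if (mean(d) == 0) 0 else sign(mean(d)) * Inf,
                p = if (mean(d) == 0) 1 else 0,
                ci = rep(mean(d), 2), mean_diff = mean(d),
                df = length(d) - 1))
  }
  tt <- stats::t.test(d)
  list(t = unname(tt$statistic), p = tt$p.value,
       ci = as.numeric(tt$conf.int), mean_diff = unname(tt$estimate),
       df = unname(tt$parameter))
}

#' @export
print.cluster_result <- function(x, ...) {
  cat(sprintf("Cluster permutation test: %d subjects, %d samples, |t| > %.3f\n",
              x$n_subjects, length(x$t), x$threshold))
  if (nrow(x$clusters) == 0) {
    cat("  no suprathreshold clusters\n")
  } else {
    print(x$clusters)
  }
  invisible(x)
}
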