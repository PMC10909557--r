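#' Full run configuration
#'
#' Aggregates every tunable of the pipeline with the paradigm constants as
#' defaults: 700-trial segments, 4 segments per block, 10% omissions,
#' 20-trial burn-in, 0.1--30 Hz band, 100 Hz analysis rate, -0.4--0.8 s
#' epochs, -0.3--0.3 s decoding window, -0.3--0 s prestimulus window, and
#' 10,000-permutation cluster testing at alpha 0.025. The simulation
#' geometry defaults to the reduced desk scale (1 block, 32 channels,
#' 35 subjects).
#'
#' @param n_subjects Cohort size (default 35).
#' @param rho True cross-modal correlation of pre-activation amplitudes.
#' @param design A [cohort_design()] list.
#' @param beta_mean,beta_sd,truncate Cohort amplitude distribution.
#' @param filter_low,filter_high Band edges in Hz.
#' @param analysis_rate Analysis sampling rate in Hz (default 100).
#' @param epoch_tmin,epoch_tmax Epoch window in seconds.
#' @param window Decoding window in seconds.
#' @param prestim Prestimulus summation window in seconds.
#' @param contrast Tendency contrast (see [tendency_curve()]).
#' @param lambda LDA shrinkage (`"auto"` or fixed).
#' @param cluster A [cluster_config()].
#' @param seed Master seed; every stochastic stage derives its own stream
#'   from it.
#' @param out_dir Optional output directory for TSV/JSON reports.
#' @return A `run_config` list.
#' @export
run_config <- function(n_subjects = 35, rho = 0, design = cohort_design(),
                       beta_mean = 0.5, beta_sd = 0.25, truncate = TRUE,
                       filter_low = 0.1, filter_high = 30,
                       analysis_rate = 100, epoch_tmin = -0.4,
                       epoch_tmax = 0.8, window = c(-0.3, 0.3),
                       prestim = c(-0.3, 0), contrast = "forward",
                       lambda = "auto", cluster = cluster_config(),
                       seed = 1, out_dir = NULL) {
  cfg <- list(n_subjects = n_subjects, rho = rho, design = design,
              beta_mean = beta_mean, beta_sd = beta_sd, truncate = truncate,
              filter_low = filter_low, filter_high = filter_high,
              analysis_rate = analysis_rate, epoch_tmin = epoch_tmin,
              epoch_tmax = epoch_tmax, window = window, prestim = prestim,
              contrast = contrast, lambda = lambda, cluster = cluster,
              seed = seed, out_dir = out_dir)
  validate_run_config(cfg)
}

#' @rdname run_config
#' @param cfg A candidate configuration list.
#' @export
validate_run_config <- function(cfg) {
  stopifnot(cfg$n_subjects >= 3, abs(cfg$rho) <= 1,
            cfg$filter_low > 0, cfg$filter_low < cfg$filter_high,
            cfg$filter_high < cfg$analysis_rate / 2,
            cfg$analysis_rate <= cfg$design$srate,
            cfg$epoch_tmin < 0, cfg$epoch_tmax > 0,
            cfg$window[1] >= cfg$epoch_tmin, cfg$window[2] <= cfg$epoch_tmax,
            cfg$prestim[1] >= cfg$window[1], cfg$prestim[2] <= cfg$window[2])
  class(cfg) <- "run_config"
  cfg
}

#' Load a run configuration from a YAML file
#'
#' Reads a YAML document whose keys override [run_config()] defaults;
#' nested keys `design:` and `cluster:` override [cohort_design()] and
#' [cluster_config()] entries. Unknown keys are rejected.
#'
#' @param path YAML file path.
#' @return A validated `run_config`.
#' @export
load_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  base <- run_config()
  known <- names(base)
  bad <- setdiff(names(y), known)
  if (length(bad)) {
    stop("unknown config keys: ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  for (k in names(y)) {
    if (k %in% c("design", "cluster")) {
      sub <- base[[k]]
      badk <- setdiff(names(y[[k]]), names(sub))
      if (length(badk)) {
        stop("unknown ", k, " keys: ", paste(badk, collapse = ", "),
             call. = FALSE)
      }
      sub[names(y[[k]])] <- y[[k]]
      base[[k]] <- sub
    } else {
      base[[k]] <- if (length(y[[k]]) > 1) unlist(y[[k]]) else y[[k]]
    }
  }
  validate_run_config(base)
}

# simulate -> filter -> resample -> epoch for one prepared recording
preprocess_recording <- function(rec, seq, cfg) {
  rec <- bandpass_filter(rec, cfg$filter_low, cfg$filter_high)
  if (cfg$analysis_rate < rec$srate) {
    rec <- resample_recording(rec, cfg$analysis_rate)
  }
  epoch_recording(rec, seq, cfg$epoch_tmin, cfg$epoch_tmax)
}

#' Run the full simulation-to-report experiment
#'
#' Simulates a two-modality cohort, preprocesses and decodes every subject,
#' and computes the group-level statistics: cluster-based permutation tests
#' of the tendency curves per modality, the cross-modal Pearson
#' correlation, Cronbach's alpha and Spearman-Brown rho of the two-modality
#' scale, split-half reliability per modality, the time-by-time cross-modal
#' reliability matrix, and the paired auditory-visual score difference
#' test. If `cfg$out_dir` is set, a reliability table (TSV) and a results
#' bundle (JSON) are written there.
#'
#' @param cfg A [run_config()].
#' @param progress Print per-subject progress (default FALSE).
#' @return A `predtend_run`: list with `scores` (data frame), `curves`
#'   (per modality subjects x time), `cluster` (per modality),
#'   `reliability` (report list), `config`, `counts`.
#' @export
run_experiment <- function(cfg = run_config(), progress = FALSE) {
  cohort <- simulate_cohort(cfg$n_subjects, cfg$rho, cfg$design,
                            seed = cfg$seed, beta_mean = cfg$beta_mean,
                            beta_sd = cfg$beta_sd, truncate = cfg$truncate)
  modalities <- c("aud", "vis")
  decodings <- list(aud = vector("list", cfg$n_subjects),
                    vis = vector("list", cfg$n_subjects))
  for (i in seq_len(cfg$n_subjects)) {
    for (m in modalities) {
      rec <- cohort$recording(i, m)
      ep <- preprocess_recording(rec, cohort$sequences[[i]][[m]], cfg)
      decodings[[m]][[i]] <- decode_subject(
        ep, cfg$window, cfg$prestim, cfg$contrast, cfg$lambda,
        seed = derive_seed(cfg$seed, 5000 + i * 10 + match(m, modalities)))
      rm(rec, ep)
    }
    if (progress) message("subject ", i, "/", cfg$n_subjects, " done")
  }
  curves <- lapply(decodings, function(dl)
    t(vapply(dl, function(d) d$curve$values,
             numeric(length(dl[[1]]$curve$times)))))
  times <- decodings$aud[[1]]$curve$times
  scores <- data.frame(
    subject = seq_len(cfg$n_subjects),
    beta_aud = cohort$params$beta_aud,
    beta_vis = cohort$params$beta_vis,
    score_aud = vapply(decodings$aud, `[[`, numeric(1), "score"),
    score_vis = vapply(decodings$vis, `[[`, numeric(1), "score"))
  eps <- 1e-9
  prestim_cols <- times >= cfg$prestim[1] - eps & times < cfg$prestim[2] - eps
  clusters <- lapply(curves, function(cv) {
    cl <- cfg$cluster
    cl$seed <- derive_seed(cfg$seed, 7777)
    cluster_permutation_test(cv, cl, times = times)
  })
  cross <- pearson_correlation(scores$score_aud, scores$score_vis)
  split_half <- lapply(modalities, function(m)
    tryCatch(split_half_reliability(
      decodings[[m]], seed = derive_seed(cfg$seed, 6000 + match(m, modalities))),
      error = function(e) NULL))
  names(split_half) <- modalities
  reliability <- list(
    cross_modal = list(r = cross$r, p = cross$p,
                       alpha = cronbach_alpha(
                         cbind(scores$score_aud, scores$score_vis)),
                       rho = spearman_brown(cross$r)),
    split_half = split_half,
    time_by_time = time_by_time_reliability(
      curves$aud, curves$vis, times, cfg$prestim),
    paired = paired_difference_test(scores$score_aud, scores$score_vis))
  counts <- list(
    n_train = lapply(decodings, function(dl)
      vapply(dl, `[[`, numeric(1), "n_train")),
    n_test = lapply(decodings, function(dl)
      vapply(dl, function(d) d$n_test[["ordered"]], numeric(1))))
  out <- structure(list(scores = scores, curves = curves, times = times,
                        cluster = clusters, reliability = reliability,
                        counts = counts, config = cfg),
                   class = "predtend_run")
  if (!is.null(cfg$out_dir)) {
    dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
    write_reliability_tsv(out, file.path(cfg$out_dir, "reliability.tsv"))
    write_scores_tsv(out, file.path(cfg$out_dir, "scores.tsv"))
    write_results_json(out, file.path(cfg$out_dir, "results.json"))
  }
  out
}

#' Write the three-row reliability table
#'
#' TSV with rows cross-modal, auditory split-half and visual split-half
#' and columns r, cronbach_alpha, spearman_brown_rho.
#'
#' @param run A `predtend_run`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_reliability_tsv <- function(run, path) {
  rel <- run$reliability
  row <- function(name, r, alpha, rho)
    data.frame(measure = name, r = r, cronbach_alpha = alpha,
               spearman_brown_rho = rho)
  sh <- function(m) {
    s <- rel$split_half[[m]]
    if (is.null(s)) row(paste0(m, "_split_half"), NA, NA, NA)
    else row(paste0(m, "_split_half"), s$r, s$alpha, s$rho)
  }
  tab <- rbind(row("cross_modal", rel$cross_modal$r, rel$cross_modal$alpha,
                   rel$cross_modal$rho),
               sh("aud"), sh("vis"))
  utils::write.table(tab, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Write per-subject scores as TSV
#'
#' @inheritParams write_reliability_tsv
#' @export
write_scores_tsv <- function(run, path) {
  utils::write.table(run$scores, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Write the results bundle as JSON
#'
#' Clusters, reliability statistics, per-subject scores, trial counts and
#' the seed/config, in one machine-readable file.
#'
#' @inheritParams write_reliability_tsv
#' @export
write_results_json <- function(run, path) {
  cl <- lapply(run$cluster, function(x) x$clusters)
  bundle <- list(
    seed = run$config$seed,
    n_subjects = run$config$n_subjects,
    scores = run$scores,
    clusters = cl,
    reliability = list(
      cross_modal = run$reliability$cross_modal,
      aud_split_half = run$reliability$split_half$aud[c("r", "rho", "alpha")],
      vis_split_half = run$reliability$split_half$vis[c("r", "rho", "alpha")],
      paired = run$reliability$paired),
    counts = run$counts)
  jsonlite::write_json(bundle, path, auto_unbox = TRUE, digits = NA,
                       na = "null")
  invisible(path)
}

#' @export
print.predtend_run <- function(x, ...) {
  cat(sprintf("predtend run: %d subjects, %d channels, %d block(s)\n",
              x$config$n_subjects, x$config$design$n_channels,
              x$config$design$n_blocks))
  cat(sprintf("cross-modal r = %.3f (alpha %.3f, rho %.3f)\n",
              x$reliability$cross_modal$r, x$reliability$cross_modal$alpha,
              x$reliability$cross_modal$rho))
  for (m in names(x$cluster)) {
    cat("[", m, "] ", sep = "")
    print(x$cluster[[m]])
  }
  invisible(x)
}

#' Deterministic miniature cohort for tests and examples
#'
#' Three subjects, 8 channels, one block of two 100-trial segments (one
#' ordered, one random), 5-trial burn-in, simulated at 300 Hz. Regenerates
#' bit-identically for a fixed seed.
#'
#' @param seed Integer seed (default 42).
#' @return List with `design`, `cohort` and, per subject, preprocessed
#'   `epochs` for the auditory modality of a default-configured pipeline.
#' @export
make_fixtures <- function(seed = 42) {
  design <- cohort_design(n_blocks = 1, segments_per_block = 2,
                          segment_length = 100, n_burn_in = 5,
                          n_channels = 8, noise_sd = 0.5)
  cohort <- simulate_cohort(3, rho = 0.5, design, seed = seed)
  cfg <- run_config(n_subjects = 3, rho = 0.5, design = design, seed = seed)
  epochs <- lapply(1:3, function(i)
    preprocess_recording(cohort$recording(i, "aud"),
                         cohort$sequences[[i]]$aud, cfg))
  list(design = design, cohort = cohort, epochs = epochs, config = cfg)
}
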