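# Orchestration of the two headline experiments: the normal-hearing
# denoising benchmark and the synthetic-cohort severity study.

#' Experiment configuration
#'
#' Bundles every tunable of the pipeline with named RNG seeds so that any
#' experiment is reproducible from its configuration alone.
#'
#' @param n_nodes Number of cochlear nodes.
#' @param n_stimuli Number of acoustic stimuli.
#' @param snr_list SNR levels (dB) for the denoising sweep.
#' @param density_display Edge density used when thresholding graphs for
#'   display.
#' @param tau Tikhonov regularization (fixed mode).
#' @param tau_mode `"fixed"` (one shared tau for every graph, the default)
#'   or `"oracle"` (per-graph held-out selection, for cross-method
#'   fairness when weight scales differ).
#' @param n_noise_reps Independent noise realizations per signal.
#' @param methods Graph-construction methods to include.
#' @param seeds Named list of seeds: `stimuli`, `noise`, `cohort`,
#'   `communities`.
#' @param f_min,f_max Tonotopic frequency span (Hz).
#' @param level_range Stimulus level range (dB).
#' @param alpha,beta,max_iter,tol Smooth-graph-learning parameters.
#' @param smear_scale,noise_scale Hearing-loss model parameters (see
#'   [impair_signal_matrix()]).
#' @param threshold_metrics Threshold graphs to `density_display` before
#'   computing metrics (off by default: metrics use the full weighted
#'   graphs).
#' @return A list of class `experiment_config` with a `hash` field.
#' @export
experiment_config <- function(n_nodes = 100, n_stimuli = 1000,
                              snr_list = c(-15, -10, -5, 0, 5),
                              density_display = 0.25, tau = 1,
                              tau_mode = "fixed", n_noise_reps = 1,
                              methods = graph_methods,
                              seeds = list(stimuli = 101, noise = 202,
                                           cohort = 303, communities = 404),
                              f_min = 20, f_max = 20000,
                              level_range = c(40, 90),
                              alpha = 1, beta = 0.5, max_iter = 10000,
                              tol = 1e-6, smear_scale = 0.10,
                              noise_scale = 1.3, threshold_metrics = FALSE) {
  stopifnot(length(snr_list) >= 1,
            all(methods %in% graph_methods),
            all(c("stimuli", "noise", "cohort", "communities") %in% names(seeds)))
  cfg <- list(n_nodes = n_nodes, n_stimuli = n_stimuli, snr_list = snr_list,
              density_display = density_display, tau = tau,
              tau_mode = match.arg(tau_mode, c("fixed", "oracle")),
              n_noise_reps = n_noise_reps, methods = methods, seeds = seeds,
              f_min = f_min, f_max = f_max, level_range = level_range,
              alpha = alpha, beta = beta, max_iter = max_iter, tol = tol,
              smear_scale = smear_scale, noise_scale = noise_scale,
              threshold_metrics = threshold_metrics)
  cfg$hash <- config_hash(cfg)
  structure(cfg, class = "experiment_config")
}

#' @export
print.experiment_config <- function(x, ...) {
  cat(sprintf("Experiment config %s: %d nodes, %d stimuli, SNRs {%s} dB, methods {%s}\n",
              x$hash, x$n_nodes, x$n_stimuli,
              paste(x$snr_list, collapse = ", "),
              paste(x$methods, collapse = ", ")))
  invisible(x)
}

provenance_of <- function(cfg, extra = list()) {
  c(list(config_hash = cfg$hash, seeds = cfg$seeds), extra)
}

build_all_graphs <- function(cfg, X, map) {
  out <- list()
  for (method in cfg$methods) {
    out[[method]] <- switch(method,
      gsp_learned = learn_graph_smooth(X, smooth_learn_config(
        alpha = cfg$alpha, beta = cfg$beta, max_iter = cfg$max_iter,
        tol = cfg$tol), map = map),
      gsp_correlation = correlation_graph(X, map = map),
      frequency = frequency_graph(map),
      linear = linear_graph(map))
  }
  out
}

#' Run the denoising benchmark
#'
#' Pipeline: tonotopic map, seeded stimulus set, signal matrix under the
#' given performance profile, the configured construction methods, and an
#' SNR sweep with shared noise and pairwise Welch tests. Fully reproducible
#' from the configuration.
#'
#' @param cfg An [experiment_config()].
#' @param profile A `performance_profile`, or `NULL` for normal hearing.
#' @return A `denoising_result` with a `provenance` field.
#' @export
run_denoising_benchmark <- function(cfg, profile = NULL) {
  stopifnot(inherits(cfg, "experiment_config"))
  map <- build_tonotopic_map(cfg$n_nodes, cfg$f_min, cfg$f_max)
  message(sprintf("[stimuli] generating %d stimuli (seed %d)",
                  cfg$n_stimuli, cfg$seeds$stimuli))
  set <- generate_stimulus_set(cfg$n_stimuli, seed = cfg$seeds$stimuli,
                               level_range = cfg$level_range)
  message("[signals] building signal matrix")
  X <- build_signal_matrix(set, map, profile, smear_scale = cfg$smear_scale,
                           noise_scale = cfg$noise_scale)
  message(sprintf("[graphs] constructing: %s", paste(cfg$methods, collapse = ", ")))
  graphs <- build_all_graphs(cfg, X, map)
  message(sprintf("[denoise] SNR sweep over {%s} dB, %d rep(s), %s tau",
                  paste(cfg$snr_list, collapse = ", "), cfg$n_noise_reps,
                  cfg$tau_mode))
  res <- snr_sweep_experiment(graphs, X, cfg$snr_list, tau = cfg$tau,
                              seed = cfg$seeds$noise,
                              n_reps = cfg$n_noise_reps,
                              tau_mode = cfg$tau_mode)
  res$provenance <- provenance_of(cfg, list(
    profile = if (is.null(profile)) "normal" else profile$source))
  res$graphs <- graphs
  res
}

demographic_names <- c("age", "sex", "race", "ethnicity")

demographic_tests <- function(patients) {
  rows <- list()
  for (mn in metric_names) {
    for (dn in demographic_names) {
      x <- patients[[mn]]
      d <- patients[[dn]]
      if (is.null(d) || stats::sd(x) == 0) next
      if (is.numeric(d)) {
        ct <- stats::cor.test(x, d, method = "pearson")
        rows[[length(rows) + 1L]] <- data.frame(
          metric = mn, demographic = dn, test = "pearson",
          statistic = unname(ct$estimate), p_value = ct$p.value)
      } else {
        dd <- factor(d)
        if (nlevels(dd) < 2) next
        fit <- stats::aov(x ~ dd)
        p <- summary(fit)[[1]][["Pr(>F)"]][1]
        rows[[length(rows) + 1L]] <- data.frame(
          metric = mn, demographic = dn, test = "anova",
          statistic = summary(fit)[[1]][["F value"]][1], p_value = p)
      }
    }
  }
  do.call(rbind, rows)
}

#' Run the synthetic-cohort severity analysis
#'
#' Synthesizes a cohort of audiograms, converts each to a per-node
#' performance profile, builds each patient's signal matrix from a shared
#' normal-hearing matrix via the hearing-loss model, learns a smooth graph
#' per patient, computes the five structural metrics, and correlates them
#' with pure-tone-average severity. Demographic-versus-metric associations
#' are tested as a negative control (demographics are sampled independently
#' of severity). Patients whose graph learning fails are excluded and
#' listed in the report, never silently dropped.
#'
#' @param cfg An [experiment_config()].
#' @param n_patients Number of patients (>= 3); the reference analysis
#'   uses 224.
#' @return An object of class `cohort_report`: list with `patients` (one
#'   row per patient: metrics, pta_db, grade, demographics),
#'   `correlations` (metric, r, p, flag), `demographics` (association
#'   tests), `failed` (patient ids), `provenance`.
#' @export
run_cohort_analysis <- function(cfg, n_patients = 224) {
  stopifnot(inherits(cfg, "experiment_config"), n_patients >= 3)
  map <- build_tonotopic_map(cfg$n_nodes, cfg$f_min, cfg$f_max)
  message(sprintf("[cohort] synthesizing %d audiograms (seed %d)",
                  n_patients, cfg$seeds$cohort))
  cohort <- synthesize_cohort(n_patients, seed = cfg$seeds$cohort)
  message(sprintf("[stimuli] generating %d stimuli (seed %d)",
                  cfg$n_stimuli, cfg$seeds$stimuli))
  set <- generate_stimulus_set(cfg$n_stimuli, seed = cfg$seeds$stimuli,
                               level_range = cfg$level_range)
  message("[signals] building normal-hearing signal matrix")
  M_nh <- build_signal_matrix(set, map)$values
  lcfg <- smooth_learn_config(alpha = cfg$alpha, beta = cfg$beta,
                              max_iter = cfg$max_iter, tol = cfg$tol)
  rows <- list()
  failed <- character(0)
  for (k in seq_along(cohort)) {
    pid <- names(cohort)[k]
    a <- cohort[[k]]
    sg <- severity_grade(a)
    prof <- performance_profile(a, map)
    M <- impair_signal_matrix(M_nh, prof, map, smear_scale = cfg$smear_scale,
                              noise_scale = cfg$noise_scale,
                              seed = derive_seed(cfg$seeds$cohort, k))
    metrics <- tryCatch({
      g <- learn_graph_smooth(M, lcfg, map = map)
      if (cfg$threshold_metrics) g <- threshold_to_density(g, cfg$density_display)
      graph_metrics(g, seed = cfg$seeds$communities)
    }, error = function(e) {
      message(sprintf("[cohort] patient %s excluded: %s", pid, conditionMessage(e)))
      NULL
    })
    if (is.null(metrics)) {
      failed <- c(failed, pid)
      next
    }
    rows[[length(rows) + 1L]] <- cbind(
      data.frame(patient_id = pid, pta_db = sg$pta_db,
                 grade = as.character(sg$grade)),
      metrics,
      as.data.frame(a$meta))
  }
  patients <- do.call(rbind, rows)
  rownames(patients) <- NULL
  message(sprintf("[analyze] correlating metrics with severity (%d patients)",
                  nrow(patients)))
  structure(list(
    patients = patients,
    correlations = metric_severity_correlation(patients, patients$pta_db),
    demographics = demographic_tests(patients),
    failed = failed,
    provenance = provenance_of(cfg, list(n_patients = n_patients))
  ), class = "cohort_report")
}

#' @export
print.cohort_report <- function(x, ...) {
  cat(sprintf("Cohort report: %d patients (%d excluded)\n",
              nrow(x$patients), length(x$failed)))
  print(x$correlations, row.names = FALSE)
  invisible(x)
}

#' Export a denoising result as CSV files
#'
#' Writes `rmse.csv` (per-signal errors), `summary.csv` (mean and SD per
#' method and SNR) and `tests.csv` (pairwise Welch p-values) plus a
#' `provenance.json` sidecar into `dir`. Reruns of the same configuration
#' produce byte-identical files.
#'
#' @param res A `denoising_result`.
#' @param dir Output directory (created if needed).
#' @param force Overwrite existing files?
#' @return `dir`, invisibly.
#' @export
export_denoising_result <- function(res, dir, force = FALSE) {
  stopifnot(inherits(res, "denoising_result"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- file.path(dir, c("rmse.csv", "summary.csv", "tests.csv"))
  if (!force && any(file.exists(paths))) {
    stop("output files exist; use `force = TRUE` to overwrite", call. = FALSE)
  }
  utils::write.csv(res$rmse, paths[1], row.names = FALSE)
  utils::write.csv(res$summary, paths[2], row.names = FALSE)
  if (!is.null(res$tests)) utils::write.csv(res$tests, paths[3], row.names = FALSE)
  if (!is.null(res$provenance)) {
    jsonlite::write_json(res$provenance, file.path(dir, "provenance.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  invisible(dir)
}

#' Export a cohort report as CSV files
#'
#' Writes `patients.csv`, `correlations.csv`, `demographics.csv` and a
#' `provenance.json` sidecar into `dir`.
#'
#' @param report A `cohort_report`.
#' @param dir Output directory (created if needed).
#' @param force Overwrite existing files?
#' @return `dir`, invisibly.
#' @export
export_cohort_report <- function(report, dir, force = FALSE) {
  stopifnot(inherits(report, "cohort_report"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- file.path(dir, c("patients.csv", "correlations.csv",
                            "demographics.csv"))
  if (!force && any(file.exists(paths))) {
    stop("output files exist; use `force = TRUE` to overwrite", call. = FALSE)
  }
  utils::write.csv(report$patients, paths[1], row.names = FALSE)
  utils::write.csv(report$correlations, paths[2], row.names = FALSE)
  utils::write.csv(report$demographics, paths[3], row.names = FALSE)
  jsonlite::write_json(report$provenance, file.path(dir, "provenance.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}
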