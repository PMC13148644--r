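# Clinical audiograms: ingestion, severity grading, conversion to per-node
# performance factors, and a synthetic cohort generator.

#' Construct an audiogram
#'
#' @param freqs_hz Strictly increasing measured frequencies in Hz
#'   (typically 250-8000 Hz).
#' @param thresholds_db_hl Hearing thresholds in dB HL, within `[-10, 120]`.
#' @param meta Optional named list of demographics (age, sex, race,
#'   ethnicity, ...).
#' @param id Optional patient identifier.
#' @return An object of class `audiogram`.
#' @export
#' @examples
#' a <- audiogram(c(250, 500, 1000, 2000, 4000, 8000), rep(15, 6))
audiogram <- function(freqs_hz, thresholds_db_hl, meta = list(), id = NULL) {
  stopifnot(is.numeric(freqs_hz), is.numeric(thresholds_db_hl),
            length(freqs_hz) == length(thresholds_db_hl),
            length(freqs_hz) >= 1)
  if (is.unsorted(freqs_hz, strictly = TRUE)) {
    stop("`freqs_hz` must be strictly increasing", call. = FALSE)
  }
  if (anyNA(thresholds_db_hl) ||
      any(thresholds_db_hl < -10 | thresholds_db_hl > 120)) {
    stop("thresholds must be within [-10, 120] dB HL", call. = FALSE)
  }
  structure(list(freqs_hz = freqs_hz, thresholds_db_hl = thresholds_db_hl,
                 meta = meta, id = id), class = "audiogram")
}

#' @export
print.audiogram <- function(x, ...) {
  cat(sprintf("Audiogram%s: %d frequencies (%g-%g Hz), thresholds %g-%g dB HL\n",
              if (is.null(x$id)) "" else paste0(" ", x$id),
              length(x$freqs_hz), min(x$freqs_hz), max(x$freqs_hz),
              min(x$thresholds_db_hl), max(x$thresholds_db_hl)))
  invisible(x)
}

#' Read audiograms from a long-format CSV
#'
#' Expects columns `patient_id`, `freq_hz`, `threshold_db_hl`; any further
#' columns are treated as per-patient demographics. One `audiogram` is
#' returned per patient, rows sorted by frequency.
#'
#' @param path Path to a CSV file (or a connection readable by
#'   [utils::read.csv()]).
#' @return Named list of `audiogram` objects.
#' @export
#' @examples
#' path <- system.file("extdata", "synthetic_cohort_example.csv",
#'                     package = "cochleagraph")
#' auds <- read_audiograms(path)
#' severity_report(auds)
read_audiograms <- function(path) {
  df <- utils::read.csv(path, comment.char = "#")
  if (nrow(df) == 0) return(list())
  req <- c("patient_id", "freq_hz", "threshold_db_hl")
  if (!all(req %in% names(df))) {
    stop("CSV must contain columns patient_id, freq_hz, threshold_db_hl",
         call. = FALSE)
  }
  if (!is.numeric(df$threshold_db_hl) || anyNA(df$threshold_db_hl)) {
    stop("non-numeric threshold_db_hl values", call. = FALSE)
  }
  if (anyDuplicated(df[, c("patient_id", "freq_hz")])) {
    stop("duplicate (patient_id, freq_hz) rows", call. = FALSE)
  }
  demo_cols <- setdiff(names(df), req)
  out <- lapply(split(df, df$patient_id), function(d) {
    d <- d[order(d$freq_hz), ]
    meta <- if (length(demo_cols)) as.list(d[1, demo_cols, drop = FALSE]) else list()
    audiogram(d$freq_hz, d$threshold_db_hl, meta = meta, id = d$patient_id[1])
  })
  out[unique(df$patient_id)]
}

#' Write a collection of audiograms as long-format CSV
#'
#' @param audiograms Named list of `audiogram` objects.
#' @param path Output path.
#' @param force Overwrite an existing file?
#' @return The path, invisibly.
#' @export
write_audiograms <- function(audiograms, path, force = FALSE) {
  if (file.exists(path) && !force) {
    stop(sprintf("'%s' exists; use `force = TRUE` to overwrite", path), call. = FALSE)
  }
  ids <- names(audiograms)
  if (is.null(ids)) ids <- sprintf("P%03d", seq_along(audiograms))
  demo_cols <- unique(unlist(lapply(audiograms, function(a) names(a$meta))))
  rows <- lapply(seq_along(audiograms), function(k) {
    a <- audiograms[[k]]
    d <- data.frame(patient_id = ids[k], freq_hz = a$freqs_hz,
                    threshold_db_hl = a$thresholds_db_hl)
    for (cn in demo_cols) d[[cn]] <- if (is.null(a$meta[[cn]])) NA else a$meta[[cn]]
    d
  })
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE)
  invisible(path)
}

pta_frequencies <- c(500, 1000, 2000, 4000)

interp_threshold <- function(a, freqs) {
  if (length(a$freqs_hz) == 1) return(rep(a$thresholds_db_hl, length(freqs)))
  stats::approx(log(a$freqs_hz), a$thresholds_db_hl, xout = log(freqs),
                rule = 2)$y
}

#' Grade hearing-loss severity from an audiogram
#'
#' Computes the four-frequency pure-tone average (PTA: mean threshold at
#' 0.5, 1, 2 and 4 kHz, interpolated linearly in log-frequency where a PTA
#' frequency was not measured directly) and assigns the WHO 2021 grade:
#' `< 20` normal, `20-34.9` mild, `35-49.9` moderate, `50-64.9`
#' moderately_severe, `65-79.9` severe, `>= 80` profound.
#'
#' @param a An `audiogram` whose measured span covers 500-4000 Hz.
#' @return An object of class `severity_grade`: list with `pta_db` and
#'   `grade` (ordered factor).
#' @export
#' @examples
#' severity_grade(audiogram(c(250, 500, 1000, 2000, 4000, 8000), rep(85, 6)))
severity_grade <- function(a) {
  stopifnot(inherits(a, "audiogram"))
  if (min(a$freqs_hz) > min(pta_frequencies) ||
      max(a$freqs_hz) < max(pta_frequencies)) {
    stop("audiogram does not cover 500-4000 Hz; PTA is not interpolable",
         call. = FALSE)
  }
  pta <- mean(interp_threshold(a, pta_frequencies))
  grade <- cut(pta, breaks = c(-Inf, 20, 35, 50, 65, 80, Inf), right = FALSE,
               labels = c("normal", "mild", "moderate", "moderately_severe",
                          "severe", "profound"), ordered_result = TRUE)
  structure(list(pta_db = pta, grade = grade), class = "severity_grade")
}

#' @export
print.severity_grade <- function(x, ...) {
  cat(sprintf("PTA %.1f dB HL: %s\n", x$pta_db, as.character(x$grade)))
  invisible(x)
}

#' Normal-hearing performance profile
#'
#' @param map A `tonotopic_map`.
#' @return A `performance_profile` with all factors 1.
#' @export
normal_profile <- function(map) {
  stopifnot(inherits(map, "tonotopic_map"))
  structure(list(factors = rep(1, map$n_nodes), source = "normal"),
            class = "performance_profile")
}

#' Convert an audiogram into per-node performance factors
#'
#' Thresholds are interpolated to each node's characteristic frequency
#' linearly in log-frequency (end values held flat outside the measured
#' range) and mapped to a gain factor `10^(-HL / 40)` clipped to `[0, 1]`.
#' The compressive exponent (-HL/40 rather than the physical -HL/20)
#' preserves a graded dynamic range across the clinical severity scale:
#' 0 dB HL gives 1.0, 40 dB gives 0.1, 120 dB gives 1e-3.
#'
#' @param a An `audiogram` (nonempty).
#' @param map A `tonotopic_map`.
#' @return An object of class `performance_profile`: list with `factors`
#'   (length `map$n_nodes`, in `[0, 1]`) and `source`.
#' @export
#' @examples
#' map <- build_tonotopic_map(10)
#' a <- audiogram(c(250, 1000, 4000), c(40, 40, 40))
#' performance_profile(a, map)$factors
performance_profile <- function(a, map) {
  stopifnot(inherits(a, "audiogram"), inherits(map, "tonotopic_map"))
  if (length(a$freqs_hz) == 0) stop("empty audiogram", call. = FALSE)
  hl <- interp_threshold(a, map$cf_hz)
  factors <- pmin(1, pmax(0, 10^(-hl / 40)))
  structure(list(factors = factors,
                 source = if (is.null(a$id)) "audiogram" else a$id),
            class = "performance_profile")
}

#' @export
print.performance_profile <- function(x, ...) {
  cat(sprintf("Performance profile (%s): %d nodes, factors %.3g-%.3g\n",
              x$source, length(x$factors), min(x$factors), max(x$factors)))
  invisible(x)
}

cohort_shapes <- list(
  flat = function(f) rep(0, length(f)),
  gentle_slope = function(f) pmax(0, 10 * log2(f / 1000)),
  steep_slope = function(f) pmax(0, 30 * log2(f / 2000)),
  notched = function(f) 35 * exp(-(log2(f / 4000))^2 / (2 * 0.45^2))
)

#' Synthesize a cohort of audiograms
#'
#' Emulates a clinical hearing-loss cohort spanning normal hearing through
#' profound loss. Each patient draws (a) an overall severity grade uniform
#' over the six WHO bands with a target PTA uniform within the band
#' (profound capped at 110 dB), (b) a configuration shape from
#' {flat, gently sloping high-frequency, steeply sloping, notched}, and
#' (c) per-frequency Gaussian jitter with SD 5 dB, clipped to the clinical
#' range `[-10, 120]`. Demographics (age 1-18 years, sex, race, ethnicity)
#' are sampled independently of severity, so true demographic-metric
#' correlations are zero by construction. The reference analysis uses 224
#' patients.
#'
#' @param n_patients Number of patients (>= 1).
#' @param seed RNG seed; the same seed reproduces the cohort exactly.
#' @param freqs_hz Measured audiogram frequencies.
#' @return Named list of `audiogram` objects (`P001`, `P002`, ...).
#' @export
#' @examples
#' cohort <- synthesize_cohort(5, seed = 1)
#' sapply(cohort, function(a) severity_grade(a)$pta_db)
synthesize_cohort <- function(n_patients, seed = 1,
                              freqs_hz = c(250, 500, 1000, 2000, 4000, 8000)) {
  if (!is.numeric(n_patients) || length(n_patients) != 1L || n_patients < 1 ||
      n_patients != round(n_patients)) {
    stop("`n_patients` must be an integer >= 1", call. = FALSE)
  }
  band_lo <- c(0, 20, 35, 50, 65, 80)
  band_hi <- c(20, 35, 50, 65, 80, 110)
  at_pta <- freqs_hz %in% pta_frequencies |
    vapply(freqs_hz, function(f) any(abs(log(f / pta_frequencies)) < 1e-9), logical(1))
  out <- with_seed(seed, {
    lapply(seq_len(n_patients), function(j) {
      g <- sample(6, 1)
      target <- stats::runif(1, band_lo[g], band_hi[g])
      shape_fun <- cohort_shapes[[sample(length(cohort_shapes), 1)]]
      shape <- shape_fun(freqs_hz)
      offset <- target - mean(shape[at_pta])
      thr <- pmin(120, pmax(-10, shape + offset + stats::rnorm(length(freqs_hz), 0, 5)))
      meta <- list(
        age = sample(1:18, 1),
        sex = sample(c("female", "male"), 1),
        race = sample(c("white", "black", "asian", "multiracial", "other"), 1,
                      prob = c(0.45, 0.25, 0.1, 0.1, 0.1)),
        ethnicity = sample(c("hispanic", "non_hispanic"), 1, prob = c(0.25, 0.75))
      )
      audiogram(freqs_hz, thr, meta = meta, id = sprintf("P%03d", j))
    })
  })
  names(out) <- sprintf("P%03d", seq_len(n_patients))
  out
}

#' Severity report for a collection of audiograms
#'
#' @param audiograms Named list of `audiogram` objects.
#' @return A data frame with `patient_id`, `pta_db`, `grade`.
#' @export
severity_report <- function(audiograms) {
  ids <- names(audiograms)
  if (is.null(ids)) ids <- sprintf("P%03d", seq_along(audiograms))
  grades <- lapply(audiograms, severity_grade)
  data.frame(patient_id = ids,
             pta_db = vapply(grades, function(g) g$pta_db, numeric(1)),
             grade = vapply(grades, function(g) as.character(g$grade), character(1)),
             row.names = NULL)
}
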