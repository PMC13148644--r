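# Lightweight auditory-periphery simulator. Each inner-hair-cell node is a
# 4th-order gammatone channel at its characteristic frequency followed by
# transduction (rectification), membrane low-pass smoothing and a
# compressive nonlinearity. The node's graph signal for a stimulus is the
# time-mean of this response.

human_erb <- function(cf_hz) 24.7 * (4.37 * cf_hz / 1000 + 1)

# FFT of the zero-padded, peak-gain-normalized 4th-order gammatone impulse
# response. Returned vector has length nfft.
gammatone_spectrum <- function(cf, fs, n_ir, nfft) {
  t <- (seq_len(n_ir) - 1) / fs
  b <- 1.019 * human_erb(cf)
  g <- t^3 * exp(-2 * pi * b * t) * cos(2 * pi * cf * t)
  G <- stats::fft(c(g, numeric(nfft - n_ir)))
  G / max(Mod(G))
}

ihc_lowpass <- function(x, fs, fc = 1000) {
  a <- exp(-2 * pi * fc / fs)
  y <- stats::filter((1 - a) * x, a, method = "recursive")
  # stats::filter returns ts/matrix; strip attributes
  if (is.matrix(x)) matrix(as.numeric(y), nrow = nrow(x)) else as.numeric(y)
}

ihc_compress <- function(x, exponent = 0.6) x^exponent

#' Simulate an inner hair cell's response to a stimulus
#'
#' Processing chain: (1) 4th-order gammatone band-pass filter centered at
#' `cf` with bandwidth from the standard human ERB formula
#' `ERB = 24.7 (4.37 f/1000 + 1)`; (2) multiplication by the node's
#' `performance` factor (1 = normal hearing, 0 = dead region); (3) half-wave
#' rectification; (4) first-order low-pass at 1 kHz (membrane smoothing);
#' (5) instantaneous compressive nonlinearity `y^0.6`. The result is a
#' nonnegative time series whose time-mean is the node's scalar graph
#' signal.
#'
#' @param stimulus A `stimulus` (see [generate_stimulus_set()]).
#' @param cf Characteristic frequency in Hz.
#' @param performance Gain factor in `[0, 1]`.
#' @return Nonnegative numeric vector, same length as the stimulus waveform.
#' @export
#' @examples
#' s <- generate_stimulus_set(1, seed = 1)$stimuli[[1]]
#' r <- simulate_ihc_response(s, cf = 1000)
#' mean(r)
simulate_ihc_response <- function(stimulus, cf, performance = 1) {
  stopifnot(inherits(stimulus, "stimulus"))
  if (length(stimulus$waveform) == 0) {
    stop("stimulus waveform is empty", call. = FALSE)
  }
  stopifnot_scalar_number(cf, "cf", min = 1e-3)
  stopifnot_scalar_number(performance, "performance", min = 0, max = 1)
  x <- stimulus$waveform
  fs <- stimulus$sample_rate
  n <- length(x)
  nfft <- stats::nextn(2L * n - 1L, c(2, 3, 5))
  G <- gammatone_spectrum(cf, fs, n, nfft)
  X <- stats::fft(c(x, numeric(nfft - n)))
  y <- Re(stats::fft(X * G, inverse = TRUE))[seq_len(n)] / nfft
  r <- pmax(performance * y, 0)
  ihc_compress(ihc_lowpass(r, fs))
}

# Batch path used by build_signal_matrix: identical pipeline, all stimuli of
# equal length processed per node as one matrix.
nh_signal_matrix <- function(set, map) {
  lens <- vapply(set$stimuli, function(s) length(s$waveform), integer(1))
  stopifnot(length(unique(lens)) == 1L)
  n <- lens[1]
  fs <- set$sample_rate
  nfft <- stats::nextn(2L * n - 1L, c(2, 3, 5))
  X <- stats::mvfft(vapply(set$stimuli,
                           function(s) c(s$waveform, numeric(nfft - n)),
                           numeric(nfft)))
  M <- matrix(0, map$n_nodes, set$n)
  for (i in seq_len(map$n_nodes)) {
    G <- gammatone_spectrum(map$cf_hz[i], fs, n, nfft)
    Y <- Re(stats::mvfft(X * G, inverse = TRUE))[seq_len(n), , drop = FALSE] / nfft
    R <- ihc_compress(ihc_lowpass(pmax(Y, 0), fs))
    M[i, ] <- colMeans(R)
  }
  M
}

#' Apply a hearing-loss performance profile to a clean signal matrix
#'
#' Models the three canonical consequences of sensorineural hearing loss on
#' the per-node scalar graph signals of a normal-hearing matrix:
#'
#' * **Sensitivity loss**: because the transduction chain is homogeneous in
#'   its input gain, scaling the gammatone output by the performance factor
#'   `p` scales the scalar graph signal by exactly `p^0.6`; this closed form
#'   is applied per node.
#' * **Loss of frequency selectivity**: broadened cochlear tuning is modeled
#'   as Gaussian smearing of the signal matrix across tonotopically
#'   neighboring nodes, with kernel SD (in normalized place units)
#'   `smear_scale * HL / 120` where `HL = -40 log10(p)` dB is the node's
#'   equivalent hearing level.
#' * **Elevated internal noise**: seeded additive Gaussian noise with
#'   per-node SD `noise_scale * (HL / 120) * RMS(row)`, truncated at zero to
#'   keep signals nonnegative. The default `noise_scale = 1.3` makes a
#'   total-loss (120 dB HL) node's signals carry roughly -2.3 dB internal
#'   signal-to-noise ratio relative to their clean counterparts.
#'
#' For an all-unity profile the matrix is returned unchanged; for an
#' all-zero profile it is identically zero.
#'
#' @param M Numeric node x stimulus matrix (or `signal_matrix`).
#' @param profile A `performance_profile`.
#' @param map The `tonotopic_map` of the rows.
#' @param smear_scale Selectivity-loss kernel scale in place units per full
#'   (120 dB) loss.
#' @param noise_scale Internal-noise scale per full loss.
#' @param seed RNG seed for the internal noise.
#' @return A matrix of the same shape, entries finite and >= 0.
#' @export
impair_signal_matrix <- function(M, profile, map, smear_scale = 0.10,
                                 noise_scale = 1.3, seed = 1) {
  if (inherits(M, "signal_matrix")) M <- M$values
  stopifnot(inherits(profile, "performance_profile"),
            inherits(map, "tonotopic_map"),
            nrow(M) == map$n_nodes,
            length(profile$factors) == map$n_nodes)
  p <- pmin(1, pmax(profile$factors, 1e-3))
  hl <- -40 * log10(p)                       # equivalent dB HL per node
  gain <- profile$factors^0.6                # exact homogeneity of the chain
  sev <- hl / 120
  # tonotopic smearing: row i becomes a kernel-weighted average of rows
  sigma <- smear_scale * sev
  out <- M
  for (i in seq_len(nrow(M))) {
    if (sigma[i] > 1e-9) {
      kw <- exp(-(map$place - map$place[i])^2 / (2 * sigma[i]^2))
      kw <- kw / sum(kw)
      out[i, ] <- as.numeric(kw %*% M)
    }
  }
  out <- out * gain
  if (noise_scale > 0 && any(sev > 0)) {
    sds <- noise_scale * sev * sqrt(rowMeans(out^2))
    noise <- with_seed(seed, matrix(stats::rnorm(length(out)), nrow(out)) * sds)
    out <- pmax(out + noise, 0)
  }
  out
}

#' Build the node x stimulus graph-signal matrix
#'
#' Entry `(i, j)` is the time-mean of [simulate_ihc_response()] for
#' stimulus `j` at the CF of node `i`. With a non-normal performance
#' profile the hearing-loss model of [impair_signal_matrix()] is applied to
#' the normal-hearing matrix. The reference configuration is 100 nodes by
#' 1,000 stimuli.
#'
#' @param set A `stimulus_set`.
#' @param map A `tonotopic_map`.
#' @param profile A `performance_profile`, or `NULL` for normal hearing.
#' @param smear_scale,noise_scale,impair_seed Hearing-loss model parameters,
#'   see [impair_signal_matrix()]; `impair_seed` defaults to a stream
#'   derived from the stimulus-set seed.
#' @return An object of class `signal_matrix`: list with `values`
#'   (n_nodes x n_stimuli, finite, >= 0), `map_ref`, `profile_ref`.
#' @export
#' @examples
#' map <- build_tonotopic_map(10)
#' set <- generate_stimulus_set(4, seed = 1)
#' X <- build_signal_matrix(set, map)
#' dim(X$values)
build_signal_matrix <- function(set, map, profile = NULL, smear_scale = 0.10,
                                noise_scale = 1.3, impair_seed = NULL) {
  stopifnot(inherits(set, "stimulus_set"), inherits(map, "tonotopic_map"))
  if (!is.null(profile) && length(profile$factors) != map$n_nodes) {
    stop("profile length must equal the map's n_nodes", call. = FALSE)
  }
  M <- nh_signal_matrix(set, map)
  if (!is.null(profile) && !all(profile$factors == 1)) {
    if (is.null(impair_seed)) impair_seed <- derive_seed(set$seed, 7L)
    M <- impair_signal_matrix(M, profile, map, smear_scale = smear_scale,
                              noise_scale = noise_scale, seed = impair_seed)
  }
  src <- if (is.null(profile)) "normal" else profile$source
  structure(list(values = M, map_ref = map,
                 profile_ref = if (is.null(profile)) normal_profile(map) else profile,
                 source = src),
            class = "signal_matrix")
}

#' @export
print.signal_matrix <- function(x, ...) {
  cat(sprintf("Signal matrix: %d nodes x %d stimuli (profile: %s)\n",
              nrow(x$values), ncol(x$values), x$source))
  invisible(x)
}

#' Add white Gaussian noise at a target signal-to-noise ratio
#'
#' Noise variance is `P_signal * 10^(-snr_db / 10)` with `P_signal` the mean
#' squared value of `signal`; the draw is seeded and therefore reproducible.
#'
#' @param signal Numeric vector with positive power.
#' @param snr_db Target SNR in dB (negative = more noise than signal).
#' @param seed RNG seed.
#' @return `signal + noise`, same length.
#' @export
#' @examples
#' x <- sin(seq(0, 10, length.out = 100))
#' y <- add_noise_at_snr(x, snr_db = 0, seed = 1)
add_noise_at_snr <- function(signal, snr_db, seed = 1) {
  stopifnot(is.numeric(signal), length(signal) > 0)
  p_sig <- mean(signal^2)
  if (p_sig == 0) stop("`signal` has zero power; SNR is undefined", call. = FALSE)
  stopifnot_scalar_number(snr_db, "snr_db")
  sigma <- sqrt(p_sig * 10^(-snr_db / 10))
  with_seed(seed, signal + stats::rnorm(length(signal), 0, sigma))
}

#' Write / read a signal matrix as CSV
#'
#' Long-lived exchange format: a `node_id` column followed by one column per
#' stimulus (`s1`, `s2`, ...).
#'
#' @param X A `signal_matrix` or plain matrix.
#' @param path CSV path.
#' @param force Overwrite an existing file?
#' @return `write_signal_matrix`: the path, invisibly;
#'   `read_signal_matrix`: a numeric matrix.
#' @export
write_signal_matrix <- function(X, path, force = FALSE) {
  if (inherits(X, "signal_matrix")) X <- X$values
  if (file.exists(path) && !force) {
    stop(sprintf("'%s' exists; use `force = TRUE` to overwrite", path), call. = FALSE)
  }
  df <- data.frame(node_id = seq_len(nrow(X)), X)
  names(df) <- c("node_id", paste0("s", seq_len(ncol(X))))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_signal_matrix
#' @export
read_signal_matrix <- function(path) {
  df <- utils::read.csv(path)
  stopifnot("node_id" %in% names(df))
  as.matrix(df[order(df$node_id), setdiff(names(df), "node_id"), drop = FALSE])
}
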