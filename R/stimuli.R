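# Acoustic stimulus synthesis for the periphery simulator. Levels are in dB
# re an arbitrary full-scale reference: 100 dB corresponds to peak amplitude
# 1 for a pure tone.

raised_cosine_env <- function(n, fs, ramp_s = 0.005) {
  nr <- min(floor(ramp_s * fs), floor(n / 2))
  env <- rep(1, n)
  if (nr > 0) {
    r <- 0.5 * (1 - cos(pi * seq_len(nr) / nr))
    env[seq_len(nr)] <- r
    env[(n - nr + 1):n] <- rev(r)
  }
  env
}

level_to_amp <- function(level_db) 10^((level_db - 100) / 20)

new_stimulus <- function(waveform, sample_rate, duration, kind, params) {
  structure(list(waveform = waveform, sample_rate = sample_rate,
                 duration = duration, kind = kind, params = params),
            class = "stimulus")
}

synth_pure_tone <- function(freq, level_db, duration, fs) {
  n <- round(duration * fs)
  t <- (seq_len(n) - 1) / fs
  phase <- stats::runif(1, 0, 2 * pi)
  w <- level_to_amp(level_db) * sin(2 * pi * freq * t + phase) *
    raised_cosine_env(n, fs)
  new_stimulus(w, fs, duration, "pure_tone",
               list(freqs_hz = freq, level_db = level_db))
}

synth_tone_complex <- function(f0, level_db, duration, fs, f_max_hz) {
  n <- round(duration * fs)
  t <- (seq_len(n) - 1) / fs
  n_comp <- sample(2:5, 1)
  harmonic <- stats::runif(1) < 0.5
  if (harmonic) {
    ks <- seq_len(n_comp)
    freqs <- ks * f0
    freqs <- freqs[freqs <= f_max_hz]
    if (length(freqs) == 0) freqs <- f0
  } else {
    freqs <- sort(exp(stats::runif(n_comp, log(50), log(f_max_hz))))
  }
  amp <- level_to_amp(level_db) / sqrt(length(freqs))
  phases <- stats::runif(length(freqs), 0, 2 * pi)
  w <- rowSums(sapply(seq_along(freqs), function(i) {
    amp * sin(2 * pi * freqs[i] * t + phases[i])
  }))
  w <- w * raised_cosine_env(n, fs)
  new_stimulus(w, fs, duration, "tone_complex",
               list(freqs_hz = freqs, level_db = level_db, harmonic = harmonic))
}

synth_band_noise <- function(center, level_db, duration, fs, f_max_hz) {
  n <- round(duration * fs)
  lo <- max(50, center * 2^(-1 / 6))
  hi <- min(f_max_hz, center * 2^(1 / 6))
  x <- stats::rnorm(n)
  spec <- stats::fft(x)
  freqs <- (seq_len(n) - 1) * fs / n
  freqs <- pmin(freqs, fs - freqs)  # fold to physical frequency
  mask <- as.numeric(freqs >= lo & freqs <= hi)
  y <- Re(stats::fft(spec * mask, inverse = TRUE)) / n
  rms_target <- level_to_amp(level_db) / sqrt(2)  # match tone RMS convention
  y_rms <- sqrt(mean(y^2))
  if (y_rms > 0) y <- y * rms_target / y_rms
  y <- y * raised_cosine_env(n, fs)
  new_stimulus(y, fs, duration, "band_noise",
               list(freqs_hz = c(lo, hi), center_hz = center, level_db = level_db))
}

#' Generate a reproducible set of acoustic stimuli
#'
#' Draws stimuli with equal probability from pure tones, tone complexes
#' (2-5 harmonic or inharmonic partials) and 1/3-octave band noises.
#' Fundamental/center frequencies are log-uniform on `freq_range`
#' (default 50 Hz - 16 kHz), presentation levels uniform in `level_range`,
#' and every stimulus lasts `duration` seconds (default 100 ms). The set is
#' fully determined by `seed`: regenerating with the same arguments yields
#' bitwise-identical waveforms. The reference experiments use 1,000 stimuli
#' to probe functional links between cochlear nodes.
#'
#' @param n_stimuli Number of stimuli (>= 1).
#' @param seed RNG seed.
#' @param level_range Length-2 dB level range (uniform draw).
#' @param duration Stimulus duration in seconds.
#' @param sample_rate Sampling rate in Hz.
#' @param freq_range Log-uniform frequency draw range in Hz.
#' @return An object of class `stimulus_set`: list with `stimuli` (list of
#'   `stimulus`), `seed` and `n`.
#' @export
#' @examples
#' s <- generate_stimulus_set(5, seed = 1)
#' s$n
generate_stimulus_set <- function(n_stimuli, seed = 1, level_range = c(40, 90),
                                  duration = 0.1, sample_rate = 44100,
                                  freq_range = c(50, 16000)) {
  if (!is.numeric(n_stimuli) || length(n_stimuli) != 1L || n_stimuli < 1 ||
      n_stimuli != round(n_stimuli)) {
    stop("`n_stimuli` must be an integer >= 1", call. = FALSE)
  }
  stopifnot(length(level_range) == 2L, length(freq_range) == 2L,
            freq_range[1] > 0, freq_range[2] <= sample_rate / 2)
  n_stimuli <- as.integer(n_stimuli)
  stimuli <- with_seed(seed, {
    lapply(seq_len(n_stimuli), function(j) {
      kind <- sample(c("pure_tone", "tone_complex", "band_noise"), 1)
      f <- exp(stats::runif(1, log(freq_range[1]), log(freq_range[2])))
      lev <- stats::runif(1, level_range[1], level_range[2])
      switch(kind,
        pure_tone = synth_pure_tone(f, lev, duration, sample_rate),
        tone_complex = synth_tone_complex(f, lev, duration, sample_rate,
                                          freq_range[2]),
        band_noise = synth_band_noise(f, lev, duration, sample_rate,
                                      freq_range[2]))
    })
  })
  structure(list(stimuli = stimuli, seed = as.integer(seed), n = n_stimuli,
                 sample_rate = sample_rate, duration = duration,
                 level_range = level_range, freq_range = freq_range),
            class = "stimulus_set")
}

#' @export
print.stimulus_set <- function(x, ...) {
  kinds <- table(vapply(x$stimuli, function(s) s$kind, character(1)))
  cat(sprintf("Stimulus set: %d stimuli @ %g Hz, %.0f ms (seed %d)\n",
              x$n, x$sample_rate, x$duration * 1000, x$seed))
  print(kinds)
  invisible(x)
}

#' Write a stimulus as a 16-bit PCM WAV file
#'
#' Minimal RIFF/WAVE writer for auditioning synthesized stimuli. The
#' waveform is clipped to `[-1, 1]` before quantization.
#'
#' @param stimulus A `stimulus`.
#' @param path Output path.
#' @param force Overwrite an existing file?
#' @return The path, invisibly.
#' @export
write_stimulus_wav <- function(stimulus, path, force = FALSE) {
  stopifnot(inherits(stimulus, "stimulus"))
  if (file.exists(path) && !force) {
    stop(sprintf("'%s' exists; use `force = TRUE` to overwrite", path), call. = FALSE)
  }
  w <- pmin(1, pmax(-1, stimulus$waveform))
  pcm <- as.integer(round(w * 32767))
  fs <- as.integer(stimulus$sample_rate)
  con <- file(path, "wb")
  on.exit(close(con))
  data_bytes <- 2L * length(pcm)
  writeChar("RIFF", con, eos = NULL)
  writeBin(as.integer(36L + data_bytes), con, size = 4, endian = "little")
  writeChar("WAVEfmt ", con, eos = NULL)
  writeBin(16L, con, size = 4, endian = "little")
  writeBin(1L, con, size = 2, endian = "little")        # PCM
  writeBin(1L, con, size = 2, endian = "little")        # mono
  writeBin(fs, con, size = 4, endian = "little")
  writeBin(2L * fs, con, size = 4, endian = "little")   # byte rate
  writeBin(2L, con, size = 2, endian = "little")        # block align
  writeBin(16L, con, size = 2, endian = "little")       # bits/sample
  writeChar("data", con, eos = NULL)
  writeBin(data_bytes, con, size = 4, endian = "little")
  writeBin(pcm, con, size = 2, endian = "little")
  invisible(path)
}
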