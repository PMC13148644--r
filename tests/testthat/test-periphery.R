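test_that("stimulus sets are seeded, bounded in frequency, and well formed", {
  s1 <- generate_stimulus_set(30, seed = 5)
  s2 <- generate_stimulus_set(30, seed = 5)
  expect_identical(s1, s2)
  expect_equal(s1$n, 30L)
  for (st in s1$stimuli) {
    expect_equal(length(st$waveform), round(st$duration * st$sample_rate))
    expect_true(all(is.finite(st$waveform)))
    expect_true(all(st$params$freqs_hz >= 50 - 1e-9))
    expect_true(all(st$params$freqs_hz <= 16000 + 1e-9))
    expect_true(st$kind %in% c("pure_tone", "tone_complex", "band_noise"))
  }
  s3 <- generate_stimulus_set(30, seed = 6)
  expect_false(identical(s1$stimuli[[1]]$waveform, s3$stimuli[[1]]$waveform))
  expect_error(generate_stimulus_set(0), ">= 1")
})

test_that("IHC response is tuned to CF, gated by performance, zero for silence", {
  st <- cochleagraph:::synth_pure_tone(1000, 80, 0.1, 44100)
  on_cf <- mean(simulate_ihc_response(st, cf = 1000))
  off_cf <- mean(simulate_ihc_response(st, cf = 2000))
  expect_gt(on_cf, off_cf)

  expect_equal(simulate_ihc_response(st, 1000, performance = 0),
               rep(0, length(st$waveform)))
  silent <- st
  silent$waveform <- rep(0, length(st$waveform))
  expect_equal(simulate_ihc_response(silent, 1000), rep(0, 4410))
  expect_true(all(simulate_ihc_response(st, 1000) >= 0))
  empty <- st
  empty$waveform <- numeric(0)
  expect_error(simulate_ihc_response(empty, 1000), "empty")
})

test_that("pure tones excite the node nearest their frequency (95% within 1 node)", {
  map <- ref_map()
  set.seed(21)
  freqs <- exp(runif(200, log(50), log(16000)))
  tones <- lapply(freqs, function(f) {
    cochleagraph:::synth_pure_tone(f, 80, 0.1, 44100)
  })
  set <- structure(list(stimuli = tones, seed = 0L, n = 200L,
                        sample_rate = 44100, duration = 0.1),
                   class = "stimulus_set")
  M <- cochleagraph:::nh_signal_matrix(set, map)
  hits <- vapply(seq_along(freqs), function(j) {
    abs(which.max(M[, j]) -
          which.min(abs(log(map$cf_hz) - log(freqs[j])))) <= 1
  }, logical(1))
  expect_gte(mean(hits), 0.95)
})

test_that("scalar response is nondecreasing in the performance factor", {
  st <- cochleagraph:::synth_pure_tone(500, 70, 0.1, 44100)
  for (cf in c(400, 500, 2000)) {
    means <- vapply(seq(0, 1, by = 0.1), function(p) {
      mean(simulate_ihc_response(st, cf, performance = p))
    }, numeric(1))
    expect_true(all(diff(means) >= -1e-15))
  }
})

test_that("signal matrix has the contracted shape and gate propagation", {
  map <- build_tonotopic_map(12)
  set <- generate_stimulus_set(6, seed = 9)
  X <- build_signal_matrix(set, map)
  expect_equal(dim(X$values), c(12L, 6L))
  expect_true(all(is.finite(X$values)) && all(X$values >= 0))
  # batch path agrees with per-call simulation
  direct <- mean(simulate_ihc_response(set$stimuli[[3]], map$cf_hz[5]))
  expect_equal(X$values[5, 3], direct, tolerance = 1e-10)
  # all-unity profile identical; all-zero profile zero
  ones <- normal_profile(map)
  expect_equal(build_signal_matrix(set, map, ones)$values, X$values)
  zeros <- structure(list(factors = rep(0, 12), source = "dead"),
                     class = "performance_profile")
  expect_equal(build_signal_matrix(set, map, zeros,
                                   noise_scale = 0)$values,
               matrix(0, 12, 6))
  bad <- structure(list(factors = rep(1, 5), source = "short"),
                   class = "performance_profile")
  expect_error(build_signal_matrix(set, map, bad), "n_nodes")
})

test_that("impairment model is deterministic under seed and identity for normal", {
  map <- build_tonotopic_map(15)
  M <- matrix(abs(rnorm(15 * 10)), 15, 10)
  prof <- structure(list(factors = rep(c(1, 0.3), length.out = 15),
                         source = "toy"), class = "performance_profile")
  a <- impair_signal_matrix(M, prof, map, seed = 4)
  b <- impair_signal_matrix(M, prof, map, seed = 4)
  expect_identical(a, b)
  expect_true(all(a >= 0) && all(is.finite(a)))
  nh <- normal_profile(map)
  expect_equal(impair_signal_matrix(M, nh, map, seed = 4), M)
})

test_that("added noise hits the requested SNR and is seeded", {
  x <- sin(seq(0, 50, length.out = 1e5))
  y <- add_noise_at_snr(x, 0, seed = 3)
  noise_ratio <- mean((y - x)^2) / mean(x^2)
  expect_lt(abs(noise_ratio - 1), 0.05)
  y60 <- add_noise_at_snr(x, 60, seed = 3)
  expect_lt(sqrt(mean((y60 - x)^2)) / sqrt(mean(x^2)), 0.002)
  expect_identical(add_noise_at_snr(x, 0, seed = 3), y)
  expect_error(add_noise_at_snr(rep(0, 10), 0), "zero power")

  # measured SNR within 0.5 dB averaged over 100 seeds at length 100
  x100 <- sin(seq(0, 20, length.out = 100))
  snr_meas <- vapply(1:100, function(s) {
    w <- add_noise_at_snr(x100, 6, seed = s) - x100
    10 * log10(mean(x100^2) / mean(w^2))
  }, numeric(1))
  expect_lt(abs(mean(snr_meas) - 6), 0.5)
})

test_that("WAV export writes a well-formed mono PCM file", {
  st <- generate_stimulus_set(1, seed = 2)$stimuli[[1]]
  path <- withr::local_tempfile(fileext = ".wav")
  write_stimulus_wav(st, path)
  expect_equal(file.size(path), 44 + 2 * length(st$waveform))
  hdr <- readBin(path, "raw", 12)
  expect_equal(rawToChar(hdr[1:4]), "RIFF")
  expect_equal(rawToChar(hdr[9:12]), "WAVE")
  expect_error(write_stimulus_wav(st, path), "force")
})

test_that("signal matrices survive a CSV round trip", {
  M <- matrix(abs(rnorm(20)), 4, 5)
  path <- withr::local_tempfile(fileext = ".csv")
  write_signal_matrix(M, path)
  back <- read_signal_matrix(path)
  expect_equal(unname(as.matrix(back)), M, tolerance = 1e-12)
})
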