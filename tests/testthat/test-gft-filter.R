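test_that("spectral basis solves the Laplacian eigenproblem", {
  b <- spectral_basis(linear_graph(2))
  expect_equal(b$values, c(0, 2), tolerance = 1e-12)
  # connected graphs have exactly one (near-)zero eigenvalue
  for (g in list(linear_graph(7), complete_graph(5))) {
    vals <- spectral_basis(g)$values
    expect_lt(vals[1], 1e-8)
    expect_gt(vals[2], 1e-8)
  }
  map <- build_tonotopic_map(10)
  set <- generate_stimulus_set(8, seed = 71)
  g <- learn_graph_smooth(build_signal_matrix(set, map))
  b <- spectral_basis(g)
  expect_true(all(b$values >= 0))
  # reconstruction and orthonormality
  expect_equal(b$vectors %*% diag(b$values) %*% t(b$vectors), g$L,
               tolerance = 1e-8)
  expect_equal(crossprod(b$vectors), diag(g$n), tolerance = 1e-8)
})

test_that("Parseval identity holds for the GFT", {
  set.seed(73)
  g <- learn_graph_smooth(matrix(rnorm(12 * 30), 12, 30))
  b <- spectral_basis(g)
  for (k in 1:10) {
    x <- rnorm(12)
    expect_equal(sum(x^2), sum(gft(b, x)^2), tolerance = 1e-8)
    expect_equal(as.numeric(igft(b, gft(b, x))), x, tolerance = 1e-8)
  }
})

test_that("Tikhonov filter honors its limits", {
  set.seed(79)
  g <- learn_graph_smooth(matrix(rnorm(15 * 30), 15, 30))
  x <- rnorm(15)
  # tau = 0 is the identity
  expect_identical(tikhonov_denoise(g, x, tau = 0), x)
  # constant signals are untouched for every tau
  ones <- rep(3.7, 15)
  for (tau in c(0.1, 1, 100)) {
    expect_equal(tikhonov_denoise(g, ones, tau), ones, tolerance = 1e-9)
  }
  # tau -> Inf converges to the mean on a connected graph
  expect_equal(tikhonov_denoise(linear_graph(15), x, tau = 1e12),
               rep(mean(x), 15), tolerance = 1e-6)
  expect_error(tikhonov_denoise(g, x, tau = -1), "tau")
  expect_error(tikhonov_denoise(g, rnorm(9), tau = 1), "length")
})

test_that("filtering never increases the Laplacian quadratic form", {
  set.seed(83)
  g <- learn_graph_smooth(matrix(rnorm(15 * 30), 15, 30))
  for (tau in c(0.01, 1, 10)) {
    for (k in 1:5) {
      x <- rnorm(15)
      y <- tikhonov_denoise(g, x, tau)
      expect_lte(as.numeric(t(y) %*% g$L %*% y),
                 as.numeric(t(x) %*% g$L %*% x) + 1e-10)
    }
  }
})

test_that("rmse is the root mean squared error", {
  expect_equal(rmse(1:5, 1:5), 0)
  expect_equal(rmse(c(0, 0), c(3, 4)), sqrt(25 / 2))
  expect_equal(sqrt(25 / 2), 3.5355, tolerance = 1e-4)
  a <- rnorm(10); b <- rnorm(10)
  expect_equal(rmse(a, b), rmse(b, a))
  expect_error(rmse(1:3, 1:4), "length")
})

test_that("welch_ttest matches the closed-form statistic and conventions", {
  expect_equal(welch_ttest(c(1, 2, 3), c(2, 3, 4)),
               welch_by_hand(c(1, 2, 3), c(2, 3, 4)), tolerance = 1e-10)
  x <- c(1.2, 3.4, 2.2, 5.6)
  expect_equal(welch_ttest(x, x), 1)           # t = 0
  set.seed(89)
  expect_lt(welch_ttest(rnorm(1000), rnorm(1000, 1)), 1e-4)
  expect_warning(p <- welch_ttest(c(2, 2), c(2, 2)), "zero variance")
  expect_equal(p, 1)
})

test_that("SNR sweep is seeded, paired across methods, and noise-monotone", {
  map <- build_tonotopic_map(10)
  set <- generate_stimulus_set(12, seed = 97)
  X <- build_signal_matrix(set, map)
  graphs <- list(gsp_learned = learn_graph_smooth(X),
                 linear = linear_graph(map))
  res <- snr_sweep_experiment(graphs, X, snrs = c(-10, 0, 10), tau = 1,
                              seed = 5, n_reps = 2)
  expect_s3_class(res, "denoising_result")
  expect_equal(nrow(res$summary), 2 * 3)
  expect_equal(sort(unique(res$rmse$snr_db)), c(-10, 0, 10))
  expect_identical(res$rmse,
                   snr_sweep_experiment(graphs, X, c(-10, 0, 10), tau = 1,
                                        seed = 5, n_reps = 2)$rmse)
  expect_equal(nrow(res$tests), 3)   # one pair x three SNRs
  expect_error(snr_sweep_experiment(graphs, X, numeric(0)), "nonempty")
  # single method -> no pairwise tests
  solo <- snr_sweep_experiment(graphs["linear"], X, c(0), tau = 1, seed = 5)
  expect_null(solo$tests)

  # mean RMSE per method nonincreasing in SNR, averaged over 10 seeds
  agg <- matrix(0, 2, 3, dimnames = list(names(graphs), NULL))
  for (s in 1:10) {
    r <- snr_sweep_experiment(graphs, X, c(-10, 0, 10), tau = 1, seed = s)
    agg <- agg + vapply(c(-10, 0, 10), function(snr) {
      vapply(names(graphs), function(m) {
        mean(r$rmse$rmse[r$rmse$method == m & r$rmse$snr_db == snr])
      }, numeric(1))
    }, numeric(2))
  }
  for (m in 1:2) expect_true(all(diff(agg[m, ]) < 0))
})

test_that("oracle tau selection picks stronger smoothing at worse SNR", {
  map <- build_tonotopic_map(10)
  set <- generate_stimulus_set(20, seed = 98)
  X <- build_signal_matrix(set, map)
  graphs <- list(linear = linear_graph(map))
  res <- snr_sweep_experiment(graphs, X, snrs = c(-15, 10), seed = 6,
                              tau_mode = "oracle")
  taus <- res$taus
  expect_gte(taus$tau[taus$snr_db == -15], taus$tau[taus$snr_db == 10])
})
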