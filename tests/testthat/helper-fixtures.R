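# Shared fixtures (built lazily and cached for the session) and independent
# oracles used by several test files.

.fixture_env <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (!exists(name, envir = .fixture_env)) {
    assign(name, builder(), envir = .fixture_env)
  }
  get(name, envir = .fixture_env)
}

# Reference 100-node map and a 200-stimulus normal-hearing signal matrix,
# shared by the denoising and cohort experiments.
ref_map <- function() fixture("map", function() build_tonotopic_map(100))
ref_stimuli <- function() fixture("stimuli", function() {
  generate_stimulus_set(200, seed = 101)
})
ref_nh_matrix <- function() fixture("nh_matrix", function() {
  build_signal_matrix(ref_stimuli(), ref_map())
})

# Small helper graphs used by the metric fixtures.
graph_from_edges <- function(n, edges, weights = 1) {
  W <- matrix(0, n, n)
  weights <- rep_len(weights, nrow(edges))
  for (k in seq_len(nrow(edges))) {
    W[edges[k, 1], edges[k, 2]] <- weights[k]
    W[edges[k, 2], edges[k, 1]] <- weights[k]
  }
  cochlea_graph(W, "linear")
}

two_triangles <- function() {
  graph_from_edges(6, rbind(c(1, 2), c(2, 3), c(1, 3),
                            c(4, 5), c(5, 6), c(4, 6)))
}

complete_graph <- function(n) {
  W <- matrix(1, n, n)
  diag(W) <- 0
  cochlea_graph(W, "linear")
}

# A minimal tonotopic-map stand-in with prescribed CFs (base-first order),
# for graph constructions that only need frequencies.
toy_map <- function(cf_desc) {
  n <- length(cf_desc)
  place <- seq(1, 0, length.out = n)
  structure(list(n_nodes = n, cf_hz = cf_desc, place = place,
                 xyz_mm = spiral_coordinates(place),
                 orientation = "base_first"),
            class = "tonotopic_map")
}

# Independent brute-force minimizer of the log-degree-barrier objective
# (general-purpose optimizers on the 6 free weights of a 4-node instance):
# BFGS over log-weights plus box-constrained L-BFGS-B over the weights,
# multiple restarts, best value kept.
brute_force_objective <- function(Z, alpha, beta, restarts = 8) {
  n <- nrow(Z)
  ut <- which(upper.tri(Z))
  z <- Z[ut]
  m <- length(z)
  ei <- row(Z)[ut]
  ej <- col(Z)[ut]
  degs <- function(w) vapply(seq_len(n),
                             function(i) sum(w[ei == i | ej == i]), numeric(1))
  f_w <- function(w) {
    d <- degs(w)
    if (any(d <= 0)) return(1e10)
    2 * sum(z * w) - alpha * sum(log(d)) + beta * sum(w^2)
  }
  f_u <- function(u) f_w(exp(u))
  g_u <- function(u) {
    w <- exp(u)
    d <- degs(w)
    (2 * z - alpha * (1 / d[ei] + 1 / d[ej]) + 2 * beta * w) * w
  }
  best <- Inf
  for (r in seq_len(restarts)) {
    u0 <- log(stats::runif(m, 0.01, 1))
    o <- tryCatch(stats::optim(u0, f_u, g_u, method = "BFGS",
                               control = list(maxit = 2000, reltol = 1e-14)),
                  error = function(e) NULL)
    if (!is.null(o)) best <- min(best, o$value)
    w0 <- stats::runif(m, 0.05, 1)
    o2 <- tryCatch(stats::optim(w0, f_w, method = "L-BFGS-B", lower = 1e-12,
                                control = list(maxit = 2000, factr = 1e3)),
                   error = function(e) NULL)
    if (!is.null(o2)) best <- min(best, o2$value)
  }
  best
}

# Closed-form Welch t-test (statistic + Welch-Satterthwaite df), used as the
# oracle for the packaged wrapper.
welch_by_hand <- function(a, b) {
  va <- stats::var(a) / length(a)
  vb <- stats::var(b) / length(b)
  t <- (mean(a) - mean(b)) / sqrt(va + vb)
  df <- (va + vb)^2 / (va^2 / (length(a) - 1) + vb^2 / (length(b) - 1))
  2 * stats::pt(-abs(t), df)
}
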