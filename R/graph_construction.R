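# The four cochlea-graph construction methods: smooth-signal graph
# learning, signal correlation, inverse CF difference, and the linear
# tonotopic path; plus density thresholding.

graph_methods <- c("gsp_learned", "gsp_correlation", "frequency", "linear")

#' Construct a cochlea graph from a weight matrix
#'
#' @param W Symmetric nonnegative weight matrix with zero diagonal.
#' @param method One of `"gsp_learned"`, `"gsp_correlation"`, `"frequency"`,
#'   `"linear"`.
#' @param map Optional `tonotopic_map` carried for export/visualization.
#' @return An object of class `cochlea_graph`: list with `W`, `L`
#'   (combinatorial Laplacian `D - W`, cached), `method`, `map_ref`, `n`.
#' @export
cochlea_graph <- function(W, method, map = NULL) {
  method <- match.arg(method, graph_methods)
  W <- as.matrix(W)
  n <- nrow(W)
  if (ncol(W) != n) stop("`W` must be square", call. = FALSE)
  if (max(abs(W - t(W))) > 1e-10 * max(1, max(abs(W)))) {
    stop("`W` must be symmetric", call. = FALSE)
  }
  W <- (W + t(W)) / 2
  if (any(W < 0)) {
    if (min(W) < -1e-12 * max(1, max(W))) {
      stop("`W` must be nonnegative", call. = FALSE)
    }
    W[W < 0] <- 0
  }
  diag(W) <- 0
  L <- diag(rowSums(W)) - W
  structure(list(W = W, L = L, method = method, map_ref = map, n = n),
            class = "cochlea_graph")
}

#' @export
print.cochlea_graph <- function(x, ...) {
  m <- sum(x$W[upper.tri(x$W)] > 0)
  cat(sprintf("Cochlea graph [%s]: %d nodes, %d edges (density %.3f), total weight %.3g\n",
              x$method, x$n, m, m / (x$n * (x$n - 1) / 2),
              sum(x$W[upper.tri(x$W)])))
  invisible(x)
}

#' Configuration for smooth-signal graph learning
#'
#' @param alpha Log-degree barrier weight (> 0); rescales the learned
#'   weights without changing their structure when `beta = 0`.
#' @param beta Frobenius ridge (>= 0); spreads weight over near-tied
#'   candidate edges. The default 0.5 (on mean-normalized distances) keeps
#'   the learned graph from collapsing onto a bare nearest-neighbor path,
#'   so triangle-based metrics start from a non-degenerate baseline; `beta`
#'   must be > 0 when some pairwise signal distances are exactly zero
#'   (otherwise the objective is unbounded below).
#' @param max_iter Iteration cap for the primal-dual solver.
#' @param tol Relative convergence tolerance on the weight iterate.
#' @param standardize Z-score each node row across stimuli before computing
#'   pairwise distances, so the graph reflects signal co-variation rather
#'   than response amplitude.
#' @param normalize_distances Divide the squared-distance matrix by its mean
#'   off-diagonal value, the standard scale normalization that makes
#'   `alpha = 1` a usable default.
#' @return A list of class `smooth_learn_config`.
#' @export
smooth_learn_config <- function(alpha = 1, beta = 0.5, max_iter = 10000,
                                tol = 1e-8, standardize = TRUE,
                                normalize_distances = TRUE) {
  stopifnot_scalar_number(alpha, "alpha", min = 1e-12)
  stopifnot_scalar_number(beta, "beta", min = 0)
  stopifnot_scalar_number(tol, "tol", min = 1e-16)
  structure(list(alpha = alpha, beta = beta, max_iter = as.integer(max_iter),
                 tol = tol, standardize = standardize,
                 normalize_distances = normalize_distances),
            class = "smooth_learn_config")
}

#' Log-degree-barrier graph-learning objective
#'
#' Evaluates `||W o Z||_1 - alpha * 1' log(W 1) + (beta/2) ||W||_F^2` for a
#' symmetric weight matrix `W` and squared-distance matrix `Z` (both full
#' matrices; the L1 term therefore counts each edge twice, as in the matrix
#' form of the objective).
#'
#' @param W Symmetric nonnegative weight matrix (or a `cochlea_graph`).
#' @param Z Symmetric squared-distance matrix.
#' @param alpha,beta Objective parameters.
#' @return The objective value (scalar; `Inf` if any degree is zero and
#'   `alpha > 0`).
#' @export
smooth_graph_objective <- function(W, Z, alpha = 1, beta = 0) {
  if (inherits(W, "cochlea_graph")) W <- W$W
  d <- rowSums(W)
  if (any(d <= 0)) return(Inf)
  sum(W * Z) - alpha * sum(log(d)) + beta / 2 * sum(W^2)
}

# Pairwise squared-distance matrix used by the learner, exposed for tests.
signal_distance_matrix <- function(X, standardize = TRUE, normalize = TRUE) {
  if (inherits(X, "signal_matrix")) X <- X$values
  X <- as.matrix(X)
  if (nrow(X) < 2 || ncol(X) < 2) {
    stop("need at least 2 nodes and 2 stimuli", call. = FALSE)
  }
  if (standardize) {
    sds <- apply(X, 1, stats::sd)
    if (any(sds == 0)) {
      stop(sprintf("node %d has zero-variance signals; cannot standardize",
                   which(sds == 0)[1]), call. = FALSE)
    }
    X <- (X - rowMeans(X)) / sds
  }
  Z <- as.matrix(stats::dist(X))^2
  if (normalize) {
    mz <- mean(Z[upper.tri(Z)])
    if (mz == 0) {
      stop("all node rows are identical; the distance matrix is degenerate",
           call. = FALSE)
    }
    Z <- Z / mz
  }
  Z
}

#' Learn a cochlea graph from smooth graph signals
#'
#' Infers a weighted graph under the assumption that graph-signal values
#' change smoothly between connected nodes. With `z` the vector of pairwise
#' squared Euclidean distances between (standardized) node signal rows and
#' `w` the upper-triangular weight vector, the learner solves
#'
#' \deqn{\min_{w \ge 0} \; 2 z^\top w \;-\; \alpha 1^\top \log(S w)
#'       \;+\; \beta \lVert w \rVert^2,}
#'
#' the log-degree-barrier model (`S w` is the weighted degree vector; the
#' barrier forces every node to stay connected while the linear term favors
#' linking nodes with similar signals). The problem is solved with a
#' forward-backward-forward primal-dual splitting scheme in which both
#' proximal steps are closed-form: a shifted nonnegative clip for the
#' weights and a quadratic root for the degree barrier.
#'
#' @param X A `signal_matrix` or plain node x stimulus matrix (>= 2 nodes,
#'   >= 2 stimuli).
#' @param cfg A [smooth_learn_config()].
#' @param map Optional `tonotopic_map` (taken from `X` when available).
#' @return A `cochlea_graph` with method `"gsp_learned"`. Attributes:
#'   `objective` (final objective value), `Z` (the distance matrix actually
#'   used), `iterations`, `converged`.
#' @export
#' @examples
#' X <- matrix(rnorm(40), 4, 10)
#' g <- learn_graph_smooth(X, smooth_learn_config(beta = 0.1))
#' attr(g, "objective")
learn_graph_smooth <- function(X, cfg = smooth_learn_config(), map = NULL) {
  stopifnot(inherits(cfg, "smooth_learn_config"))
  if (inherits(X, "signal_matrix") && is.null(map)) map <- X$map_ref
  Z <- signal_distance_matrix(X, standardize = cfg$standardize,
                              normalize = cfg$normalize_distances)
  n <- nrow(Z)
  ut <- which(upper.tri(Z))
  z <- Z[ut]
  if (cfg$beta == 0 && any(z == 0)) {
    stop(paste("some node pairs have identical signals (zero distance);",
               "the objective is unbounded with beta = 0 - set beta > 0"),
         call. = FALSE)
  }
  m <- length(z)
  edge_i <- row(Z)[ut]
  edge_j <- col(Z)[ut]
  S <- Matrix::sparseMatrix(i = c(edge_i, edge_j), j = rep(seq_len(m), 2),
                            x = 1, dims = c(n, m))
  alpha <- cfg$alpha
  beta <- cfg$beta
  # FBF step size: bounded by the Lipschitz constant of the smooth term
  # (2*beta) plus the operator norm of S, sqrt(2*(n-1)).
  gamma <- 0.9 / (2 * beta + sqrt(2 * (n - 1)))
  w <- rep(mean(z), m)
  v <- as.numeric(S %*% w)
  converged <- FALSE
  iter <- 0L
  p1 <- w
  for (iter in seq_len(cfg$max_iter)) {
    Stv <- as.numeric(Matrix::crossprod(S, v))
    y1 <- w - gamma * (2 * beta * w + Stv)
    y2 <- v + gamma * as.numeric(S %*% w)
    p1 <- pmax(0, y1 - 2 * gamma * z)
    p2 <- (y2 - sqrt(y2^2 + 4 * alpha * gamma)) / 2
    q1 <- p1 - gamma * (2 * beta * p1 + as.numeric(Matrix::crossprod(S, p2)))
    q2 <- p2 + gamma * as.numeric(S %*% p1)
    w_new <- w - y1 + q1
    v_new <- v - y2 + q2
    rel <- sqrt(sum((w_new - w)^2)) / max(sqrt(sum(w^2)), 1e-12)
    w <- w_new
    v <- v_new
    if (rel < cfg$tol) {
      converged <- TRUE
      break
    }
  }
  if (!converged) {
    warning(sprintf("graph learning did not converge in %d iterations; returning last iterate",
                    cfg$max_iter), call. = FALSE)
  }
  w_out <- pmax(0, p1)   # the proximal point is always feasible
  W <- matrix(0, n, n)
  W[ut] <- w_out
  W <- W + t(W)
  g <- cochlea_graph(W, "gsp_learned", map = map)
  attr(g, "objective") <- smooth_graph_objective(W, Z, alpha, beta)
  attr(g, "Z") <- Z
  attr(g, "config") <- cfg
  attr(g, "iterations") <- iter
  attr(g, "converged") <- converged
  g
}

#' Correlation cochlea graph
#'
#' Weights are the Pearson correlation coefficients between the signal rows
#' of each node pair, with negative correlations clipped to zero so that
#' Laplacian-based filtering remains well defined.
#'
#' @param X A `signal_matrix` or plain node x stimulus matrix.
#' @param map Optional `tonotopic_map` (taken from `X` when available).
#' @return A `cochlea_graph` with method `"gsp_correlation"`.
#' @export
correlation_graph <- function(X, map = NULL) {
  if (inherits(X, "signal_matrix")) {
    if (is.null(map)) map <- X$map_ref
    X <- X$values
  }
  X <- as.matrix(X)
  sds <- apply(X, 1, stats::sd)
  if (any(sds == 0)) {
    stop(sprintf("node %d has zero-variance signals; correlation is undefined",
                 which(sds == 0)[1]), call. = FALSE)
  }
  W <- pmax(stats::cor(t(X)), 0)
  diag(W) <- 0
  cochlea_graph(W, "gsp_correlation", map = map)
}

#' Frequency cochlea graph
#'
#' Weights are the inverse absolute characteristic-frequency difference of
#' each node pair, normalized so the largest weight is 1.
#'
#' @param map A `tonotopic_map` with pairwise-distinct CFs.
#' @return A `cochlea_graph` with method `"frequency"`.
#' @export
frequency_graph <- function(map) {
  stopifnot(inherits(map, "tonotopic_map"))
  cf <- map$cf_hz
  D <- abs(outer(cf, cf, "-"))
  dup <- which(D == 0 & upper.tri(D), arr.ind = TRUE)
  if (nrow(dup) > 0) {
    stop(sprintf("nodes %d and %d share the same CF; inverse difference is undefined",
                 dup[1, 1], dup[1, 2]), call. = FALSE)
  }
  W <- 1 / D
  diag(W) <- 0
  W <- W / max(W)
  cochlea_graph(W, "frequency", map = map)
}

#' Linear (path) cochlea graph
#'
#' The traditional auditory-processing paradigm: unweighted links between
#' tonotopically adjacent nodes only.
#'
#' @param map A `tonotopic_map`, or a single integer node count.
#' @return A `cochlea_graph` with method `"linear"`.
#' @export
linear_graph <- function(map) {
  if (inherits(map, "tonotopic_map")) {
    n <- map$n_nodes
  } else {
    n <- as.integer(map)
    map <- NULL
  }
  if (n < 2) stop("need at least 2 nodes", call. = FALSE)
  W <- matrix(0, n, n)
  W[cbind(seq_len(n - 1), seq_len(n - 1) + 1)] <- 1
  W <- W + t(W)
  cochlea_graph(W, "linear", map = map)
}

#' Threshold a graph to a target edge density
#'
#' Keeps the `floor(target_density * n * (n - 1) / 2)` largest-weight edges
#' (ties broken deterministically toward the lower node-index pair) and
#' zeroes the rest; retained weights are unchanged. Used for display at the
#' conventional 0.25 density.
#'
#' @param g A `cochlea_graph`.
#' @param target_density Fraction of all possible edges to keep, in
#'   `(0, 1]`.
#' @return A `cochlea_graph` of the same method.
#' @export
threshold_to_density <- function(g, target_density) {
  stopifnot(inherits(g, "cochlea_graph"))
  stopifnot_scalar_number(target_density, "target_density", min = 1e-12, max = 1)
  n <- g$n
  m_keep <- floor(target_density * n * (n - 1) / 2)
  if (m_keep < 1) {
    stop("`target_density` would keep zero edges", call. = FALSE)
  }
  ut <- which(upper.tri(g$W))
  w <- g$W[ut]
  ord <- order(-w, row(g$W)[ut], col(g$W)[ut])
  keep <- ord[seq_len(min(m_keep, length(ord)))]
  W <- matrix(0, n, n)
  W[ut[keep]] <- w[keep]
  W <- W + t(W)
  cochlea_graph(W, g$method, map = g$map_ref)
}
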