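# Structural metrics of cochlea graphs: communities/modularity, global
# efficiency, weighted clustering, density, and severity correlations.

as_igraph <- function(g) {
  stopifnot(inherits(g, "cochlea_graph"))
  igraph::graph_from_adjacency_matrix(g$W, mode = "undirected", weighted = TRUE)
}

#' Detect communities by modularity maximization
#'
#' Louvain greedy modularity maximization on the weighted graph, seeded so
#' reruns are deterministic. The returned modularity is
#' `Q = (1/2m) * sum_ij [W_ij - k_i k_j / (2m)] delta(c_i, c_j)` with `k`
#' the weighted degree and `m` the total edge weight.
#'
#' @param g A `cochlea_graph` with at least one edge.
#' @param seed RNG seed for the (stochastic) Louvain sweep order.
#' @return An object of class `community_partition`: list with
#'   `assignment` (integer module id per node), `n_modules`, `Q`.
#' @export
#' @examples
#' g <- linear_graph(6)
#' detect_communities(g, seed = 1)
detect_communities <- function(g, seed = 1) {
  stopifnot(inherits(g, "cochlea_graph"))
  if (all(g$W == 0)) stop("graph has no edges; no communities to detect", call. = FALSE)
  ig <- as_igraph(g)
  cl <- with_seed(seed, igraph::cluster_louvain(ig, weights = igraph::E(ig)$weight))
  assignment <- as.integer(igraph::membership(cl))
  structure(list(assignment = assignment,
                 n_modules = length(unique(assignment)),
                 Q = igraph::modularity(ig, assignment,
                                        weights = igraph::E(ig)$weight)),
            class = "community_partition")
}

#' @export
print.community_partition <- function(x, ...) {
  cat(sprintf("Community partition: %d modules, Q = %.4f\n", x$n_modules, x$Q))
  invisible(x)
}

#' Modularity of an explicit partition
#'
#' @param g A `cochlea_graph`.
#' @param assignment Integer module id per node.
#' @return The weighted modularity Q.
#' @export
partition_modularity <- function(g, assignment) {
  ig <- as_igraph(g)
  igraph::modularity(ig, assignment, weights = igraph::E(ig)$weight)
}

#' Global efficiency of a weighted graph
#'
#' `E = (1 / (n (n - 1))) * sum_{i != j} 1 / d_ij` with `d_ij` the weighted
#' shortest-path length using edge length `1 / weight` (weights are
#' similarities, so strong edges are short). Unreachable pairs contribute 0.
#'
#' @param g A `cochlea_graph` (n >= 2).
#' @param weighted Use `1 / weight` edge lengths (default); otherwise hop
#'   counts.
#' @return Efficiency in `[0, 1]` for weight-normalized graphs.
#' @export
#' @examples
#' global_efficiency(linear_graph(3))  # 5/6
global_efficiency <- function(g, weighted = TRUE) {
  stopifnot(inherits(g, "cochlea_graph"), g$n >= 2)
  if (all(g$W == 0)) return(0)
  ig <- as_igraph(g)
  wts <- if (weighted) 1 / igraph::E(ig)$weight else NA
  D <- igraph::distances(ig, weights = wts)
  iD <- 1 / D
  diag(iD) <- 0
  iD[is.infinite(D)] <- 0
  sum(iD) / (g$n * (g$n - 1))
}

#' Average weighted clustering coefficient
#'
#' Geometric-mean (Onnela-type) weighted clustering: weights are first
#' normalized by the maximum weight, each triangle contributes the
#' geometric mean of its three normalized weights, and node `i`'s
#' coefficient divides the triangle intensity by `k_i (k_i - 1)` with `k_i`
#' the number of neighbors. Nodes with degree < 2 contribute 0; the mean is
#' over all nodes.
#'
#' @param g A `cochlea_graph` (n >= 3).
#' @return Average clustering in `[0, 1]`.
#' @export
#' @examples
#' W <- matrix(0, 3, 3); W[1,2] <- W[2,1] <- 1; W[2,3] <- W[3,2] <- 1
#' W[1,3] <- W[3,1] <- 0.5
#' average_clustering(cochlea_graph(W, "linear"))
average_clustering <- function(g) {
  stopifnot(inherits(g, "cochlea_graph"), g$n >= 3)
  mx <- max(g$W)
  if (mx == 0) return(0)
  Wh <- (g$W / mx)^(1 / 3)
  tri <- diag(Wh %*% Wh %*% Wh)
  k <- rowSums(g$W > 0)
  ci <- ifelse(k >= 2, tri / (k * (k - 1)), 0)
  mean(ci)
}

#' Edge density of a graph
#'
#' Number of strictly positive-weight edges divided by `n (n - 1) / 2`.
#'
#' @param g A `cochlea_graph` (n >= 2).
#' @return Density in `[0, 1]`.
#' @export
graph_density <- function(g) {
  stopifnot(inherits(g, "cochlea_graph"), g$n >= 2)
  sum(g$W[upper.tri(g$W)] > 0) / (g$n * (g$n - 1) / 2)
}

#' All five structural metrics of a cochlea graph
#'
#' @param g A `cochlea_graph`.
#' @param seed Seed passed to [detect_communities()].
#' @return A one-row data frame with `density`, `modularity`, `n_modules`,
#'   `global_efficiency`, `avg_clustering`.
#' @export
graph_metrics <- function(g, seed = 1) {
  part <- detect_communities(g, seed = seed)
  data.frame(density = graph_density(g),
             modularity = part$Q,
             n_modules = part$n_modules,
             global_efficiency = global_efficiency(g),
             avg_clustering = average_clustering(g))
}

metric_names <- c("density", "modularity", "n_modules", "global_efficiency",
                  "avg_clustering")

#' Correlate graph metrics with hearing-loss severity
#'
#' Pearson correlation (with two-sided p-value) between each structural
#' metric and the per-patient pure-tone average. Metrics that are constant
#' across patients are flagged rather than failing.
#'
#' @param metrics Data frame with one row per patient containing the five
#'   metric columns (see [graph_metrics()]).
#' @param severities Numeric vector of per-patient PTA in dB HL.
#' @return Data frame with `metric`, `r`, `p`, `flag`.
#' @export
metric_severity_correlation <- function(metrics, severities) {
  stopifnot(is.data.frame(metrics), nrow(metrics) == length(severities),
            nrow(metrics) >= 3)
  if (stats::sd(severities) == 0) {
    stop("severities are constant; correlation is undefined", call. = FALSE)
  }
  rows <- lapply(metric_names, function(mn) {
    x <- metrics[[mn]]
    if (is.null(x)) stop(sprintf("metrics lacks column '%s'", mn), call. = FALSE)
    if (stats::sd(x) == 0) {
      data.frame(metric = mn, r = NA_real_, p = NA_real_,
                 flag = "constant_metric")
    } else {
      ct <- stats::cor.test(x, severities, method = "pearson")
      data.frame(metric = mn, r = unname(ct$estimate), p = ct$p.value,
                 flag = "ok")
    }
  })
  do.call(rbind, rows)
}
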