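# Graph serialization: GraphML (via igraph) and edge-list CSV, with node
# attributes for downstream visualization and a provenance sidecar.

attach_node_attributes <- function(ig, map) {
  if (!is.null(map)) {
    igraph::V(ig)$cf_hz <- map$cf_hz
    igraph::V(ig)$x_mm <- map$xyz_mm[, 1]
    igraph::V(ig)$y_mm <- map$xyz_mm[, 2]
    igraph::V(ig)$z_mm <- map$xyz_mm[, 3]
  }
  igraph::V(ig)$name <- paste0("n", seq_len(igraph::vcount(ig)))
  ig
}

write_provenance_sidecar <- function(path, provenance) {
  if (is.null(provenance)) return(invisible(NULL))
  jsonlite::write_json(provenance, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(NULL)
}

#' Export a cochlea graph
#'
#' Writes either GraphML (with `weight` edge attribute and `cf_hz`,
#' `x_mm`, `y_mm`, `z_mm` node attributes) or an edge-list CSV with columns
#' `node_a`, `node_b`, `weight`. A write followed by [import_graph()]
#' reproduces the weights to within 1e-12. When `provenance` is given, a
#' JSON sidecar (`<path>.json`) records it.
#'
#' @param g A `cochlea_graph`.
#' @param map Optional `tonotopic_map` (defaults to the graph's own).
#' @param path Output path.
#' @param format `"graphml"` or `"edgelist_csv"`.
#' @param force Overwrite an existing file?
#' @param provenance Optional list (config hash, seeds, ...) for the
#'   sidecar.
#' @return The path, invisibly.
#' @export
export_graph <- function(g, map = NULL, path, format = c("graphml", "edgelist_csv"),
                         force = FALSE, provenance = NULL) {
  stopifnot(inherits(g, "cochlea_graph"))
  format <- match.arg(format)
  if (file.exists(path) && !force) {
    stop(sprintf("'%s' exists; use `force = TRUE` to overwrite", path), call. = FALSE)
  }
  if (is.null(map)) map <- g$map_ref
  if (format == "graphml") {
    ig <- attach_node_attributes(as_igraph(g), map)
    igraph::write_graph(ig, path, format = "graphml")
  } else {
    ut <- which(upper.tri(g$W) & g$W > 0)
    df <- data.frame(node_a = row(g$W)[ut], node_b = col(g$W)[ut],
                     weight = g$W[ut])
    df <- df[order(df$node_a, df$node_b), ]
    con <- file(path, "w")
    writeLines("node_a,node_b,weight", con)
    writeLines(sprintf("%d,%d,%.17g", df$node_a, df$node_b, df$weight), con)
    close(con)
  }
  write_provenance_sidecar(path, provenance)
  invisible(path)
}

#' Import a cochlea graph written by [export_graph()]
#'
#' @param path Input path.
#' @param format `"graphml"` or `"edgelist_csv"`.
#' @param method Method tag for the reconstructed graph.
#' @param n Node count (required for edge lists whose trailing nodes are
#'   isolated; inferred otherwise).
#' @return A `cochlea_graph`.
#' @export
import_graph <- function(path, format = c("graphml", "edgelist_csv"),
                         method = "gsp_learned", n = NULL) {
  format <- match.arg(format)
  if (format == "graphml") {
    ig <- igraph::read_graph(path, format = "graphml")
    W <- as.matrix(igraph::as_adjacency_matrix(ig, attr = "weight", sparse = FALSE))
    g <- cochlea_graph(W, method)
    if (!is.null(igraph::vertex_attr(ig, "cf_hz"))) {
      attr(g, "cf_hz") <- igraph::V(ig)$cf_hz
      attr(g, "xyz_mm") <- cbind(x_mm = igraph::V(ig)$x_mm,
                                 y_mm = igraph::V(ig)$y_mm,
                                 z_mm = igraph::V(ig)$z_mm)
    }
    g
  } else {
    df <- utils::read.csv(path, comment.char = "#")
    if (is.null(n)) n <- max(df$node_a, df$node_b)
    W <- matrix(0, n, n)
    W[cbind(df$node_a, df$node_b)] <- df$weight
    W <- W + t(W)
    cochlea_graph(W, method)
  }
}
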