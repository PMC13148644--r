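# Tonotopic scaffold: place-frequency mapping and 3D spiral coordinates for
# the inner-hair-cell nodes of a cochlea graph.

#' Greenwood place-frequency map (human)
#'
#' Converts normalized cochlear place to characteristic frequency using the
#' Greenwood function `f = A * (10^(a * x) - k)` with the standard human
#' constants `A = 165.4`, `a = 2.1`, `k = 0.88`. `x` is the fractional
#' distance from the apex, so `x = 0` is the low-frequency apex
#' (about 19.9 Hz) and `x = 1` the high-frequency base (about 20.7 kHz).
#'
#' @param place Numeric vector of normalized distances from the apex in
#'   `[0, 1]`.
#' @param A,a,k Greenwood constants for the human cochlea.
#' @return Characteristic frequency in Hz, same length as `place`.
#' @seealso [greenwood_place()] for the inverse map.
#' @export
#' @examples
#' greenwood_cf(c(0, 0.5, 1))
greenwood_cf <- function(place, A = 165.4, a = 2.1, k = 0.88) {
  if (!is.numeric(place) || anyNA(place) || any(place < 0 | place > 1)) {
    stop("`place` must be numeric in [0, 1]", call. = FALSE)
  }
  A * (10^(a * place) - k)
}

#' Inverse Greenwood map: frequency to normalized place
#'
#' @param cf_hz Characteristic frequency in Hz; must lie within the range
#'   spanned by the Greenwood function on `[0, 1]`.
#' @inheritParams greenwood_cf
#' @return Normalized distance from the apex in `[0, 1]`.
#' @export
#' @examples
#' greenwood_place(greenwood_cf(0.3))
greenwood_place <- function(cf_hz, A = 165.4, a = 2.1, k = 0.88) {
  lo <- A * (1 - k)
  hi <- A * (10^a - k)
  if (!is.numeric(cf_hz) || anyNA(cf_hz) || any(cf_hz < lo * (1 - 1e-12) | cf_hz > hi * (1 + 1e-12))) {
    stop(sprintf("`cf_hz` must lie within the Greenwood range [%.3f, %.1f] Hz", lo, hi),
         call. = FALSE)
  }
  pmin(1, pmax(0, log10(cf_hz / A + k) / a))
}

#' Coordinates on a parametric cochlear spiral
#'
#' Places a normalized cochlear position on a conical helix of 2.75 turns
#' (the human convention), basal radius 5.0 mm tapering to 1.0 mm at the
#' apex, total height 5.0 mm. The accumulated angle is
#' `theta = 2.75 * 2 * pi * place`. Coordinates are for visualization and
#' export only; they never enter graph construction.
#'
#' @param place Numeric vector of normalized distances from the apex in
#'   `[0, 1]` (1 = base).
#' @param turns Number of helix turns.
#' @param r_base,r_apex Basal and apical radii in mm.
#' @param height Total helix height in mm.
#' @return A numeric matrix with columns `x_mm`, `y_mm`, `z_mm`.
#' @export
#' @examples
#' spiral_coordinates(c(0, 0.5, 1))
spiral_coordinates <- function(place, turns = 2.75, r_base = 5.0, r_apex = 1.0,
                               height = 5.0) {
  if (!is.numeric(place) || anyNA(place) || any(place < 0 | place > 1)) {
    stop("`place` must be numeric in [0, 1]", call. = FALSE)
  }
  theta <- turns * 2 * pi * place
  r <- r_apex + (r_base - r_apex) * place
  out <- cbind(x_mm = r * cos(theta), y_mm = r * sin(theta),
               z_mm = height * (1 - place))
  rownames(out) <- NULL
  out
}

#' Build the tonotopic node map of a cochlea graph
#'
#' Lays `n_nodes` inner-hair-cell nodes along the cochlea with equally
#' spaced normalized places and characteristic frequencies from the
#' Greenwood map, rescaled in the place domain so that the endpoint CFs are
#' exactly `f_min` and `f_max`. Node 1 is the base (highest CF), matching
#' the convention that connectivity matrices are labeled from high to low
#' characteristic frequency.
#'
#' @param n_nodes Number of nodes (>= 2); the reference configuration uses
#'   100.
#' @param f_min,f_max Frequency span in Hz, `0 < f_min < f_max`.
#' @return An object of class `tonotopic_map`: a list with `n_nodes`,
#'   `cf_hz` (strictly decreasing), `place` (strictly decreasing, endpoints
#'   1 and 0), `xyz_mm` (n x 3 matrix) and `orientation = "base_first"`.
#' @export
#' @examples
#' map <- build_tonotopic_map(100)
#' range(map$cf_hz)
build_tonotopic_map <- function(n_nodes = 100, f_min = 20, f_max = 20000) {
  if (!is.numeric(n_nodes) || length(n_nodes) != 1L || n_nodes < 2 ||
      n_nodes != round(n_nodes)) {
    stop("`n_nodes` must be an integer >= 2", call. = FALSE)
  }
  stopifnot_scalar_number(f_min, "f_min", min = 1e-9)
  stopifnot_scalar_number(f_max, "f_max")
  if (f_min >= f_max) stop("`f_min` must be < `f_max`", call. = FALSE)
  lo <- 165.4 * (1 - 0.88)
  f_min_g <- max(f_min, lo * (1 + 1e-9))  # keep inversion inside the map's range
  n_nodes <- as.integer(n_nodes)
  place <- seq(1, 0, length.out = n_nodes)      # base first
  x_min <- greenwood_place(f_min_g)
  x_max <- greenwood_place(min(f_max, greenwood_cf(1)))
  cf <- greenwood_cf(x_min + (x_max - x_min) * place)
  cf[1L] <- f_max
  cf[n_nodes] <- f_min
  structure(list(
    n_nodes = n_nodes,
    cf_hz = cf,
    place = place,
    xyz_mm = spiral_coordinates(place),
    orientation = "base_first"
  ), class = "tonotopic_map")
}

#' @export
print.tonotopic_map <- function(x, ...) {
  cat(sprintf("Tonotopic map: %d nodes, CF %.1f Hz (apex) to %.1f Hz (base), %s\n",
              x$n_nodes, min(x$cf_hz), max(x$cf_hz), x$orientation))
  invisible(x)
}

#' Export a tonotopic map as a node table
#'
#' Writes a CSV with columns `node_id`, `cf_hz`, `place`, `x_mm`, `y_mm`,
#' `z_mm`. Node ids start at 1 at the base.
#'
#' @param map A `tonotopic_map`.
#' @param path Output CSV path.
#' @param force Overwrite an existing file?
#' @return The path, invisibly.
#' @export
export_node_table <- function(map, path, force = FALSE) {
  stopifnot(inherits(map, "tonotopic_map"))
  if (file.exists(path) && !force) {
    stop(sprintf("'%s' exists; use `force = TRUE` to overwrite", path), call. = FALSE)
  }
  df <- data.frame(node_id = seq_len(map$n_nodes), cf_hz = map$cf_hz,
                   place = map$place, x_mm = map$xyz_mm[, 1],
                   y_mm = map$xyz_mm[, 2], z_mm = map$xyz_mm[, 3])
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
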