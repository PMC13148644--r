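# Internal helpers shared across modules.

#' Evaluate code under a temporary RNG seed
#'
#' Runs `code` with the global RNG seeded to `seed` and restores the previous
#' RNG state afterwards, so seeded operations never disturb the caller's
#' random stream.
#'
#' @param seed Integer seed.
#' @param code Expression to evaluate.
#' @return The value of `code`.
#' @keywords internal
#' @noRd
with_seed <- function(seed, code) {
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed)) {
    stop("`seed` must be a single finite number", call. = FALSE)
  }
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  }, add = TRUE)
  set.seed(as.integer(seed))
  force(code)
}

#' Derive a child seed from a parent seed and an offset
#'
#' Deterministic mixing that keeps results inside the 32-bit integer range,
#' used to give every stage (stimuli, noise replicate, patient, ...) its own
#' reproducible stream.
#'
#' @param seed Parent integer seed.
#' @param offset Nonnegative integer stream index.
#' @return A single integer in `[1, 2^31 - 2]`.
#' @export
#' @examples
#' derive_seed(42, 1)
derive_seed <- function(seed, offset = 0L) {
  s <- (as.double(seed) %% 2147483647) * 48271 + as.double(offset) * 1664525 + 12345
  as.integer(s %% 2147483646 + 1)
}

# FNV-1a over a canonical deparse; cheap content hash for provenance stamps.
config_hash <- function(x) {
  txt <- paste(deparse(x, control = c("keepNA", "keepInteger")), collapse = "")
  bytes <- utf8ToInt(txt)
  h <- 2166136261
  for (b in bytes) {
    h <- bitwXor(as.integer(h %% 2^31), b)
    h <- (h * 16777619) %% 2^31
  }
  sprintf("%08x", as.integer(h))
}

stopifnot_scalar_number <- function(x, name, min = -Inf, max = Inf) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x < min || x > max) {
    stop(sprintf("`%s` must be a single finite number in [%s, %s]", name,
                 format(min), format(max)), call. = FALSE)
  }
  invisible(x)
}
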