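# internal helpers shared across modules

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_arm <- function(...) stop(sprintf(...), call. = FALSE)
warn_arm <- function(...) warning(sprintf(...), call. = FALSE)

#' Run code with a temporary RNG seed
#'
#' Saves and restores `.Random.seed` so library code never perturbs the
#' caller's RNG stream.
#' @keywords internal
#' @noRd
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

# polynomial rolling hash of a character scalar, 8 hex digits; config
# fingerprints for run manifests (no digest dependency). Exact in doubles:
# h < 2^31 so h * 31 + b < 2^36 << 2^53.
poly_hash <- function(x) {
  bytes <- as.integer(charToRaw(paste(x, collapse = "\n")))
  h <- 5381
  for (b in bytes) h <- (h * 31 + b) %% 2147483647
  sprintf("%08x", h)
}

# derive a per-stage 31-bit seed from a global seed
stage_seed <- function(seed, index) {
  (as.numeric(seed) * 48271 + 11 * index) %% 2147483647
}

vnorm <- function(v) sqrt(sum(v^2))

# cross product, vectorized over rows of 3-col matrices
row_cross <- function(a, b) {
  cbind(a[, 2] * b[, 3] - a[, 3] * b[, 2],
        a[, 3] * b[, 1] - a[, 1] * b[, 3],
        a[, 1] * b[, 2] - a[, 2] * b[, 1])
}
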