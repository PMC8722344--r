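# internal helpers shared across modules

# Encode 0-based (u, v) pixel pairs as a single double key.
# Exact for u, v < 2^16 (image sides are far below that).
pix_key <- function(pixels) {
  if (nrow(pixels) == 0L) return(numeric(0))
  pixels[, 1L] * 65536 + pixels[, 2L]
}

key_to_pix <- function(keys) {
  u <- keys %/% 65536
  cbind(u = as.integer(u), v = as.integer(keys - u * 65536))
}

# Run `code` under a temporary RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

# depth lookup at 0-based pixel coordinates; depth is a height x width matrix
depth_at <- function(depth, pixels) {
  depth[cbind(pixels[, 2L] + 1L, pixels[, 1L] + 1L)]
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stopifnot_scalar_num <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stop(sprintf("'%s' must be a finite numeric scalar", name), call. = FALSE)
}
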