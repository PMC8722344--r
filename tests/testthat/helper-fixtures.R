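# shared fixtures and independent oracles

K_default <- function(f = 500, width = 640, height = 480)
  camera_intrinsics(f, f, width / 2, height / 2, width, height)

flat_depth <- function(d, width = 640, height = 480) matrix(d, height, width)

# literal argmax-and-zero re-implementation, written with explicit loops and
# kept independent of greedy_assign
oracle_greedy <- function(A, gamma) {
  pairs <- matrix(integer(0), 0, 2)
  repeat {
    best <- -Inf; br <- 0L; bc <- 0L
    for (r in seq_len(nrow(A))) {
      for (cc in seq_len(ncol(A))) {
        if (A[r, cc] > best) { best <- A[r, cc]; br <- r; bc <- cc }
      }
    }
    if (!is.finite(best) || !(best > gamma)) break
    pairs <- rbind(pairs, c(br, bc))
    A[br, ] <- -Inf
    A[, bc] <- -Inf
  }
  pairs
}

# per-pixel reprojection oracle for a pure camera translation (tx, ty, 0) and
# uniform scene depth d: plain arithmetic, no package geometry calls
oracle_shift_pixels <- function(pixels, d, tx, ty, K) {
  out <- NULL
  for (i in seq_len(nrow(pixels))) {
    x <- (pixels[i, 1] - K$cx) * d / K$fx - tx
    y <- (pixels[i, 2] - K$cy) * d / K$fy - ty
    u <- round(K$fx * x / d + K$cx)
    v <- round(K$fy * y / d + K$cy)
    if (u >= 0 && u < K$width && v >= 0 && v < K$height)
      out <- rbind(out, c(u, v))
  }
  if (is.null(out)) matrix(integer(0), 0, 2) else unique(out)
}

sort_pixels <- function(px) {
  px <- as.matrix(px)
  dimnames(px) <- NULL
  if (nrow(px) == 0) return(px)
  px[order(px[, 1], px[, 2]), , drop = FALSE]
}

expect_same_pixels <- function(a, b) {
  expect_equal(sort_pixels(a), sort_pixels(b), ignore_attr = TRUE)
}

# hand-built translating-object sequence: one w x h rectangle moving
# `step` pixels per frame along u, no depth/odometry
moving_rect_frames <- function(n_frames, w = 10, h = 10, step = 9,
                               u0 = 24, v0 = 100, sub = "SB") {
  lapply(seq_len(n_frames) - 1L, function(k)
    frame_record(k, list(rect_mask(u0 + step * k, v0, w, h,
                                   super_class = "plant", sub_class = sub))))
}

# small clean synthetic row used by several suites
small_row <- function(n_objects, seed, mode = "field", ...) {
  spec <- scene_spec(mode = mode, n_objects = n_objects,
                     width = 320, height = 240, fx = 300, fy = 300,
                     row_length = 480, size_range = c(12, 24), ...)
  render_sequence(generate_scene(spec, seed = seed),
                  traverse_spec(speed = 0.008, odo_noise = 0.001),
                  seed = seed + 1000L)
}
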