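#' Instance segmentation mask
#'
#' One segmented object in one frame: a set of 0-based `(u, v)` pixel
#' coordinates plus a coarse super-class label (e.g. `"plant"`,
#' `"sweet_pepper"`), a fine-grained sub-class label (species or ripeness),
#' and a detector confidence in `[0, 1]`.
#'
#' @param pixels Integer n x 2 matrix of 0-based `(u, v)` coordinates.
#' @param super_class Character super-class label.
#' @param sub_class Character sub-class label, or `NA`.
#' @param confidence Detection confidence in `[0, 1]`.
#' @param allow_empty Permit an empty pixel set (used by reprojection, which
#'   may legitimately drop every pixel).
#' @return An object of class `instance_mask`.
#' @export
instance_mask <- function(pixels, super_class = "object", sub_class = NA_character_,
                          confidence = 1, allow_empty = FALSE) {
  pixels <- as.matrix(pixels)
  if (ncol(pixels) != 2L && nrow(pixels) > 0L) stop("pixels must be n x 2")
  if (nrow(pixels) == 0L) {
    if (!allow_empty) stop("empty mask: no pixels")
    pixels <- matrix(integer(0), 0, 2)
  }
  storage.mode(pixels) <- "integer"
  if (nrow(pixels) && any(pixels < 0L)) stop("pixel coordinates must be >= 0")
  colnames(pixels) <- c("u", "v")
  if (!is.numeric(confidence) || confidence < 0 || confidence > 1)
    stop("confidence must lie in [0, 1]")
  structure(list(pixels = pixels, super_class = super_class,
                 sub_class = sub_class, confidence = confidence),
            class = "instance_mask")
}

#' @export
print.instance_mask <- function(x, ...) {
  cat(sprintf("<instance_mask> %d px  super=%s sub=%s conf=%.3f\n",
              nrow(x$pixels), x$super_class, x$sub_class, x$confidence))
  invisible(x)
}

#' @rdname instance_mask
#' @param mask An `instance_mask`.
#' @export
is_empty_mask <- function(mask) nrow(mask$pixels) == 0L

#' Build a rectangular mask (mainly for tests and simulation)
#'
#' @param u0,v0 Top-left pixel (0-based).
#' @param w,h Width and height in pixels.
#' @param ... Passed to [instance_mask()].
#' @export
rect_mask <- function(u0, v0, w, h, ...) {
  g <- expand.grid(u = seq.int(u0, u0 + w - 1L), v = seq.int(v0, v0 + h - 1L))
  instance_mask(as.matrix(g), ...)
}

#' Convert between a mask and a logical image matrix
#'
#' The matrix is height x width with `[v + 1, u + 1]` indexing, matching the
#' depth-image convention.
#' @param mask An [instance_mask()].
#' @param width,height Image size in pixels.
#' @export
mask_to_matrix <- function(mask, width, height) {
  m <- matrix(FALSE, height, width)
  if (nrow(mask$pixels))
    m[cbind(mask$pixels[, 2L] + 1L, mask$pixels[, 1L] + 1L)] <- TRUE
  m
}

#' @rdname mask_to_matrix
#' @param x Logical height x width matrix.
#' @param ... Passed to [instance_mask()].
#' @export
mask_from_matrix <- function(x, ...) {
  idx <- which(x, arr.ind = TRUE)
  instance_mask(cbind(u = idx[, 2L] - 1L, v = idx[, 1L] - 1L),
                ..., allow_empty = TRUE)
}

#' Mask geometry: bounding box, center of mass, dynamic radius
#'
#' The center is the arithmetic mean of pixel coordinates. The dynamic radius
#' (DR) is the greatest bounding-box extent in either axis, scaled by
#' `dr_weight`; extents are inclusive pixel counts (a 1-pixel object has
#' extent 1). A weight of 1.0 was found optimal among 0.5/0.75/1.0.
#'
#' @param mask A non-empty [instance_mask()].
#' @param dr_weight Positive scalar multiplying the bounding-box extent.
#' @return List with `bbox` (`u_min, v_min, u_max, v_max`, inclusive),
#'   `center` (`(u, v)` continuous), and `dynamic_radius` (pixels).
#' @export
mask_geometry <- function(mask, dr_weight = 1.0) {
  if (is_empty_mask(mask)) stop("empty mask has no geometry")
  if (dr_weight <= 0) stop("dr_weight must be positive")
  px <- mask$pixels
  bbox <- c(u_min = min(px[, 1L]), v_min = min(px[, 2L]),
            u_max = max(px[, 1L]), v_max = max(px[, 2L]))
  extent <- max(bbox["u_max"] - bbox["u_min"] + 1L,
                bbox["v_max"] - bbox["v_min"] + 1L)
  list(bbox = bbox,
       center = c(u = mean(px[, 1L]), v = mean(px[, 2L])),
       dynamic_radius = dr_weight * extent)
}

#' Estimate object surface area from registered depth
#'
#' Sums `d_i^2 / (fx * fy)` over the mask's pixels, using each pixel's
#' registered depth in meters. Pixels with invalid (zero) depth contribute
#' nothing — the estimate degrades toward an underestimate rather than
#' inventing geometry.
#'
#' @param mask An [instance_mask()].
#' @param depth Height x width depth matrix, meters, 0 = invalid.
#' @param K [camera_intrinsics()].
#' @return Area in square meters, with attribute `n_valid` giving the number
#'   of valid-depth pixels used.
#' @export
estimate_area <- function(mask, depth, K) {
  px <- mask$pixels
  if (nrow(px) == 0L) return(structure(0, n_valid = 0L))
  d <- depth_at(depth, px)
  ok <- is.finite(d) & d > 0
  structure(sum(d[ok]^2) / (K$fx * K$fy), n_valid = sum(ok))
}

#' Depth window for detection filtering
#'
#' @param tau_l Lower depth bound, meters.
#' @param tau_h Upper depth bound, meters, or `Inf` for unbounded.
#' @param q_threshold Minimum inlier percentage in `(0, 100]` for a detection
#'   to be kept (the paper-style default keeps masks with `q > 50`).
#' @export
depth_window <- function(tau_l = 0.4, tau_h = Inf, q_threshold = 50) {
  if (is.finite(tau_h) && tau_l >= tau_h) stop("tau_l must be below tau_h")
  if (q_threshold <= 0 || q_threshold > 100)
    stop("q_threshold must be in (0, 100]")
  structure(list(tau_l = tau_l, tau_h = tau_h, q_threshold = q_threshold),
            class = "depth_window")
}

#' Percentage of mask pixels inside a depth window
#'
#' `q = 100 * #(valid pixels with tau_l <= d <= tau_h) / #(valid pixels)`.
#' The denominator counts valid-depth pixels only, so depth holes do not
#' dilute the fraction; a mask with no valid depth gets `q = 0` (treated as
#' outside the window).
#'
#' @param mask A non-empty [instance_mask()].
#' @param depth Height x width depth matrix, meters, 0 = invalid.
#' @param window A [depth_window()].
#' @return Percentage in `[0, 100]`.
#' @export
depth_inlier_percentage <- function(mask, depth, window) {
  if (is_empty_mask(mask)) stop("empty mask")
  d <- depth_at(depth, mask$pixels)
  valid <- is.finite(d) & d > 0
  if (!any(valid)) return(0)
  100 * sum(d[valid] >= window$tau_l & d[valid] <= window$tau_h) / sum(valid)
}

#' Field-of-view filter with entry/exit zones
#'
#' Drops masks that are only partially visible: any mask whose bounding box
#' touches an image border is excluded, and a margin-wide entry zone and exit
#' zone along the travel axis additionally excludes masks entering or leaving
#' the frame.
#'
#' @param masks List of [instance_mask()].
#' @param width,height Image size in pixels.
#' @param margin Entry/exit zone width in pixels along the travel axis.
#' @param travel_axis `"u"` (robot travels along image columns) or `"v"`.
#' @return The retained subset of `masks`.
#' @export
fov_filter <- function(masks, width, height, margin = 20, travel_axis = c("u", "v")) {
  travel_axis <- match.arg(travel_axis)
  if (margin < 0) stop("margin must be >= 0")
  extent <- if (travel_axis == "u") width else height
  if (margin >= extent / 2)
    stop("margin must be below half the image extent along the travel axis")
  keep <- vapply(masks, function(m) {
    if (is_empty_mask(m)) return(FALSE)
    b <- mask_geometry(m)$bbox
    inside <- b["u_min"] > 0L && b["v_min"] > 0L &&
      b["u_max"] < width - 1L && b["v_max"] < height - 1L
    if (!inside) return(FALSE)
    if (travel_axis == "u")
      b["u_min"] >= margin && b["u_max"] <= width - 1L - margin
    else
      b["v_min"] >= margin && b["v_max"] <= height - 1L - margin
  }, logical(1))
  masks[keep]
}

#' Caliper-based area bounds for a fruit
#'
#' From hand measurements (height `h`, maximum width `w_max`, near-bottom
#' width `w_min`, all cm) computes a rectangular upper bound
#' `rec_A = h * w_max` and a trapezoidal lower bound
#' `trp_A = rec_A - h * (w_max - w_min)`.
#'
#' @param h,w_max,w_min Caliper measurements in cm, with `w_min <= w_max`.
#' @return Named vector `c(rec_A, trp_A)` in square centimeters.
#' @export
caliper_bounds <- function(h, w_max, w_min) {
  if (any(c(h, w_max, w_min) < 0)) stop("measurements must be non-negative")
  if (w_min > w_max) stop("w_min must not exceed w_max")
  rec_A <- h * w_max
  c(rec_A = rec_A, trp_A = rec_A - h * (w_max - w_min))
}
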