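#' Camera intrinsics
#'
#' Pinhole camera parameters. Pixel coordinates are 0-based with
#' `(u, v) = (column, row)`; continuous coordinates refer to pixel centers.
#'
#' @param fx,fy Focal lengths in pixels (positive).
#' @param cx,cy Principal point in pixels; must lie inside the image.
#' @param width,height Image size in pixels.
#' @return An object of class `camera_intrinsics`.
#' @examples
#' K <- camera_intrinsics(500, 500, 320, 240, 640, 480)
#' project(c(0, 0, 1), K)  # optical axis -> principal point
#' @export
camera_intrinsics <- function(fx, fy, cx, cy, width, height) {
  for (nm in c("fx", "fy", "cx", "cy", "width", "height"))
    stopifnot_scalar_num(get(nm), nm)
  if (fx <= 0 || fy <= 0) stop("focal lengths must be positive")
  if (cx < 0 || cx >= width || cy < 0 || cy >= height)
    stop("principal point must lie within the image")
  structure(list(fx = fx, fy = fy, cx = cx, cy = cy,
                 width = as.integer(width), height = as.integer(height)),
            class = "camera_intrinsics")
}

#' @export
print.camera_intrinsics <- function(x, ...) {
  cat(sprintf("<camera_intrinsics> %dx%d  f=(%.6g, %.6g)  c=(%.6g, %.6g)\n",
              x$width, x$height, x$fx, x$fy, x$cx, x$cy))
  invisible(x)
}

#' Rigid pose (SE(3)) as a 4x4 homogeneous matrix
#'
#' @param rotation 3x3 orthonormal rotation matrix with determinant +1.
#' @param translation Length-3 translation vector, meters.
#' @return A 4x4 homogeneous transform matrix.
#' @export
rigid_pose <- function(rotation = diag(3), translation = c(0, 0, 0)) {
  rotation <- as.matrix(rotation)
  if (!all(dim(rotation) == c(3L, 3L))) stop("rotation must be 3x3")
  if (max(abs(crossprod(rotation) - diag(3))) > 1e-8)
    stop("rotation is not orthonormal")
  if (abs(det(rotation) - 1) > 1e-8) stop("rotation must have determinant +1")
  if (length(translation) != 3L) stop("translation must have length 3")
  T <- diag(4)
  T[1:3, 1:3] <- rotation
  T[1:3, 4] <- translation
  T
}

#' Rotation about the camera/body z axis (yaw)
#' @param angle Angle in radians.
#' @return 3x3 rotation matrix.
#' @export
rotation_z <- function(angle) {
  c <- cos(angle); s <- sin(angle)
  matrix(c(c, s, 0, -s, c, 0, 0, 0, 1), 3, 3)
}

check_pose <- function(T, name = "pose") {
  T <- as.matrix(T)
  if (!all(dim(T) == c(4L, 4L))) stop(sprintf("'%s' must be 4x4", name))
  if (max(abs(T[4, ] - c(0, 0, 0, 1))) > 1e-9)
    stop(sprintf("'%s' has an invalid homogeneous bottom row", name))
  T
}

#' Project camera-frame points onto the image plane
#'
#' Pinhole projection `u = fx * x / z + cx`, `v = fy * y / z + cy`.
#' Continuous (sub-pixel) coordinates are returned; rounding onto the integer
#' grid is the caller's concern.
#'
#' @param points Numeric length-3 vector or an n x 3 matrix of camera-frame
#'   points in meters.
#' @param K [camera_intrinsics()].
#' @return An n x 2 matrix of `(u, v)` pixel coordinates.
#' @export
project <- function(points, K) {
  if (is.null(dim(points))) points <- matrix(points, ncol = 3, byrow = TRUE)
  if (ncol(points) != 3L) stop("points must be n x 3")
  z <- points[, 3L]
  if (any(!is.finite(z)) || any(z <= 0))
    stop("cannot project points with non-positive depth")
  cbind(u = K$fx * points[, 1L] / z + K$cx,
        v = K$fy * points[, 2L] / z + K$cy)
}

#' Back-project pixels into the camera frame
#'
#' Inverse pinhole model: `x = (u - cx) d / fx`, `y = (v - cy) d / fy`,
#' `z = d`.
#'
#' @param pixels Length-2 vector or n x 2 matrix of `(u, v)` coordinates.
#' @param depth Depth in meters; scalar or length n. Zero marks invalid depth
#'   and is rejected.
#' @param K [camera_intrinsics()].
#' @return An n x 3 matrix of camera-frame points, meters.
#' @export
backproject <- function(pixels, depth, K) {
  if (is.null(dim(pixels))) pixels <- matrix(pixels, ncol = 2, byrow = TRUE)
  if (ncol(pixels) != 2L) stop("pixels must be n x 2")
  if (length(depth) == 1L) depth <- rep(depth, nrow(pixels))
  if (any(!is.finite(depth)) || any(depth <= 0))
    stop("invalid depth: all depths must be positive and finite")
  cbind(x = (pixels[, 1L] - K$cx) * depth / K$fx,
        y = (pixels[, 2L] - K$cy) * depth / K$fy,
        z = depth)
}

#' Relative camera transform between two odometry poses
#'
#' Conjugates the relative wheel-odometry motion into the camera frame:
#' `H_ij = E^-1 (W_j^-1 W_i) E`, mapping camera-frame points of frame i into
#' camera frame j. `W_i`, `W_j` are world-from-body poses; `E` maps the camera
#' frame into the odometry body frame.
#'
#' @param W_i,W_j 4x4 world-from-body odometry poses of frames i and j.
#' @param E 4x4 camera-to-body extrinsics (default identity).
#' @return A 4x4 transform mapping frame-i camera points into frame j.
#' @export
relative_camera_transform <- function(W_i, W_j, E = diag(4)) {
  W_i <- check_pose(W_i, "W_i"); W_j <- check_pose(W_j, "W_j")
  E <- check_pose(E, "E")
  solve(E) %*% solve(W_j) %*% W_i %*% E
}

#' Apply a homogeneous transform to 3-D points
#' @param H 4x4 transform.
#' @param points n x 3 matrix of points.
#' @return n x 3 matrix of transformed points.
#' @export
transform_points <- function(H, points) {
  if (is.null(dim(points))) points <- matrix(points, ncol = 3, byrow = TRUE)
  out <- cbind(points, 1) %*% t(H)
  out[, 1:3, drop = FALSE]
}

#' Reproject an instance mask into another frame
#'
#' Every mask pixel with valid depth is back-projected with its own depth,
#' moved by `H`, re-projected, and rounded to the nearest pixel (ties to
#' even, R's default). Pixels with invalid (zero) depth, pixels transformed
#' behind the camera, and pixels landing outside the image are dropped. The
#' result keeps the source mask's class labels and confidence; it may be
#' empty, which the tracker treats as unmatched rather than as an error.
#'
#' @param mask [instance_mask()] in the geometry of the source frame.
#' @param depth Either a height x width depth matrix (meters, 0 = invalid)
#'   registered to the source frame, or a numeric vector of per-pixel depths
#'   aligned with `mask$pixels`.
#' @param H 4x4 transform from the source camera frame to the target camera
#'   frame (see [relative_camera_transform()]).
#' @param K [camera_intrinsics()] (shared by both frames).
#' @return An [instance_mask()] in the target frame's pixel grid.
#' @export
reproject_mask <- function(mask, depth, H, K) {
  stopifnot(inherits(mask, "instance_mask"))
  px <- mask$pixels
  d <- if (is.matrix(depth)) depth_at(depth, px) else as.numeric(depth)
  if (!is.matrix(depth) && length(d) != nrow(px))
    stop("per-pixel depth vector must align with mask pixels")
  ok <- is.finite(d) & d > 0
  if (!any(ok)) return(empty_mask_like(mask))
  pts <- backproject(px[ok, , drop = FALSE], d[ok], K)
  pts <- transform_points(H, pts)
  front <- pts[, 3L] > 0
  if (!any(front)) return(empty_mask_like(mask))
  uv <- project(pts[front, , drop = FALSE], K)
  u <- as.integer(round(uv[, 1L]))
  v <- as.integer(round(uv[, 2L]))
  keep <- u >= 0L & u < K$width & v >= 0L & v < K$height
  px2 <- unique(cbind(u = u[keep], v = v[keep]))
  instance_mask(px2, super_class = mask$super_class,
                sub_class = mask$sub_class, confidence = mask$confidence,
                allow_empty = TRUE)
}

empty_mask_like <- function(mask) {
  instance_mask(matrix(integer(0), 0, 2), super_class = mask$super_class,
                sub_class = mask$sub_class, confidence = mask$confidence,
                allow_empty = TRUE)
}
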