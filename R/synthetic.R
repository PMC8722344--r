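#' Synthetic scene specification
#'
#' Describes a static row scene the simulator renders as a robot traverse.
#' `"field"` mode emulates a downward-facing camera over a ground plane with
#' many small objects of skewed species frequencies (sugar-beet-like);
#' `"wall"` mode emulates a sideways-facing camera on a crop wall with a
#' second distractor layer beyond a metric depth boundary (glasshouse heat
#' rails, ~1.05 m from the sensor).
#'
#' Default class frequencies follow the two datasets' training-set label
#' distributions, so class imbalance effects are reproduced.
#'
#' @param mode `"field"` or `"wall"`.
#' @param n_objects Number of near-layer (countable) objects.
#' @param size_range Object pixel diameter range (min, max).
#' @param class_freqs Named numeric vector of sub-class frequencies (summing
#'   to 1); default is the mode's dataset-like distribution.
#' @param object_depth Camera-to-object distance, meters (ground plane in
#'   field mode, near crop layer in wall mode).
#' @param distractor_depth Depth of the distractor layer (wall mode), meters;
#'   must exceed `object_depth`.
#' @param n_distractors Number of distractor-layer objects (wall mode).
#' @param bg_depth Background depth, meters (defaults: ground plane depth in
#'   field mode, 3 m in wall mode).
#' @param width,height,fx,fy,cx,cy Camera model (pixels).
#' @param row_length Length of the strip objects are scattered over, pixels
#'   at `object_depth`.
#' @param hole_rate i.i.d. probability that a depth pixel is invalid (0),
#'   emulating stereo registration holes.
#' @param min_gap Minimum clearance between object bounding circles, pixels.
#' @export
scene_spec <- function(mode = c("field", "wall"), n_objects = 20,
                       size_range = c(12, 30), class_freqs = NULL,
                       object_depth = if (mode == "field") 0.8 else 0.7,
                       distractor_depth = 1.3, n_distractors = if (mode == "wall") 8 else 0,
                       bg_depth = if (mode == "field") object_depth else 3.0,
                       width = 640, height = 480, fx = 500, fy = 500,
                       cx = width / 2, cy = height / 2,
                       row_length = 2L * width, hole_rate = 0,
                       min_gap = 4) {
  mode <- match.arg(mode)
  if (is.null(class_freqs)) {
    class_freqs <- if (mode == "field")
      c(SB = 388, Ch = 106, Th = 317, Bi = 166, Pe = 313, Uk = 116,
        Cy = 10, An = 8)
    else c(Rd = 158, Yl = 318, Gn = 2774, Mr = 100, My = 189)
    class_freqs <- class_freqs / sum(class_freqs)
  }
  if (abs(sum(class_freqs) - 1) > 1e-9) stop("class_freqs must sum to 1")
  if (object_depth <= 0 || bg_depth <= 0) stop("depths must be positive")
  if (mode == "wall" && distractor_depth <= object_depth)
    stop("distractor layer must lie beyond the near layer")
  structure(list(mode = mode, n_objects = n_objects, size_range = size_range,
                 class_freqs = class_freqs, object_depth = object_depth,
                 distractor_depth = distractor_depth,
                 n_distractors = n_distractors, bg_depth = bg_depth,
                 width = as.integer(width), height = as.integer(height),
                 fx = fx, fy = fy, cx = cx, cy = cy,
                 row_length = row_length, hole_rate = hole_rate,
                 min_gap = min_gap),
            class = "scene_spec")
}

#' Robot traverse specification
#'
#' Defaults emulate a platform moving at 0.2 m/s filmed at 30 fps
#' (~6.7 mm/frame) with a small wheel-odometry translation error per frame.
#'
#' @param speed Camera translation along the travel axis, m/frame.
#' @param n_frames Number of frames; `NULL` = enough for the camera to pass
#'   the whole strip.
#' @param odo_noise Std of the per-frame recorded-pose translation
#'   perturbation, meters (the rendered geometry stays exact; only the
#'   odometry log is noisy).
#' @export
traverse_spec <- function(speed = 0.0067, n_frames = NULL, odo_noise = 0.002) {
  if (speed < 0) stop("speed must be >= 0")
  structure(list(speed = speed, n_frames = n_frames, odo_noise = odo_noise),
            class = "traverse_spec")
}

#' Detector corruption specification
#'
#' Stresses the tracker the way a real detector does: per-object-per-frame
#' dropout, centroid jitter, morphological growth/shrinkage, spurious
#' instances, and sub-class label flips. Ground truth is never touched.
#'
#' @param dropout Per-object per-frame miss probability.
#' @param jitter_sd Std of the integer centroid jitter, pixels.
#' @param morph_range Integer range of the dilation (+) / erosion (-) radius
#'   sampled per detection.
#' @param spurious_rate Expected spurious instances per frame (Poisson).
#' @param flip_prob Probability a detection's sub-class label is flipped to a
#'   random other label.
#' @param conf_true,conf_spurious Uniform confidence ranges assigned to true
#'   and spurious detections.
#' @param spurious_size Pixel diameter range of spurious blobs.
#' @export
corruption_spec <- function(dropout = 0, jitter_sd = 0, morph_range = c(0, 0),
                            spurious_rate = 0, flip_prob = 0,
                            conf_true = c(0.7, 1), conf_spurious = c(0.2, 0.6),
                            spurious_size = c(8, 20)) {
  for (p in c(dropout, flip_prob))
    if (p < 0 || p > 1) stop("probabilities must be in [0, 1]")
  structure(list(dropout = dropout, jitter_sd = jitter_sd,
                 morph_range = as.integer(morph_range),
                 spurious_rate = spurious_rate, flip_prob = flip_prob,
                 conf_true = conf_true, conf_spurious = conf_spurious,
                 spurious_size = spurious_size),
            class = "corruption_spec")
}

# filled ellipse template centered on (0, 0): integer offsets
ellipse_template <- function(a, b) {
  ra <- ceiling(a); rb <- ceiling(b)
  g <- expand.grid(du = -ra:ra, dv = -rb:rb)
  keep <- (g$du / a)^2 + (g$dv / b)^2 <= 1
  as.matrix(g[keep, , drop = FALSE])
}

#' Generate a static synthetic scene
#'
#' Objects are randomized filled ellipses with known pixel extent; each
#' object's true physical area is `n_pixels * d^2 / (fx * fy)` by
#' construction, so area recovery is exact up to depth holes. Placement
#' rejects overlaps (bounding circles closer than `min_gap`); an infeasible
#' packing is an explicit error. In wall mode an additional distractor layer
#' is placed at the far depth.
#'
#' @param spec A [scene_spec()].
#' @param seed Integer seed; the same seed yields an identical scene.
#' @return A `scene`: the spec plus an `objects` list (id, sub_class, layer,
#'   depth, template offsets, strip position, area).
#' @export
generate_scene <- function(spec, seed = 1L) {
  with_seed(seed, {
    objects <- list()
    place_layer <- function(n, depth, layer, id0) {
      placed <- list()
      # strip coordinates are pixels at the layer's own depth; the strip
      # starts one image width ahead of the frame-0 view so every object
      # crosses the full field of view, and deeper layers (which shift more
      # slowly, by parallax) get a proportionally shorter strip
      u_lo <- spec$width
      u_hi <- spec$width + spec$row_length * spec$object_depth / depth
      for (k in seq_len(n)) {
        ok <- FALSE
        for (try in seq_len(1000L)) {
          dia <- stats::runif(1, spec$size_range[1], spec$size_range[2])
          a <- dia / 2 * stats::runif(1, 0.7, 1); b <- dia / 2 * stats::runif(1, 0.7, 1)
          r <- max(a, b)
          u0 <- stats::runif(1, u_lo, u_hi)
          v0 <- stats::runif(1, ceiling(b) + 2, spec$height - 3 - ceiling(b))
          clear <- TRUE
          for (o in placed) {
            if (sqrt((o$u0 - u0)^2 + (o$v0 - v0)^2) <
                r + o$r + spec$min_gap) { clear <- FALSE; break }
          }
          if (clear) { ok <- TRUE; break }
        }
        if (!ok) stop("infeasible packing: cannot place objects within the overlap budget")
        sub <- sample(names(spec$class_freqs), 1, prob = spec$class_freqs)
        tmpl <- ellipse_template(a, b)
        placed[[k]] <- list(id = id0 + k, sub_class = sub, layer = layer,
                            depth = depth, u0 = u0, v0 = round(v0), r = r,
                            template = tmpl, n_px = nrow(tmpl),
                            area_m2 = nrow(tmpl) * depth^2 / (spec$fx * spec$fy))
      }
      placed
    }
    near <- place_layer(spec$n_objects, spec$object_depth, "near", 0L)
    far <- if (spec$mode == "wall" && spec$n_distractors > 0)
      place_layer(spec$n_distractors, spec$distractor_depth, "distractor",
                  spec$n_objects) else list()
    structure(list(spec = spec, objects = c(near, far), seed = seed),
              class = "scene")
  })
}

translation_pose <- function(x, y = 0, z = 0) rigid_pose(diag(3), c(x, y, z))

#' Render a robot traverse of a synthetic scene
#'
#' Each frame shifts the camera by `speed` meters along the image-u travel
#' axis; per-frame instance masks are the exact geometric projections of the
#' scene objects (objects at different depths shift with parallax), depth
#' images carry object/background depths with optional invalid-pixel holes,
#' and the odometry log records the true poses perturbed by the configured
#' noise.
#'
#' @param scene A [generate_scene()] result.
#' @param traverse A [traverse_spec()].
#' @param seed Seed for depth holes and odometry noise.
#' @return A `synthetic_sequence`: list with `frames` (list of
#'   [frame_record()]; each mask carries a `gt_id` attribute), `K`
#'   ([camera_intrinsics()]), `E` (extrinsics, identity), and `manifest`
#'   (see Details).
#' @details The manifest plays the role of the human visual ground truth: a
#'   per-object table (id, sub_class, layer, depth, pixels, area m^2), the
#'   per-sub-class near-layer counts (`counts`, the ground truth when a depth
#'   window excludes the distractor layer), and `counts_all` including
#'   distractors.
#' @export
render_sequence <- function(scene, traverse = traverse_spec(), seed = 1L) {
  spec <- scene$spec
  K <- camera_intrinsics(spec$fx, spec$fy, spec$cx, spec$cy,
                         spec$width, spec$height)
  px_per_frame <- spec$fx * traverse$speed / spec$object_depth
  n_frames <- traverse$n_frames %||%
    ceiling((spec$row_length + spec$width) / max(px_per_frame, 1e-9))
  objs <- scene$objects
  # painter order: far layer first so near objects overwrite it in depth
  paint_order <- order(-vapply(objs, function(o) o$depth, numeric(1)))
  with_seed(seed, {
    frames <- vector("list", n_frames)
    for (k in seq_len(n_frames)) {
      x_cam <- traverse$speed * (k - 1L)
      depth <- matrix(spec$bg_depth, spec$height, spec$width)
      vis <- list()
      for (oi in paint_order) {
        o <- objs[[oi]]
        shift <- round(spec$fx * x_cam / o$depth)
        px <- cbind(u = o$template[, 1L] + round(o$u0) - shift,
                    v = o$template[, 2L] + o$v0)
        keep <- px[, 1L] >= 0L & px[, 1L] < spec$width &
                px[, 2L] >= 0L & px[, 2L] < spec$height
        if (!any(keep)) next
        px <- px[keep, , drop = FALSE]
        depth[cbind(px[, 2L] + 1L, px[, 1L] + 1L)] <- o$depth
        vis[[length(vis) + 1L]] <- list(o = o, px = px)
      }
      # a detector only sees visible surfaces: clip each mask to the pixels
      # the object still owns in the depth buffer (nearer layers occlude)
      masks <- list()
      for (vrec in vis) {
        own <- depth_at(depth, vrec$px) == vrec$o$depth
        if (!any(own)) next
        m <- instance_mask(vrec$px[own, , drop = FALSE],
                           super_class = "object",
                           sub_class = vrec$o$sub_class, confidence = 1)
        attr(m, "gt_id") <- vrec$o$id
        masks[[length(masks) + 1L]] <- m
      }
      if (spec$hole_rate > 0) {
        holes <- stats::runif(length(depth)) < spec$hole_rate
        depth[holes] <- 0
      }
      pose <- translation_pose(x_cam + stats::rnorm(1, 0, traverse$odo_noise),
                               stats::rnorm(1, 0, traverse$odo_noise))
      frames[[k]] <- frame_record(k - 1L, masks, depth, pose)
    }
    manifest_df <- do.call(rbind, lapply(objs, function(o)
      data.frame(id = o$id, sub_class = o$sub_class, layer = o$layer,
                 depth = o$depth, n_px = o$n_px, area_m2 = o$area_m2)))
    near <- manifest_df[manifest_df$layer == "near", ]
    manifest <- list(
      objects = manifest_df,
      counts = c(table(factor(near$sub_class,
                              levels = names(spec$class_freqs)))),
      counts_all = c(table(factor(manifest_df$sub_class,
                                  levels = names(spec$class_freqs)))),
      total = nrow(near), total_all = nrow(manifest_df))
    structure(list(frames = frames, K = K, E = diag(4), manifest = manifest,
                   scene = scene, traverse = traverse),
              class = "synthetic_sequence")
  })
}

#' @export
print.synthetic_sequence <- function(x, ...) {
  cat(sprintf("<synthetic_sequence> %d frames, %d objects (%d near), %dx%d\n",
              length(x$frames), x$manifest$total_all, x$manifest$total,
              x$K$width, x$K$height))
  invisible(x)
}

morph_mask <- function(px, r, width, height) {
  if (r == 0L || nrow(px) == 0L) return(px)
  keys <- pix_key(px)
  off <- as.matrix(expand.grid(du = -abs(r):abs(r), dv = -abs(r):abs(r)))
  if (r > 0L) {  # dilation
    grown <- do.call(rbind, lapply(seq_len(nrow(off)), function(i)
      cbind(px[, 1L] + off[i, 1L], px[, 2L] + off[i, 2L])))
    grown <- unique(grown)
    keep <- grown[, 1L] >= 0L & grown[, 1L] < width &
            grown[, 2L] >= 0L & grown[, 2L] < height
    grown[keep, , drop = FALSE]
  } else {       # erosion: keep pixels whose full neighborhood is in the set
    inside <- rep(TRUE, nrow(px))
    for (i in seq_len(nrow(off)))
      inside <- inside &
        (pix_key(cbind(px[, 1L] + off[i, 1L], px[, 2L] + off[i, 2L])) %in% keys)
    px[inside, , drop = FALSE]
  }
}

#' Corrupt a rendered detection stream
#'
#' Applies dropout, centroid jitter, morphological perturbation, spurious
#' instances (uniform placement, random sub-class) and sub-class flips to the
#' per-frame masks of a [render_sequence()] output. The ground-truth manifest
#' and depth/odometry are untouched. True detections get confidences drawn
#' from `conf_true`, spurious ones from `conf_spurious`.
#'
#' @param sequence A `synthetic_sequence`.
#' @param corruption A [corruption_spec()].
#' @param seed Integer seed.
#' @return A `synthetic_sequence` with degraded detections.
#' @export
corrupt_detections <- function(sequence, corruption, seed = 1L) {
  K <- sequence$K
  vocab <- names(sequence$scene$spec$class_freqs)
  with_seed(seed, {
    frames <- lapply(sequence$frames, function(fr) {
      out <- list()
      for (m in fr$masks) {
        if (stats::runif(1) < corruption$dropout) next
        px <- m$pixels
        if (corruption$jitter_sd > 0) {
          d <- round(stats::rnorm(2, 0, corruption$jitter_sd))
          px <- cbind(px[, 1L] + d[1L], px[, 2L] + d[2L])
          keep <- px[, 1L] >= 0L & px[, 1L] < K$width &
                  px[, 2L] >= 0L & px[, 2L] < K$height
          px <- px[keep, , drop = FALSE]
        }
        if (any(corruption$morph_range != 0L)) {
          r <- sample(seq(corruption$morph_range[1L],
                          corruption$morph_range[2L]), 1L)
          px <- morph_mask(px, r, K$width, K$height)
        }
        if (nrow(px) == 0L) next
        sub <- m$sub_class
        if (stats::runif(1) < corruption$flip_prob && length(vocab) > 1L)
          sub <- sample(setdiff(vocab, sub), 1L)
        m2 <- instance_mask(px, super_class = m$super_class, sub_class = sub,
                            confidence = stats::runif(1, corruption$conf_true[1L],
                                                      corruption$conf_true[2L]))
        attr(m2, "gt_id") <- attr(m, "gt_id")
        out[[length(out) + 1L]] <- m2
      }
      n_spur <- stats::rpois(1, corruption$spurious_rate)
      for (s in seq_len(n_spur)) {
        dia <- stats::runif(1, corruption$spurious_size[1L],
                            corruption$spurious_size[2L])
        tmpl <- ellipse_template(dia / 2, dia / 2)
        c0 <- c(sample.int(K$width, 1L) - 1L, sample.int(K$height, 1L) - 1L)
        px <- cbind(tmpl[, 1L] + c0[1L], tmpl[, 2L] + c0[2L])
        keep <- px[, 1L] >= 0L & px[, 1L] < K$width &
                px[, 2L] >= 0L & px[, 2L] < K$height
        if (!any(keep)) next
        out[[length(out) + 1L]] <- instance_mask(
          px[keep, , drop = FALSE], super_class = "object",
          sub_class = sample(vocab, 1L),
          confidence = stats::runif(1, corruption$conf_spurious[1L],
                                    corruption$conf_spurious[2L]))
      }
      frame_record(fr$frame_id, out, fr$depth, fr$pose)
    })
    out <- sequence
    out$frames <- frames
    out
  })
}
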