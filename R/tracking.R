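#' Tracker configuration
#'
#' Defaults follow the published protocol: IoU matching threshold
#' `gamma = 0.1`, keep-alive `alpha = 5` processed frames, a minimum of 10
#' matched segmentations for a tracklet to count as a valid track (reduced to
#' 3 when striding every 5th frame), and dynamic-radius weight 1.0.
#'
#' @param gamma IoU matching threshold in (0, 1).
#' @param alpha Keep-alive: a tracklet is closed after more than `alpha`
#'   processed frames without an update.
#' @param min_track_length Matched detections required for a tracklet to be
#'   counted in the yield report.
#' @param criterion `"iou"` or `"dr"` (dynamic radius).
#' @param reprojection Reproject each active tracklet's last mask into the
#'   current frame (requires depth + odometry) before matching.
#' @param dr_weight Positive scalar on the dynamic radius.
#' @param depth_window A [depth_window()] to filter detections, or `NULL`.
#' @param fov_margin Entry/exit zone width in pixels (see [fov_filter()]).
#' @param travel_axis `"u"` or `"v"`.
#' @param frame_stride Process every `frame_stride`-th frame (5 reproduces
#'   the frame-skip protocol).
#' @param subclass_vote `"majority"` (ties to the most recent label),
#'   `"last"`, or `"confidence"` (confidence-weighted vote).
#' @export
tracker_config <- function(gamma = 0.1, alpha = 5, min_track_length = 10,
                           criterion = c("iou", "dr"), reprojection = FALSE,
                           dr_weight = 1.0, depth_window = NULL,
                           fov_margin = 20, travel_axis = "u",
                           frame_stride = 1,
                           subclass_vote = c("majority", "last", "confidence")) {
  criterion <- match.arg(criterion)
  subclass_vote <- match.arg(subclass_vote)
  if (gamma <= 0 || gamma >= 1) stop("gamma must be in (0, 1)")
  if (alpha < 0) stop("alpha must be >= 0")
  if (min_track_length < 1) stop("min_track_length must be >= 1")
  if (dr_weight <= 0) stop("dr_weight must be positive")
  if (frame_stride < 1) stop("frame_stride must be >= 1")
  structure(list(gamma = gamma, alpha = alpha,
                 min_track_length = min_track_length, criterion = criterion,
                 reprojection = isTRUE(reprojection), dr_weight = dr_weight,
                 depth_window = depth_window, fov_margin = fov_margin,
                 travel_axis = travel_axis,
                 frame_stride = as.integer(frame_stride),
                 subclass_vote = subclass_vote),
            class = "tracker_config")
}

#' Intersection-over-union of two masks
#'
#' @param a,b [instance_mask()] objects in the same frame geometry.
#' @return IoU in `[0, 1]`; 0 when either mask is empty.
#' @export
iou_affinity <- function(a, b) {
  ka <- pix_key(a$pixels); kb <- pix_key(b$pixels)
  if (!length(ka) || !length(kb)) return(0)
  inter <- sum(ka %in% kb)
  inter / (length(ka) + length(kb) - inter)
}

#' Dynamic-radius match for one tracklet
#'
#' Among candidates whose center of mass lies within the tracklet's dynamic
#' radius (Euclidean distance in pixels), returns the index of the nearest
#' one, or `NA` if none qualifies.
#'
#' @param tracklet_geom [mask_geometry()] of the tracklet's reference mask.
#' @param candidates List of [mask_geometry()] for the frame's detections.
#' @return Integer candidate index or `NA_integer_`.
#' @export
dr_match <- function(tracklet_geom, candidates) {
  if (!length(candidates)) return(NA_integer_)
  d <- vapply(candidates, function(g)
    sqrt(sum((g$center - tracklet_geom$center)^2)), numeric(1))
  ok <- d <= tracklet_geom$dynamic_radius
  if (!any(ok)) return(NA_integer_)
  which(ok & d == min(d[ok]))[1L]
}

#' Greedy one-to-one assignment by repeated global argmax
#'
#' Repeatedly takes the global maximum of the affinity matrix; while it
#' exceeds `gamma`, records the (tracklet, candidate) pair and masks that
#' pair's entire row and column so neither is reused. Ties break to the
#' lowest tracklet (row) index, then the lowest candidate (column) index, so
#' assignment is fully deterministic.
#'
#' @param affinity Tracklets x candidates numeric matrix (IoU values, or
#'   radius-gated negative distances for the dynamic-radius criterion, with
#'   `-Inf` marking unmatchable pairs).
#' @param gamma Matching threshold: only entries strictly above it match.
#'   Use `-Inf` for pre-gated affinities.
#' @return List with `pairs` (m x 2 matrix of row/col indices) and
#'   `unmatched_candidates` (column indices never assigned).
#' @export
greedy_assign <- function(affinity, gamma) {
  affinity <- as.matrix(affinity)
  pairs <- matrix(integer(0), 0, 2, dimnames = list(NULL, c("tracklet", "candidate")))
  if (length(affinity)) repeat {
    mx <- suppressWarnings(max(affinity))
    if (!is.finite(mx) || !(mx > gamma)) break
    hits <- which(affinity == mx, arr.ind = TRUE)
    hit <- hits[order(hits[, 1L], hits[, 2L])[1L], ]
    pairs <- rbind(pairs, hit)
    affinity[hit[1L], ] <- -Inf
    affinity[, hit[2L]] <- -Inf
  }
  list(pairs = pairs,
       unmatched_candidates = setdiff(seq_len(ncol(affinity)), pairs[, 2L]))
}

# affinity matrix for one frame under the configured criterion
criterion_affinity <- function(ref_masks, candidates, config) {
  nt <- length(ref_masks); nc <- length(candidates)
  A <- matrix(-Inf, nt, nc)
  if (config$criterion == "iou") {
    for (i in seq_len(nt)) {
      if (is_empty_mask(ref_masks[[i]])) next
      for (j in seq_len(nc))
        A[i, j] <- iou_affinity(ref_masks[[i]], candidates[[j]])
    }
    list(affinity = A, gamma = config$gamma)
  } else {
    cand_geom <- lapply(candidates, mask_geometry, dr_weight = config$dr_weight)
    for (i in seq_len(nt)) {
      if (is_empty_mask(ref_masks[[i]])) next
      g <- mask_geometry(ref_masks[[i]], dr_weight = config$dr_weight)
      for (j in seq_len(nc)) {
        d <- sqrt(sum((cand_geom[[j]]$center - g$center)^2))
        if (d <= g$dynamic_radius) A[i, j] <- -d
      }
    }
    list(affinity = A, gamma = -Inf)
  }
}

#' One synchronized frame of a row traverse
#'
#' @param frame_id Integer frame index within the sequence.
#' @param masks List of [instance_mask()] detections for the frame.
#' @param depth Height x width depth matrix (meters, 0 = invalid), or `NULL`.
#' @param pose 4x4 world-from-body odometry pose, or `NULL`.
#' @export
frame_record <- function(frame_id, masks = list(), depth = NULL, pose = NULL) {
  structure(list(frame_id = as.integer(frame_id), masks = masks,
                 depth = depth, pose = pose),
            class = "frame_record")
}

new_tracklet <- function(id, fid, mask, area, depths, pose) {
  list(id = id,
       history = list(list(frame_id = fid, mask = mask, area = area,
                           sub_class = mask$sub_class,
                           confidence = mask$confidence)),
       last_mask = mask, last_depths = depths, last_pose = pose,
       frames_since_update = 0L, state = "active")
}

#' Track a row traverse (tracking-via-segmentation)
#'
#' Greedy per-frame association of instance masks to tracklets. Per processed
#' frame (after stride subsampling): detections are obtained from the frame
#' record or a detector function, filtered by the depth window (inlier
#' percentage above the window's threshold) and the field-of-view operator;
#' when reprojection is enabled, each active tracklet's last mask is
#' reprojected into the current frame before affinities are computed; the
#' configured criterion is matched greedily; matched tracklets absorb the
#' detection and reset their idle counter; unmatched detections spawn new
#' tracklets (matchable from the next processed frame); tracklets idle for
#' more than `alpha` processed frames are closed. All tracklets close at the
#' end of the sequence.
#'
#' @param frames Ordered list of [frame_record()].
#' @param config A [tracker_config()].
#' @param K [camera_intrinsics()] (needed for reprojection and areas).
#' @param E 4x4 camera-to-body extrinsics (default identity).
#' @param detector Optional function `frame_id -> list of instance_mask`
#'   replacing the masks stored in the frame records.
#' @return A `track_set`: list with `tracklets`, `config`, `n_frames`.
#' @export
track_sequence <- function(frames, config = tracker_config(), K = NULL,
                           E = diag(4), detector = NULL) {
  idx <- seq(1L, length(frames), by = config$frame_stride)
  frames <- frames[idx]
  needs_depth <- config$reprojection || !is.null(config$depth_window)
  if (config$reprojection) {
    if (is.null(K)) stop("reprojection requires camera intrinsics")
    if (any(vapply(frames, function(f) is.null(f$pose), logical(1))))
      stop("reprojection requires an odometry pose on every frame")
  }
  if (needs_depth &&
      any(vapply(frames, function(f) is.null(f$depth), logical(1))))
    stop("depth filtering/reprojection requires a depth image on every frame")

  tracklets <- list()
  active <- integer(0)
  next_id <- 1L

  for (fr in frames) {
    masks <- if (is.null(detector)) fr$masks else detector(fr$frame_id)
    masks <- Filter(Negate(is_empty_mask), masks)
    if (!is.null(config$depth_window) && length(masks)) {
      q <- vapply(masks, depth_inlier_percentage, numeric(1),
                  depth = fr$depth, window = config$depth_window)
      masks <- masks[q > config$depth_window$q_threshold]
    }
    if (!is.null(K) && length(masks))
      masks <- fov_filter(masks, K$width, K$height,
                          margin = config$fov_margin,
                          travel_axis = config$travel_axis)

    get_depths <- function(m) {
      if (is.null(fr$depth)) rep(NA_real_, nrow(m$pixels))
      else depth_at(fr$depth, m$pixels)
    }
    get_area <- function(m) {
      if (is.null(fr$depth) || is.null(K)) NA_real_
      else as.numeric(estimate_area(m, fr$depth, K))
    }

    if (!length(active)) {
      for (m in masks) {
        tracklets[[next_id]] <- new_tracklet(next_id, fr$frame_id, m,
                                             get_area(m), get_depths(m),
                                             fr$pose)
        active <- c(active, next_id)
        next_id <- next_id + 1L
      }
      next
    }

    refs <- lapply(tracklets[active], function(t) {
      if (!config$reprojection) return(t$last_mask)
      H <- relative_camera_transform(t$last_pose, fr$pose, E)
      reproject_mask(t$last_mask, t$last_depths, H, K)
    })
    matched_t <- integer(0); unmatched_c <- seq_along(masks)
    if (length(masks)) {
      ca <- criterion_affinity(refs, masks, config)
      asg <- greedy_assign(ca$affinity, ca$gamma)
      if (nrow(asg$pairs)) {
        for (p in seq_len(nrow(asg$pairs))) {
          ti <- active[asg$pairs[p, 1L]]
          m <- masks[[asg$pairs[p, 2L]]]
          t <- tracklets[[ti]]
          t$history[[length(t$history) + 1L]] <-
            list(frame_id = fr$frame_id, mask = m, area = get_area(m),
                 sub_class = m$sub_class, confidence = m$confidence)
          t$last_mask <- m
          t$last_depths <- get_depths(m)
          t$last_pose <- fr$pose
          t$frames_since_update <- 0L
          tracklets[[ti]] <- t
        }
        matched_t <- active[asg$pairs[, 1L]]
      }
      unmatched_c <- asg$unmatched_candidates
    }
    # Psi: age and close idle tracklets
    for (ti in setdiff(active, matched_t)) {
      t <- tracklets[[ti]]
      t$frames_since_update <- t$frames_since_update + 1L
      if (t$frames_since_update > config$alpha) t$state <- "closed"
      tracklets[[ti]] <- t
    }
    active <- Filter(function(ti) tracklets[[ti]]$state == "active",
                     union(active, integer(0)))
    # spawn new tracklets from unused detections
    for (j in unmatched_c) {
      m <- masks[[j]]
      tracklets[[next_id]] <- new_tracklet(next_id, fr$frame_id, m,
                                           get_area(m), get_depths(m),
                                           fr$pose)
      active <- c(active, next_id)
      next_id <- next_id + 1L
    }
  }
  for (ti in seq_along(tracklets)) tracklets[[ti]]$state <- "closed"
  structure(list(tracklets = tracklets, config = config,
                 n_frames = length(frames)),
            class = "track_set")
}

#' @export
print.track_set <- function(x, ...) {
  cat(sprintf("<track_set> %d tracklets over %d processed frames\n",
              length(x$tracklets), x$n_frames))
  invisible(x)
}

vote_subclass <- function(history, how) {
  labs <- vapply(history, function(h)
    if (is.na(h$sub_class)) "NA" else h$sub_class, character(1))
  if (how == "last") return(labs[length(labs)])
  w <- if (how == "confidence")
    vapply(history, function(h) h$confidence, numeric(1)) else rep(1, length(labs))
  tot <- tapply(w, labs, sum)
  best <- names(tot)[tot == max(tot)]
  if (length(best) == 1L) return(best)
  # tie: the most recent frame's label among the tied ones
  labs[max(which(labs %in% best))]
}

#' Per-row yield report
#'
#' Tracklets with fewer than `min_track_length` matched detections are
#' dropped. Each surviving tracklet contributes one count to its voted
#' sub-class (majority by default, ties resolved to the most recent frame's
#' label) and reports the maximum of its per-frame areas.
#'
#' @param tracks A `track_set` from [track_sequence()].
#' @param config Tracker configuration (defaults to the one stored in
#'   `tracks`).
#' @return A `row_report`: list with `tracklets` (data frame: id, sub_class,
#'   n_matches, max_area_m2, max_area_cm2), `counts` (named per-sub-class
#'   vector), and `total`.
#' @export
yield_report <- function(tracks, config = tracks$config) {
  keep <- Filter(function(t) length(t$history) >= config$min_track_length,
                 tracks$tracklets)
  rows <- lapply(keep, function(t) {
    areas <- vapply(t$history, function(h) h$area %||% NA_real_, numeric(1))
    amax <- if (all(is.na(areas))) NA_real_ else max(areas, na.rm = TRUE)
    data.frame(id = t$id,
               sub_class = vote_subclass(t$history, config$subclass_vote),
               n_matches = length(t$history),
               max_area_m2 = amax, max_area_cm2 = amax * 1e4)
  })
  tab <- if (length(rows)) do.call(rbind, rows) else
    data.frame(id = integer(0), sub_class = character(0),
               n_matches = integer(0), max_area_m2 = numeric(0),
               max_area_cm2 = numeric(0))
  counts <- if (nrow(tab)) table(tab$sub_class) else table(character(0))
  structure(list(tracklets = tab,
                 counts = stats::setNames(as.integer(counts), names(counts)),
                 total = nrow(tab)),
            class = "row_report")
}

#' @export
print.row_report <- function(x, ...) {
  cat(sprintf("<row_report> total objects: %d\n", x$total))
  if (length(x$counts)) {
    for (nm in names(x$counts)) cat(sprintf("  %-12s %d\n", nm, x$counts[[nm]]))
  }
  if (nrow(x$tracklets)) {
    a <- x$tracklets$max_area_cm2
    if (any(!is.na(a)))
      cat(sprintf("  mean max area: %.1f cm^2\n", mean(a, na.rm = TRUE)))
  }
  invisible(x)
}
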