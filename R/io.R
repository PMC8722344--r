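# dataset serialization: the on-disk formats the pipeline consumes.
# Depth is stored as 16-bit binary PGM (P5, maxval 65535) in millimeters with
# 0 marking invalid pixels; PGM is used because no pre-installed package
# writes 16-bit PNG. Odometry is JSONL (one 4x4 row-major world-from-body
# transform per frame); intrinsics/extrinsics are YAML; annotations are
# COCO-style JSON; the manifest is CSV.

#' Write / read a 16-bit depth image (PGM, millimeters)
#'
#' @param depth Height x width matrix of depths in meters (0 = invalid).
#' @param path File path (`.pgm`).
#' @export
write_depth_pgm <- function(depth, path) {
  mm <- round(pmin(pmax(depth, 0), 65.535) * 1000)
  con <- file(path, "wb")
  on.exit(close(con))
  writeLines(c("P5", paste(ncol(mm), nrow(mm)), "65535"), con, sep = "\n")
  writeBin(as.integer(t(mm)), con, size = 2L, endian = "big")
  invisible(path)
}

#' @rdname write_depth_pgm
#' @export
read_depth_pgm <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- readLines(con, n = 1L)
  if (magic != "P5") stop("not a binary PGM file")
  dims <- scan(con, integer(), n = 2L, quiet = TRUE)
  maxval <- scan(con, integer(), n = 1L, quiet = TRUE)
  if (maxval != 65535) stop("expected a 16-bit PGM")
  vals <- readBin(con, "integer", n = prod(dims), size = 2L,
                  signed = FALSE, endian = "big")
  t(matrix(vals, dims[1L], dims[2L])) / 1000
}

#' Write / read camera calibration (YAML)
#'
#' Keys: `fx, fy, cx, cy, width, height`, and `extrinsics` as a 4x4 row-major
#' matrix (camera-to-body).
#' @param K [camera_intrinsics()].
#' @param E 4x4 extrinsics.
#' @param path YAML file path.
#' @export
write_calibration <- function(K, path, E = diag(4)) {
  yaml::write_yaml(list(fx = K$fx, fy = K$fy, cx = K$cx, cy = K$cy,
                        width = K$width, height = K$height,
                        extrinsics = as.numeric(t(E))), path)
  invisible(path)
}

#' @rdname write_calibration
#' @export
read_calibration <- function(path) {
  y <- yaml::read_yaml(path)
  list(K = camera_intrinsics(y$fx, y$fy, y$cx, y$cy, y$width, y$height),
       E = matrix(as.numeric(unlist(y$extrinsics)), 4, 4, byrow = TRUE))
}

#' Write / read a wheel-odometry log (JSONL)
#'
#' One record per frame:
#' `{"frame_id": i, "timestamp_s": t, "T": [...16 row-major...]}` with `T`
#' the world-from-body pose.
#' @param poses List of 4x4 poses.
#' @param frame_ids Integer frame ids.
#' @param path Output path.
#' @param fps Frames per second used for timestamps.
#' @export
write_odometry <- function(poses, frame_ids, path, fps = 30) {
  lines <- vapply(seq_along(poses), function(i)
    jsonlite::toJSON(list(frame_id = frame_ids[i],
                          timestamp_s = frame_ids[i] / fps,
                          T = as.numeric(t(poses[[i]]))),
                     auto_unbox = TRUE, digits = NA), character(1))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_odometry
#' @export
read_odometry <- function(path) {
  recs <- lapply(readLines(path), jsonlite::fromJSON)
  ids <- vapply(recs, function(r) as.integer(r$frame_id), integer(1))
  poses <- lapply(recs, function(r)
    matrix(as.numeric(r$T), 4, 4, byrow = TRUE))
  ord <- order(ids)
  list(frame_ids = ids[ord], poses = poses[ord])
}

#' Write a synthetic sequence to disk as a complete dataset
#'
#' Emits exactly the formats the pipeline consumes: `annotations.json`
#' (COCO-style), `depth/frame_%04d.pgm` (16-bit, millimeters),
#' `odometry.jsonl`, `calibration.yaml`, `manifest.csv` (per-object ground
#' truth) and `counts.csv` (visual-ground-truth row counts layout).
#'
#' @param sequence A [render_sequence()] (optionally
#'   [corrupt_detections()]-ed) result.
#' @param dir Output directory (created if missing).
#' @param row_id Row identifier used in `counts.csv`.
#' @export
write_dataset <- function(sequence, dir, row_id = "R1") {
  dir.create(file.path(dir, "depth"), recursive = TRUE, showWarnings = FALSE)
  vocab <- names(sequence$scene$spec$class_freqs)
  dets <- lapply(sequence$frames, function(fr) fr$masks)
  fids <- vapply(sequence$frames, function(fr) fr$frame_id, integer(1))
  save_annotations(dets, file.path(dir, "annotations.json"),
                   width = sequence$K$width, height = sequence$K$height,
                   vocab = vocab, frame_ids = fids)
  for (fr in sequence$frames)
    write_depth_pgm(fr$depth,
                    file.path(dir, "depth", sprintf("frame_%04d.pgm", fr$frame_id)))
  write_odometry(lapply(sequence$frames, function(fr) fr$pose), fids,
                 file.path(dir, "odometry.jsonl"))
  write_calibration(sequence$K, file.path(dir, "calibration.yaml"), sequence$E)
  utils::write.csv(sequence$manifest$objects, file.path(dir, "manifest.csv"),
                   row.names = FALSE)
  counts <- sequence$manifest$counts
  df <- as.data.frame(as.list(counts), check.names = FALSE)
  df <- cbind(data.frame(row = row_id), df, data.frame(total = sum(counts)))
  write_row_counts(df, file.path(dir, "counts.csv"))
  invisible(dir)
}

#' Read a dataset directory back into frame records
#'
#' @param dir Dataset directory produced by [write_dataset()] (or following
#'   the same layout).
#' @return List with `frames` (list of [frame_record()]), `K`, `E`,
#'   `manifest` (data frame or `NULL`), `counts` (data frame or `NULL`),
#'   `vocab`.
#' @export
read_dataset <- function(dir) {
  cal <- read_calibration(file.path(dir, "calibration.yaml"))
  ann <- load_annotations(file.path(dir, "annotations.json"))
  fids <- attr(ann, "frame_ids")
  odo_path <- file.path(dir, "odometry.jsonl")
  odo <- if (file.exists(odo_path)) read_odometry(odo_path) else NULL
  frames <- lapply(seq_along(fids), function(i) {
    dp <- file.path(dir, "depth", sprintf("frame_%04d.pgm", fids[i]))
    depth <- if (file.exists(dp)) read_depth_pgm(dp) else NULL
    pose <- if (!is.null(odo)) odo$poses[[match(fids[i], odo$frame_ids)]] else NULL
    frame_record(fids[i], ann[[i]], depth, pose)
  })
  man_path <- file.path(dir, "manifest.csv")
  cnt_path <- file.path(dir, "counts.csv")
  list(frames = frames, K = cal$K, E = cal$E,
       manifest = if (file.exists(man_path)) utils::read.csv(man_path) else NULL,
       counts = if (file.exists(cnt_path)) read_row_counts(cnt_path) else NULL,
       vocab = attr(ann, "vocab"))
}

#' Serialize a track set to JSON
#'
#' Per tracklet: id, matched frame ids, per-frame sub-class votes, confidences
#' and areas; masks are included as uncompressed RLE only on request.
#'
#' @param tracks A `track_set`.
#' @param path Output path.
#' @param K [camera_intrinsics()] (needed when `include_masks = TRUE`).
#' @param include_masks Include per-frame RLE masks.
#' @export
write_trackset <- function(tracks, path, K = NULL, include_masks = FALSE) {
  tl <- lapply(tracks$tracklets, function(t) {
    rec <- list(id = t$id,
                frame_ids = vapply(t$history, function(h) h$frame_id, integer(1)),
                sub_classes = vapply(t$history, function(h)
                  h$sub_class %||% NA_character_, character(1)),
                confidences = vapply(t$history, function(h) h$confidence, numeric(1)),
                areas_m2 = vapply(t$history, function(h)
                  h$area %||% NA_real_, numeric(1)))
    if (include_masks)
      rec$masks <- lapply(t$history, function(h)
        rle_encode(h$mask, K$width, K$height))
    rec
  })
  jsonlite::write_json(list(n_frames = tracks$n_frames,
                            config = unclass(tracks$config)[
                              !vapply(unclass(tracks$config), is.null, logical(1))],
                            tracklets = tl),
                       path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}
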