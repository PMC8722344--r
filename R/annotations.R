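#' Built-in sub-class vocabularies
#'
#' The label sets are configuration, not code: a dataset declares its
#' sub-class vocabulary, and annotation loading validates labels against it.
#' Two vocabularies ship with the package: `"SB20"` (sugar beet plus seven
#' weed species/unknown) and `"BUP20"` (sweet-pepper ripeness).
#'
#' @param name `"SB20"` or `"BUP20"`, or a character vector to use verbatim.
#' @return Character vector of canonical sub-class ids.
#' @export
subclass_vocabulary <- function(name) {
  if (length(name) > 1L) return(name)
  switch(name,
    SB20 = c("SB", "Ch", "Th", "Bi", "Pe", "Uk", "Cy", "An"),
    BUP20 = c("Rd", "Yl", "Gn", "Mr", "My"),
    name)
}

# ---- uncompressed RLE (COCO convention: column-major, leading zero run) ----

rle_encode <- function(mask, width, height) {
  flat <- as.vector(mask_to_matrix(mask, width, height))
  r <- rle(flat)
  counts <- r$lengths
  if (length(counts) && r$values[1L]) counts <- c(0L, counts)
  list(size = c(height, width), counts = as.integer(counts))
}

rle_decode <- function(seg) {
  size <- as.integer(unlist(seg$size))
  counts <- as.integer(unlist(seg$counts))
  n <- prod(size)
  vals <- rep(rep(c(FALSE, TRUE), length.out = length(counts)), counts)
  if (length(vals) != n) stop("RLE counts do not cover the image")
  mask_from_matrix(matrix(vals, size[1L], size[2L]))
}

# ---- polygon rasterisation, even-odd rule on pixel centers ----

polygon_fill <- function(xy, width, height) {
  # xy: matrix with columns x, y (continuous, 0-based pixel coordinates)
  n <- nrow(xy)
  if (n < 3L) return(matrix(integer(0), 0, 2))
  x <- xy[, 1L]; y <- xy[, 2L]
  x2 <- c(x[-1L], x[1L]); y2 <- c(y[-1L], y[1L])
  v0 <- max(0L, floor(min(y) - 0.5))
  v1 <- min(height - 1L, ceiling(max(y)))
  out <- vector("list", max(0L, v1 - v0 + 1L))
  for (v in v0:v1) {
    yc <- v + 0.5
    # edges crossing the scanline (half-open rule avoids double counting)
    cross <- (y <= yc & y2 > yc) | (y2 <= yc & y > yc)
    if (!any(cross)) next
    xs <- sort(x[cross] + (yc - y[cross]) * (x2[cross] - x[cross]) /
                 (y2[cross] - y[cross]))
    # even-odd: fill alternate intervals
    for (k in seq(1L, length(xs) - 1L, by = 2L)) {
      ua <- max(0L, ceiling(xs[k] - 0.5))
      ub <- min(width - 1L, floor(xs[k + 1L] - 0.5 - 1e-9))
      if (ua <= ub) out[[v - v0 + 1L]] <-
          rbind(out[[v - v0 + 1L]], cbind(ua:ub, v))
    }
  }
  px <- do.call(rbind, out)
  if (is.null(px)) matrix(integer(0), 0, 2) else px
}

decode_segmentation <- function(seg, width, height) {
  if (!is.null(seg$counts)) return(rle_decode(seg)$pixels)
  # polygon(s): list of flat [x1, y1, x2, y2, ...] rings, combined even-odd
  rings <- if (is.numeric(seg)) list(seg) else seg
  acc <- matrix(FALSE, height, width)
  n_raw <- 0L
  for (ring in rings) {
    ring <- as.numeric(unlist(ring))
    xy <- matrix(ring, ncol = 2, byrow = TRUE)
    px <- polygon_fill(xy, width, height)
    n_raw <- n_raw + nrow(px)
    if (nrow(px))
      acc[cbind(px[, 2L] + 1L, px[, 1L] + 1L)] <-
        !acc[cbind(px[, 2L] + 1L, px[, 1L] + 1L)]  # even-odd across rings
  }
  if (n_raw != sum(acc))
    warning("overlapping polygon rings decoded with the even-odd rule")
  idx <- which(acc, arr.ind = TRUE)
  cbind(u = idx[, 2L] - 1L, v = idx[, 1L] - 1L)
}

#' Save per-frame instance annotations to a COCO-style JSON file
#'
#' Each annotation carries an uncompressed RLE segmentation, a super-class
#' `category_id`, a fine-grained `sub_category_id`, and a confidence `score`.
#' The `images` table carries `frame_id` ordering.
#'
#' @param detections List (one element per frame) of lists of
#'   [instance_mask()]; frame ids taken from `names()` or `frame_ids`.
#' @param path Output file path.
#' @param width,height Image size in pixels.
#' @param vocab Sub-class vocabulary (character vector or a name understood
#'   by [subclass_vocabulary()]).
#' @param frame_ids Optional integer frame ids (default `0:(n-1)`).
#' @export
save_annotations <- function(detections, path, width, height, vocab,
                             frame_ids = NULL) {
  vocab <- subclass_vocabulary(vocab)
  if (is.null(frame_ids)) frame_ids <- seq_along(detections) - 1L
  supers <- unique(unlist(lapply(detections, function(fr)
    vapply(fr, function(m) m$super_class, character(1)))))
  if (length(supers) == 0L) supers <- "object"
  images <- data.frame(id = seq_along(frame_ids), frame_id = frame_ids,
                       width = width, height = height,
                       file_name = sprintf("frame_%04d", frame_ids))
  anns <- list(); aid <- 0L
  for (i in seq_along(detections)) {
    for (m in detections[[i]]) {
      aid <- aid + 1L
      anns[[aid]] <- list(
        id = aid, image_id = i,
        category_id = match(m$super_class, supers),
        sub_category_id = if (is.na(m$sub_class)) NULL
                          else match(m$sub_class, vocab),
        score = m$confidence,
        segmentation = rle_encode(m, width, height))
    }
  }
  doc <- list(
    images = images,
    categories = data.frame(id = seq_along(supers), name = supers),
    sub_categories = data.frame(id = seq_along(vocab), name = vocab),
    annotations = anns)
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Load per-frame instance annotations from a COCO-style JSON file
#'
#' Masks are decoded to pixel sets (uncompressed RLE, or polygons filled by
#' the even-odd rule — self-intersecting polygons decode with a warning).
#' Sub-class labels are validated against the vocabulary; an unknown label is
#' an error naming the offender. Frames are ordered by `frame_id`.
#'
#' @param path Annotation file path.
#' @param vocab Optional vocabulary override; defaults to the file's
#'   `sub_categories` table.
#' @return List of per-frame lists of [instance_mask()], with attributes
#'   `frame_ids`, `width`, `height`, `vocab`.
#' @export
load_annotations <- function(path, vocab = NULL) {
  doc <- jsonlite::read_json(path, simplifyVector = FALSE)
  images <- doc$images
  frame_ids <- vapply(images, function(x) as.integer(x$frame_id), integer(1))
  ord <- order(frame_ids)
  images <- images[ord]; frame_ids <- frame_ids[ord]
  file_vocab <- vapply(doc$sub_categories %||% list(),
                       function(x) x$name, character(1))
  vocab <- if (is.null(vocab)) file_vocab else subclass_vocabulary(vocab)
  if (length(file_vocab)) {
    bad <- setdiff(file_vocab, vocab)
    if (length(bad))
      stop(sprintf("unknown sub-class label(s): %s", paste(bad, collapse = ", ")))
  }
  supers <- vapply(doc$categories %||% list(), function(x) x$name, character(1))
  anns <- doc$annotations %||% list()
  ann_img <- vapply(anns, function(a) as.integer(a$image_id), integer(1))
  frames <- vector("list", length(images))
  for (i in seq_along(images)) {
    img <- images[[i]]
    rows <- which(ann_img == img$id)
    frames[[i]] <- lapply(rows, function(r) {
      a <- anns[[r]]
      seg <- a$segmentation
      if (!is.null(seg$counts)) seg$counts <- as.integer(unlist(seg$counts))
      px <- decode_segmentation(seg, as.integer(img$width),
                                as.integer(img$height))
      sub <- if (is.null(a$sub_category_id)) NA_character_
             else vocab[[a$sub_category_id]]
      instance_mask(px, super_class = supers[[a$category_id]],
                    sub_class = sub, confidence = a$score %||% 1,
                    allow_empty = TRUE)
    })
  }
  structure(frames, frame_ids = frame_ids,
            width = as.integer(images[[1L]]$width),
            height = as.integer(images[[1L]]$height),
            vocab = vocab)
}
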