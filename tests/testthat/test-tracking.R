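test_that("IoU affinity matches hand-counted overlaps", {
  a <- rect_mask(0, 0, 10, 10)
  expect_equal(iou_affinity(a, a), 1)
  expect_equal(iou_affinity(a, rect_mask(50, 50, 10, 10)), 0)
  # 10x10 squares offset by (5, 5): overlap 25, union 175
  expect_equal(iou_affinity(a, rect_mask(5, 5, 10, 10)), 25 / 175)
  empty <- instance_mask(matrix(0, 0, 2), allow_empty = TRUE)
  expect_equal(iou_affinity(a, empty), 0)
  expect_equal(iou_affinity(empty, empty), 0)
})

test_that("dynamic-radius match picks the nearest candidate inside the radius", {
  t_geom <- mask_geometry(rect_mask(100, 100, 10, 10))  # radius 10
  cand <- function(du, dv) mask_geometry(rect_mask(100 + du, 100 + dv, 10, 10))
  expect_equal(dr_match(t_geom, list(cand(9, 0))), 1L)           # dist 9 <= 10
  expect_equal(dr_match(t_geom, list(cand(0, 0))), 1L)           # dist 0
  expect_true(is.na(dr_match(t_geom, list(cand(11, 0), cand(0, 15)))))
  expect_equal(dr_match(t_geom, list(cand(8, 0), cand(3, 0), cand(-30, 0))), 2L)
  expect_true(is.na(dr_match(t_geom, list())))
})

test_that("greedy assignment equals the argmax-and-zero oracle", {
  # the spec's 2x2 example
  A <- matrix(c(0.9, 0.85, 0.8, 0.2), 2, 2)
  res <- greedy_assign(A, 0.1)
  expect_equal(unname(res$pairs), rbind(c(1L, 1L), c(2L, 2L)))
  expect_length(res$unmatched_candidates, 0)

  expect_equal(unname(greedy_assign(matrix(0.5, 1, 1), 0.1)$pairs),
               cbind(1L, 1L))
  none <- greedy_assign(matrix(0.05, 3, 2), 0.1)
  expect_equal(nrow(none$pairs), 0)
  expect_equal(none$unmatched_candidates, 1:2)

  set.seed(99)
  for (i in 1:300) {
    nr <- sample(1:5, 1); nc <- sample(1:5, 1)
    A <- matrix(sample(seq(0, 1, by = 0.05), nr * nc, replace = TRUE), nr, nc)
    expect_equal(unname(greedy_assign(A, 0.1)$pairs),
                 unname(oracle_greedy(A, 0.1)))
  }
})

test_that("static objects give one validated tracklet each, all criteria", {
  masks <- list(rect_mask(50, 50, 12, 12, sub_class = "SB"),
                rect_mask(120, 80, 8, 8, sub_class = "Th"),
                rect_mask(200, 150, 20, 20, sub_class = "SB"),
                rect_mask(300, 60, 10, 14, sub_class = "Pe"),
                rect_mask(400, 200, 16, 9, sub_class = "Ch"))
  frames <- lapply(0:49, function(k) frame_record(k, masks))
  K <- K_default()
  for (crit in c("iou", "dr")) {
    cfg <- tracker_config(criterion = crit, min_track_length = 10)
    ts <- track_sequence(frames, cfg, K = K)
    expect_length(ts$tracklets, 5)
    rep <- yield_report(ts)
    expect_equal(rep$total, 5)
    expect_equal(rep$counts[["SB"]], 2)
    expect_true(all(rep$tracklets$n_matches == 50))
  }
})

test_that("fast small objects fragment under IoU but not under DR", {
  frames <- moving_rect_frames(20, w = 10, h = 10, step = 9)
  K <- K_default(500, 320, 240)
  iou_ts <- track_sequence(frames, tracker_config(criterion = "iou",
                                                  gamma = 0.1,
                                                  min_track_length = 3), K = K)
  dr_ts <- track_sequence(frames, tracker_config(criterion = "dr",
                                                 min_track_length = 3), K = K)
  # per-frame IoU = 10/190 ~ 0.053 < 0.1, center shift 9 < radius 10
  expect_gt(length(iou_ts$tracklets), 1)
  expect_length(dr_ts$tracklets, 1)
  expect_equal(yield_report(dr_ts)$total, 1)
})

test_that("empty detection streams give an empty track set", {
  frames <- lapply(0:9, function(k) frame_record(k, list()))
  ts <- track_sequence(frames, tracker_config(), K = K_default())
  expect_length(ts$tracklets, 0)
  expect_equal(yield_report(ts)$total, 0)
})

test_that("every surviving detection lands in exactly one tracklet per frame", {
  seqc <- small_row(8, seed = 21)
  cfg <- tracker_config(criterion = "dr", min_track_length = 3)
  ts <- track_sequence(seqc$frames, cfg, K = seqc$K)
  # conservation: per frame, assigned masks across tracklets are disjoint and
  # their count equals the number of FOV-surviving detections
  per_frame <- list()
  for (t in ts$tracklets) for (h in t$history) {
    fid <- as.character(h$frame_id)
    per_frame[[fid]] <- c(per_frame[[fid]], list(h$mask))
  }
  for (fr in seqc$frames) {
    kept <- fov_filter(Filter(Negate(is_empty_mask), fr$masks),
                       seqc$K$width, seqc$K$height, cfg$fov_margin)
    got <- per_frame[[as.character(fr$frame_id)]] %||% list()
    expect_length(got, length(kept))
    keys <- unlist(lapply(got, function(m) pix_key(m$pixels)))
    expect_equal(anyDuplicated(keys), 0)
  }
})

test_that("tracking is deterministic", {
  seqc <- small_row(6, seed = 5)
  cfg <- tracker_config(criterion = "iou", min_track_length = 3)
  t1 <- track_sequence(seqc$frames, cfg, K = seqc$K)
  t2 <- track_sequence(seqc$frames, cfg, K = seqc$K)
  expect_identical(t1, t2)
})

test_that("keep-alive bridges dropouts up to alpha processed frames", {
  masks <- list(rect_mask(100, 100, 12, 12, sub_class = "SB"))
  frames <- lapply(0:29, function(k) {
    # object disappears for 3 consecutive frames twice
    if (k %in% c(10:12, 20:22)) frame_record(k, list())
    else frame_record(k, masks)
  })
  K <- K_default()
  ts <- track_sequence(frames, tracker_config(alpha = 5, min_track_length = 10), K = K)
  expect_length(ts$tracklets, 1)
  # with alpha = 2 the 3-frame gaps split the track
  ts2 <- track_sequence(frames, tracker_config(alpha = 2, min_track_length = 3), K = K)
  expect_length(ts2$tracklets, 3)
})

test_that("yield report enforces min track length, majority vote and max area", {
  mk <- function(fid, sub, area) list(frame_id = fid,
                                      mask = rect_mask(0, 0, 2, 2, sub_class = sub),
                                      area = area, sub_class = sub,
                                      confidence = 1)
  t_short <- list(id = 1L, history = lapply(1:9, function(i) mk(i, "Gn", 1e-4)),
                  state = "closed")
  hist <- c(lapply(1:12, function(i) mk(i, "Gn", c(0.0030, 0.0044, 0.0038)[i %% 3 + 1])),
            lapply(13:15, function(i) mk(i, "My", 0.0020)))
  t_ok <- list(id = 2L, history = hist, state = "closed")
  ts <- structure(list(tracklets = list(t_short, t_ok),
                       config = tracker_config(), n_frames = 15),
                  class = "track_set")
  rep <- yield_report(ts, tracker_config(min_track_length = 10))
  expect_equal(rep$total, 1)                      # 9 matches < 10 excluded
  expect_equal(rep$tracklets$sub_class, "Gn")     # 12 Gn vs 3 My
  expect_equal(rep$tracklets$max_area_cm2, 44)    # max of per-frame areas

  # tie in the vote resolves to the most recent frame's label
  tie <- list(id = 3L, history = c(lapply(1:2, function(i) mk(i, "Gn", 1e-4)),
                                   lapply(3:4, function(i) mk(i, "My", 1e-4))),
              state = "closed")
  ts2 <- structure(list(tracklets = list(tie), config = tracker_config(),
                        n_frames = 4), class = "track_set")
  expect_equal(yield_report(ts2, tracker_config(min_track_length = 2))$tracklets$sub_class,
               "My")

  # alternative vote modes: last label wins / confidence-weighted
  expect_equal(yield_report(ts, tracker_config(min_track_length = 10,
                                               subclass_vote = "last"))$tracklets$sub_class,
               "My")
  conf_hist <- c(lapply(1:6, function(i) {
    h <- mk(i, "Gn", 1e-4); h$confidence <- 0.2; h
  }), lapply(7:10, function(i) {
    h <- mk(i, "My", 1e-4); h$confidence <- 0.9; h
  }))
  ts3 <- structure(list(tracklets = list(list(id = 4L, history = conf_hist,
                                              state = "closed")),
                        config = tracker_config(), n_frames = 10),
                   class = "track_set")
  expect_equal(yield_report(ts3, tracker_config(min_track_length = 5,
                                                subclass_vote = "confidence"))$tracklets$sub_class,
               "My")    # 4 x 0.9 outweighs 6 x 0.2
  expect_equal(yield_report(ts3, tracker_config(min_track_length = 5))$tracklets$sub_class,
               "Gn")    # plain majority disagrees
})

test_that("configuration errors surface before processing", {
  frames <- lapply(0:3, function(k) frame_record(k, list(rect_mask(50, 50, 5, 5))))
  expect_error(track_sequence(frames, tracker_config(reprojection = TRUE),
                              K = K_default()), "odometry|pose")
  expect_error(track_sequence(frames,
                              tracker_config(depth_window = depth_window(0.4, 1)),
                              K = K_default()), "depth")
  expect_error(tracker_config(gamma = 1.2), "gamma")
  expect_error(tracker_config(frame_stride = 0), "stride")
})
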