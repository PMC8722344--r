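#' Run configuration for the pipeline commands
#'
#' Bundles the simulation specs, tracker settings, evaluation options and
#' output location consumed by [cmd_simulate()], [cmd_track()] and
#' [cmd_evaluate()]. A YAML file with the same nesting can be loaded with
#' [read_run_config()].
#'
#' @param output_dir Run directory; every output lands under it.
#' @param seed Integer seed for all randomized stages.
#' @param scene A [scene_spec()].
#' @param traverse A [traverse_spec()].
#' @param corruption A [corruption_spec()] or `NULL` for clean detections.
#' @param tracker A [tracker_config()] (base settings for the sweep).
#' @param criteria Character vector of matching criteria to run
#'   (subset of `c("iou", "dr")`).
#' @param reprojection Logical vector of reprojection settings to run.
#' @param depth_sweep Numeric vector of upper depth bounds `tau_h` to sweep
#'   (`NA` = no depth filtering), or `NULL` to keep the tracker's own window.
#'   The protocol sweep is `c(1.0, 1.4, NA)` with `tau_l = 0.4`.
#' @param tau_l Lower depth bound used in the sweep, meters.
#' @param eval_iou IoU threshold for detection/segmentation evaluation.
#' @export
run_config <- function(output_dir = "croptrack_run", seed = 1L,
                       scene = scene_spec(), traverse = traverse_spec(),
                       corruption = NULL, tracker = tracker_config(),
                       criteria = c("iou", "dr"),
                       reprojection = c(FALSE, TRUE),
                       depth_sweep = NULL, tau_l = 0.4, eval_iou = 0.4) {
  stopifnot(all(criteria %in% c("iou", "dr")))
  structure(list(output_dir = output_dir, seed = as.integer(seed),
                 scene = scene, traverse = traverse, corruption = corruption,
                 tracker = tracker, criteria = criteria,
                 reprojection = reprojection, depth_sweep = depth_sweep,
                 tau_l = tau_l, eval_iou = eval_iou),
            class = "run_config")
}

#' @rdname run_config
#' @param path YAML file with keys mirroring the `run_config` arguments
#'   (nested maps for `scene`, `traverse`, `corruption`, `tracker`).
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  build <- function(ctor, args) if (is.null(args)) NULL else do.call(ctor, args)
  run_config(
    output_dir = y$output_dir %||% dirname(path),
    seed = y$seed %||% 1L,
    scene = build(scene_spec, y$scene) %||% scene_spec(),
    traverse = build(traverse_spec, y$traverse) %||% traverse_spec(),
    corruption = build(corruption_spec, y$corruption),
    tracker = build(tracker_config, y$tracker) %||% tracker_config(),
    criteria = y$criteria %||% c("iou", "dr"),
    reprojection = as.logical(y$reprojection %||% c(FALSE, TRUE)),
    depth_sweep = if (is.null(y$depth_sweep)) NULL
                  else as.numeric(unlist(y$depth_sweep)),
    tau_l = y$tau_l %||% 0.4,
    eval_iou = y$eval_iou %||% 0.4)
}

write_provenance <- function(config, dir, stage) {
  cfg_path <- file.path(dir, sprintf("%s_config.yaml", stage))
  yaml::write_yaml(rapply(unclass(config), unclass, how = "replace"), cfg_path)
  jsonlite::write_json(list(stage = stage, seed = config$seed,
                            config_md5 = unname(tools::md5sum(cfg_path)),
                            package_version =
                              as.character(utils::packageVersion("croptrack")),
                            timestamp = format(Sys.time(), tz = "UTC")),
                       file.path(dir, sprintf("%s_provenance.json", stage)),
                       auto_unbox = TRUE)
  invisible(NULL)
}

#' Simulate: write a synthetic dataset to disk
#'
#' Generates the configured scene, renders the traverse, optionally corrupts
#' the detections, and writes the dataset plus a provenance block under
#' `output_dir/dataset`.
#'
#' @param config A [run_config()].
#' @return The rendered `synthetic_sequence`, invisibly.
#' @export
cmd_simulate <- function(config) {
  dir <- file.path(config$output_dir, "dataset")
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  scene <- generate_scene(config$scene, seed = config$seed)
  seq <- render_sequence(scene, config$traverse, seed = config$seed + 1L)
  if (!is.null(config$corruption))
    seq <- corrupt_detections(seq, config$corruption, seed = config$seed + 2L)
  write_dataset(seq, dir)
  write_provenance(config, config$output_dir, "simulate")
  invisible(seq)
}

sweep_settings <- function(config) {
  windows <- if (is.null(config$depth_sweep)) list(config$tracker$depth_window)
  else lapply(config$depth_sweep, function(th)
    if (is.na(th)) NULL else depth_window(config$tau_l, th))
  window_labels <- if (is.null(config$depth_sweep)) {
    if (is.null(config$tracker$depth_window)) "none"
    else sprintf("%.2f", config$tracker$depth_window$tau_h)
  } else ifelse(is.na(config$depth_sweep), "none",
                sprintf("%.2f", config$depth_sweep))
  grid <- expand.grid(criterion = config$criteria,
                      reprojection = config$reprojection,
                      window = seq_along(windows),
                      stringsAsFactors = FALSE)
  list(grid = grid, windows = windows, labels = window_labels)
}

#' Track: run the tracker sweep over a dataset
#'
#' Runs every combination of matching criterion, reprojection setting and
#' depth window in the config over the dataset (on disk under
#' `output_dir/dataset`, or passed in-memory), writing per-run track sets and
#' yield reports plus one joint sweep table.
#'
#' @param config A [run_config()].
#' @param dataset Optional in-memory dataset (a `synthetic_sequence` or the
#'   result of [read_dataset()]); defaults to reading
#'   `output_dir/dataset`.
#' @return Data frame summarizing the sweep (criterion, reprojection,
#'   depth window, total count), with the reports as attribute `reports`.
#' @export
cmd_track <- function(config, dataset = NULL) {
  if (is.null(dataset)) dataset <- read_dataset(file.path(config$output_dir, "dataset"))
  frames <- dataset$frames
  K <- dataset$K
  E <- dataset$E %||% diag(4)
  sw <- sweep_settings(config)
  out_dir <- file.path(config$output_dir, "tracking")
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  reports <- list()
  rows <- list()
  for (i in seq_len(nrow(sw$grid))) {
    g <- sw$grid[i, ]
    cfg <- config$tracker
    cfg$criterion <- g$criterion
    cfg$reprojection <- g$reprojection
    cfg$depth_window <- sw$windows[[g$window]]
    if (cfg$reprojection &&
        any(vapply(frames, function(f) is.null(f$pose), logical(1))))
      stop("reprojection requested but the dataset has no odometry")
    tracks <- track_sequence(frames, cfg, K = K, E = E)
    rep <- yield_report(tracks, cfg)
    tag <- sprintf("%s%s_tau%s", g$criterion,
                   if (g$reprojection) "_reproj" else "", sw$labels[g$window])
    write_trackset(tracks, file.path(out_dir, sprintf("trackset_%s.json", tag)), K)
    jsonlite::write_json(list(counts = as.list(rep$counts), total = rep$total),
                         file.path(out_dir, sprintf("report_%s.json", tag)),
                         auto_unbox = TRUE)
    reports[[tag]] <- rep
    rows[[i]] <- data.frame(criterion = g$criterion,
                            reprojection = g$reprojection,
                            depth_window = sw$labels[g$window],
                            total = rep$total)
  }
  sweep <- do.call(rbind, rows)
  utils::write.csv(sweep, file.path(out_dir, "sweep.csv"), row.names = FALSE)
  write_provenance(config, config$output_dir, "track")
  structure(sweep, reports = reports)
}

#' Evaluate detections of one sequence against ground truth
#'
#' Pools frames to compute detection precision/recall/F1 (at the P = R
#' operating point of the confidence sweep), segmentation IoU under both the
#' instance and the semantic protocol, and sub-class confusion accuracy.
#'
#' @param pred_frames,gt_frames Lists (per frame) of lists of
#'   [instance_mask()].
#' @param K [camera_intrinsics()].
#' @param vocab Sub-class vocabulary.
#' @param iou_threshold Match threshold.
#' @export
evaluate_sequence <- function(pred_frames, gt_frames, K, vocab,
                              iou_threshold = 0.4) {
  stopifnot(length(pred_frames) == length(gt_frames))
  tp <- fp <- fn <- 0L
  all_pred <- list(); all_gt <- list()
  inst_fg <- inst_bg <- inst_matched <- numeric(0)
  sem <- matrix(0, 0, 2)
  C <- matrix(0, length(vocab), length(vocab),
              dimnames = list(gt = vocab, pred = vocab))
  for (i in seq_along(pred_frames)) {
    mm <- match_detections(pred_frames[[i]], gt_frames[[i]], iou_threshold)
    tp <- tp + mm$TP; fp <- fp + mm$FP; fn <- fn + mm$FN
    ev <- instance_vs_semantic_eval(pred_frames[[i]], gt_frames[[i]],
                                    K$width, K$height, iou_threshold)
    n_inst <- mm$TP + mm$FP + mm$FN
    if (n_inst > 0) {
      inst_fg <- c(inst_fg, rep(ev$instance$fg_iou, n_inst))
      inst_bg <- c(inst_bg, rep(ev$instance$bg_iou, n_inst))
    }
    if (!is.na(ev$instance$fg_iou_matched))
      inst_matched <- c(inst_matched, rep(ev$instance$fg_iou_matched, mm$TP))
    sem <- rbind(sem, c(ev$semantic$bg_iou, ev$semantic$fg_iou))
    if (nrow(mm$pairs)) for (k in seq_len(nrow(mm$pairs))) {
      g <- gt_frames[[i]][[mm$pairs$gt[k]]]$sub_class
      p <- pred_frames[[i]][[mm$pairs$pred[k]]]$sub_class
      if (!is.na(g) && !is.na(p)) C[g, p] <- C[g, p] + 1
    }
  }
  P <- if (tp + fp == 0) 1 else tp / (tp + fp)
  R <- if (tp + fn == 0) 1 else tp / (tp + fn)
  pr <- tryCatch(pr_curve_f1(pred_frames, gt_frames, iou_threshold),
                 error = function(e) NULL)
  rs <- rowSums(C)
  C[rs > 0, ] <- C[rs > 0, , drop = FALSE] / rs[rs > 0]
  present <- rs > 0
  instance <- list(bg_iou = if (length(inst_bg)) mean(inst_bg) else 1,
                   fg_iou = if (length(inst_fg)) mean(inst_fg) else 1,
                   fg_iou_matched = if (length(inst_matched))
                     mean(inst_matched) else NA_real_)
  instance$mu_iou <- (instance$bg_iou + instance$fg_iou) / 2
  semantic <- list(bg_iou = if (nrow(sem)) mean(sem[, 1L]) else 1,
                   fg_iou = if (nrow(sem)) mean(sem[, 2L]) else 1)
  semantic$mu_iou <- (semantic$bg_iou + semantic$fg_iou) / 2
  list(precision = P, recall = R, f1 = f1_score(P, R),
       f1_pr_eq = if (is.null(pr)) NA_real_ else pr$f1,
       instance = instance, semantic = semantic,
       confusion = C,
       conf_acc = if (any(present))
         mean(diag(C)[present]) else NA_real_)
}

#' Evaluate: metric report for a run
#'
#' Computes the detection, segmentation and confusion metrics of the
#' dataset's detections against its ground truth (available when the dataset
#' was simulated with corruption: the manifest frames are the truth), plus
#' count agreement (mu-NAE, and R^2 when 2+ rows are given) between tracked
#' yield reports and ground-truth counts.
#'
#' @param config A [run_config()].
#' @param dataset Optional in-memory dataset (see [cmd_track()]).
#' @param gt_frames Optional list of per-frame ground-truth mask lists; when
#'   simulating, pass the clean render's frames.
#' @param row_counts Optional data frame with columns `gt` and `pred` of
#'   per-row totals for count metrics.
#' @return List with `detection`, `counts` (or `NULL`), written also as
#'   JSON under `output_dir/evaluation`.
#' @export
cmd_evaluate <- function(config, dataset = NULL, gt_frames = NULL,
                         row_counts = NULL) {
  if (is.null(dataset)) dataset <- read_dataset(file.path(config$output_dir, "dataset"))
  out_dir <- file.path(config$output_dir, "evaluation")
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  vocab <- dataset$vocab %||% names(config$scene$class_freqs)
  detection <- NULL
  if (!is.null(gt_frames)) {
    pred <- lapply(dataset$frames, function(fr) fr$masks)
    detection <- evaluate_sequence(pred, gt_frames, dataset$K, vocab,
                                   config$eval_iou)
  }
  counts <- NULL
  if (!is.null(row_counts)) {
    counts <- list(mu_nae = mu_nae(row_counts$gt, row_counts$pred))
    counts$r_squared <- if (nrow(row_counts) >= 2 &&
                            stats::var(row_counts$gt) > 0)
      r_squared(row_counts$gt, row_counts$pred) else NA_real_
  }
  report <- list(detection = detection, counts = counts)
  jsonlite::write_json(
    list(detection = if (is.null(detection)) NULL else
           detection[setdiff(names(detection), "confusion")],
         conf_acc = detection$conf_acc,
         counts = counts),
    file.path(out_dir, "metrics.json"), auto_unbox = TRUE, null = "null",
    digits = NA)
  write_provenance(config, config$output_dir, "evaluate")
  report
}
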