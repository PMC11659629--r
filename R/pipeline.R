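#' Run configuration
#'
#' Bundles the per-stage configurations of the full detection pipeline.
#'
#' @param tiling A [tile_config()].
#' @param proposer A [proposer_config()].
#' @param training A [train_config()].
#' @param augment A [perturb_config()].
#' @param matching A [match_config()].
#' @param backend A segmenter backend (default [reference_backend()]).
#' @param border_merge_um Centroid distance below which detections from
#'   different tiles are treated as the same object split by a tile border
#'   (default 6 um, about one nucleus diameter, so the part-centroids of a
#'   split two-lobed figure still merge); complements slide-frame box NMS,
#'   which cannot merge
#'   two adjacent non-overlapping part-boxes.
#' @param seed Master seed of the run.
#' @return An object of class \code{run_config}.
#' @export
run_config <- function(tiling = tile_config(),
                       proposer = proposer_config(),
                       training = train_config(),
                       augment = perturb_config(),
                       matching = match_config(),
                       backend = reference_backend(),
                       border_merge_um = 6,
                       seed = 0L) {
  structure(list(tiling = tiling, proposer = proposer, training = training,
                 augment = augment, matching = matching, backend = backend,
                 border_merge_um = border_merge_um,
                 seed = as.integer(seed)),
            class = "run_config")
}

#' Detect mitotic figures on an image
#'
#' Runs the full two-stage pipeline: background removal and tile planning,
#' per-tile object proposal with the configured backend, 64x64 crop
#' extraction, classification by one or more trained models (majority vote
#' when several), and cross-tile deduplication by slide-frame box NMS so an
#' object straddling a tile border is reported at most once. Deterministic
#' for a deterministic backend and fixed models.
#'
#' @param rgb Full-resolution y-by-x-by-3 raster in \code{[0,255]}.
#' @param models A \code{model_bundle} or list of bundles (ensemble).
#' @param config A [run_config()].
#' @param meta An [image_meta()]; derived from the raster when missing.
#' @return A \code{detection_set}: data.frame with one row per surviving
#'   candidate (\code{x_um}, \code{y_um}, \code{probability_mf},
#'   \code{label}, \code{tile_id}, \code{quality}, \code{area_um2}), with
#'   per-stage counters in \code{attr(, "counts")}.
#' @export
run_detection <- function(rgb, models, config = run_config(), meta = NULL) {
  if (inherits(models, "model_bundle")) models <- list(models)
  if (length(models) < 1L) stop("at least one trained model is required")
  if (is.null(meta)) {
    meta <- image_meta(dim(rgb)[2], dim(rgb)[1])
  }
  counts <- list(tiles_total = 0L, tiles_kept = 0L, candidates = 0L,
                 detections_mf = 0L)
  gray <- downsample_gray(rgb, config$tiling$downsample_factor)
  plan <- plan_tiles(meta, gray, config$tiling)
  counts$tiles_total <- ceiling(meta$width_px / config$tiling$tile_px) *
    ceiling(meta$height_px / config$tiling$tile_px)
  counts$tiles_kept <- nrow(plan)
  cands <- list()
  crops <- list()
  for (i in seq_len(nrow(plan))) {
    tile <- cut_tile(rgb, plan$origin_x_px[i], plan$origin_y_px[i],
                     config$tiling$tile_px)
    tc <- propose_objects(tile, config$backend, config$proposer, meta,
                          tile_origin = c(plan$origin_x_px[i], plan$origin_y_px[i]),
                          tile_id = plan$tile_id[i])
    for (cm in tc) {
      cands[[length(cands) + 1L]] <- cm
      crops[[length(crops) + 1L]] <- extract_object_crop(tile, cm,
                                                         config$proposer$crop_px)
    }
  }
  counts$candidates <- length(cands)
  if (length(cands) == 0L) {
    out <- data.frame(x_um = numeric(), y_um = numeric(),
                      probability_mf = numeric(),
                      label = factor(character(), levels = c("non-MF", "MF")),
                      tile_id = integer(), quality = numeric(),
                      area_um2 = numeric())
    attr(out, "counts") <- counts
    class(out) <- c("detection_set", "data.frame")
    return(out)
  }
  d <- stack_crops(crops, models[[1]]$spec)
  thr <- config$training$decision_threshold
  recs <- lapply(models, function(m) predict_scores(m, d, thr))
  ens <- ensemble_vote(recs)
  out <- data.frame(
    x_um = vapply(cands, `[[`, numeric(1), "slide_x") * meta$pixel_size_um,
    y_um = vapply(cands, `[[`, numeric(1), "slide_y") * meta$pixel_size_um,
    probability_mf = ens$probability_mf,
    label = ens$label,
    tile_id = vapply(cands, function(c) as.integer(c$tile_id), integer(1)),
    quality = vapply(cands, `[[`, numeric(1), "quality"),
    area_um2 = vapply(cands, `[[`, numeric(1), "area_um2"))
  # cross-tile duplicate suppression in the slide frame
  slide_boxes <- lapply(seq_along(cands), function(i) {
    b <- cands[[i]]$bbox
    ox <- cands[[i]]$slide_x - cands[[i]]$centroid_x
    oy <- cands[[i]]$slide_y - cands[[i]]$centroid_y
    c(b[1] + ox, b[2] + oy, b[3] + ox, b[4] + oy)
  })
  keep <- rep(TRUE, nrow(out))
  ord <- order(-out$quality, seq_len(nrow(out)))
  for (a in seq_along(ord)) {
    i <- ord[a]
    if (!keep[i]) next
    for (b in seq_len(a - 1L)) {
      j <- ord[b]
      if (!keep[j] || out$tile_id[i] == out$tile_id[j]) next
      dist_um <- sqrt((out$x_um[i] - out$x_um[j])^2 + (out$y_um[i] - out$y_um[j])^2)
      if (.box_iou(slide_boxes[[i]], slide_boxes[[j]]) > config$proposer$nms_iou ||
          dist_um < config$border_merge_um) {
        keep[i] <- FALSE
        break
      }
    }
  }
  out <- out[keep, , drop = FALSE]
  rownames(out) <- NULL
  counts$detections_mf <- sum(out$label == "MF")
  attr(out, "counts") <- counts
  class(out) <- c("detection_set", "data.frame")
  out
}

#' Train the classifier over several seeds
#'
#' Repeats training once per seed in \code{config$training$seeds}, each with
#' its own stratified train/validation split, and reports per-seed
#' validation metrics with mean and standard deviation.
#'
#' @param crops List of \code{object_crop}s (or pre-stacked matrix).
#' @param is_mf Logical binary target per crop.
#' @param config A [run_config()].
#' @param augment Apply stain/flip augmentation to the training crops once
#'   before training (default FALSE; desk-scale runs learn from clean
#'   renders).
#' @return List with \code{bundles} (one \code{model_bundle} per seed) and
#'   \code{report} (data.frame of per-seed validation accuracy plus a
#'   mean/sd summary attribute).
#' @export
run_train <- function(crops, is_mf, config = run_config(), augment = FALSE) {
  seeds <- config$training$seeds
  if (augment && !is.matrix(crops)) {
    set.seed(config$seed)
    crops <- lapply(crops, augment_crop, config = config$augment)
  }
  d <- if (is.matrix(crops)) crops else stack_crops(crops)
  bundles <- vector("list", length(seeds))
  rows <- vector("list", length(seeds))
  for (k in seq_along(seeds)) {
    bundles[[k]] <- train_classifier(d, is_mf, config$training, seed = seeds[k])
    h <- utils::tail(bundles[[k]]$history, 1L)
    rows[[k]] <- data.frame(seed = seeds[k], val_loss = h$val_loss,
                            val_acc = h$val_acc,
                            split_hash = paste(range(bundles[[k]]$split$val),
                                               collapse = "-"))
  }
  report <- do.call(rbind, rows)
  attr(report, "summary") <- data.frame(
    val_acc_mean = mean(report$val_acc),
    val_acc_sd = if (nrow(report) > 1L) stats::sd(report$val_acc) else 0,
    single_run = nrow(report) == 1L)
  list(bundles = bundles, report = report)
}

#' Evaluate detection sets against ground truth
#'
#' Matches each per-seed detection set (label "MF" rows) to the ground
#' truth, computes precision/recall/F1, and aggregates them with the
#' ensemble row into a benchmark-style report.
#'
#' @param detection_sets List of \code{detection_set}s (one per seed) or a
#'   single set.
#' @param truth data.frame with \code{x_um}, \code{y_um} of true mitotic
#'   figures (optionally a \code{group} column for per-group rows).
#' @param config A [run_config()].
#' @param ensemble Optional ensemble \code{detection_set}.
#' @return List with \code{per_run} (list of \code{metrics}),
#'   \code{ensemble} (metrics or NULL) and \code{report} (data.frame from
#'   [summarize_runs()]).
#' @export
run_eval <- function(detection_sets, truth, config = run_config(),
                     ensemble = NULL) {
  if (inherits(detection_sets, "detection_set")) {
    detection_sets <- list(detection_sets)
  }
  eval_one <- function(ds) {
    mf <- ds[ds$label == "MF", , drop = FALSE]
    compute_metrics(match_detections(mf, truth, config$matching))
  }
  per_run <- lapply(detection_sets, eval_one)
  ens_metrics <- if (!is.null(ensemble)) eval_one(ensemble) else NULL
  report <- summarize_runs(per_run, ensemble = ens_metrics)
  list(per_run = per_run, ensemble = ens_metrics, report = report)
}
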