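#' Proposal-stage configuration
#'
#' Defaults follow the detection protocol: a 64x64 point-prompt grid per
#' 1024 px tile (4096 prompts), predicted-quality (AI-IoU) and stability
#' thresholds of 0.8 (strictly greater-than), an admissible object area of
#' 2.25-225 um^2 (inclusive), and greedy box NMS at IoU 0.7.
#'
#' @param points_per_side Prompt-grid points along each tile dimension.
#' @param quality_min Minimum predicted-quality (AI-IoU) score, exclusive.
#' @param stability_min Minimum stability score, exclusive.
#' @param area_min_um2,area_max_um2 Inclusive object-area band in um^2.
#' @param nms_iou Non-maximum-suppression IoU threshold.
#' @param stability_offset Symmetric logit offset defining the high/low
#'   masks of the stability score.
#' @param crop_px Object crop edge length for the classifier stage.
#' @return An object of class \code{proposer_config}.
#' @export
proposer_config <- function(points_per_side = 64L,
                            quality_min = 0.8,
                            stability_min = 0.8,
                            area_min_um2 = 2.25,
                            area_max_um2 = 225,
                            nms_iou = 0.7,
                            stability_offset = 1.0,
                            crop_px = 64L) {
  stopifnot(points_per_side >= 1,
            quality_min >= 0, quality_min <= 1,
            stability_min >= 0, stability_min <= 1,
            area_min_um2 > 0, area_max_um2 > area_min_um2,
            nms_iou > 0, nms_iou <= 1, stability_offset > 0, crop_px >= 8)
  structure(list(points_per_side = as.integer(points_per_side),
                 quality_min = quality_min, stability_min = stability_min,
                 area_min_um2 = area_min_um2, area_max_um2 = area_max_um2,
                 nms_iou = nms_iou, stability_offset = stability_offset,
                 crop_px = as.integer(crop_px)),
            class = "proposer_config")
}

#' Generate an evenly spaced, cell-centred point-prompt grid
#'
#' Points are placed at the centres of a \code{points_per_side} square grid
#' of cells: spacing \code{tile_px / points_per_side}, first point at half a
#' spacing. The default configuration on a 1024 px tile yields 4096 prompts.
#'
#' @param tile_px Tile edge length in pixels.
#' @param points_per_side Points along each dimension.
#' @return Two-column matrix (x, y) of 0-based pixel coordinates,
#'   row-major (x fastest).
#' @export
generate_point_grid <- function(tile_px, points_per_side = 64L) {
  if (tile_px <= 0 || points_per_side <= 0) stop("inputs must be positive")
  s <- tile_px / points_per_side
  coords <- s * (seq_len(points_per_side) - 0.5)
  cbind(x = rep(coords, times = points_per_side),
        y = rep(coords, each = points_per_side))
}

#' Convert bounding boxes to box prompts
#'
#' Passes each positive-area box through as a prompt, preserving order; this
#' is the curation mode in which existing bounding-box annotations drive the
#' segmenter instead of a point grid.
#'
#' @param boxes Matrix or data.frame with columns \code{x0, y0, x1, y1}.
#' @return List of length-4 numeric prompts.
#' @export
prompts_from_boxes <- function(boxes) {
  boxes <- as.matrix(boxes)
  if (nrow(boxes) == 0L) return(list())
  if (ncol(boxes) != 4L) stop("boxes must have columns x0, y0, x1, y1")
  w <- boxes[, 3] - boxes[, 1]
  h <- boxes[, 4] - boxes[, 2]
  bad <- which(w <= 0 | h <= 0)
  if (length(bad)) {
    stop("zero-area box at index ", paste(bad, collapse = ", "))
  }
  lapply(seq_len(nrow(boxes)), function(i) {
    stats::setNames(as.numeric(boxes[i, ]), c("x0", "y0", "x1", "y1"))
  })
}

#' Stability score of a predicted mask-logit raster
#'
#' The intersection-over-union between the binary masks obtained by
#' thresholding the logits at a high (\code{+offset}) and a low
#' (\code{-offset}) value; a mask insensitive to the threshold scores near 1.
#' An empty union (no pixel above even the low threshold) scores 0.
#'
#' @param logits Numeric matrix of mask logits.
#' @param offset Positive symmetric logit offset (default 1).
#' @return Stability in \code{[0,1]}.
#' @export
compute_stability_score <- function(logits, offset = 1.0) {
  if (length(logits) == 0L) stop("empty logits raster")
  high <- logits >= offset
  low <- logits >= -offset
  uni <- sum(high | low)
  if (uni == 0L) return(0)
  sum(high & low) / uni
}

# Measure a binary mask: area, centroid (0-based px), bbox, boundary length.
.measure_mask <- function(mask) {
  px <- which(mask, arr.ind = TRUE)
  if (nrow(px) == 0L) return(NULL)
  # boundary pixels: mask pixels with a 4-neighbour outside the mask
  padded <- matrix(FALSE, nrow(mask) + 2L, ncol(mask) + 2L)
  padded[2:(nrow(mask) + 1L), 2:(ncol(mask) + 1L)] <- mask
  core <- padded[2:(nrow(mask) + 1L), 2:(ncol(mask) + 1L)] &
    padded[1:nrow(mask), 2:(ncol(mask) + 1L)] &
    padded[3:(nrow(mask) + 2L), 2:(ncol(mask) + 1L)] &
    padded[2:(nrow(mask) + 1L), 1:ncol(mask)] &
    padded[2:(nrow(mask) + 1L), 3:(ncol(mask) + 2L)]
  list(area_px = nrow(px),
       centroid_x = mean(px[, 2] - 1), centroid_y = mean(px[, 1] - 1),
       bbox = c(x0 = min(px[, 2]) - 1, y0 = min(px[, 1]) - 1,
                x1 = max(px[, 2]) - 1, y1 = max(px[, 1]) - 1),
       boundary_px = sum(mask & !core))
}

#' Construct a candidate mask record
#'
#' @param mask Logical tile-local mask matrix.
#' @param quality Predicted-quality (AI-IoU) score in \code{[0,1]}.
#' @param stability Stability score in \code{[0,1]}.
#' @param pixel_size_um Pixel size used to convert the area to um^2.
#' @return An object of class \code{candidate_mask}, or \code{NULL} for an
#'   empty mask.
#' @export
candidate_mask <- function(mask, quality, stability, pixel_size_um = 0.25) {
  m <- .measure_mask(mask)
  if (is.null(m)) return(NULL)
  structure(list(mask = mask, quality = quality, stability = stability,
                 area_px = m$area_px,
                 area_um2 = m$area_px * pixel_size_um^2,
                 centroid_x = m$centroid_x, centroid_y = m$centroid_y,
                 bbox = m$bbox, boundary_px = m$boundary_px),
            class = "candidate_mask")
}

#' Filter candidates by quality, stability and area
#'
#' A candidate is kept iff its quality and stability scores are strictly
#' greater than their thresholds and its area lies inside the inclusive
#' \code{[area_min_um2, area_max_um2]} band.
#'
#' @param candidates List of [candidate_mask()] records.
#' @param config A [proposer_config()].
#' @param pixel_size_um Pixel size; used to (re)derive area in um^2 when a
#'   candidate lacks it.
#' @return Filtered list (a subset of the input, order preserved).
#' @export
filter_candidates <- function(candidates, config = proposer_config(),
                              pixel_size_um = 0.25) {
  keep <- vapply(candidates, function(cm) {
    a2 <- if (!is.null(cm$area_um2)) cm$area_um2 else cm$area_px * pixel_size_um^2
    cm$quality > config$quality_min &&
      cm$stability > config$stability_min &&
      a2 >= config$area_min_um2 && a2 <= config$area_max_um2
  }, logical(1))
  candidates[keep]
}

# IoU of two inclusive pixel bounding boxes c(x0, y0, x1, y1)
.box_iou <- function(a, b) {
  ix <- max(0, min(a[3], b[3]) - max(a[1], b[1]) + 1)
  iy <- max(0, min(a[4], b[4]) - max(a[2], b[2]) + 1)
  inter <- ix * iy
  if (inter <= 0) return(0)
  area_a <- (a[3] - a[1] + 1) * (a[4] - a[2] + 1)
  area_b <- (b[3] - b[1] + 1) * (b[4] - b[2] + 1)
  inter / (area_a + area_b - inter)
}

.mask_iou <- function(a, b) {
  inter <- sum(a & b)
  uni <- sum(a | b)
  if (uni == 0L) 0 else inter / uni
}

#' Greedy non-maximum suppression of candidate masks
#'
#' Candidates are ranked by descending quality (ties broken by lower input
#' index); walking down the ranking, a candidate is suppressed if its IoU
#' with an already kept candidate exceeds \code{nms_iou}. Bounding-box IoU is
#' the default; mask IoU is available behind a flag.
#'
#' @param candidates List of [candidate_mask()] records.
#' @param nms_iou Suppression threshold (exclusive).
#' @param use_mask Use exact mask IoU instead of box IoU.
#' @return Deduplicated list in ranking order.
#' @export
nms_dedupe <- function(candidates, nms_iou = 0.7, use_mask = FALSE) {
  n <- length(candidates)
  if (n <= 1L) return(candidates)
  q <- vapply(candidates, `[[`, numeric(1), "quality")
  ord <- order(-q, seq_len(n))
  kept <- integer(0)
  for (i in ord) {
    clash <- FALSE
    for (j in kept) {
      iou <- if (use_mask) .mask_iou(candidates[[i]]$mask, candidates[[j]]$mask)
             else .box_iou(candidates[[i]]$bbox, candidates[[j]]$bbox)
      if (iou > nms_iou) { clash <- TRUE; break }
    }
    if (!clash) kept <- c(kept, i)
  }
  candidates[kept]
}

#' Reference segmenter backend
#'
#' A deterministic, self-contained promptable segmenter used for testing and
#' desk-scale runs: near-white glass (grey >= \code{glass_cut}) is excluded,
#' the tile is thresholded at \code{nuclei_factor} times the median grey of
#' the remaining tissue pixels (the tissue mode, robust to tiles that are
#' part glass), connected components are labelled, and each component with a
#' prompt point on it, or within \code{snap_px} of it, is returned as a
#' candidate (a promptable segmenter tolerates small prompt offsets; without
#' the snap, an object smaller than the prompt spacing can fall between four
#' grid points and be lost). The
#' predicted-quality score is one minus a boundary-roughness proxy
#' (\code{1 - 0.2 * (1 - circularity)}, circularity = 4 pi A / P^2 clamped
#' to \code{[0,1]}), so compact nuclei score near 1; the stability score is
#' 1 by construction (the mask is binary, not a logit map).
#'
#' @param nuclei_factor Multiplier of the tissue-mode grey defining the
#'   nucleus threshold (default 0.85).
#' @param glass_cut Grey value at and above which pixels count as glass and
#'   are excluded from the tissue-mode estimate (default 240).
#' @param snap_px Radius (pixels) within which a prompt point snaps to the
#'   nearest labelled component (default 3).
#' @param min_px Components smaller than this many pixels are ignored.
#' @return An object of class \code{reference_backend}.
#' @export
reference_backend <- function(nuclei_factor = 0.85, glass_cut = 240,
                              snap_px = 3L, min_px = 4L) {
  structure(list(nuclei_factor = nuclei_factor, glass_cut = glass_cut,
                 snap_px = as.integer(snap_px), min_px = as.integer(min_px)),
            class = "reference_backend")
}

#' Segment a tile with a backend
#'
#' Generic dispatch for segmenter backends. A backend receives an RGB tile
#' and prompt points and returns a list of \code{(mask, quality, stability)}
#' candidates whose mask raster matches the tile shape.
#'
#' @param backend A backend object, e.g. [reference_backend()].
#' @param tile_rgb y-by-x-by-3 array in \code{[0,255]}.
#' @param points Two-column (x, y) prompt matrix, 0-based pixels.
#' @param pixel_size_um Pixel size forwarded to [candidate_mask()].
#' @return List of [candidate_mask()] records.
#' @export
segment_tile <- function(backend, tile_rgb, points, pixel_size_um = 0.25) {
  UseMethod("segment_tile")
}

#' @export
segment_tile.reference_backend <- function(backend, tile_rgb, points,
                                           pixel_size_um = 0.25) {
  gray <- downsample_gray(tile_rgb, 1L)
  tissue <- gray[gray < backend$glass_cut]
  if (length(tissue) == 0L) return(list())
  thr <- backend$nuclei_factor * stats::median(tissue)
  bin <- gray < thr
  if (!any(bin)) return(list())
  lab <- EBImage::bwlabel(bin)
  # labels hit by a prompt point, allowing a small snap radius: nearer
  # offsets take precedence so each prompt selects its closest component
  py <- pmin(pmax(round(points[, 2]) + 1L, 1L), nrow(gray))
  px <- pmin(pmax(round(points[, 1]) + 1L, 1L), ncol(gray))
  offs <- expand.grid(dy = -backend$snap_px:backend$snap_px,
                      dx = -backend$snap_px:backend$snap_px)
  offs <- offs[order(offs$dy^2 + offs$dx^2), , drop = FALSE]
  sel <- integer(length(py))
  for (k in seq_len(nrow(offs))) {
    todo <- sel == 0L
    if (!any(todo)) break
    yy <- pmin(pmax(py[todo] + offs$dy[k], 1L), nrow(gray))
    xx <- pmin(pmax(px[todo] + offs$dx[k], 1L), ncol(gray))
    sel[todo] <- lab[cbind(yy, xx)]
  }
  hit <- sort(unique(sel))
  hit <- hit[hit > 0]
  out <- list()
  for (id in hit) {
    mask <- lab == id
    if (sum(mask) < backend$min_px) next
    cm <- candidate_mask(mask, quality = NA_real_, stability = 1.0,
                         pixel_size_um = pixel_size_um)
    circ <- 4 * pi * cm$area_px / max(cm$boundary_px, 1)^2
    circ <- min(max(circ, 0), 1)
    cm$quality <- 1 - 0.2 * (1 - circ)
    out[[length(out) + 1L]] <- cm
  }
  out
}

#' Propose candidate objects on one tile
#'
#' Orchestrates the proposal stage: generate the point-prompt grid, run the
#' segmenter backend, measure and score candidates, apply the
#' quality/stability/area filter and greedy NMS. Deterministic for a
#' deterministic backend.
#'
#' @param tile_rgb y-by-x-by-3 tile raster in \code{[0,255]}.
#' @param backend A segmenter backend (see [segment_tile()]).
#' @param config A [proposer_config()].
#' @param meta An [image_meta()] (supplies the pixel size).
#' @param tile_origin Length-2 (x, y) pixel origin of the tile in the slide
#'   frame; stored on each candidate as \code{slide_x / slide_y}.
#' @param tile_id Identifier attached to error messages and candidates.
#' @return List of [candidate_mask()] records that survived filter and NMS,
#'   each annotated with slide-frame centroid coordinates.
#' @export
propose_objects <- function(tile_rgb, backend, config = proposer_config(),
                            meta = image_meta(dim(tile_rgb)[2], dim(tile_rgb)[1]),
                            tile_origin = c(0, 0), tile_id = 1L) {
  grid <- generate_point_grid(dim(tile_rgb)[2], config$points_per_side)
  cands <- tryCatch(
    segment_tile(backend, tile_rgb, grid, pixel_size_um = meta$pixel_size_um),
    error = function(e) stop("segmenter backend failed on tile ", tile_id,
                             ": ", conditionMessage(e)))
  cands <- filter_candidates(cands, config, meta$pixel_size_um)
  cands <- nms_dedupe(cands, config$nms_iou)
  lapply(cands, function(cm) {
    cm$tile_id <- tile_id
    cm$slide_x <- cm$centroid_x + tile_origin[1]
    cm$slide_y <- cm$centroid_y + tile_origin[2]
    cm
  })
}

# reflecting (symmetric) index into 1..n for 1-based positions
.reflect_index <- function(idx, n) {
  idx <- idx - 1L
  period <- 2L * n
  idx <- idx %% period
  idx <- ifelse(idx < 0L, idx + period, idx)
  ifelse(idx < n, idx, period - idx - 1L) + 1L
}

#' Extract a classifier crop around a candidate
#'
#' Cuts a \code{crop_px} square window centred on the candidate's mask
#' centroid at native resolution. The RGB channels are reflect-padded where
#' the window leaves the tile; the mask channel uses the candidate's own mask
#' and is zero outside it (and outside the tile), so the crop's mask area
#' never exceeds the candidate's.
#'
#' @param tile_rgb y-by-x-by-3 tile raster.
#' @param candidate A [candidate_mask()].
#' @param crop_px Window edge length (default 64); must not exceed the tile.
#' @return An \code{object_crop}: list with \code{rgb}, \code{mask} and the
#'   source candidate's centroid.
#' @export
extract_object_crop <- function(tile_rgb, candidate, crop_px = 64L) {
  ny <- dim(tile_rgb)[1]
  nx <- dim(tile_rgb)[2]
  if (crop_px > ny || crop_px > nx) stop("crop_px larger than tile")
  cx <- round(candidate$centroid_x) + 1L  # 1-based column
  cy <- round(candidate$centroid_y) + 1L
  half <- crop_px %/% 2L
  xs <- (cx - half + 1L):(cx - half + crop_px)
  ys <- (cy - half + 1L):(cy - half + crop_px)
  xr <- .reflect_index(xs, nx)
  yr <- .reflect_index(ys, ny)
  rgb <- tile_rgb[yr, xr, , drop = FALSE]
  mask <- matrix(FALSE, crop_px, crop_px)
  inside_x <- xs >= 1L & xs <= nx
  inside_y <- ys >= 1L & ys <= ny
  mask[inside_y, inside_x] <- candidate$mask[ys[inside_y], xs[inside_x]]
  structure(list(rgb = rgb, mask = mask,
                 centroid_x = candidate$centroid_x,
                 centroid_y = candidate$centroid_y),
            class = "object_crop")
}

#' Tabulate candidates for export
#'
#' @param candidates List of [candidate_mask()] records (as returned by
#'   [propose_objects()]).
#' @return data.frame with tile_id, slide/tile coordinates, quality,
#'   stability and area columns.
#' @export
candidates_as_df <- function(candidates) {
  if (length(candidates) == 0L) {
    return(data.frame(tile_id = integer(), x_px = numeric(), y_px = numeric(),
                      quality = numeric(), stability = numeric(),
                      area_um2 = numeric()))
  }
  data.frame(
    tile_id = vapply(candidates, function(c) as.integer(c$tile_id %||% NA_integer_), integer(1)),
    x_px = vapply(candidates, function(c) c$slide_x %||% c$centroid_x, numeric(1)),
    y_px = vapply(candidates, function(c) c$slide_y %||% c$centroid_y, numeric(1)),
    quality = vapply(candidates, `[[`, numeric(1), "quality"),
    stability = vapply(candidates, `[[`, numeric(1), "stability"),
    area_um2 = vapply(candidates, `[[`, numeric(1), "area_um2"))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
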