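#' Image metadata
#'
#' @param width_px,height_px Raster dimensions in pixels.
#' @param pixel_size_um Pixel edge length in micrometres (default 0.25,
#'   i.e. a 40x scan).
#' @param magnification_label Optional free-text label such as "40x".
#' @return An object of class \code{image_meta}.
#' @export
image_meta <- function(width_px, height_px, pixel_size_um = 0.25,
                       magnification_label = NULL) {
  stopifnot(width_px >= 1, height_px >= 1, pixel_size_um > 0)
  structure(list(width_px = as.integer(width_px),
                 height_px = as.integer(height_px),
                 pixel_size_um = pixel_size_um,
                 magnification_label = magnification_label),
            class = "image_meta")
}

#' Tiling configuration
#'
#' @param tile_px Tile edge length in pixels (default 1024).
#' @param downsample_factor Integer factor for the low-resolution grayscale
#'   analysis used for background removal (default 8).
#' @param min_tissue_fraction Minimum fraction of tissue pixels for a tile to
#'   be retained (default 0.1).
#' @param perimeter_factor Coefficient of the perimeter background-threshold
#'   rule (default 0.9): tissue iff grey value < perimeter_factor times the
#'   mean of the one-pixel border ring.
#' @return An object of class \code{tile_config}.
#' @export
tile_config <- function(tile_px = 1024L, downsample_factor = 8L,
                        min_tissue_fraction = 0.1, perimeter_factor = 0.9) {
  stopifnot(tile_px >= 64, downsample_factor >= 1,
            min_tissue_fraction >= 0, min_tissue_fraction <= 1,
            perimeter_factor > 0)
  structure(list(tile_px = as.integer(tile_px),
                 downsample_factor = as.integer(downsample_factor),
                 min_tissue_fraction = min_tissue_fraction,
                 perimeter_factor = perimeter_factor),
            class = "tile_config")
}

#' Downsample an RGB raster to grayscale
#'
#' Converts to luminance (Rec. 601: 0.299 R + 0.587 G + 0.114 B) and
#' block-averages by an integer factor. Dimensions that are not multiples of
#' the factor are truncated to the largest covered multiple.
#'
#' @param rgb y-by-x-by-3 array in \code{[0,255]}, or an y-by-x matrix
#'   already in grayscale.
#' @param factor Integer block size, >= 1.
#' @return Grayscale matrix with values in \code{[0,255]}.
#' @export
downsample_gray <- function(rgb, factor = 1L) {
  if (length(rgb) == 0L) stop("empty raster")
  stopifnot(factor >= 1)
  factor <- as.integer(factor)
  gray <- if (length(dim(rgb)) == 3L) {
    0.299 * rgb[, , 1] + 0.587 * rgb[, , 2] + 0.114 * rgb[, , 3]
  } else {
    rgb
  }
  if (factor == 1L) return(gray)
  ny <- nrow(gray) %/% factor
  nx <- ncol(gray) %/% factor
  if (ny < 1L || nx < 1L) stop("raster smaller than one block")
  gray <- gray[seq_len(ny * factor), seq_len(nx * factor), drop = FALSE]
  # block mean via two rowsum passes
  g <- rowsum(gray, rep(seq_len(ny), each = factor)) / factor
  g <- t(rowsum(t(g), rep(seq_len(nx), each = factor)) / factor)
  g
}

#' Estimate the background threshold from the image perimeter
#'
#' Whole-slide scans carry mostly empty (bright) glass at their edges, so the
#' one-pixel border ring estimates the background intensity. The threshold is
#' \code{perimeter_factor} times the ring's mean grey value; a pixel counts
#' as tissue iff its grey value is strictly below the threshold.
#'
#' @param gray Grayscale matrix, at least 3x3.
#' @param perimeter_factor Threshold coefficient (default 0.9).
#' @return Scalar threshold on the grey scale of the input.
#' @export
estimate_background_threshold <- function(gray, perimeter_factor = 0.9) {
  if (nrow(gray) < 3L || ncol(gray) < 3L) stop("raster must be at least 3x3")
  ring <- c(gray[1, ], gray[nrow(gray), ],
            gray[2:(nrow(gray) - 1L), 1], gray[2:(nrow(gray) - 1L), ncol(gray)])
  thr <- perimeter_factor * mean(ring)
  if (thr <= 0) {
    message("degenerate background threshold (dark perimeter): no tissue will be detected")
  }
  thr
}

#' Tissue fraction of a tile
#'
#' @param gray_tile Grayscale matrix.
#' @param threshold Background threshold; tissue iff grey < threshold.
#' @return Fraction of tissue pixels in \code{[0,1]}.
#' @export
tissue_fraction <- function(gray_tile, threshold) {
  if (length(gray_tile) == 0L) stop("empty tile")
  mean(gray_tile < threshold)
}

#' Plan tissue tiles over a raster
#'
#' Lays non-overlapping tiles of \code{tile_px} at stride \code{tile_px} over
#' the raster (0-based half-open pixel intervals, x rightwards, y downwards),
#' white-padding partial edge tiles, and retains tiles whose tissue fraction
#' is at least \code{min_tissue_fraction}. The tissue fraction is computed on
#' the supplied grayscale raster, which may be a downsampled version of the
#' slide: pass the matching \code{downsample_factor} so tile footprints are
#' scaled accordingly while reported origins stay in full-resolution pixels.
#'
#' @param meta An [image_meta()] describing the full-resolution raster.
#' @param gray Grayscale matrix (full resolution or downsampled).
#' @param config A [tile_config()].
#' @param threshold Optional precomputed background threshold; estimated from
#'   the perimeter of \code{gray} when missing.
#' @return A \code{tile_plan}: data.frame with columns \code{tile_id},
#'   \code{origin_x_px}, \code{origin_y_px}, \code{tissue_fraction}, sorted
#'   by (y, x), with the config and threshold attached as attributes.
#' @export
plan_tiles <- function(meta, gray, config = tile_config(), threshold = NULL) {
  stopifnot(inherits(meta, "image_meta"), inherits(config, "tile_config"))
  f <- config$downsample_factor
  tile_lr <- config$tile_px / f
  if (tile_lr != round(tile_lr)) {
    stop("tile_px must be a multiple of downsample_factor")
  }
  tile_lr <- as.integer(tile_lr)
  if (is.null(threshold)) {
    threshold <- estimate_background_threshold(gray, config$perimeter_factor)
  }
  nx <- max(1L, as.integer(ceiling(meta$width_px / config$tile_px)))
  ny <- max(1L, as.integer(ceiling(meta$height_px / config$tile_px)))
  # white-pad the low-res raster to the planned extent
  pad_y <- ny * tile_lr
  pad_x <- nx * tile_lr
  g <- matrix(255, pad_y, pad_x)
  g[seq_len(min(nrow(gray), pad_y)), seq_len(min(ncol(gray), pad_x))] <-
    gray[seq_len(min(nrow(gray), pad_y)), seq_len(min(ncol(gray), pad_x))]
  rows <- list()
  k <- 0L
  for (iy in seq_len(ny)) {
    for (ix in seq_len(nx)) {
      sub <- g[((iy - 1L) * tile_lr + 1L):(iy * tile_lr),
               ((ix - 1L) * tile_lr + 1L):(ix * tile_lr)]
      fr <- tissue_fraction(sub, threshold)
      if (fr >= config$min_tissue_fraction) {
        k <- k + 1L
        rows[[k]] <- data.frame(
          tile_id = k,
          origin_x_px = (ix - 1L) * config$tile_px,
          origin_y_px = (iy - 1L) * config$tile_px,
          tissue_fraction = fr)
      }
    }
  }
  plan <- if (k > 0L) do.call(rbind, rows) else
    data.frame(tile_id = integer(), origin_x_px = integer(),
               origin_y_px = integer(), tissue_fraction = numeric())
  attr(plan, "threshold") <- threshold
  attr(plan, "config") <- config
  class(plan) <- c("tile_plan", "data.frame")
  plan
}

#' Cut one planned tile out of a full-resolution raster
#'
#' Returns the \code{tile_px} square at the given origin, white-padding
#' (value 255) beyond the raster edge so every tile has a uniform shape.
#'
#' @param rgb Full-resolution y-by-x-by-3 raster.
#' @param origin_x_px,origin_y_px 0-based tile origin in pixels.
#' @param tile_px Tile edge length.
#' @return y-by-x-by-3 array of size \code{tile_px}.
#' @export
cut_tile <- function(rgb, origin_x_px, origin_y_px, tile_px) {
  out <- array(255, dim = c(tile_px, tile_px, 3L))
  y0 <- origin_y_px + 1L
  x0 <- origin_x_px + 1L
  ys <- y0:min(nrow(rgb), origin_y_px + tile_px)
  xs <- x0:min(ncol(rgb), origin_x_px + tile_px)
  if (length(ys) > 0L && length(xs) > 0L && ys[1] <= nrow(rgb) && xs[1] <= ncol(rgb)) {
    out[seq_along(ys), seq_along(xs), ] <- rgb[ys, xs, , drop = FALSE]
  }
  out
}
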