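#' Registration configuration
#'
#' Settings for RANSAC affine estimation between an immunolabelled slide and
#' its restained H&E counterpart, and for chromogen-positivity thresholds.
#' The shipped RGB thresholds (\code{dab_default}) select a brown DAB-like
#' chromogen on a pale background; they are illustrative defaults, not
#' calibrated to any particular scanner or stain batch.
#'
#' @param ransac_iters RANSAC iterations (default 2000).
#' @param inlier_tol_px Inlier residual tolerance in pixels (default 3).
#' @param min_correspondences Minimum point pairs required (>= 3).
#' @param rgb_thresholds Named list of per-channel \code{c(min, max)}
#'   intervals (\code{r}, \code{g}, \code{b}) defining chromogen positivity.
#' @param min_area_px Positive components smaller than this are discarded.
#' @param seed Integer seed for the RANSAC sampler.
#' @return An object of class \code{registration_config}.
#' @export
registration_config <- function(ransac_iters = 2000L,
                                inlier_tol_px = 3.0,
                                min_correspondences = 3L,
                                rgb_thresholds = list(r = c(110, 210),
                                                      g = c(0, 130),
                                                      b = c(0, 110)),
                                min_area_px = 16L,
                                seed = 0L) {
  stopifnot(ransac_iters >= 1, inlier_tol_px > 0, min_correspondences >= 3,
            all(vapply(rgb_thresholds, function(iv)
              length(iv) == 2 && iv[1] >= 0 && iv[2] <= 255 && iv[1] <= iv[2], TRUE)))
  structure(list(ransac_iters = as.integer(ransac_iters),
                 inlier_tol_px = inlier_tol_px,
                 min_correspondences = as.integer(min_correspondences),
                 rgb_thresholds = rgb_thresholds,
                 min_area_px = as.integer(min_area_px),
                 seed = as.integer(seed)),
            class = "registration_config")
}

#' Extract a chromogen-positive mask from an immunolabelled raster
#'
#' A pixel is positive iff every channel lies inside its configured interval;
#' connected components below the minimum area are discarded.
#'
#' @param ihc_rgb y-by-x-by-3 array in \code{[0,255]}.
#' @param rgb_thresholds Named list of \code{c(min, max)} intervals per
#'   channel (see [registration_config()]).
#' @param min_area_px Minimum component area in pixels.
#' @return List with \code{mask} (logical matrix), \code{labels} (integer
#'   component matrix) and \code{components} (data.frame: id, area_px,
#'   x_px, y_px centroids, 0-based).
#' @export
extract_positive_mask <- function(ihc_rgb,
                                  rgb_thresholds = registration_config()$rgb_thresholds,
                                  min_area_px = 16L) {
  th <- rgb_thresholds
  mask <- ihc_rgb[, , 1] >= th$r[1] & ihc_rgb[, , 1] <= th$r[2] &
          ihc_rgb[, , 2] >= th$g[1] & ihc_rgb[, , 2] <= th$g[2] &
          ihc_rgb[, , 3] >= th$b[1] & ihc_rgb[, , 3] <= th$b[2]
  comps <- data.frame(id = integer(), area_px = integer(),
                      x_px = numeric(), y_px = numeric())
  labels <- matrix(0L, nrow(mask), ncol(mask))
  if (any(mask)) {
    labels <- EBImage::bwlabel(mask)
    tab <- tabulate(labels[labels > 0])
    keep <- which(tab >= min_area_px)
    drop <- which(tab < min_area_px)
    for (id in drop) {
      sel <- labels == id
      labels[sel] <- 0L
      mask[sel] <- FALSE
    }
    if (length(keep)) {
      comps <- do.call(rbind, lapply(keep, function(id) {
        px <- which(labels == id, arr.ind = TRUE)
        data.frame(id = id, area_px = nrow(px),
                   x_px = mean(px[, 2] - 1), y_px = mean(px[, 1] - 1))
      }))
    }
  }
  list(mask = mask, labels = labels, components = comps)
}

# least-squares affine fit: dst ~ A src + t, returns 2x3 matrix
.fit_affine <- function(src, dst) {
  x <- cbind(src, 1)
  coef <- qr.solve(x, dst)   # 3 x 2
  t(coef)                    # 2 x 3: rows (a11 a12 tx; a21 a22 ty)
}

.apply_affine <- function(transform, pts) {
  pts <- as.matrix(pts)
  sweep(pts %*% t(transform[, 1:2]), 2L, transform[, 3], `+`)
}

#' Estimate an affine transform by RANSAC
#'
#' Repeatedly fits an affine map to random 3-point samples of the
#' correspondences, scores it by the count of inliers (residual within
#' \code{inlier_tol_px}), and refits the best model on its full inlier set
#' by least squares. Reproducible for a fixed seed.
#'
#' @param src,dst Two-column (x, y) matrices of corresponding points in
#'   pixels.
#' @param config A [registration_config()].
#' @return List with \code{transform} (2x3 matrix), \code{inliers} (integer
#'   indices), \code{n_inliers} and \code{ok} (FALSE when no model reached 3
#'   inliers).
#' @export
estimate_affine_ransac <- function(src, dst, config = registration_config()) {
  src <- as.matrix(src)
  dst <- as.matrix(dst)
  n <- nrow(src)
  if (n != nrow(dst)) stop("src and dst must pair up")
  if (n < 3L) stop("at least 3 correspondences are required")
  if (n < config$min_correspondences) {
    stop("fewer than min_correspondences point pairs")
  }
  set.seed(config$seed)
  best_inl <- integer(0)
  for (it in seq_len(config$ransac_iters)) {
    s <- sample.int(n, 3L)
    tf <- tryCatch(.fit_affine(src[s, , drop = FALSE], dst[s, , drop = FALSE]),
                   error = function(e) NULL)
    if (is.null(tf)) next
    res <- sqrt(rowSums((.apply_affine(tf, src) - dst)^2))
    inl <- which(res <= config$inlier_tol_px)
    if (length(inl) > length(best_inl)) best_inl <- inl
  }
  if (length(best_inl) < 3L) {
    return(list(transform = NULL, inliers = integer(0), n_inliers = 0L,
                ok = FALSE))
  }
  tf <- .fit_affine(src[best_inl, , drop = FALSE], dst[best_inl, , drop = FALSE])
  res <- sqrt(rowSums((.apply_affine(tf, src) - dst)^2))
  inl <- which(res <= config$inlier_tol_px)
  list(transform = tf, inliers = inl, n_inliers = length(inl), ok = TRUE)
}

#' Invert an affine transform
#'
#' @param transform 2x3 affine matrix.
#' @return The inverse 2x3 matrix.
#' @export
affine_invert <- function(transform) {
  a <- transform[, 1:2]
  if (abs(det(a)) < 1e-12) stop("singular transform")
  ainv <- solve(a)
  cbind(ainv, -ainv %*% transform[, 3])
}

#' Transfer annotations through an affine transform
#'
#' Maps centroid annotations (and optionally masks) from one slide frame to
#' another. Centroids transform exactly; masks are resampled
#' nearest-neighbour through the inverse transform. Objects landing outside
#' the target raster are flagged \code{out_of_bounds}, never silently
#' dropped.
#'
#' @param annotations data.frame with \code{x_px}, \code{y_px} (0-based
#'   pixel centroids in the source frame); other columns pass through.
#' @param transform 2x3 affine matrix mapping source to target pixels.
#' @param target_meta An [image_meta()] for the target raster.
#' @param masks Optional list of logical source-frame masks aligned with
#'   the annotation rows.
#' @return The annotations with transformed \code{x_px}, \code{y_px}, an
#'   \code{out_of_bounds} flag, and (when masks were given) a
#'   \code{"masks"} attribute of transformed target-frame masks.
#' @export
transfer_annotations <- function(annotations, transform, target_meta,
                                 masks = NULL) {
  if (abs(det(transform[, 1:2])) < 1e-12) stop("singular transform")
  pts <- .apply_affine(transform, cbind(annotations$x_px, annotations$y_px))
  out <- annotations
  out$x_px <- pts[, 1]
  out$y_px <- pts[, 2]
  out$out_of_bounds <- pts[, 1] < 0 | pts[, 1] > target_meta$width_px - 1 |
    pts[, 2] < 0 | pts[, 2] > target_meta$height_px - 1
  if (!is.null(masks)) {
    inv <- affine_invert(transform)
    new_masks <- lapply(masks, function(m) {
      tm <- matrix(FALSE, target_meta$height_px, target_meta$width_px)
      xs <- rep(0:(target_meta$width_px - 1L), each = target_meta$height_px)
      ys <- rep(0:(target_meta$height_px - 1L), times = target_meta$width_px)
      sp <- .apply_affine(inv, cbind(xs, ys))
      sx <- round(sp[, 1]) + 1L
      sy <- round(sp[, 2]) + 1L
      ok <- sx >= 1L & sx <= ncol(m) & sy >= 1L & sy <= nrow(m)
      tm[cbind(ys + 1L, xs + 1L)[ok, , drop = FALSE]] <- m[cbind(sy, sx)[ok, , drop = FALSE]]
      tm
    })
    attr(out, "masks") <- new_masks
  }
  out
}
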