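#' Synthetic H&E scene configuration
#'
#' Describes a rendered scene: a bright eosin-washed background carrying four
#' classes of cell-scale objects with distinct morphology and haematoxylin
#' uptake, emulating the object taxonomy of a curated mitosis dataset:
#' \itemize{
#'   \item \code{ordinary} - smooth ellipses with moderate haematoxylin
#'     (interphase nuclei),
#'   \item \code{mf} - two-lobed "barbell" shapes with high haematoxylin
#'     (condensed chromosomes of a dividing cell),
#'   \item \code{mlf} - small dense round bodies (pyknotic nuclei/apoptotic
#'     bodies, the classic mitosis mimics),
#'   \item \code{clutter} - faint elongated fragments (debris, artefacts).
#' }
#' Objects are drawn as stain concentrations, mapped through the stain matrix
#' to optical density and then to RGB, so stain deconvolution recovers the
#' planted concentrations exactly (up to the configured OD noise).
#'
#' @param scene_px Scene edge length in pixels (default 1024).
#' @param pixel_size_um Pixel size (default 0.25 um).
#' @param counts Named integer vector with entries \code{ordinary}, \code{mf},
#'   \code{mlf}, \code{clutter}.
#' @param area_um2 Named list of length-2 numeric ranges (um^2) per class.
#'   Mitotic-figure areas default inside the proposal stage's admissible
#'   band of 2.25-225 um^2.
#' @param h_conc Named list of length-2 haematoxylin-concentration ranges
#'   per class (arbitrary OD units).
#' @param background_e Range of the uniform eosin wash concentration.
#' @param min_spacing_um Minimum centroid-to-centroid spacing (default 12).
#' @param noise_sd Gaussian pixel noise standard deviation in OD space
#'   (default 0.02).
#' @param seed Optional integer seed; fixed seed gives a bit-identical scene.
#' @return An object of class \code{scene_config}.
#' @export
scene_config <- function(scene_px = 1024L,
                         pixel_size_um = 0.25,
                         counts = c(ordinary = 10L, mf = 3L, mlf = 3L, clutter = 5L),
                         area_um2 = list(ordinary = c(20, 60), mf = c(25, 80),
                                         mlf = c(4, 10), clutter = c(3, 15)),
                         h_conc = list(ordinary = c(0.35, 0.55), mf = c(0.9, 1.3),
                                       mlf = c(0.9, 1.3), clutter = c(0.10, 0.22)),
                         background_e = c(0.18, 0.28),
                         min_spacing_um = 12,
                         noise_sd = 0.02,
                         seed = NULL) {
  cls <- c("ordinary", "mf", "mlf", "clutter")
  counts <- counts[cls]
  counts[is.na(counts)] <- 0L
  names(counts) <- cls
  stopifnot(all(counts >= 0), min_spacing_um >= 0, noise_sd >= 0,
            scene_px >= 64, pixel_size_um > 0,
            all(vapply(area_um2[cls], function(r) r[1] > 0 && r[2] >= r[1], TRUE)))
  structure(list(scene_px = as.integer(scene_px),
                 pixel_size_um = pixel_size_um,
                 counts = counts, area_um2 = area_um2, h_conc = h_conc,
                 background_e = background_e,
                 min_spacing_um = min_spacing_um,
                 noise_sd = noise_sd, seed = seed),
            class = "scene_config")
}

# Rasterise an ellipse (or two-lobed union) into a logical mask on an
# npx-square grid. Centres/axes in pixels, 0-based pixel-centre coordinates.
.ellipse_mask <- function(npx, cx, cy, a, b, theta) {
  xs <- matrix(rep(0:(npx - 1L), each = npx), npx, npx)  # [row, col] = x
  ys <- matrix(rep(0:(npx - 1L), times = npx), npx, npx) # [row, col] = y
  dx <- xs - cx
  dy <- ys - cy
  u <- (dx * cos(theta) + dy * sin(theta)) / a
  v <- (-dx * sin(theta) + dy * cos(theta)) / b
  u * u + v * v <= 1
}

# Sample one object's shape parameters and rasterised mask for a class.
# Returns list(mask, area_px) or NULL if the mask is empty/out of bounds.
.draw_object_mask <- function(class, npx, cx, cy, area_px) {
  if (class == "mf") {
    # barbell: two overlapping lobes of roughly half the target area each
    half <- area_px / 2
    theta <- stats::runif(1, 0, pi)
    r <- stats::runif(1, 1.1, 1.6)
    a <- sqrt(half * r / pi)
    b <- sqrt(half / (pi * r))
    sep <- stats::runif(1, 0.9, 1.3) * a
    m1 <- .ellipse_mask(npx, cx - cos(theta) * sep / 2, cy - sin(theta) * sep / 2, a, b, theta)
    m2 <- .ellipse_mask(npx, cx + cos(theta) * sep / 2, cy + sin(theta) * sep / 2, a, b, theta)
    mask <- m1 | m2
  } else if (class == "mlf") {
    r <- sqrt(area_px / pi)
    mask <- .ellipse_mask(npx, cx, cy, r, r, 0)
  } else if (class == "clutter") {
    asp <- stats::runif(1, 2, 4)
    a <- sqrt(area_px * asp / pi)
    b <- sqrt(area_px / (pi * asp))
    mask <- .ellipse_mask(npx, cx, cy, a, b, stats::runif(1, 0, pi))
  } else {
    asp <- stats::runif(1, 1, 1.8)
    a <- sqrt(area_px * asp / pi)
    b <- sqrt(area_px / (pi * asp))
    mask <- .ellipse_mask(npx, cx, cy, a, b, stats::runif(1, 0, pi))
  }
  if (!any(mask)) return(NULL)
  list(mask = mask, area_px = sum(mask))
}

# Compose the concentration array for a scene from its records + background.
.scene_concentrations <- function(records, masks, scene_px, background_e) {
  conc <- array(0, dim = c(scene_px, scene_px, 3L))
  conc[, , 2] <- background_e
  for (i in seq_along(masks)) {
    conc[, , 1][masks[[i]]] <- conc[, , 1][masks[[i]]] + records$h_conc[i]
  }
  conc
}

#' Render a synthetic scene's raster from its records
#'
#' Deterministically reproduces a scene's RGB raster from its object records,
#' background and stored noise seed; the generator is therefore its own
#' oracle, since re-rendering must match the raster bit for bit.
#'
#' @param scene A \code{synthetic_scene} from [generate_scene()].
#' @return y-by-x-by-3 RGB array in \code{[0,255]}.
#' @export
render_scene <- function(scene) {
  conc <- .scene_concentrations(scene$records, scene$masks,
                                scene$config$scene_px, scene$background_e)
  od <- matrix(conc, ncol = 3L) %*% scene$stain$m
  if (scene$config$noise_sd > 0) {
    rs <- .Random.seed_save()
    set.seed(scene$noise_seed)
    od <- od + stats::rnorm(length(od), 0, scene$config$noise_sd)
    .Random.seed_restore(rs)
  }
  od <- pmax(od, 0)
  od_transform(array(od, dim = c(scene$config$scene_px, scene$config$scene_px, 3L)),
               "inverse", i0 = scene$stain$i0)
}

# save/restore the global RNG state so render_scene is side-effect free
.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
}
.Random.seed_restore <- function(rs) {
  if (!is.null(rs)) assign(".Random.seed", rs, envir = globalenv())
}

#' Generate a synthetic H&E scene with exhaustive ground truth
#'
#' Places the configured number of objects per class by rejection sampling
#' under the minimum-spacing policy, rasterises their masks, renders the
#' scene in OD space through the stain model, and returns raster plus a
#' record for every object drawn.
#'
#' @param config A [scene_config()].
#' @param stain A [stain_model()] used for rendering.
#' @return A \code{synthetic_scene}: list with \code{rgb} raster,
#'   \code{records} (data.frame: class, x_px, y_px, x_um, y_um, area_px,
#'   area_um2, h_conc), \code{masks} (list of logical matrices aligned with
#'   records), \code{background_e}, \code{noise_seed}, \code{config},
#'   \code{stain}, \code{meta}.
#' @export
generate_scene <- function(config = scene_config(), stain = stain_model()) {
  stopifnot(inherits(config, "scene_config"))
  if (!is.null(config$seed)) set.seed(config$seed)
  npx <- config$scene_px
  psz <- config$pixel_size_um
  spacing_px <- config$min_spacing_um / psz
  margin_px <- max(8, spacing_px / 2)
  background_e <- stats::runif(1, config$background_e[1], config$background_e[2])

  classes <- rep(names(config$counts), times = config$counts)
  n <- length(classes)
  recs <- vector("list", n)
  masks <- vector("list", n)
  centres <- matrix(numeric(0), ncol = 2)
  for (i in seq_along(classes)) {
    cl <- classes[i]
    placed <- FALSE
    for (try in seq_len(200L)) {
      cx <- stats::runif(1, margin_px, npx - 1 - margin_px)
      cy <- stats::runif(1, margin_px, npx - 1 - margin_px)
      if (nrow(centres) > 0 &&
          min(sqrt((centres[, 1] - cx)^2 + (centres[, 2] - cy)^2)) < spacing_px) next
      area_um2 <- stats::runif(1, config$area_um2[[cl]][1], config$area_um2[[cl]][2])
      obj <- .draw_object_mask(cl, npx, cx, cy, area_um2 / psz^2)
      if (is.null(obj)) next
      hc <- stats::runif(1, config$h_conc[[cl]][1], config$h_conc[[cl]][2])
      px <- which(obj$mask, arr.ind = TRUE)
      recs[[i]] <- data.frame(
        class = cl,
        x_px = mean(px[, 2] - 1), y_px = mean(px[, 1] - 1),
        area_px = obj$area_px, area_um2 = obj$area_px * psz^2,
        h_conc = hc)
      masks[[i]] <- obj$mask
      centres <- rbind(centres, c(cx, cy))
      placed <- TRUE
      break
    }
    if (!placed) {
      stop("infeasible packing: could not place all objects at min_spacing_um = ",
           config$min_spacing_um)
    }
  }
  records <- if (n > 0L) do.call(rbind, recs) else
    data.frame(class = character(), x_px = numeric(), y_px = numeric(),
               area_px = integer(), area_um2 = numeric(), h_conc = numeric())
  records$x_um <- records$x_px * psz
  records$y_um <- records$y_px * psz
  noise_seed <- sample.int(.Machine$integer.max - 1L, 1L)
  scene <- structure(list(records = records, masks = masks,
                          background_e = background_e, noise_seed = noise_seed,
                          config = config, stain = stain,
                          meta = image_meta(npx, npx, psz)),
                     class = "synthetic_scene")
  scene$rgb <- render_scene(scene)
  scene
}

#' Generate labelled 64x64 object crops
#'
#' Renders \code{n_per_class} single-object crops for each of the four scene
#' classes, each with its exact binary mask channel, centred with a small
#' random jitter. The binary training target follows the two-class scheme of
#' the detection problem: mitotic figures versus everything else (mimics,
#' ordinary nuclei, clutter).
#'
#' @param n_per_class Crops per class (>= 1).
#' @param config A [scene_config()]; only per-class morphology/staining and
#'   noise settings are used.
#' @param crop_px Crop edge length (default 64).
#' @param stain A [stain_model()].
#' @return A \code{crop_dataset}: list with \code{crops} (list of
#'   \code{object_crop}: rgb, mask, class), \code{class} (factor) and
#'   \code{is_mf} (logical binary target).
#' @export
generate_labelled_crops <- function(n_per_class, config = scene_config(),
                                    crop_px = 64L, stain = stain_model()) {
  stopifnot(n_per_class >= 1)
  if (!is.null(config$seed)) set.seed(config$seed)
  psz <- config$pixel_size_um
  classes <- rep(c("mf", "ordinary", "mlf", "clutter"), each = n_per_class)
  crops <- vector("list", length(classes))
  for (i in seq_along(classes)) {
    cl <- classes[i]
    bg_e <- stats::runif(1, config$background_e[1], config$background_e[2])
    obj <- NULL
    while (is.null(obj)) {
      cx <- crop_px / 2 - 0.5 + stats::runif(1, -4, 4)
      cy <- crop_px / 2 - 0.5 + stats::runif(1, -4, 4)
      area_um2 <- stats::runif(1, config$area_um2[[cl]][1], config$area_um2[[cl]][2])
      obj <- .draw_object_mask(cl, crop_px, cx, cy, area_um2 / psz^2)
    }
    hc <- stats::runif(1, config$h_conc[[cl]][1], config$h_conc[[cl]][2])
    conc <- array(0, dim = c(crop_px, crop_px, 3L))
    conc[, , 2] <- bg_e
    conc[, , 1][obj$mask] <- hc
    od <- matrix(conc, ncol = 3L) %*% stain$m
    if (config$noise_sd > 0) {
      od <- od + stats::rnorm(length(od), 0, config$noise_sd)
    }
    rgb <- od_transform(array(pmax(od, 0), dim = dim(conc)), "inverse", i0 = stain$i0)
    crops[[i]] <- structure(list(rgb = rgb, mask = obj$mask, class = cl),
                            class = "object_crop")
  }
  structure(list(crops = crops, class = factor(classes),
                 is_mf = classes == "mf"),
            class = "crop_dataset")
}

#' Generate a multi-tile whole-slide-like mosaic with ground truth
#'
#' Lays \code{n_tiles} synthetic scene tiles on a grid surrounded by a white
#' glass gutter, leaving \code{n_blank} of the grid positions as empty glass
#' (together these exercise perimeter-based background removal), and returns
#' the mosaic raster with a slide-frame ground-truth table.
#'
#' @param n_tiles Total tiles in the mosaic (>= 1).
#' @param config A [scene_config()]; \code{scene_px} is the tile size.
#' @param n_blank Number of blank (glass) tiles, chosen deterministically as
#'   the last tiles in row-major order.
#' @param gutter_px Width of the white glass frame around the tissue grid
#'   (default half a tile), so the slide perimeter is background as the
#'   tiling stage assumes.
#' @param stain A [stain_model()].
#' @return List with \code{rgb} mosaic, \code{truth} (data.frame: tile,
#'   class, x_um, y_um, x_px, y_px, area_um2 in the slide frame),
#'   \code{meta}, \code{scenes} (per-tile scene objects or NULL for blanks),
#'   and \code{origins} (per-tile pixel origins).
#' @export
generate_wsi_like <- function(n_tiles, config = scene_config(), n_blank = 1L,
                              gutter_px = NULL, stain = stain_model()) {
  stopifnot(n_tiles >= 1, n_blank >= 0, n_blank < n_tiles || n_tiles == n_blank)
  if (!is.null(config$seed)) set.seed(config$seed)
  npx <- config$scene_px
  if (is.null(gutter_px)) gutter_px <- npx %/% 2L
  ncol_t <- ceiling(sqrt(n_tiles))
  nrow_t <- ceiling(n_tiles / ncol_t)
  rgb <- array(255, dim = c(nrow_t * npx + 2L * gutter_px,
                            ncol_t * npx + 2L * gutter_px, 3L))
  scenes <- vector("list", n_tiles)
  origins <- data.frame(tile = seq_len(n_tiles), origin_x_px = NA_real_,
                        origin_y_px = NA_real_)
  truth <- list()
  blank <- seq_len(n_tiles) > (n_tiles - n_blank)
  subcfg <- config
  subcfg$seed <- NULL  # tiles draw from the already-seeded stream
  for (t in seq_len(n_tiles)) {
    iy <- (t - 1L) %/% ncol_t
    ix <- (t - 1L) %% ncol_t
    origins$origin_x_px[t] <- ix * npx + gutter_px
    origins$origin_y_px[t] <- iy * npx + gutter_px
    if (blank[t]) next
    sc <- generate_scene(subcfg, stain)
    scenes[[t]] <- sc
    rgb[(iy * npx + gutter_px + 1):((iy + 1) * npx + gutter_px),
        (ix * npx + gutter_px + 1):((ix + 1) * npx + gutter_px), ] <- sc$rgb
    if (nrow(sc$records) > 0L) {
      tr <- sc$records
      tr$x_px <- tr$x_px + ix * npx + gutter_px
      tr$y_px <- tr$y_px + iy * npx + gutter_px
      tr$x_um <- tr$x_px * config$pixel_size_um
      tr$y_um <- tr$y_px * config$pixel_size_um
      tr$tile <- t
      truth[[length(truth) + 1L]] <- tr[, c("tile", "class", "x_um", "y_um",
                                            "x_px", "y_px", "area_um2")]
    }
  }
  truth <- if (length(truth)) do.call(rbind, truth) else
    data.frame(tile = integer(), class = character(), x_um = numeric(),
               y_um = numeric(), x_px = numeric(), y_px = numeric(),
               area_um2 = numeric())
  rownames(truth) <- NULL
  list(rgb = rgb, truth = truth,
       meta = image_meta(dim(rgb)[2], dim(rgb)[1], config$pixel_size_um),
       scenes = scenes, origins = origins, gutter_px = gutter_px)
}
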