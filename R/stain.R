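#' H&E stain model
#'
#' Builds a 3x3 optical-density stain matrix whose rows are unit-norm stain
#' vectors for haematoxylin, eosin and a residual channel. The defaults are
#' the classical Ruifrok-Johnston H&E vectors, with the residual taken as the
#' normalised cross product of H and E so the matrix is always full rank.
#'
#' Stain contributions are additive in optical density (OD), so a pixel's OD
#' vector is \code{c \%*\% M} for per-stain concentrations \code{c}; stain
#' deconvolution inverts this linear map.
#'
#' @param h,e Numeric length-3 stain vectors (RGB order) for haematoxylin and
#'   eosin. Normalised internally.
#' @param residual Optional third stain vector; defaults to the normalised
#'   cross product of \code{h} and \code{e}.
#' @param i0 Reference (incident light) intensity, default 255.
#' @return An object of class \code{stain_model} with elements \code{m}
#'   (3x3 matrix, rows H, E, residual) and \code{i0}.
#' @examples
#' sm <- stain_model()
#' rowSums(sm$m^2)  # unit rows
#' @export
stain_model <- function(h = c(0.650, 0.704, 0.286),
                        e = c(0.072, 0.990, 0.105),
                        residual = NULL,
                        i0 = 255) {
  unit <- function(v) v / sqrt(sum(v^2))
  h <- unit(h)
  e <- unit(e)
  if (is.null(residual)) {
    residual <- c(h[2] * e[3] - h[3] * e[2],
                  h[3] * e[1] - h[1] * e[3],
                  h[1] * e[2] - h[2] * e[1])
  }
  residual <- unit(residual)
  m <- rbind(haematoxylin = h, eosin = e, residual = residual)
  colnames(m) <- c("r", "g", "b")
  if (abs(det(m)) < 1e-8) {
    stop("stain matrix is singular; choose independent stain vectors")
  }
  structure(list(m = m, i0 = i0), class = "stain_model")
}

#' Convert between transmitted intensity and optical density
#'
#' Forward: \code{OD = -log10((pixel + eps) / i0)}; the small \code{eps}
#' guards against zero intensities. Inverse: \code{i0 * 10^(-OD) - eps}.
#' The two directions compose to the identity within 8-bit quantisation.
#'
#' @param raster Numeric array (any shape) of intensities in \code{[0, i0]}
#'   for the forward direction, or of non-negative OD values for the inverse.
#' @param direction \code{"forward"} (intensity to OD) or \code{"inverse"}.
#' @param i0 Reference intensity (default 255).
#' @param eps Guard added to intensities before the log, in grey levels.
#' @return Array of the same shape.
#' @export
od_transform <- function(raster, direction = c("forward", "inverse"),
                         i0 = 255, eps = 1) {
  direction <- match.arg(direction)
  if (length(raster) == 0L) stop("empty raster")
  if (direction == "forward") {
    if (any(raster < 0)) stop("negative intensities are not physical")
    out <- -log10((raster + eps) / i0)
  } else {
    out <- i0 * 10^(-raster) - eps
    out <- pmin(pmax(out, 0), i0)
  }
  if (!is.null(dim(raster))) dim(out) <- dim(raster)
  out
}

#' Deconvolve an OD raster into stain concentrations
#'
#' Per-pixel solve of \code{OD = c \%*\% M} for the concentration vector
#' \code{c}. Exact (to numerical precision) on noiseless renders.
#'
#' @param od y-by-x-by-3 array of optical densities.
#' @param model A [stain_model()].
#' @return y-by-x-by-3 array of concentrations (H, E, residual).
#' @export
deconvolve_concentrations <- function(od, model = stain_model()) {
  stopifnot(inherits(model, "stain_model"))
  d <- dim(od)
  if (is.null(d) || length(d) != 3L || d[3] != 3L) {
    stop("od must be a y-by-x-by-3 array")
  }
  minv <- solve(model$m)
  flat <- matrix(od, ncol = 3L)
  conc <- flat %*% minv  # solve c in  c %*% M = OD  row-wise
  array(conc, dim = d)
}

#' Reconstruct an RGB raster from stain concentrations
#'
#' Inverse of [deconvolve_concentrations()] composed with the inverse OD
#' transform; output clipped to \code{[0, i0]}.
#'
#' @param conc y-by-x-by-3 concentration array (H, E, residual).
#' @param model A [stain_model()].
#' @param eps Guard used in the matching forward OD transform.
#' @return y-by-x-by-3 RGB array in \code{[0, i0]}.
#' @export
reconstruct_rgb <- function(conc, model = stain_model(), eps = 1) {
  d <- dim(conc)
  if (is.null(d) || length(d) != 3L || d[3] != 3L) {
    stop("conc must be a y-by-x-by-3 array")
  }
  od <- matrix(conc, ncol = 3L) %*% model$m
  rgb <- od_transform(array(od, dim = d), "inverse", i0 = model$i0, eps = eps)
  rgb
}

#' Stain-perturbation / augmentation configuration
#'
#' @param sigma Half-width of the uniform perturbation of stain
#'   concentrations (default 0.14).
#' @param flip_p Probability of a horizontal flip (default 0.4).
#' @param seed Optional integer seed recorded with the config.
#' @param perturb_residual Should the residual channel be perturbed too?
#'   Default \code{FALSE}: only H and E are perturbed.
#' @return An object of class \code{perturb_config}.
#' @export
perturb_config <- function(sigma = 0.14, flip_p = 0.4, seed = NULL,
                           perturb_residual = FALSE) {
  stopifnot(sigma >= 0, flip_p >= 0, flip_p <= 1)
  structure(list(sigma = sigma, flip_p = flip_p, seed = seed,
                 perturb_residual = perturb_residual),
            class = "perturb_config")
}

#' Perturb stain concentrations and reconstruct RGB
#'
#' Per stain channel i, concentrations are rescaled and shifted,
#' \code{c'_i = alpha_i * c_i + beta_i}, with \code{alpha_i ~ U(1 - sigma,
#' 1 + sigma)} and \code{beta_i ~ U(-sigma, sigma)} drawn once per channel
#' per call. By default only the H and E channels are perturbed. The
#' perturbed concentrations are reconstructed to RGB and clipped.
#'
#' @param conc y-by-x-by-3 concentration array.
#' @param config A [perturb_config()].
#' @param model A [stain_model()].
#' @return y-by-x-by-3 RGB array.
#' @export
perturb_concentrations <- function(conc, config = perturb_config(),
                                   model = stain_model()) {
  stopifnot(inherits(config, "perturb_config"))
  s <- config$sigma
  nchan <- if (isTRUE(config$perturb_residual)) 3L else 2L
  alpha <- stats::runif(nchan, 1 - s, 1 + s)
  beta <- stats::runif(nchan, -s, s)
  for (i in seq_len(nchan)) {
    conc[, , i] <- alpha[i] * conc[, , i] + beta[i]
  }
  reconstruct_rgb(conc, model)
}

#' Augment an object crop
#'
#' Applies stain-concentration colour perturbation to the RGB channels only,
#' then a horizontal flip with probability \code{flip_p} applied identically
#' to the RGB and mask channels, so crop and mask stay aligned and the mask
#' area is conserved.
#'
#' @param crop An \code{object_crop} (see [extract_object_crop()]): a list
#'   with \code{rgb} (y-by-x-by-3, \code{[0,255]}) and \code{mask}
#'   (logical y-by-x).
#' @param config A [perturb_config()].
#' @param model A [stain_model()].
#' @return The augmented \code{object_crop}.
#' @export
augment_crop <- function(crop, config = perturb_config(),
                         model = stain_model()) {
  stopifnot(is.list(crop), !is.null(crop$rgb), !is.null(crop$mask))
  od <- od_transform(crop$rgb, "forward", i0 = model$i0)
  conc <- deconvolve_concentrations(od, model)
  crop$rgb <- perturb_concentrations(conc, config, model)
  if (stats::runif(1) < config$flip_p) {
    crop$rgb <- crop$rgb[, dim(crop$rgb)[2]:1, , drop = FALSE]
    crop$mask <- crop$mask[, ncol(crop$mask):1, drop = FALSE]
  }
  crop
}
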