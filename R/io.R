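#' Read a raster image
#'
#' Reads a PNG or TIFF file into a y-by-x-by-3 numeric array scaled to
#' \code{[0,255]}. Grayscale inputs are replicated to three channels; an
#' alpha channel, if present, is dropped.
#'
#' @param path File path (.png, .tif/.tiff).
#' @return y-by-x-by-3 array in \code{[0,255]}.
#' @export
read_raster <- function(path) {
  ext <- tolower(tools::file_ext(path))
  img <- if (ext == "png") {
    png::readPNG(path)
  } else if (ext %in% c("tif", "tiff")) {
    if (!requireNamespace("tiff", quietly = TRUE)) {
      stop("reading TIFF requires the 'tiff' package")
    }
    tiff::readTIFF(path)
  } else {
    stop("unsupported raster format: ", ext)
  }
  if (is.matrix(img)) img <- array(rep(img, 3L), dim = c(dim(img), 3L))
  if (dim(img)[3] > 3L) img <- img[, , 1:3, drop = FALSE]
  img * 255
}

#' Write a raster image as PNG
#'
#' @param rgb y-by-x-by-3 array in \code{[0,255]}.
#' @param path Output .png path.
#' @return The path, invisibly.
#' @export
write_raster <- function(rgb, path) {
  png::writePNG(pmin(pmax(rgb / 255, 0), 1), path)
  invisible(path)
}

#' Write a tile plan as CSV
#'
#' @param plan A \code{tile_plan} from [plan_tiles()].
#' @param path Output .csv path.
#' @return The path, invisibly.
#' @export
write_tile_plan <- function(plan, path) {
  utils::write.csv(as.data.frame(plan)[, c("tile_id", "origin_x_px",
                                           "origin_y_px", "tissue_fraction")],
                   path, row.names = FALSE)
  invisible(path)
}

#' Write a detection set as CSV
#'
#' @param detections A \code{detection_set} from [run_detection()].
#' @param path Output .csv path.
#' @return The path, invisibly.
#' @export
write_detections <- function(detections, path) {
  df <- as.data.frame(detections)
  df$label <- as.character(df$label)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Read ground truth or detections from CSV
#'
#' Expects at least \code{x_um} and \code{y_um} columns (the schema shared
#' by ground-truth tables and exported detections).
#'
#' @param path CSV path.
#' @return data.frame.
#' @export
read_annotations <- function(path) {
  df <- utils::read.csv(path)
  if (is.null(df$x_um) || is.null(df$y_um)) {
    stop("annotation CSV must carry x_um and y_um columns")
  }
  df
}
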