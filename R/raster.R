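#' @useDynLib retfusion, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

rf_error <- function(class, message, ...) {
  stop(structure(class = c(class, "retfusionError", "error", "condition"),
                 list(message = message, call = sys.call(-1), ...)))
}

#' Construct a RasterImage
#'
#' @param pixels numeric array `H x W x C` (or an `H x W` matrix for gray)
#'   with values in `[0, 255]`.
#' @param colorspace `"gray"` or `"RGB"`; inferred from the channel count
#'   when missing.
#' @return A [RasterImage-class].
#' @export
rasterImage8 <- function(pixels, colorspace = NULL) {
  if (is.matrix(pixels)) pixels <- array(pixels, c(dim(pixels), 1L))
  if (is.null(colorspace)) colorspace <- if (dim(pixels)[3] == 1L) "gray" else "RGB"
  new("RasterImage", pixels = pixels, colorspace = colorspace)
}

#' @describeIn rasterImage8 pixel array accessor.
#' @param img a [RasterImage-class].
#' @export
imgPixels <- function(img) img@pixels

#' @describeIn rasterImage8 image height in px.
#' @export
imgHeight <- function(img) dim(img@pixels)[1]

#' @describeIn rasterImage8 image width in px.
#' @export
imgWidth <- function(img) dim(img@pixels)[2]

#' @describeIn rasterImage8 channel count.
#' @export
imgChannels <- function(img) dim(img@pixels)[3]

#' Convert an image to grayscale
#'
#' RGB images are collapsed with the luma weights (0.299, 0.587, 0.114);
#' gray images pass through. Used consistently across metrics and
#' segmentation.
#'
#' @param img a [RasterImage-class].
#' @return An `H x W` numeric matrix in `[0, 255]`.
#' @export
toGray <- function(img) {
  p <- img@pixels
  if (dim(p)[3] == 1L) return(p[, , 1])
  0.299 * p[, , 1] + 0.587 * p[, , 2] + 0.114 * p[, , 3]
}

#' Replicate gray pixels to a 3-channel RGB image
#' @param img a [RasterImage-class].
#' @return An RGB [RasterImage-class].
#' @export
toRGB <- function(img) {
  if (imgChannels(img) == 3L) return(img)
  g <- img@pixels[, , 1]
  rasterImage8(array(rep(g, 3L), c(dim(g), 3L)), "RGB")
}

clamp255 <- function(x) {
  x[x < 0] <- 0
  x[x > 255] <- 255
  x
}

to_ebimage <- function(img) {
  p <- aperm(img@pixels, c(2, 1, 3)) / 255
  if (dim(p)[3] == 1L) {
    EBImage::Image(p[, , 1], colormode = "Grayscale")
  } else {
    EBImage::Image(p, colormode = "Color")
  }
}

from_ebimage <- function(eb, colorspace = NULL) {
  d <- EBImage::imageData(eb)
  if (length(dim(d)) == 2L) d <- array(d, c(dim(d), 1L))
  p <- clamp255(aperm(d, c(2, 1, 3)) * 255)
  rasterImage8(p, colorspace)
}

#' Read an 8-bit image from PNG or JPEG
#'
#' @param path file path (`.png`, `.jpg`/`.jpeg`).
#' @return A [RasterImage-class] (RGB when the file has 3+ channels).
#' @export
readRasterImage <- function(path) {
  eb <- EBImage::readImage(path)
  d <- EBImage::imageData(eb)
  if (length(dim(d)) == 3L && dim(d)[3] > 3L) d <- d[, , 1:3]  # drop alpha
  if (length(dim(d)) == 2L) {
    from_ebimage(EBImage::Image(d, colormode = "Grayscale"))
  } else {
    from_ebimage(EBImage::Image(d, colormode = "Color"))
  }
}

#' Write an image to PNG (lossless) or JPEG
#'
#' JPEG writes use quality 95, the setting used for dataset files; fixtures
#' and bit-exact comparisons should use PNG.
#'
#' @param img a [RasterImage-class].
#' @param path destination ending in `.png`, `.jpg` or `.jpeg`.
#' @param quality JPEG quality (ignored for PNG).
#' @return `path`, invisibly.
#' @export
writeRasterImage <- function(img, path, quality = 95) {
  eb <- to_ebimage(img)
  if (grepl("\\.(jpg|jpeg)$", path, ignore.case = TRUE)) {
    EBImage::writeImage(eb, path, quality = quality)
  } else {
    EBImage::writeImage(eb, path)
  }
  invisible(path)
}

#' Construct a scan window
#'
#' @param x0,y0,x1,y1 half-open rectangle bounds `[x0, x1) x [y0, y1)` in
#'   0-based pixel coordinates.
#' @return A [ScanWindow-class].
#' @export
scanWindow <- function(x0, y0, x1, y1) {
  new("ScanWindow", x0 = x0, y0 = y0, x1 = x1, y1 = y1)
}

window_slices <- function(window, img) {
  H <- imgHeight(img); W <- imgWidth(img)
  if (window@x1 > W || window@y1 > H) {
    rf_error("parameterError", "scan window exceeds the image")
  }
  list(rows = (window@y0 + 1):window@y1, cols = (window@x0 + 1):window@x1)
}

setMethod("show", "RasterImage", function(object) {
  cat(sprintf("RasterImage %dx%d px, %s (%d channel%s)\n",
              imgWidth(object), imgHeight(object), object@colorspace,
              imgChannels(object), if (imgChannels(object) > 1) "s" else ""))
})

setMethod("show", "ThicknessField", function(object) {
  cat(sprintf(
    "ThicknessField %dx%d px | %.0f-%.0f um | fovea (%.1f, %.1f) | grade %s\n",
    ncol(object@values), nrow(object@values), min(object@values),
    max(object@values), object@foveaCenter[1], object@foveaCenter[2],
    object@gradeLabel))
})

setMethod("show", "ScanWindow", function(object) {
  cat(sprintf("ScanWindow [%g, %g) x [%g, %g)\n",
              object@x0, object@x1, object@y0, object@y1))
})

setMethod("show", "FAZSegmentation", function(object) {
  cat(sprintf("FAZSegmentation: %d contour points, centroid (%.2f, %.2f)\n",
              nrow(object@contour), object@centroid[1], object@centroid[2]))
})

setMethod("show", "PairedSample", function(object) {
  cat(sprintf("PairedSample '%s' (%s): %dx%d crops, %dx%d composite\n",
              object@id, object@gradeLabel,
              imgWidth(object@faCrop), imgHeight(object@faCrop),
              imgWidth(object@composite), imgHeight(object@composite)))
})

setMethod("show", "CheckpointSet", function(object) {
  cat(sprintf("CheckpointSet (%s): %d snapshots at epochs %s\n",
              object@direction, length(object@epochs),
              paste(object@epochs, collapse = ", ")))
})

setMethod("show", "FIDCurve", function(object) {
  cat(sprintf("FIDCurve over %d checkpoints; best epoch %d (FID %.4f)\n",
              length(object@epochs), object@epochs[object@bestIndex],
              object@fid[object@bestIndex]))
})

setMethod("show", "HDResult", function(object) {
  cat(sprintf("Hamming distance %d/64 (%.3f) -> %s\n",
              object@raw, object@normalized, object@category))
})

setMethod("show", "MetricReport", function(object) {
  cat(sprintf("MetricReport over %d pairs\n", nrow(object@perPair)))
  print(object@aggregate)
})
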