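# Co-registration preprocessing: mirroring to right-eye orientation,
# colored-square detection on OCT reports, FAZ segmentation and centroid
# localization on FA frames, fovea-centered cropping, final resize,
# side-by-side concatenation, reader's-folder QC output, and the
# DR-stratified train/test split.
#
# Conventions: 0-based pixel coordinates, (x = column, y = row), rectangles
# half-open.

#' Mirror left-eye images to right-eye orientation
#'
#' Horizontal flip iff `laterality == "left"`; right-eye images are
#' returned unchanged. Applied to every image so the whole dataset reads as
#' right eyes (mirroring is an involution, so applying it twice with
#' `"left"` restores the original).
#'
#' @param img a [RasterImage-class].
#' @param laterality `"left"` or `"right"`.
#' @return A [RasterImage-class].
#' @export
mirrorToRight <- function(img, laterality) {
  if (!laterality %in% c("left", "right")) {
    rf_error("parameterError", "laterality must be 'left' or 'right'")
  }
  if (laterality == "right") return(img)
  rasterImage8(flip_h(img@pixels), img@colorspace)
}

#' Default OCT scan window
#'
#' Central square of half the report dimension -- large enough to contain
#' the thickness square, small enough to keep the color bar out.
#'
#' @param img the OCT report.
#' @return A [ScanWindow-class].
#' @export
defaultOctWindow <- function(img) {
  H <- imgHeight(img); W <- imgWidth(img)
  side <- round(min(H, W) / 2)
  x0 <- round((W - side) / 2); y0 <- round((H - side) / 2)
  scanWindow(x0, y0, x0 + side, y0 + side)
}

#' Default FA scan window
#'
#' Square of half the frame dimension with its center shifted 10% of the
#' width toward the left half of the image, keeping dark frame outlines out
#' of the thresholded area.
#'
#' @param img the FA frame.
#' @return A [ScanWindow-class].
#' @export
defaultFaWindow <- function(img) {
  H <- imgHeight(img); W <- imgWidth(img)
  side <- round(min(H, W) / 2)
  x0 <- max(0, round((W - side) / 2 - 0.1 * W))
  y0 <- round((H - side) / 2)
  scanWindow(x0, y0, x0 + side, y0 + side)
}

#' Detect the color-coded thickness square
#'
#' Scans the window for colored pixels -- chroma `max(R,G,B) - min(R,G,B)`
#' strictly above `saturationThreshold` -- and returns their tight bounding
#' box with its midpoint, the presumed foveal location on OCT reports. The
#' color-bar strip must lie outside the window.
#'
#' @param octReport an RGB [RasterImage-class].
#' @param window a [ScanWindow-class] (default: [defaultOctWindow()]).
#' @param saturationThreshold chroma threshold in gray levels (default 30).
#' @return A [ColorMapRegion-class].
#' @export
detectColorSquare <- function(octReport, window = defaultOctWindow(octReport),
                              saturationThreshold = 30) {
  if (imgChannels(octReport) != 3L) {
    rf_error("parameterError", "octReport must be RGB")
  }
  sl <- window_slices(window, octReport)
  p <- octReport@pixels[sl$rows, sl$cols, , drop = FALSE]
  chroma <- pmax(p[, , 1], p[, , 2], p[, , 3]) - pmin(p[, , 1], p[, , 2], p[, , 3])
  hit <- which(chroma > saturationThreshold, arr.ind = TRUE)
  if (nrow(hit) == 0L) {
    rf_error("NoColorMapFound", "no colored pixel inside the scan window")
  }
  # back to 0-based full-image coordinates
  ys <- hit[, 1] - 1 + window@y0
  xs <- hit[, 2] - 1 + window@x0
  bbox <- scanWindow(min(xs), min(ys), max(xs) + 1, max(ys) + 1)
  new("ColorMapRegion", bbox = bbox,
      center = c((bbox@x0 + bbox@x1 - 1) / 2, (bbox@y0 + bbox@y1 - 1) / 2))
}

parse_threshold_policy <- function(policy, values) {
  if (is.numeric(policy)) return(policy)
  if (identical(policy, "otsu")) return(faz_otsu_threshold(values))
  if (grepl("^fixed:", policy)) return(as.numeric(sub("^fixed:", "", policy)))
  rf_error("parameterError", "threshold policy must be 'otsu', 'fixed:<v>' or numeric")
}

# Otsu adjusted to highlight the FAZ: when the first split leaves a dark
# class far too large to be the small avascular zone (frames with broad
# hyperfluorescent leakage split at background-vs-bright instead), Otsu is
# re-applied within the dark class until it isolates a plausibly small
# dark region (at most maxFrac of the window) or the iteration cap hits.
faz_otsu_threshold <- function(values, maxFrac = 0.2, maxIter = 3L) {
  thr <- otsu_threshold(values)
  for (i in seq_len(maxIter)) {
    frac <- mean(values < thr)
    if (frac <= maxFrac) break
    thr <- otsu_threshold(values[values < thr])
  }
  thr
}

# Otsu's threshold on a 256-bin histogram of 8-bit values
otsu_threshold <- function(values) {
  h <- tabulate(floor(values) + 1L, nbins = 256L)
  p <- h / sum(h)
  levels <- 0:255
  w0 <- cumsum(p)
  mu <- cumsum(p * levels)
  muT <- mu[256]
  sigma_b <- (muT * w0 - mu)^2 / (w0 * (1 - w0))
  sigma_b[!is.finite(sigma_b)] <- -Inf
  levels[which.max(sigma_b)] + 0.5
}

#' Segment the foveal avascular zone
#'
#' Binary thresholding over the scan window of the grayscale frame: dark
#' (hypofluorescent) pixels below the threshold become white (255), the
#' rest 0; pixels of value exactly 0 are treated as background frame
#' outline and ignored. The largest connected component is selected, its
#' contour extracted, and its centroid -- the presumed foveal location --
#' computed from the spatial moments of the filled region.
#'
#' @param faFrame a [RasterImage-class] (RGB is converted to grayscale).
#' @param window a [ScanWindow-class] (default: [defaultFaWindow()]).
#' @param thresholdPolicy `"otsu"` (default: Otsu's threshold on the
#'   windowed values), `"fixed:<v>"`, or a numeric threshold.
#' @return A [FAZSegmentation-class].
#' @export
segmentFAZ <- function(faFrame, window = defaultFaWindow(faFrame),
                       thresholdPolicy = "otsu") {
  g <- toGray(faFrame)
  sl <- window_slices(window, faFrame)
  sub <- g[sl$rows, sl$cols, drop = FALSE]
  thr <- parse_threshold_policy(thresholdPolicy, sub)
  fg <- sub < thr & sub > 0
  if (!any(fg)) rf_error("NoFAZFound", "no pixel below threshold in the window")
  mask <- matrix(0, imgHeight(faFrame), imgWidth(faFrame))
  mask[sl$rows, sl$cols][fg] <- 255
  lab <- EBImage::bwlabel(EBImage::Image(t(mask) / 255))
  labData <- EBImage::imageData(lab)
  nObj <- max(labData)
  if (nObj < 1) rf_error("NoFAZFound", "no connected component found")
  sizes <- tabulate(labData[labData > 0], nbins = nObj)
  # largest area wins; ties broken by smallest bounding-box top-left in
  # scan order (which() returns candidates in label order, so resolve
  # explicitly)
  best <- which(sizes == max(sizes))
  if (length(best) > 1L) {
    tl <- vapply(best, function(k) {
      idx <- which(labData == k, arr.ind = TRUE)
      min((idx[, 2] - 1) * dim(labData)[1] + (idx[, 1] - 1))
    }, numeric(1))
    best <- best[which.min(tl)]
  }
  idx <- which(labData == best, arr.ind = TRUE)  # col 1 = x index, col 2 = y
  centroid <- c(mean(idx[, 1]) - 1, mean(idx[, 2]) - 1)
  contour <- EBImage::ocontour(lab)[[best]]
  keep <- labData
  keep[] <- ifelse(labData == best, 255, 0)
  new("FAZSegmentation", mask = t(keep), contour = unname(contour),
      centroid = centroid)
}

#' Square crop centered on the fovea
#'
#' Crop of side `sidePx` centered at the fovea reference point, edge-
#' clamped with replication padding when the square exceeds the frame.
#'
#' @param img a [RasterImage-class].
#' @param fovea `(x, y)` reference point, 0-based; must lie inside the
#'   image.
#' @param sidePx crop side in px (> 0).
#' @return A `sidePx x sidePx` [RasterImage-class].
#' @export
cropFoveaCentered <- function(img, fovea, sidePx) {
  H <- imgHeight(img); W <- imgWidth(img)
  if (sidePx < 1) rf_error("parameterError", "sidePx must be > 0")
  if (fovea[1] < 0 || fovea[1] > W - 1 || fovea[2] < 0 || fovea[2] > H - 1) {
    rf_error("parameterError", "fovea must lie inside the image")
  }
  x0 <- round(fovea[1] - (sidePx - 1) / 2)
  y0 <- round(fovea[2] - (sidePx - 1) / 2)
  xs <- pmin(W - 1, pmax(0, x0:(x0 + sidePx - 1)))
  ys <- pmin(H - 1, pmax(0, y0:(y0 + sidePx - 1)))
  rasterImage8(img@pixels[ys + 1, xs + 1, , drop = FALSE], img@colorspace)
}

#' Crop a detected rectangle
#'
#' @param img a [RasterImage-class].
#' @param rect a [ScanWindow-class] contained in the image.
#' @return The cropped [RasterImage-class].
#' @export
cropRect <- function(img, rect) {
  sl <- window_slices(rect, img)
  rasterImage8(img@pixels[sl$rows, sl$cols, , drop = FALSE], img@colorspace)
}

#' Resize to correct camera/OCT magnification difference
#'
#' Bilinear resize by a scale factor; output dimensions are
#' `round(input * factor)`. The factor is 1 for phantoms (FA and OCT
#' phantoms share one coordinate frame); for real data it is the
#' camera-to-OCT magnification ratio and must be supplied.
#'
#' @param img a [RasterImage-class].
#' @param scaleFactor positive scale factor.
#' @return A [RasterImage-class].
#' @export
scaleForMagnification <- function(img, scaleFactor) {
  if (!is.numeric(scaleFactor) || scaleFactor <= 0) {
    rf_error("parameterError", "scaleFactor must be > 0")
  }
  if (scaleFactor == 1) return(img)
  H <- imgHeight(img); W <- imgWidth(img)
  eb <- EBImage::resize(to_ebimage(img), w = round(W * scaleFactor),
                        h = round(H * scaleFactor))
  out <- from_ebimage(eb, img@colorspace)
  rasterImage8(round(out@pixels), img@colorspace)
}

#' Finalize a crop to the training canvas
#'
#' Resizes to `size x size` (512 by default, the dataset canvas) and
#' replicates grayscale to 3 equal channels, the channel contract of the
#' translator.
#'
#' @param img a nonempty [RasterImage-class].
#' @param size output side in px.
#' @return A `size x size` RGB [RasterImage-class].
#' @export
finalizeCrop <- function(img, size = 512) {
  img <- toRGB(img)
  if (imgHeight(img) == size && imgWidth(img) == size) return(img)
  eb <- EBImage::resize(to_ebimage(img), w = size, h = size)
  out <- from_ebimage(eb, "RGB")
  rasterImage8(round(out@pixels), "RGB")
}

#' Concatenate a pair side by side
#'
#' FA on the left, OCT on the right, producing the `2s x s` composite
#' (1024 x 512 at full scale) that paired translation training consumes.
#'
#' @param fa,oct square [RasterImage-class] of equal dimensions and
#'   channel count.
#' @return The composite [RasterImage-class].
#' @export
concatenatePair <- function(fa, oct) {
  if (!identical(dim(fa@pixels), dim(oct@pixels))) {
    rf_error("parameterError", "fa and oct must share dimensions and channels")
  }
  d <- dim(fa@pixels)
  comp <- array(0, c(d[1], 2 * d[2], d[3]))
  comp[, 1:d[2], ] <- fa@pixels
  comp[, (d[2] + 1):(2 * d[2]), ] <- oct@pixels
  rasterImage8(comp, fa@colorspace)
}

#' Split a composite back into its halves
#'
#' Inverse of [concatenatePair()]: bit-exact round trip when saved
#' losslessly.
#'
#' @param composite a [RasterImage-class] of width `2 x height`.
#' @return list with `fa` (left half) and `oct` (right half).
#' @export
splitComposite <- function(composite) {
  W <- imgWidth(composite)
  if (W %% 2 != 0) rf_error("parameterError", "composite width must be even")
  half <- W / 2
  list(
    fa = rasterImage8(composite@pixels[, 1:half, , drop = FALSE],
                      composite@colorspace),
    oct = rasterImage8(composite@pixels[, (half + 1):W, , drop = FALSE],
                       composite@colorspace)
  )
}

mark_point <- function(img, point, color = c(255, 0, 0), armLen = 3) {
  img <- toRGB(img)
  p <- img@pixels
  H <- dim(p)[1]; W <- dim(p)[2]
  x <- round(point[1]); y <- round(point[2])
  xs <- pmin(W - 1, pmax(0, (x - armLen):(x + armLen)))
  ys <- pmin(H - 1, pmax(0, (y - armLen):(y + armLen)))
  for (ch in 1:3) {
    p[y + 1, xs + 1, ch] <- color[ch]
    p[ys + 1, x + 1, ch] <- color[ch]
  }
  rasterImage8(p, "RGB")
}

#' Write a reader's folder for one eye
#'
#' Quality-control folder with exactly five files: the color fundus
#' photograph, the FA frame, the FA frame with the fovea marked, the
#' binary FAZ image with the centroid marked, and the concatenated pair.
#' Re-running overwrites the same file set.
#'
#' @param sample a [PairedSample-class] (provides the composite and id).
#' @param colorFundus,faFrame [RasterImage-class] QC images.
#' @param seg the [FAZSegmentation-class] used for cropping.
#' @param outDir destination directory (created if needed).
#' @return The folder path, invisibly.
#' @export
buildReadersFolder <- function(sample, colorFundus, faFrame, seg, outDir) {
  dir <- file.path(outDir, sample@id)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(dir)) rf_error("ioError", paste("cannot create", dir))
  writeRasterImage(colorFundus, file.path(dir, "1_color_fundus.png"))
  writeRasterImage(faFrame, file.path(dir, "2_fa_frame.png"))
  writeRasterImage(mark_point(faFrame, seg@centroid),
                   file.path(dir, "3_fa_fovea_marked.png"))
  binary <- rasterImage8(array(seg@mask, c(dim(seg@mask), 1L)), "gray")
  writeRasterImage(mark_point(binary, seg@centroid),
                   file.path(dir, "4_faz_binary_centroid.png"))
  writeRasterImage(sample@composite, file.path(dir, "5_composite.png"))
  invisible(dir)
}

#' DR-stratified train/test split
#'
#' Selects a test set of size `nTest` with per-stage counts as equal as the
#' arithmetic allows (the 110-image test set of the study design equally
#' represents all five DR stages); the remaining samples form the training
#' set. When a stage is too small to honor the equality rule, allocation
#' falls back to proportional rounding with a warning. Deterministic for a
#' fixed seed.
#'
#' @param gradeLabels character vector of per-sample ETDRS grades.
#' @param nTest test-set size (< number of samples).
#' @param seed integer seed.
#' @param stratifyByGrade set `FALSE` for a simple random split.
#' @return list with integer index vectors `train` and `test` (disjoint,
#'   union = all samples).
#' @export
splitDataset <- function(gradeLabels, nTest, seed = 1L, stratifyByGrade = TRUE) {
  n <- length(gradeLabels)
  if (nTest >= n) rf_error("parameterError", "nTest must be < number of samples")
  withr::with_seed(as.integer(seed), {
    if (!stratifyByGrade) {
      test <- sort(sample.int(n, nTest))
      return(list(train = setdiff(seq_len(n), test), test = test))
    }
    strata <- split(seq_len(n), factor(gradeLabels,
                    levels = intersect(GRADE_LEVELS, unique(gradeLabels))))
    k <- length(strata)
    sizes <- lengths(strata)
    base <- nTest %/% k
    quota <- rep(base, k)
    extra <- nTest %% k
    if (extra > 0) {
      bump <- sample.int(k, extra)
      quota[bump] <- quota[bump] + 1L
    }
    if (any(quota > sizes)) {
      warning("test quota not partitionable equally over DR stages; ",
              "falling back to proportional allocation")
      quota <- floor(nTest * sizes / n)
      while (sum(quota) < nTest) {
        room <- which(quota < sizes)
        j <- room[which.max((sizes / n * nTest - quota)[room])]
        quota[j] <- quota[j] + 1L
      }
    }
    test <- sort(unlist(mapply(function(idx, q) sample(idx, q),
                               strata, quota, SIMPLIFY = FALSE), use.names = FALSE))
    list(train = setdiff(seq_len(n), test), test = test)
  })
}

#' Preprocess one raw FA/OCT report pair
#'
#' The full per-eye pipeline: mirror both images to right-eye orientation,
#' correct FA magnification, detect the colored thickness square on the
#' OCT report and crop it, segment the FAZ on the FA frame and crop a
#' square of the same side centered on its centroid, resize both crops to
#' the training canvas, and concatenate. Pairs whose FAZ segmentation
#' fails are routed to the manual-correction path (`qc_status "manual"`)
#' instead of aborting.
#'
#' @param fa,oct raw report [RasterImage-class]s.
#' @param laterality `"left"` or `"right"`.
#' @param id digit-string sample id.
#' @param gradeLabel ETDRS stage tag.
#' @param outSize training canvas side (512 at full scale).
#' @param saturationThreshold chroma threshold for square detection.
#' @param fazPolicy threshold policy for [segmentFAZ()].
#' @param magScale FA magnification correction factor.
#' @param octWindow,faWindow scan windows (defaults as in the respective
#'   detectors).
#' @return list with `sample` (a [PairedSample-class], or `NULL` on manual
#'   routing), `seg`, `region`, and a one-row `manifest` data.frame
#'   (id, laterality, grade, split placeholder, FAZ centroid, map center,
#'   qc_status).
#' @export
preprocessPair <- function(fa, oct, laterality, id, gradeLabel = "no_DR",
                           outSize = 512, saturationThreshold = 30,
                           fazPolicy = "otsu", magScale = 1.0,
                           octWindow = NULL, faWindow = NULL) {
  fa <- mirrorToRight(fa, laterality)
  oct <- mirrorToRight(oct, laterality)
  fa <- scaleForMagnification(fa, magScale)
  region <- detectColorSquare(oct, octWindow %||% defaultOctWindow(oct),
                              saturationThreshold)
  side <- round(((region@bbox@x1 - region@bbox@x0) +
                 (region@bbox@y1 - region@bbox@y0)) / 2)
  octCrop <- cropFoveaCentered(oct, region@center, side)
  seg <- tryCatch(
    segmentFAZ(fa, faWindow %||% defaultFaWindow(fa), fazPolicy),
    NoFAZFound = function(e) NULL)
  if (is.null(seg)) {
    manifest <- data.frame(id = id, laterality = laterality,
                           grade_label = gradeLabel, split = NA_character_,
                           faz_centroid_x = NA_real_, faz_centroid_y = NA_real_,
                           map_center_x = region@center[1],
                           map_center_y = region@center[2],
                           qc_status = "manual")
    return(list(sample = NULL, seg = NULL, region = region, manifest = manifest))
  }
  faCrop <- cropFoveaCentered(fa, seg@centroid, side)
  faFinal <- finalizeCrop(faCrop, outSize)
  octFinal <- finalizeCrop(octCrop, outSize)
  sample <- new("PairedSample", faCrop = faFinal, octCrop = octFinal,
                composite = concatenatePair(faFinal, octFinal),
                gradeLabel = gradeLabel, id = id)
  manifest <- data.frame(id = id, laterality = laterality,
                         grade_label = gradeLabel, split = NA_character_,
                         faz_centroid_x = seg@centroid[1],
                         faz_centroid_y = seg@centroid[2],
                         map_center_x = region@center[1],
                         map_center_y = region@center[2],
                         qc_status = "auto")
  list(sample = sample, seg = seg, region = region, manifest = manifest)
}

#' Preprocess a phantom dataset and split it
#'
#' Runs [preprocessPair()] over a [generateDataset()] output, assembles the
#' manifest, and applies the DR-stratified split to the successfully
#' auto-processed samples.
#'
#' @param rawSamples output of [generateDataset()].
#' @param nTest test-set size.
#' @param seed split seed.
#' @param outSize training canvas side.
#' @param ... passed to [preprocessPair()].
#' @return list with `samples` (list of [PairedSample-class]), `manifest`
#'   (data.frame with the `split` column filled), and `split` (index
#'   lists into `samples`).
#' @export
preprocessDataset <- function(rawSamples, nTest, seed = 1L, outSize = 512, ...) {
  res <- lapply(rawSamples, function(s) {
    preprocessPair(s$fa, s$oct, s$laterality, s$id, s$gradeLabel,
                   outSize = outSize, ...)
  })
  manifest <- do.call(rbind, lapply(res, `[[`, "manifest"))
  ok <- !vapply(res, function(r) is.null(r$sample), logical(1))
  samples <- lapply(res[ok], `[[`, "sample")
  grades <- vapply(samples, function(s) s@gradeLabel, character(1))
  split <- splitDataset(grades, nTest, seed = seed)
  manifest$split[ok][split$train] <- "train"
  manifest$split[ok][split$test] <- "test"
  list(samples = samples, manifest = manifest, split = split)
}
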