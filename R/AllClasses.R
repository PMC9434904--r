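#' @import methods
NULL

GRADE_LEVELS <- c("no_DR", "mild_NPDR", "moderate_NPDR", "severe_NPDR", "PDR")

#' 8-bit raster image
#'
#' The universal currency of the pipeline: a 2-D 8-bit image with an
#' explicit channel count and color-space tag. Pixels are stored as a
#' numeric `H x W x C` array in `[0, 255]`, row = y, column = x
#' (0-based pixel coordinates `(x, y)` index `pixels[y + 1, x + 1, ]`).
#'
#' @slot pixels numeric array `H x W x C`, values in `[0, 255]`.
#' @slot colorspace `"gray"` (C = 1) or `"RGB"` (C = 3).
#' @export
setClass("RasterImage",
  representation(pixels = "array", colorspace = "character"),
  validity = function(object) {
    p <- object@pixels
    if (length(dim(p)) != 3L) return("pixels must be an H x W x C array")
    if (dim(p)[1] < 1L || dim(p)[2] < 1L) return("H and W must be >= 1")
    if (!dim(p)[3] %in% c(1L, 3L)) return("channel count must be 1 or 3")
    if (anyNA(p) || any(p < 0) || any(p > 255)) {
      return("pixel values must be finite and within [0, 255]")
    }
    cs <- object@colorspace
    if (!identical(cs, "gray") && !identical(cs, "RGB")) {
      return("colorspace must be 'gray' or 'RGB'")
    }
    if (cs == "gray" && dim(p)[3] != 1L) return("gray images must have 1 channel")
    if (cs == "RGB" && dim(p)[3] != 3L) return("RGB images must have 3 channels")
    TRUE
  }
)

#' Retinal thickness field
#'
#' A grid of retinal thickness in micrometers (measured, on the device the
#' phantoms emulate, from the internal limiting membrane to the
#' photoreceptor outer segment/RPE junction), plus the foveal center and a
#' diabetic-retinopathy grade label on the ETDRS five-stage ladder.
#'
#' @slot values numeric matrix (rows = y, cols = x) of thickness in um.
#' @slot foveaCenter numeric length-2 `(x, y)` in 0-based pixel coordinates.
#' @slot gradeLabel one of `no_DR`, `mild_NPDR`, `moderate_NPDR`,
#'   `severe_NPDR`, `PDR`.
#' @export
setClass("ThicknessField",
  representation(values = "matrix", foveaCenter = "numeric",
                 gradeLabel = "character"),
  validity = function(object) {
    v <- object@values
    if (anyNA(v) || any(!is.finite(v))) return("thickness values must be finite")
    if (any(v < 0)) return("thickness values must be >= 0")
    fc <- object@foveaCenter
    if (length(fc) != 2L) return("foveaCenter must be (x, y)")
    if (fc[1] < 0 || fc[1] > ncol(v) - 1 || fc[2] < 0 || fc[2] > nrow(v) - 1) {
      return("foveaCenter must lie inside the grid")
    }
    if (!object@gradeLabel %in% GRADE_LEVELS) {
      return(paste("gradeLabel must be one of:", paste(GRADE_LEVELS, collapse = ", ")))
    }
    TRUE
  }
)

#' Thickness-to-color scale
#'
#' Ordered color stops mapping retinal thickness (um) to RGB, emulating the
#' 0-500 um color bar of clinical macular thickness maps: low values in
#' violet/blue, normal in green, progressively thicker in yellow, orange,
#' red and white. Thickness above the top stop clips to the top color.
#'
#' @slot stops data.frame with columns `thickness`, `r`, `g`, `b`
#'   (thickness strictly increasing, colors in 0-255).
#' @slot maxThickness top of the scale in um (500 by default).
#' @export
setClass("ThicknessColorScale",
  representation(stops = "data.frame", maxThickness = "numeric"),
  validity = function(object) {
    s <- object@stops
    need <- c("thickness", "r", "g", "b")
    if (!all(need %in% names(s))) return("stops needs thickness, r, g, b columns")
    if (nrow(s) < 2L) return("need at least two color stops")
    if (any(diff(s$thickness) <= 0)) return("stop thicknesses must be strictly increasing")
    if (s$thickness[1] != 0) return("scale must start at 0 um")
    if (utils::tail(s$thickness, 1) != object@maxThickness) {
      return("last stop must sit at maxThickness")
    }
    if (any(s[, c("r", "g", "b")] < 0) || any(s[, c("r", "g", "b")] > 255)) {
      return("stop colors must be 8-bit")
    }
    TRUE
  }
)

#' Phantom generation parameters
#'
#' Geometry, lesion content and noise level of one synthetic FA / OCT report
#' pair. Leakage halos on the FA side and edema bumps on the OCT side share
#' centers, which is exactly the co-dependence the translator must learn
#' (leakage predicts thickening).
#'
#' @slot canvasSize canvas side in px (square reports).
#' @slot vesselDepth recursion depth of the branching vessel tree.
#' @slot vesselWidth trunk width in px.
#' @slot fazRadius radius of the dark foveal avascular zone disc, px.
#' @slot nMicroaneurysms number of bright microaneurysm dots.
#' @slot leakageMode `"none"`, `"focal"` or `"diffuse"`.
#' @slot edemaCenters n x 2 matrix of `(x, y)` bump centers (may have 0 rows).
#' @slot edemaAmplitudes bump heights in um.
#' @slot edemaRadii bump radii (Gaussian sd) in px.
#' @slot laterality `"left"` or `"right"`.
#' @slot noiseSd additive Gaussian noise sd (gray levels / um).
#' @slot seed integer RNG seed.
#' @export
setClass("PhantomParams",
  representation(canvasSize = "numeric", vesselDepth = "numeric",
                 vesselWidth = "numeric", fazRadius = "numeric",
                 nMicroaneurysms = "numeric", leakageMode = "character",
                 edemaCenters = "matrix", edemaAmplitudes = "numeric",
                 edemaRadii = "numeric", laterality = "character",
                 noiseSd = "numeric", seed = "numeric"),
  validity = function(object) {
    if (object@canvasSize < 64) return("canvasSize must be >= 64")
    if (object@fazRadius <= 0) return("fazRadius must be > 0")
    if (!object@leakageMode %in% c("none", "focal", "diffuse")) {
      return("leakageMode must be none, focal or diffuse")
    }
    if (!object@laterality %in% c("left", "right")) {
      return("laterality must be left or right")
    }
    nb <- nrow(object@edemaCenters)
    if (length(object@edemaAmplitudes) != nb || length(object@edemaRadii) != nb) {
      return("edema centers, amplitudes and radii must agree in length")
    }
    if (nb > 0 && any(object@edemaAmplitudes < 0)) {
      return("edema amplitudes must be >= 0")
    }
    if (object@noiseSd < 0) return("noiseSd must be >= 0")
    TRUE
  }
)

#' Rectangular scan window
#'
#' Half-open pixel rectangle `[x0, x1) x [y0, y1)` in 0-based coordinates,
#' used to restrict FAZ thresholding and colored-square detection to a
#' sub-area of the report (keeping the color bar and frame edges out).
#'
#' @slot x0,y0,x1,y1 rectangle bounds.
#' @export
setClass("ScanWindow",
  representation(x0 = "numeric", y0 = "numeric", x1 = "numeric", y1 = "numeric"),
  validity = function(object) {
    if (object@x1 <= object@x0 || object@y1 <= object@y0) {
      return("window must be nonempty")
    }
    if (object@x0 < 0 || object@y0 < 0) return("window bounds must be >= 0")
    TRUE
  }
)

#' FAZ segmentation result
#'
#' Binary mask (FAZ mapped to white, 255), the detected contour of the
#' largest dark component, and its centroid -- the presumed foveal location.
#'
#' @slot mask matrix in \{0, 255\} (rows = y).
#' @slot contour n x 2 matrix of 0-based `(x, y)` contour points.
#' @slot centroid numeric `(x, y)`.
#' @export
setClass("FAZSegmentation",
  representation(mask = "matrix", contour = "matrix", centroid = "numeric"),
  validity = function(object) {
    if (!all(object@mask %in% c(0, 255))) return("mask must be binary 0/255")
    if (length(object@centroid) != 2L) return("centroid must be (x, y)")
    if (nrow(object@contour) > 0) {
      bx <- range(object@contour[, 1]); by <- range(object@contour[, 2])
      cx <- object@centroid
      if (cx[1] < bx[1] - 0.5 || cx[1] > bx[2] + 0.5 ||
          cx[2] < by[1] - 0.5 || cx[2] > by[2] + 0.5) {
        return("centroid must fall inside the contour bounding box")
      }
    }
    TRUE
  }
)

#' Detected color-coded map region
#'
#' Tight bounding box of the colored thickness square inside the scan
#' window, with its midpoint (the presumed foveal location on OCT reports).
#'
#' @slot bbox a [ScanWindow-class] rectangle.
#' @slot center numeric `(x, y)` midpoint of the box (pixel centers).
#' @export
setClass("ColorMapRegion",
  representation(bbox = "ScanWindow", center = "numeric"),
  validity = function(object) {
    if (length(object@center) != 2L) return("center must be (x, y)")
    mid <- c((object@bbox@x0 + object@bbox@x1 - 1) / 2,
             (object@bbox@y0 + object@bbox@y1 - 1) / 2)
    if (max(abs(mid - object@center)) > 1e-6) {
      return("center must be the bbox midpoint")
    }
    TRUE
  }
)

#' Co-registered training pair
#'
#' A fovea-centered FA crop, its OCT thickness-map crop, and their
#' side-by-side composite (FA left, OCT right), all 8-bit RGB.
#'
#' @slot faCrop,octCrop square [RasterImage-class] crops of equal side.
#' @slot composite the `2s x s` composite.
#' @slot gradeLabel ETDRS stage tag.
#' @slot id source identifier (digit string).
#' @export
setClass("PairedSample",
  representation(faCrop = "RasterImage", octCrop = "RasterImage",
                 composite = "RasterImage", gradeLabel = "character",
                 id = "character"),
  validity = function(object) {
    df <- dim(object@faCrop@pixels); do <- dim(object@octCrop@pixels)
    dc <- dim(object@composite@pixels)
    if (!identical(df, do)) return("fa and oct crops must share dimensions")
    if (dc[1] != df[1] || dc[2] != df[2] + do[2]) {
      return("composite width must equal fa width + oct width")
    }
    if (!object@gradeLabel %in% GRADE_LEVELS) return("invalid gradeLabel")
    TRUE
  }
)

#' Translator training configuration
#'
#' All pix2pix hyperparameters. Full-scale defaults: 512 px images,
#' 200 epochs, a generator snapshot every 10 epochs, and lambda = 100
#' weighting the L1 reconstruction loss against the adversarial loss.
#' Tiny image sizes (32/64) keep the same architecture valid for desk-scale
#' runs because the U-Net depth scales with log2(image size).
#'
#' @slot imageSize input/output side in px (power of two, >= 32).
#' @slot epochs training epochs.
#' @slot checkpointInterval epochs between generator snapshots.
#' @slot lambdaL1 weight of the L1 loss in the composite generator loss.
#' @slot batchSize images per update (1, as in the original recipe).
#' @slot learningRate,adamBeta1 Adam optimizer settings.
#' @slot ngf,ndf base channel widths of generator / discriminator.
#' @slot seed integer RNG seed.
#' @slot direction `"fa_to_oct"` or `"oct_to_fa"`.
#' @export
setClass("TrainConfig",
  representation(imageSize = "numeric", epochs = "numeric",
                 checkpointInterval = "numeric", lambdaL1 = "numeric",
                 batchSize = "numeric", learningRate = "numeric",
                 adamBeta1 = "numeric", ngf = "numeric", ndf = "numeric",
                 seed = "numeric", direction = "character"),
  validity = function(object) {
    s <- object@imageSize
    if (s < 32 || bitwAnd(as.integer(s), as.integer(s) - 1L) != 0L) {
      return("imageSize must be a power of two >= 32")
    }
    if (object@epochs < object@checkpointInterval) {
      return("epochs must be >= checkpointInterval")
    }
    if (object@lambdaL1 < 0) return("lambdaL1 must be >= 0")
    if (!object@direction %in% c("fa_to_oct", "oct_to_fa")) {
      return("direction must be fa_to_oct or oct_to_fa")
    }
    TRUE
  }
)

#' Saved generator checkpoints
#'
#' The generator snapshots taken every `checkpointInterval` epochs during
#' one training direction, with their epoch indices.
#'
#' @slot epochs strictly increasing integer epoch indices.
#' @slot generators list of generator parameter sets, parallel to `epochs`.
#' @slot direction training direction tag.
#' @export
setClass("CheckpointSet",
  representation(epochs = "numeric", generators = "list",
                 direction = "character"),
  validity = function(object) {
    if (length(object@epochs) != length(object@generators)) {
      return("epochs and generators must be parallel")
    }
    if (length(object@epochs) > 1 && any(diff(object@epochs) <= 0)) {
      return("epochs must be strictly increasing")
    }
    TRUE
  }
)

#' Feature-space Gaussian summary
#'
#' Sample mean and covariance of image feature embeddings; the two
#' ingredients of the Frechet distance between real and synthesized sets.
#'
#' @slot mu mean vector.
#' @slot sigma covariance matrix (symmetric, PSD within tolerance).
#' @export
setClass("GaussianStats",
  representation(mu = "numeric", sigma = "matrix"),
  validity = function(object) {
    d <- length(object@mu)
    if (nrow(object@sigma) != d || ncol(object@sigma) != d) {
      return("sigma must be d x d with d = length(mu)")
    }
    if (max(abs(object@sigma - t(object@sigma))) > 1e-8 * max(1, max(abs(object@sigma)))) {
      return("sigma must be symmetric")
    }
    TRUE
  }
)

#' FID-vs-checkpoint curve
#'
#' Frechet distance of each saved generator's synthesized set against the
#' real target set, with the argmin checkpoint (earliest epoch on ties --
#' later checkpoints risk overfitting).
#'
#' @slot epochs checkpoint epoch indices.
#' @slot fid scores, parallel to `epochs`.
#' @slot bestIndex 1-based index of the argmin.
#' @export
setClass("FIDCurve",
  representation(epochs = "numeric", fid = "numeric", bestIndex = "numeric"),
  validity = function(object) {
    if (length(object@epochs) != length(object@fid)) {
      return("epochs and fid must be parallel")
    }
    bi <- object@bestIndex
    if (bi < 1 || bi > length(object@fid)) return("bestIndex out of range")
    if (object@fid[bi] > min(object@fid) + 1e-12) {
      return("bestIndex must point at the minimum score")
    }
    TRUE
  }
)

#' 64-bit perceptual hash
#'
#' Average-hash fingerprint: the image is reduced to 8 x 8 grayscale and
#' each of the 64 cells contributes one bit (1 iff strictly above the mean),
#' row-major.
#'
#' @slot bits integer vector of 64 zeros/ones.
#' @slot sourceDims `(H, W)` of the hashed image.
#' @export
setClass("PerceptualHash",
  representation(bits = "integer", sourceDims = "integer"),
  validity = function(object) {
    if (length(object@bits) != 64L) return("fingerprint must have 64 bits")
    if (!all(object@bits %in% c(0L, 1L))) return("bits must be 0/1")
    TRUE
  }
)

#' Hamming-distance result
#'
#' Raw bit-difference count between two fingerprints, its normalized form
#' (raw/64), and the interpretation band: 0 = similar, 1-10 = potential
#' variation, >10 = likely a different image.
#'
#' @slot raw integer 0-64.
#' @slot normalized raw / 64.
#' @slot category `"similar"`, `"potential_variation"` or `"likely_different"`.
#' @export
setClass("HDResult",
  representation(raw = "integer", normalized = "numeric", category = "character"),
  validity = function(object) {
    if (object@raw < 0L || object@raw > 64L) return("raw must be in 0..64")
    want <- if (object@raw == 0L) "similar"
            else if (object@raw <= 10L) "potential_variation"
            else "likely_different"
    if (!identical(object@category, want)) return("category inconsistent with raw")
    if (abs(object@normalized - object@raw / 64) > 1e-12) {
      return("normalized must equal raw / 64")
    }
    TRUE
  }
)

#' Paired-image metric report
#'
#' Per-pair PSNR (dB), SSIM, Hamming distance (raw and normalized) and
#' learned feature distance, plus mean +/- sd aggregates. Infinite PSNR
#' (bit-identical pairs) is kept as a sentinel per pair but excluded, with a
#' count, from the aggregates.
#'
#' @slot perPair data.frame, one row per pair.
#' @slot aggregate data.frame of mean/sd per metric.
#' @slot nInfinitePsnr number of pairs excluded from the PSNR aggregate.
#' @export
setClass("MetricReport",
  representation(perPair = "data.frame", aggregate = "data.frame",
                 nInfinitePsnr = "integer"),
  validity = function(object) {
    if (any(object@aggregate$sd < 0, na.rm = TRUE)) return("sd must be >= 0")
    TRUE
  }
)
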