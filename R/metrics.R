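# Objective paired-image quality suite: PSNR from MSE, SSIM
# (luminance-contrast-structure over Gaussian-weighted local windows),
# 8x8/64-bit average-hash Hamming distance with interpretation bands, and
# an LPIPS-style learned feature distance with spatial distance maps.

check_same_dims <- function(a, b) {
  if (!identical(dim(a@pixels), dim(b@pixels))) {
    rf_error("parameterError", "images must share dimensions and channels")
  }
}

#' Mean squared error between two images
#'
#' Mean over all pixels and channels of the squared 8-bit difference.
#'
#' @param a,b [RasterImage-class]s of identical dimensions.
#' @return nonnegative scalar.
#' @export
mseImage <- function(a, b) {
  check_same_dims(a, b)
  mean((a@pixels - b@pixels)^2)
}

#' Peak signal-to-noise ratio in decibels
#'
#' `10 log10(255^2 / MSE)`; higher means less distortion. Identical images
#' (MSE = 0) return `Inf` as a sentinel; aggregation excludes it with a
#' count.
#'
#' @param a,b [RasterImage-class]s of identical dimensions (8-bit,
#'   peak 255).
#' @return decibels, possibly `Inf`.
#' @export
psnr <- function(a, b) {
  m <- mseImage(a, b)
  if (m == 0) return(Inf)
  10 * log10(255^2 / m)
}

gaussian_kernel_1d <- function(size = 11L, sigma = 1.5) {
  half <- (size - 1) / 2
  g <- exp(-((-half):half)^2 / (2 * sigma^2))
  g / sum(g)
}

# separable weighted local filtering, valid region only (all positions
# where the full window fits)
filter_valid <- function(m, g) {
  k <- length(g)
  H <- nrow(m); W <- ncol(m)
  out <- matrix(0, H, W - k + 1)
  for (j in seq_len(k)) out <- out + g[j] * m[, j:(W - k + j), drop = FALSE]
  out2 <- matrix(0, H - k + 1, ncol(out))
  for (i in seq_len(k)) out2 <- out2 + g[i] * out[i:(H - k + i), , drop = FALSE]
  out2
}

#' Structural similarity index
#'
#' Windowed luminance * contrast * structure similarity in `[-1, 1]`
#' (1 = identical). Local statistics use an 11 x 11 Gaussian window with
#' sd 1.5 and stabilizers `(0.01 * 255)^2` and `(0.03 * 255)^2`, the
#' field-standard parameterization; the mean is taken over all positions
#' where the full window fits. RGB inputs are converted to grayscale by
#' luma weights.
#'
#' @param a,b [RasterImage-class]s of identical dimensions, at least as
#'   large as the window.
#' @param windowSize odd window side.
#' @param sigma Gaussian window sd.
#' @param k1,k2 stabilizer coefficients.
#' @param dynamicRange 255 for 8-bit images.
#' @return scalar SSIM.
#' @export
ssim <- function(a, b, windowSize = 11L, sigma = 1.5, k1 = 0.01, k2 = 0.03,
                 dynamicRange = 255) {
  check_same_dims(a, b)
  x <- toGray(a); y <- toGray(b)
  if (nrow(x) < windowSize || ncol(x) < windowSize) {
    rf_error("parameterError", "image smaller than the SSIM window")
  }
  g <- gaussian_kernel_1d(windowSize, sigma)
  c1 <- (k1 * dynamicRange)^2
  c2 <- (k2 * dynamicRange)^2
  mux <- filter_valid(x, g); muy <- filter_valid(y, g)
  sxx <- filter_valid(x * x, g) - mux^2
  syy <- filter_valid(y * y, g) - muy^2
  sxy <- filter_valid(x * y, g) - mux * muy
  num <- (2 * mux * muy + c1) * (2 * sxy + c2)
  den <- (mux^2 + muy^2 + c1) * (sxx + syy + c2)
  mean(num / den)
}

# exact area-average resample of a matrix to nr x nc: each target cell
# averages its (fractional) source footprint
area_average <- function(m, nr, nc) {
  wmat <- function(nIn, nOut) {
    w <- matrix(0, nOut, nIn)
    step <- nIn / nOut
    for (i in seq_len(nOut)) {
      lo <- (i - 1) * step; hi <- i * step
      j0 <- floor(lo) + 1; j1 <- ceiling(hi)
      for (j in j0:min(j1, nIn)) {
        ov <- min(hi, j) - max(lo, j - 1)
        if (ov > 0) w[i, j] <- ov
      }
      w[i, ] <- w[i, ] / step
    }
    w
  }
  wmat(nrow(m), nr) %*% m %*% t(wmat(ncol(m), nc))
}

#' 64-bit average hash
#'
#' Rescales the image to 8 x 8 grayscale (exact area averaging) and sets
#' bit i to 1 iff cell i is strictly above the mean of the 64 cells,
#' row-major. Constant images hash to all zeros (strict-inequality tie
#' rule), and the fingerprint is invariant under brightness shifts that
#' preserve the above-mean set.
#'
#' @param img a nonempty [RasterImage-class].
#' @return A [PerceptualHash-class].
#' @export
averageHash <- function(img) {
  g <- toGray(img)
  small <- area_average(g, 8L, 8L)
  bits <- as.integer(t(small) > mean(small))  # row-major order
  new("PerceptualHash", bits = bits,
      sourceDims = c(nrow(g), ncol(g)))
}

#' Hamming distance between fingerprints
#'
#' Number of differing bit positions, normalized by 64, with the
#' interpretation bands: 0 = similar, 1-10 = potential variation,
#' >10 = likely a different image.
#'
#' @param a,b [PerceptualHash-class]s.
#' @return An [HDResult-class].
#' @export
hammingDistance <- function(a, b) {
  if (length(a@bits) != length(b@bits)) {
    rf_error("parameterError", "fingerprint lengths must match")
  }
  raw <- sum(a@bits != b@bits)
  new("HDResult", raw = as.integer(raw), normalized = raw / 64,
      category = if (raw == 0) "similar"
                 else if (raw <= 10) "potential_variation"
                 else "likely_different")
}

#' Desk perceptual backbone
#'
#' Small fixed-architecture 3-layer convolutional stack with seeded
#' deterministic weights, used as the default feature extractor for the
#' learned perceptual distance (untrained convolutional features already
#' rank perceptual similarity usefully); a pretrained classification
#' backbone can be plugged in through the same interface: a function
#' mapping a `[-1, 1]` H x W x 3 array to a list of H' x W' x C'
#' activation arrays.
#'
#' @param seed seed fixing the weights.
#' @param channels channel widths of the three layers.
#' @return A backbone function.
#' @export
deskBackbone <- function(seed = 23L, channels = c(8L, 16L, 32L)) {
  W <- withr::with_seed(as.integer(seed), {
    cins <- c(3L, channels[1], channels[2])
    lapply(1:3, function(j) {
      list(w = matrix(stats::rnorm(channels[j] * 9 * cins[j],
                                   sd = 1 / sqrt(9 * cins[j])),
                      channels[j], 9 * cins[j]),
           b = numeric(channels[j]))
    })
  })
  function(x) {
    acts <- vector("list", 3L)
    h <- x
    for (j in 1:3) {
      s <- if (j == 1) 1L else 2L
      h <- relu_fw(conv_fw(h, W[[j]]$w, W[[j]]$b, k = 3L, s = s, p = 1L))
      acts[[j]] <- h
    }
    acts
  }
}

unit_normalize_channels <- function(a, eps = 1e-10) {
  nrm <- sqrt(apply(a^2, c(1, 2), sum)) + eps
  sweep(a, c(1, 2), nrm, "/")
}

#' Learned perceptual feature distance with distance map
#'
#' Computes the distance between two images in convolutional feature
#' space: per layer, channel activations at each position are unit-
#' normalized, squared differences are averaged over channels and spatial
#' positions, and layers are summed (layer weights 1). The spatial map of
#' per-layer channel-averaged differences, bilinearly upsampled to the
#' input size and summed across layers, localizes where the two images
#' differ perceptually. Zero on identical inputs; symmetric.
#'
#' @param a,b [RasterImage-class]s of identical dimensions.
#' @param backbone layered feature extractor (default [deskBackbone()]).
#' @return list with `distance` (scalar) and `map` (numeric H x W matrix).
#' @export
featureDistance <- function(a, b, backbone = deskBackbone()) {
  check_same_dims(a, b)
  fa <- backbone(img_to_unit(a))
  fb <- backbone(img_to_unit(b))
  H <- imgHeight(a); W <- imgWidth(a)
  total <- 0
  map <- matrix(0, H, W)
  for (l in seq_along(fa)) {
    na <- unit_normalize_channels(fa[[l]])
    nb <- unit_normalize_channels(fb[[l]])
    d2 <- (na - nb)^2
    layerMap <- apply(d2, c(1, 2), mean)
    total <- total + mean(layerMap)
    up <- EBImage::imageData(EBImage::resize(EBImage::Image(t(layerMap)),
                                             w = W, h = H))
    map <- map + t(up)
  }
  list(distance = total, map = map)
}

#' Render a distance map as an 8-bit heat image
#'
#' @param map numeric matrix from [featureDistance()].
#' @return An RGB [RasterImage-class] (dark = similar, warm = different).
#' @export
distanceMapImage <- function(map) {
  rng <- range(map)
  z <- if (diff(rng) > 0) (map - rng[1]) / diff(rng) else map * 0
  cols <- grDevices::col2rgb(grDevices::hcl.colors(256, "inferno"))
  idx <- pmin(256, floor(z * 255) + 1)
  pix <- array(0, c(nrow(map), ncol(map), 3))
  for (ch in 1:3) pix[, , ch] <- matrix(cols[ch, idx], nrow(map), ncol(map))
  rasterImage8(pix, "RGB")
}

#' Evaluate a set of (ground truth, synthesized) pairs
#'
#' Computes PSNR, SSIM, Hamming distance (raw for the band rule,
#' normalized for aggregation) and the learned feature distance per pair,
#' and aggregates mean +/- sd per metric. Infinite PSNR sentinels
#' (bit-identical pairs) are excluded from the PSNR aggregate and counted.
#'
#' @param truth,synth parallel nonempty lists of [RasterImage-class]s.
#' @param ids optional pair identifiers.
#' @param backbone feature backbone for the perceptual distance.
#' @return A [MetricReport-class].
#' @export
evaluatePairs <- function(truth, synth, ids = NULL,
                          backbone = deskBackbone()) {
  if (length(truth) < 1 || length(truth) != length(synth)) {
    rf_error("parameterError", "need parallel nonempty truth/synth lists")
  }
  if (is.null(ids)) ids <- sprintf("%04d", seq_along(truth))
  rows <- lapply(seq_along(truth), function(i) {
    hd <- hammingDistance(averageHash(truth[[i]]), averageHash(synth[[i]]))
    fd <- featureDistance(truth[[i]], synth[[i]], backbone)
    data.frame(id = ids[i],
               psnr_db = psnr(truth[[i]], synth[[i]]),
               ssim = ssim(truth[[i]], synth[[i]]),
               hd_raw = hd@raw, hd_norm = hd@normalized,
               hd_category = hd@category, lpips = fd$distance)
  })
  perPair <- do.call(rbind, rows)
  finitePsnr <- perPair$psnr_db[is.finite(perPair$psnr_db)]
  agg <- data.frame(
    metric = c("psnr_db", "ssim", "hd_norm", "lpips"),
    mean = c(if (length(finitePsnr)) mean(finitePsnr) else NA_real_,
             mean(perPair$ssim), mean(perPair$hd_norm), mean(perPair$lpips)),
    sd = c(if (length(finitePsnr) > 1) stats::sd(finitePsnr) else 0,
           sd0(perPair$ssim), sd0(perPair$hd_norm), sd0(perPair$lpips)))
  new("MetricReport", perPair = perPair, aggregate = agg,
      nInfinitePsnr = sum(!is.finite(perPair$psnr_db)))
}

sd0 <- function(x) if (length(x) > 1) stats::sd(x) else 0

#' Write a metric report as CSV
#'
#' Per-pair rows followed by one aggregate row (`mean +/- sd`); column
#' headers state which Hamming distance is raw (band rule) and which is
#' normalized (aggregates).
#'
#' @param report a [MetricReport-class].
#' @param path destination CSV.
#' @return `path`, invisibly.
#' @export
writeMetricReport <- function(report, path) {
  pp <- report@perPair
  agg <- report@aggregate
  fmt <- function(metric) {
    r <- agg[agg$metric == metric, ]
    sprintf("%.4f +/- %.4f", r$mean, r$sd)
  }
  aggRow <- data.frame(id = "mean_sd", psnr_db = NA, ssim = NA, hd_raw = NA,
                       hd_norm = NA, hd_category = "", lpips = NA)
  out <- rbind(pp, aggRow)
  out$psnr_db <- as.character(out$psnr_db)
  out$ssim <- as.character(out$ssim)
  out$hd_norm <- as.character(out$hd_norm)
  out$lpips <- as.character(out$lpips)
  n <- nrow(out)
  out$psnr_db[n] <- fmt("psnr_db"); out$ssim[n] <- fmt("ssim")
  out$hd_norm[n] <- fmt("hd_norm"); out$lpips[n] <- fmt("lpips")
  names(out) <- c("id", "psnr_db", "ssim", "hd_raw_bits", "hd_normalized",
                  "hd_category", "lpips")
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}
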