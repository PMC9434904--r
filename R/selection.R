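# Checkpoint selection by Frechet distance between Gaussian fits of
# feature embeddings of real vs synthesized image sets: a lower score
# indicates better synthesis quality, and the argmin checkpoint is used
# for image synthesis (earliest epoch on ties -- training past the ideal
# epoch risks overlearning).

#' Desk feature extractor
#'
#' Deterministic fixed embedding: resize to 32 x 32 grayscale, flatten,
#' project with a seeded fixed random matrix to `outDim` dimensions.
#' Exercises the full Frechet-distance machinery without a pretrained
#' network; any deterministic image-to-vector map (e.g. an inception-style
#' backbone) can be plugged in instead.
#'
#' @param outDim embedding dimensionality.
#' @param seed seed fixing the projection matrix.
#' @return A function mapping a [RasterImage-class] to a numeric vector.
#' @export
deskExtractor <- function(outDim = 64L, seed = 17L) {
  proj <- withr::with_seed(as.integer(seed), {
    matrix(stats::rnorm(outDim * 1024) / sqrt(1024), outDim, 1024)
  })
  function(img) {
    g <- toGray(img)
    small <- EBImage::imageData(EBImage::resize(EBImage::Image(t(g) / 255),
                                                w = 32, h = 32))
    as.numeric(proj %*% as.numeric(small))
  }
}

#' Embed a set of images
#'
#' @param images nonempty list of at least 2 [RasterImage-class]s.
#' @param extractor deterministic image-to-vector map
#'   (default [deskExtractor()]).
#' @return numeric matrix, one row per image.
#' @export
embedImages <- function(images, extractor = deskExtractor()) {
  if (length(images) < 2) {
    rf_error("StatsUndefined", "need at least 2 images to embed a set")
  }
  do.call(rbind, lapply(images, extractor))
}

#' Fit feature-space Gaussian statistics
#'
#' Sample mean and unbiased sample covariance of embedding rows.
#'
#' @param features numeric matrix with >= 2 rows.
#' @return A [GaussianStats-class].
#' @export
gaussianStats <- function(features) {
  if (!is.matrix(features) || nrow(features) < 2) {
    rf_error("StatsUndefined", "need >= 2 feature rows")
  }
  new("GaussianStats", mu = colMeans(features),
      sigma = stats::cov(features))
}

# symmetric PSD matrix square root via eigendecomposition; small negative
# eigenvalues (numerical) are clamped to zero, larger ones are an error
psd_sqrt_eigvals <- function(M, tol = 1e-6) {
  ev <- eigen((M + t(M)) / 2, symmetric = TRUE, only.values = TRUE)$values
  floorNeg <- -tol * max(abs(ev), 1)
  if (any(ev < floorNeg)) {
    rf_error("numericalError", "matrix is not PSD within tolerance")
  }
  sqrt(pmax(ev, 0))
}

#' Frechet distance between two feature Gaussians
#'
#' `||mu_a - mu_b||^2 + Tr(S_a + S_b - 2 (S_a S_b)^{1/2})`, the score used
#' to compare real and synthesized image sets (lower is better). The
#' matrix square root is taken through the symmetrized product
#' `S_a^{1/2} S_b S_a^{1/2}`; small negative eigenvalues are clamped to
#' zero and the result is nonnegative within tolerance.
#'
#' @param a,b [GaussianStats-class] of matching dimension.
#' @return nonnegative score.
#' @export
frechetDistance <- function(a, b) {
  if (length(a@mu) != length(b@mu)) {
    rf_error("parameterError", "dimension mismatch between stats")
  }
  Sa <- (a@sigma + t(a@sigma)) / 2
  Sb <- (b@sigma + t(b@sigma)) / 2
  ea <- eigen(Sa, symmetric = TRUE)
  if (any(ea$values < -1e-6 * max(abs(ea$values), 1))) {
    rf_error("numericalError", "covariance not PSD within tolerance")
  }
  sqrtSa <- ea$vectors %*% (sqrt(pmax(ea$values, 0)) * t(ea$vectors))
  trSqrt <- sum(psd_sqrt_eigvals(sqrtSa %*% Sb %*% sqrtSa))
  d <- sum((a@mu - b@mu)^2) + sum(diag(Sa)) + sum(diag(Sb)) - 2 * trSqrt
  max(d, 0)
}

#' Score checkpoints by FID and select the best
#'
#' Translates all sources with each saved generator, embeds the
#' synthesized set and the real target set, computes the Frechet distance
#' per checkpoint, and returns the full curve with the argmin (earliest
#' epoch on ties).
#'
#' @param checkpoints a [CheckpointSet-class] with >= 1 snapshot.
#' @param realTargets list of >= 2 ground-truth target
#'   [RasterImage-class]s.
#' @param sources list of source [RasterImage-class]s to translate.
#' @param extractor feature extractor (default [deskExtractor()]).
#' @return A [FIDCurve-class].
#' @export
selectBestCheckpoint <- function(checkpoints, realTargets, sources,
                                 extractor = deskExtractor()) {
  if (length(checkpoints@epochs) < 1) {
    rf_error("parameterError", "need at least one checkpoint")
  }
  realStats <- gaussianStats(embedImages(realTargets, extractor))
  fid <- vapply(checkpoints@generators, function(gen) {
    synth <- lapply(sources, function(s) translateImage(gen, s))
    frechetDistance(gaussianStats(embedImages(synth, extractor)), realStats)
  }, numeric(1))
  new("FIDCurve", epochs = checkpoints@epochs, fid = fid,
      bestIndex = which.min(fid))
}

#' Write a FID curve as CSV
#'
#' @param curve a [FIDCurve-class].
#' @param path destination CSV (columns `epoch`, `fid`).
#' @return `path`, invisibly.
#' @export
writeFidCurve <- function(curve, path) {
  utils::write.csv(data.frame(epoch = curve@epochs, fid = curve@fid),
                   path, row.names = FALSE)
  invisible(path)
}
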