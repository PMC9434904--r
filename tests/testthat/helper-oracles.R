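# Independent oracle implementations used to cross-check the package's
# metric code paths. These are deliberately written differently from the
# implementations in R/ (direct window loops and closed forms instead of
# separable filtering / eigendecompositions).

# SSIM by explicit loop over every valid window with a full 2-D Gaussian
# weight matrix
oracle_ssim <- function(a, b, windowSize = 11L, sigma = 1.5) {
  x <- toGray(a); y <- toGray(b)
  half <- (windowSize - 1) / 2
  g1 <- exp(-((-half):half)^2 / (2 * sigma^2))
  W <- outer(g1, g1)
  W <- W / sum(W)
  c1 <- (0.01 * 255)^2; c2 <- (0.03 * 255)^2
  H <- nrow(x); Wd <- ncol(x)
  vals <- c()
  for (i in 1:(H - windowSize + 1)) {
    for (j in 1:(Wd - windowSize + 1)) {
      wx <- x[i:(i + windowSize - 1), j:(j + windowSize - 1)]
      wy <- y[i:(i + windowSize - 1), j:(j + windowSize - 1)]
      mx <- sum(W * wx); my <- sum(W * wy)
      vx <- sum(W * wx^2) - mx^2
      vy <- sum(W * wy^2) - my^2
      cxy <- sum(W * wx * wy) - mx * my
      vals <- c(vals, ((2 * mx * my + c1) * (2 * cxy + c2)) /
                        ((mx^2 + my^2 + c1) * (vx + vy + c2)))
    }
  }
  mean(vals)
}

# PSNR directly from the sum of squared differences
oracle_psnr <- function(a, b) {
  sq <- sum((as.numeric(a@pixels) - as.numeric(b@pixels))^2)
  n <- length(a@pixels)
  if (sq == 0) return(Inf)
  10 * log10(255^2 / (sq / n))
}

# Frechet distance between diagonal Gaussians as the sum of per-dimension
# univariate closed forms: (dmu)^2 + va + vb - 2*sqrt(va*vb)
oracle_fid_diagonal <- function(muA, varA, muB, varB) {
  sum((muA - muB)^2 + varA + varB - 2 * sqrt(varA * varB))
}

# brute-force Hamming distance on 0/1 vectors
oracle_hamming <- function(a, b) sum(abs(a - b))

clamp_arr <- function(x) {
  x[x < 0] <- 0
  x[x > 255] <- 255
  x
}

# small seeded phantom pair (FA frame + OCT report at a compact canvas)
make_phantom_pair <- function(seed, canvas = 64) {
  p <- phantomParams(canvasSize = canvas, seed = seed,
                     nMicroaneurysms = 3, leakageMode = "focal",
                     edemaCenters = matrix(c(canvas * 0.4, canvas * 0.55), 1, 2),
                     edemaAmplitudes = 120, edemaRadii = canvas * 0.05)
  f <- generateThicknessField(p, gradeLabel = "moderate_NPDR")
  list(fa = renderFaFrame(f, p),
       oct = renderThicknessMap(f, defaultColorScale(), p),
       field = f, params = p)
}
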