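test_that("MSE and PSNR reproduce the definitional values", {
  z <- rasterImage8(array(0, c(16, 16, 3)))
  w <- rasterImage8(array(255, c(16, 16, 3)))
  expect_equal(mseImage(z, z), 0)
  expect_equal(mseImage(z, w), 65025)
  d16 <- rasterImage8(array(16, c(16, 16, 3)))
  expect_equal(mseImage(z, d16), 256)
  expect_equal(psnr(z, w), 0)
  expect_equal(psnr(z, d16), 10 * log10(65025 / 256))
  expect_equal(psnr(z, d16), 24.0484, tolerance = 1e-4)
  expect_identical(psnr(z, z), Inf)
  expect_error(mseImage(z, rasterImage8(matrix(0, 8, 8))),
               class = "parameterError")
  # PSNR strictly decreasing in MSE
  imgs <- lapply(c(4, 8, 16, 32), function(a) {
    rasterImage8(array(a, c(16, 16, 3)))
  })
  ps <- vapply(imgs, function(i) psnr(z, i), numeric(1))
  expect_true(all(diff(ps) < 0))
})

test_that("SSIM: identity, constant pairs, and agreement with the oracle", {
  pp <- make_phantom_pair(3)
  expect_equal(ssim(pp$fa, pp$fa), 1)
  cst <- rasterImage8(matrix(123, 32, 32))
  expect_equal(ssim(cst, cst), 1)
  # contrast-inverted copy, cross-checked against the independently coded
  # window-loop reference
  inv <- rasterImage8(255 - pp$fa@pixels)
  expect_equal(ssim(pp$fa, inv), oracle_ssim(pp$fa, inv), tolerance = 1e-6)
  tiny <- rasterImage8(matrix(0, 8, 8))
  expect_error(ssim(tiny, tiny), class = "parameterError")
})

test_that("average hash: tie rule, half-split count, brightness invariance", {
  cst <- averageHash(rasterImage8(matrix(77, 40, 40)))
  expect_equal(sum(cst@bits), 0)  # strict > against the mean
  m <- matrix(0, 64, 64); m[, 1:32] <- 255
  half <- averageHash(rasterImage8(m))
  expect_equal(sum(half@bits), 32)
  # base image scaled for headroom so the +20 shift stays affine (no clip)
  pp <- make_phantom_pair(5)
  base <- rasterImage8(pp$fa@pixels * 0.85)
  bright <- rasterImage8(base@pixels + 20)
  expect_identical(averageHash(base)@bits, averageHash(bright)@bits)
  # invariance under positive scalings preserving the above-mean set
  for (g in c(0.5, 1.1)) {
    scaled <- rasterImage8(base@pixels * g)
    expect_identical(averageHash(scaled)@bits, averageHash(base)@bits)
  }
})

test_that("Hamming distance bands follow the interpretation rule", {
  z <- new("PerceptualHash", bits = integer(64), sourceDims = c(8L, 8L))
  o <- new("PerceptualHash", bits = rep(1L, 64), sourceDims = c(8L, 8L))
  same <- hammingDistance(z, z)
  expect_equal(same@raw, 0L)
  expect_equal(same@category, "similar")
  comp <- hammingDistance(z, o)
  expect_equal(comp@raw, 64L)
  expect_equal(comp@normalized, 1)
  expect_equal(comp@category, "likely_different")
  b5 <- integer(64); b5[c(3, 9, 22, 40, 61)] <- 1L
  v5 <- hammingDistance(z, new("PerceptualHash", bits = b5,
                               sourceDims = c(8L, 8L)))
  expect_equal(v5@raw, 5L)
  expect_equal(v5@category, "potential_variation")
  b11 <- integer(64); b11[1:11] <- 1L
  expect_equal(hammingDistance(z, new("PerceptualHash", bits = b11,
                                      sourceDims = c(8L, 8L)))@category,
               "likely_different")
})

test_that("Hamming distance is a metric on fingerprints", {
  withr::with_seed(17, {
    for (rep in 1:20) {
      a <- as.integer(stats::runif(64) > 0.5)
      b <- as.integer(stats::runif(64) > 0.5)
      c <- as.integer(stats::runif(64) > 0.5)
      ha <- new("PerceptualHash", bits = a, sourceDims = c(8L, 8L))
      hb <- new("PerceptualHash", bits = b, sourceDims = c(8L, 8L))
      hc <- new("PerceptualHash", bits = c, sourceDims = c(8L, 8L))
      expect_equal(hammingDistance(ha, hb)@raw, oracle_hamming(a, b))
      expect_equal(hammingDistance(ha, hb)@raw, hammingDistance(hb, ha)@raw)
      expect_lte(hammingDistance(ha, hc)@raw,
                 hammingDistance(ha, hb)@raw + hammingDistance(hb, hc)@raw)
    }
  })
})

test_that("feature distance is a pseudo-metric, monotone in noise dose", {
  pp <- make_phantom_pair(9)
  fd0 <- featureDistance(pp$fa, pp$fa)
  expect_equal(fd0$distance, 0)
  expect_true(all(fd0$map == 0))
  other <- make_phantom_pair(10)$fa
  ab <- featureDistance(pp$fa, other)
  ba <- featureDistance(other, pp$fa)
  expect_equal(ab$distance, ba$distance, tolerance = 1e-12)
  expect_gte(ab$distance, 0)
  expect_equal(dim(ab$map), c(64, 64))
  # increasing additive noise amplitude increases the distance on average
  amps <- c(5, 15, 40, 90)
  meanDist <- vapply(amps, function(amp) {
    mean(vapply(1:10, function(s) {
      noisy <- withr::with_seed(1000 + s, {
        rasterImage8(clamp_arr(pp$fa@pixels +
          array(stats::rnorm(length(pp$fa@pixels), sd = amp),
                dim(pp$fa@pixels))))
      })
      featureDistance(pp$fa, noisy)$distance
    }, numeric(1)))
  }, numeric(1))
  expect_true(all(diff(meanDist) > 0))
})

test_that("pair evaluation aggregates all four metrics with sentinels", {
  pp1 <- make_phantom_pair(11); pp2 <- make_phantom_pair(12)
  # identical pairs: SSIM 1, HD 0, PSNR flagged as infinite
  repIdent <- evaluatePairs(list(pp1$fa, pp2$fa), list(pp1$fa, pp2$fa))
  expect_equal(repIdent@perPair$ssim, c(1, 1))
  expect_equal(repIdent@perPair$hd_raw, c(0L, 0L))
  expect_equal(repIdent@nInfinitePsnr, 2L)
  # single pair: sd reported as 0
  rep1 <- evaluatePairs(list(pp1$fa), list(pp2$fa))
  expect_true(all(rep1@aggregate$sd == 0))
  # CSV report: one row per pair plus the aggregate row
  f <- tempfile(fileext = ".csv")
  writeMetricReport(evaluatePairs(list(pp1$fa, pp2$fa),
                                  list(pp2$fa, pp1$fa)), f)
  expect_equal(nrow(utils::read.csv(f)), 3)
  expect_error(evaluatePairs(list(), list()), class = "parameterError")
})

test_that("metric oracles agree on seeded phantom pairs", {
  # cross-implementation agreement of ssim and psnr on generated pairs
  for (s in 1:5) {
    pp <- make_phantom_pair(100 + s)
    other <- make_phantom_pair(200 + s)
    expect_equal(ssim(pp$fa, other$fa), oracle_ssim(pp$fa, other$fa),
                 tolerance = 1e-6)
    expect_equal(psnr(pp$fa, other$fa), oracle_psnr(pp$fa, other$fa),
                 tolerance = 1e-9)
  }
})
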