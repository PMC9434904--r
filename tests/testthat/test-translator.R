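tiny_cfg <- function(...) {
  trainConfig(imageSize = 32, epochs = 2, checkpointInterval = 1,
              ngf = 8, ndf = 8, seed = 7, ...)
}

tiny_pairs <- function(n, seed = 71, outSize = 32) {
  raw <- generateDataset(n, list(canvasSize = 128), seed = seed)
  preprocessDataset(raw, nTest = 1, seed = seed, outSize = outSize)$samples
}

test_that("generator maps images to bounded same-size color outputs", {
  for (size in c(32, 64)) {
    cfg <- trainConfig(imageSize = size, ngf = 8, ndf = 8, seed = 3)
    gen <- buildGenerator(cfg)
    x <- rasterImage8(array(round(runif(size * size * 3, 0, 255)),
                            c(size, size, 3)))
    y <- translateImage(gen, x)
    expect_equal(dim(y@pixels), c(size, size, 3))
    expect_true(all(y@pixels >= 0 & y@pixels <= 255))
  }
  cfg <- trainConfig(imageSize = 32, ngf = 8, ndf = 8, seed = 3)
  gen <- buildGenerator(cfg)
  bad <- rasterImage8(array(0, c(16, 16, 3)))
  expect_error(translateImage(gen, bad), class = "parameterError")
  expect_error(trainConfig(imageSize = 48), "power of two")
})

test_that("discriminator emits the patch score grid of the adopted head", {
  # 256 px input with the 4x-downsampling patch head gives a 30 x 30 grid
  cfg <- trainConfig(imageSize = 256, ngf = 4, ndf = 4, seed = 5)
  disc <- buildDiscriminator(cfg)
  src <- rasterImage8(array(128, c(256, 256, 3)))
  cand <- rasterImage8(array(round(runif(256 * 256 * 3, 0, 255)),
                             c(256, 256, 3)))
  grid <- discriminatorScores(disc, src, cand)
  expect_true(is.matrix(grid))
  expect_equal(dim(grid), c(30, 30))
  # swapping the candidate changes scores but not the grid shape
  grid2 <- discriminatorScores(disc, src, src)
  expect_equal(dim(grid2), dim(grid))
  expect_false(identical(grid, grid2))
})

test_that("composite generator loss follows the lambda-weighted formula", {
  lb <- compositeGeneratorLoss(1, 1, 100)
  expect_equal(lb@generatorLoss, 101)
  expect_equal(compositeGeneratorLoss(0.7, 0, 100)@generatorLoss, 0.7)
  expect_equal(compositeGeneratorLoss(0.7, 0.3, 0)@generatorLoss, 0.7)
  expect_error(compositeGeneratorLoss(-1, 0.5), class = "parameterError")
})

test_that("checkpoint count follows the floor(epochs / interval) law", {
  pairs <- tiny_pairs(3)
  for (sched in list(c(4, 2, 2), c(5, 2, 2), c(3, 3, 1))) {
    cfg <- trainConfig(imageSize = 32, epochs = sched[1],
                       checkpointInterval = sched[2], ngf = 8, ndf = 8,
                       seed = 13)
    run <- trainPix2pix(pairs[1:2], cfg)
    expect_length(run$checkpoints@epochs, sched[3])
    expect_equal(run$checkpoints@epochs,
                 seq(sched[2], by = sched[2], length.out = sched[3]))
  }
  expect_error(trainPix2pix(list(), tiny_cfg()), class = "parameterError")
})

test_that("training is deterministic and logs the exact loss identity", {
  pairs <- tiny_pairs(4)
  cfg <- tiny_cfg()
  r1 <- trainPix2pix(pairs[1:3], cfg)
  r2 <- trainPix2pix(pairs[1:3], cfg)
  expect_identical(r1$history, r2$history)
  # generator_loss = adversarial + lambda * L1 at every recorded epoch
  expect_equal(r1$history$generator_loss,
               r1$history$adversarial_loss + cfg@lambdaL1 * r1$history$l1_loss,
               tolerance = 1e-10)
  expect_true(all(r1$history$discriminator_loss >= 0))
})

test_that("translation is deterministic with frozen weights", {
  pairs <- tiny_pairs(3)
  run <- trainPix2pix(pairs[1:2], tiny_cfg())
  out1 <- translateImage(run$generator, pairs[[3]]@faCrop)
  out2 <- translateImage(run$generator, pairs[[3]]@faCrop)
  expect_identical(out1@pixels, out2@pixels)
})

test_that("checkpoints survive a save/load round trip", {
  pairs <- tiny_pairs(3)
  cfg <- tiny_cfg()
  run <- trainPix2pix(pairs[1:2], cfg)
  dir <- tempfile()
  saveCheckpointSet(run$checkpoints, dir, cfg)
  expect_length(list.files(dir, pattern = "^g_fa_to_oct_\\d+\\.rds$"), 2)
  back <- loadCheckpointSet(dir, "fa_to_oct")
  expect_equal(back@epochs, run$checkpoints@epochs)
  src <- pairs[[3]]@faCrop
  expect_identical(translateImage(back@generators[[2]], src)@pixels,
                   translateImage(run$checkpoints@generators[[2]], src)@pixels)
})

test_that("the L1 term pulls outputs toward the target (lambda sensitivity)", {
  # with lambda = 0 the generator has no reconstruction incentive: its
  # mean L1 against targets is at least that of the lambda = 100 run,
  # averaged over seeds
  pairs <- tiny_pairs(10, seed = 83)
  l1_of <- function(lambda, seed) {
    cfg <- trainConfig(imageSize = 32, epochs = 4, checkpointInterval = 4,
                       lambdaL1 = lambda, ngf = 8, ndf = 8, seed = seed)
    run <- trainPix2pix(pairs[1:8], cfg)
    mean(vapply(pairs[9:10], function(s) {
      out <- translateImage(run$generator, s@faCrop)
      mean(abs(out@pixels - s@octCrop@pixels)) / 255
    }, numeric(1)))
  }
  seeds <- c(101, 202, 303)
  withL1 <- mean(vapply(seeds, function(s) l1_of(100, s), numeric(1)))
  without <- mean(vapply(seeds, function(s) l1_of(0, s), numeric(1)))
  expect_gte(without, withL1)
})
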