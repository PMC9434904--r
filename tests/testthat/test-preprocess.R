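test_that("mirroring: identity on right eyes, involution, exact flip", {
  pp <- make_phantom_pair(1)
  expect_identical(mirrorToRight(pp$fa, "right")@pixels, pp$fa@pixels)
  once <- mirrorToRight(pp$fa, "left")
  expect_identical(mirrorToRight(once, "left")@pixels, pp$fa@pixels)
  # single white pixel at column x moves to column W - 1 - x
  m <- matrix(0, 8, 16); m[3, 5] <- 255  # x = 4 (0-based)
  flipped <- mirrorToRight(rasterImage8(m), "left")
  expect_equal(flipped@pixels[3, 16 - 4, 1], 255)
  expect_error(mirrorToRight(pp$fa, "up"), class = "parameterError")
})

test_that("color-square detection recovers exact painted geometry", {
  # square painted at rows [100, 612), cols [90, 602) on a 704 px report
  pix <- array(120, c(704, 704, 3))
  pix[101:612, 91:602, 2] <- 230  # green square -> high chroma
  report <- rasterImage8(pix, "RGB")
  win <- scanWindow(50, 50, 654, 654)
  reg <- detectColorSquare(report, win)
  expect_equal(c(reg@bbox@x0, reg@bbox@y0, reg@bbox@x1, reg@bbox@y1),
               c(90, 100, 602, 612))
  expect_equal(reg@center, c(345.5, 355.5))
})

test_that("color-square detection: gray content errors, saturated fills", {
  gray <- rasterImage8(array(128, c(64, 64, 3)), "RGB")
  expect_error(detectColorSquare(gray, scanWindow(10, 10, 50, 50)),
               class = "NoColorMapFound")
  full <- rasterImage8(array(rep(c(200, 40, 40), each = 64 * 64),
                             c(64, 64, 3)), "RGB")
  win <- scanWindow(8, 12, 40, 52)
  reg <- detectColorSquare(full, win)
  expect_equal(c(reg@bbox@x0, reg@bbox@y0, reg@bbox@x1, reg@bbox@y1),
               c(8, 12, 40, 52))
})

test_that("square detection is equivariant under horizontal mirroring", {
  pp <- make_phantom_pair(21, canvas = 96)
  reg <- detectColorSquare(pp$oct)
  flipped <- mirrorToRight(pp$oct, "left")
  W <- imgWidth(pp$oct)
  win <- defaultOctWindow(pp$oct)
  winF <- scanWindow(W - win@x1, win@y0, W - win@x0, win@y1)
  regF <- detectColorSquare(flipped, winF)
  expect_equal(regF@center[1], W - 1 - reg@center[1], tolerance = 1e-9)
  expect_equal(regF@center[2], reg@center[2])
})

test_that("FAZ segmentation localizes the centroid and is translation-equivariant", {
  canvas <- 128
  mk <- function(fovea) {
    p <- phantomParams(canvasSize = canvas, seed = 31, noiseSd = 2)
    f <- generateThicknessField(p, foveaCenter = fovea)
    renderFaFrame(f, p)
  }
  seg <- segmentFAZ(mk(c(64, 62)))
  expect_lt(max(abs(seg@centroid - c(64, 62))), 2)
  # mask is binary and the contour is nonempty
  expect_true(all(seg@mask %in% c(0, 255)))
  expect_gt(nrow(seg@contour), 4)
  # disc translated by (+8, -6) moves the centroid by the same amount
  seg2 <- segmentFAZ(mk(c(72, 56)))
  expect_lt(max(abs(seg2@centroid - seg@centroid - c(8, -6))), 2)
  # uniform bright frame: nothing below threshold
  bright <- rasterImage8(matrix(200, canvas, canvas))
  expect_error(segmentFAZ(bright), class = "NoFAZFound")
})

test_that("FAZ segmentation is equivariant under horizontal mirroring", {
  pp <- make_phantom_pair(33, canvas = 128)
  seg <- segmentFAZ(pp$fa)
  W <- imgWidth(pp$fa)
  win <- defaultFaWindow(pp$fa)
  winF <- scanWindow(W - win@x1, win@y0, W - win@x0, win@y1)
  segF <- segmentFAZ(mirrorToRight(pp$fa, "left"), winF)
  expect_lt(abs(segF@centroid[1] - (W - 1 - seg@centroid[1])), 0.5)
  expect_lt(abs(segF@centroid[2] - seg@centroid[2]), 0.5)
})

test_that("fovea-centered cropping: identity, alignment and degenerate side", {
  pp <- make_phantom_pair(41, canvas = 64)
  # center crop of the full frame is the identity
  full <- cropFoveaCentered(pp$fa, c(31.5, 31.5), 64)
  expect_identical(full@pixels, pp$fa@pixels)
  # 1 x 1 crop returns the fovea pixel
  one <- cropFoveaCentered(pp$fa, c(20, 30), 1)
  expect_equal(dim(one@pixels)[1:2], c(1, 1))
  expect_equal(one@pixels[1, 1, 1], pp$fa@pixels[31, 21, 1])
  expect_error(cropFoveaCentered(pp$fa, c(-5, 10), 8),
               class = "parameterError")
  # FA crop at the FAZ centroid and OCT crop at the square center cover
  # the same retinal coordinates: the edema center lands at the same
  # relative position in both crops
  pq <- make_phantom_pair(42, canvas = 128)
  seg <- segmentFAZ(pq$fa)
  reg <- detectColorSquare(pq$oct)
  side <- round(reg@bbox@x1 - reg@bbox@x0)
  ec <- pq$params@edemaCenters[1, ]
  relFa <- ec - (seg@centroid - (side - 1) / 2)
  relOct <- ec - (reg@center - (side - 1) / 2)
  expect_lt(max(abs(relFa - relOct)), 2)
})

test_that("magnification scaling follows round(dims * factor) and inverts", {
  img <- rasterImage8(matrix(runif(704 * 704, 0, 255), 704, 704))
  expect_identical(scaleForMagnification(img, 1.0)@pixels, img@pixels)
  half <- scaleForMagnification(img, 0.5)
  expect_equal(dim(half@pixels)[1:2], c(352, 352))
  back <- scaleForMagnification(half, 2.0)
  expect_equal(dim(back@pixels)[1:2], c(704, 704))
  expect_error(scaleForMagnification(img, 0), class = "parameterError")
})

test_that("finalizeCrop always yields the square RGB training canvas", {
  odd <- rasterImage8(matrix(seq(0, 255, length.out = 37 * 51), 37, 51))
  out <- finalizeCrop(odd, 64)
  expect_equal(dim(out@pixels), c(64, 64, 3))
  # grayscale input replicates to three equal channels
  expect_identical(out@pixels[, , 1], out@pixels[, , 2])
  expect_identical(out@pixels[, , 1], out@pixels[, , 3])
  # already-conforming input passes through unchanged
  sq <- rasterImage8(array(round(runif(64 * 64 * 3, 0, 255)), c(64, 64, 3)))
  expect_identical(finalizeCrop(sq, 64)@pixels, sq@pixels)
})

test_that("pair concatenation and decomposition are exact inverses", {
  a <- rasterImage8(array(round(runif(32 * 32 * 3, 0, 255)), c(32, 32, 3)))
  b <- rasterImage8(array(round(runif(32 * 32 * 3, 0, 255)), c(32, 32, 3)))
  comp <- concatenatePair(a, b)
  expect_equal(dim(comp@pixels), c(32, 64, 3))
  halves <- splitComposite(comp)
  expect_identical(halves$fa@pixels, a@pixels)
  expect_identical(halves$oct@pixels, b@pixels)
  swapped <- concatenatePair(b, a)
  expect_identical(splitComposite(swapped)$fa@pixels, b@pixels)
  expect_error(concatenatePair(a, rasterImage8(matrix(0, 16, 16))),
               class = "parameterError")
  # lossless PNG round trip of the composite is bit-exact
  f <- tempfile(fileext = ".png")
  writeRasterImage(comp, f)
  expect_identical(readRasterImage(f)@pixels, comp@pixels)
})

test_that("reader's folder contains the four QC images plus the composite", {
  pp <- make_phantom_pair(51, canvas = 128)
  res <- preprocessPair(pp$fa, pp$oct, "right", "0001", "moderate_NPDR",
                        outSize = 32)
  out <- tempfile()
  buildReadersFolder(res$sample, toRGB(pp$fa), pp$fa, res$seg, out)
  files <- list.files(file.path(out, "0001"))
  expect_length(files, 5)
  # binary QC image: two gray levels apart from the centroid mark
  bin <- readRasterImage(file.path(out, "0001", "4_faz_binary_centroid.png"))
  notMark <- !(bin@pixels[, , 1] == 255 & bin@pixels[, , 2] == 0)
  expect_true(all(bin@pixels[, , 1][notMark] %in% c(0, 255)))
  # idempotent overwrite
  buildReadersFolder(res$sample, toRGB(pp$fa), pp$fa, res$seg, out)
  expect_length(list.files(file.path(out, "0001")), 5)
})

test_that("stratified split honors the study arithmetic and conserves labels", {
  grades <- c("no_DR", "mild_NPDR", "moderate_NPDR", "severe_NPDR", "PDR")
  labels <- withr::with_seed(9, sample(grades, 1195, replace = TRUE))
  sp <- splitDataset(labels, 110, seed = 5)
  expect_length(sp$train, 1085)
  expect_length(sp$test, 110)
  expect_length(intersect(sp$train, sp$test), 0)
  expect_setequal(c(sp$train, sp$test), seq_along(labels))
  counts <- table(labels[sp$test])
  expect_true(all(counts == 22))
  # grade multiset conserved across train plus test
  expect_identical(sort(labels), sort(labels[c(sp$train, sp$test)]))
  # determinism
  expect_identical(splitDataset(labels, 110, seed = 5), sp)
  # tiny case: one per stratum
  sp5 <- splitDataset(rep(grades, 3), 5, seed = 1)
  expect_true(all(table(rep(grades, 3)[sp5$test]) == 1))
  expect_error(splitDataset(labels, 2000), class = "parameterError")
})

test_that("full preprocessing co-registers phantom pairs around the fovea", {
  raw <- generateDataset(8, list(canvasSize = 128), seed = 61)
  prep <- preprocessDataset(raw, nTest = 2, seed = 1, outSize = 32)
  for (i in seq_along(raw)) {
    m <- prep$manifest[i, ]
    expect_equal(m$qc_status, "auto")
    fovea <- raw[[i]]$field@foveaCenter
    expect_lt(max(abs(c(m$faz_centroid_x, m$faz_centroid_y) - fovea)), 3)
    expect_lt(max(abs(c(m$map_center_x, m$map_center_y) - fovea)), 3)
  }
  # composite structure: left half is the FA crop bit-exactly
  s <- prep$samples[[1]]
  expect_identical(s@composite@pixels[, 1:32, ], s@faCrop@pixels)
  expect_identical(s@composite@pixels[, 33:64, ], s@octCrop@pixels)
})
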