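test_that("thickness field: no-perturbation case is constant at baseline", {
  p <- phantomParams(canvasSize = 64, noiseSd = 0, seed = 1)
  f <- generateThicknessField(p)
  # outside the foveal dip the field equals the baseline exactly
  v <- f@values
  border <- c(v[1:5, ], v[, 1:5])
  expect_true(all(abs(border - 250) < 1))
  expect_true(all(v >= 0) && all(is.finite(v)))
})

test_that("thickness field generation is deterministic for a fixed seed", {
  p <- phantomParams(canvasSize = 64, noiseSd = 6, seed = 99)
  expect_identical(generateThicknessField(p)@values,
                   generateThicknessField(p)@values)
})

test_that("a single edema bump peaks at its center with bounded amplitude", {
  ctr <- c(20, 44)
  p <- phantomParams(canvasSize = 96, noiseSd = 0, seed = 1,
                     edemaCenters = matrix(ctr, 1, 2),
                     edemaAmplitudes = 200, edemaRadii = 6)
  f <- generateThicknessField(p)
  # the analytic construction: baseline + 200 * exp(-d^2 / (2 * 6^2)),
  # minus a foveal dip far from the bump
  idx <- which(f@values == max(f@values), arr.ind = TRUE)
  peak <- c(idx[1, 2] - 1, idx[1, 1] - 1)  # (x, y), 0-based
  expect_lte(max(abs(peak - ctr)), 1)
  expect_gte(max(f@values), 250)
  expect_lte(max(f@values), 450 + 1e-9)
})

test_that("invalid phantom parameters are rejected", {
  expect_error(phantomParams(canvasSize = 32), class = "parameterError")
  expect_error(phantomParams(canvasSize = 64,
                             edemaCenters = matrix(c(10, 10), 1, 2),
                             edemaAmplitudes = -5, edemaRadii = 3),
               class = "parameterError")
})

test_that("rendered map colors sit in the clinically expected bands", {
  p <- phantomParams(canvasSize = 64, noiseSd = 0, seed = 2)
  scale <- defaultColorScale()
  # normal baseline renders green: G dominates R and B inside the square
  f <- new("ThicknessField", values = matrix(250, 64, 64),
           foveaCenter = c(31.5, 31.5), gradeLabel = "no_DR")
  img <- renderThicknessMap(f, scale, p)
  ctr <- img@pixels[32, 32, ]
  expect_gt(ctr[2], ctr[1])
  expect_gt(ctr[2], ctr[3])
  # zero thickness renders in the violet/blue band: B dominates G
  f0 <- new("ThicknessField", values = matrix(0, 64, 64),
            foveaCenter = c(31.5, 31.5), gradeLabel = "no_DR")
  img0 <- renderThicknessMap(f0, scale, p)
  ctr0 <- img0@pixels[32, 32, ]
  expect_gt(ctr0[3], ctr0[2])
})

test_that("map rendering inverts through the color scale within one step", {
  pp <- make_phantom_pair(7, canvas = 96)
  dec <- decodeThickness(pp$oct)
  side <- round(0.30 * 96)
  x0 <- round(pp$field@foveaCenter[1]) - side %/% 2
  y0 <- round(pp$field@foveaCenter[2]) - side %/% 2
  rows <- (y0 + 1):(y0 + side); cols <- (x0 + 1):(x0 + side)
  truth <- pmin(pp$field@values[rows, cols], 500)
  expect_lt(max(abs(dec[rows, cols] - truth)), 1.0)
})

test_that("FA frame construction: dark FAZ, bright microaneurysms, leakage", {
  canvas <- 96
  ctr <- matrix(c(30, 60), 1, 2)
  base <- phantomParams(canvasSize = canvas, noiseSd = 0, seed = 5,
                        nMicroaneurysms = 1, leakageMode = "none",
                        edemaCenters = ctr, edemaAmplitudes = 100,
                        edemaRadii = 7)
  f <- generateThicknessField(base)
  fa <- renderFaFrame(f, base)
  g <- toGray(fa)
  # microaneurysm dot brighter than its surroundings
  expect_gt(g[61, 31], mean(g))
  # FAZ disc darker than the frame at large
  d2 <- outer(((0:(canvas - 1)) - f@foveaCenter[2])^2,
              ((0:(canvas - 1)) - f@foveaCenter[1])^2, `+`)
  expect_lt(mean(g[d2 < base@fazRadius^2]), mean(g[d2 > (2 * base@fazRadius)^2]))
  # leakage none: the halo annulus matches a render without any lesion
  clean <- phantomParams(canvasSize = canvas, noiseSd = 0, seed = 5)
  gClean <- toGray(renderFaFrame(generateThicknessField(clean), clean))
  dh <- outer(((0:(canvas - 1)) - 60)^2, ((0:(canvas - 1)) - 30)^2, `+`)
  annulus <- dh > 5^2 & dh < 10^2
  expect_equal(g[annulus], gClean[annulus])
  # focal leakage brightens that same annulus
  focal <- base; focal@leakageMode <- "focal"
  gFocal <- toGray(renderFaFrame(f, focal))
  expect_gt(mean(gFocal[annulus]), mean(g[annulus]))
})

test_that("left-eye renders are exact mirrors of right-eye geometry", {
  pr <- make_phantom_pair(11)
  pl <- pr$params; pl@laterality <- "left"
  faL <- renderFaFrame(pr$field, pl)
  expect_identical(mirrorToRight(faL, "left")@pixels, pr$fa@pixels)
  octL <- renderThicknessMap(pr$field, defaultColorScale(), pl)
  expect_identical(mirrorToRight(octL, "left")@pixels, pr$oct@pixels)
})

test_that("virtual FA diagrams: three canonical modes on equidistant rings", {
  imgs <- lapply(c("dots", "focal", "diffuse"), generateVirtualFA,
                 canvasSize = 128)
  # three distinct canonical drawings, deterministic
  expect_false(identical(imgs[[1]]@pixels, imgs[[2]]@pixels))
  expect_false(identical(imgs[[2]]@pixels, imgs[[3]]@pixels))
  expect_identical(generateVirtualFA("dots", 128)@pixels, imgs[[1]]@pixels)
  # dot centers lie on rings with a constant radial increment: find bright
  # dots and cluster their radii
  g <- toGray(imgs[[1]])
  hits <- which(g > 230, arr.ind = TRUE)
  r <- sqrt((hits[, 2] - 1 - 63.5)^2 + (hits[, 1] - 1 - 63.5)^2)
  rings <- sort(unique(round(stats::kmeans(r, 3)$centers[, 1])))
  expect_lt(max(abs(diff(rings) - mean(diff(rings)))), 1)
  # leakage adds hyperfluorescent area: dots < diffuse in bright pixels
  nb <- vapply(imgs, function(im) sum(toGray(im) > 130), numeric(1))
  expect_lt(nb[1], nb[3])
  expect_error(generateVirtualFA("ring", 128), class = "parameterError")
})

test_that("phantom parameters round-trip through the flat YAML file", {
  p <- phantomParams(canvasSize = 96, nMicroaneurysms = 4,
                     leakageMode = "focal",
                     edemaCenters = matrix(c(30, 60, 40, 50), 2, 2),
                     edemaAmplitudes = c(80, 120), edemaRadii = c(5, 7),
                     laterality = "left", noiseSd = 2, seed = 17)
  f <- tempfile(fileext = ".yaml")
  writePhantomParams(p, f)
  q <- readPhantomParams(f)
  for (sl in slotNames(p)) expect_equal(slot(q, sl), slot(p, sl), info = sl)
  # identical renders from the reloaded parameters
  fld <- generateThicknessField(p)
  expect_identical(renderFaFrame(fld, q)@pixels, renderFaFrame(fld, p)@pixels)
})

test_that("dataset generation is reproducible and structurally complete", {
  d1 <- generateDataset(10, list(canvasSize = 64), seed = 3)
  d2 <- generateDataset(10, list(canvasSize = 64), seed = 3)
  expect_identical(lapply(d1, function(s) s$fa@pixels),
                   lapply(d2, function(s) s$fa@pixels))
  expect_identical(lapply(d1, function(s) s$oct@pixels),
                   lapply(d2, function(s) s$oct@pixels))
  # all five DR stages appear under the default uniform stage distribution
  d50 <- generateDataset(50, list(canvasSize = 64), seed = 4)
  expect_setequal(unique(vapply(d50, `[[`, "", "gradeLabel")),
                  c("no_DR", "mild_NPDR", "moderate_NPDR", "severe_NPDR",
                    "PDR"))
  # every OCT report carries colored (chromatic) pixels by construction
  for (s in d1) {
    p <- s$oct@pixels
    chroma <- pmax(p[, , 1], p[, , 2], p[, , 3]) -
      pmin(p[, , 1], p[, , 2], p[, , 3])
    expect_gt(max(chroma), 30)
  }
  # leakage halos and edema bumps share centers (the learnable signal)
  for (s in d50) {
    if (s$params@leakageMode != "none") {
      expect_gt(nrow(s$params@edemaCenters), 0)
    }
  }
})
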