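# Phantom generator: seeded synthetic co-registered FA frames and OCT
# color-coded macular thickness map reports, plus the three diagrammatic
# "virtual FA" drawings used to probe a trained FA->OCT generator.
#
# Canonical geometry is a right eye; left-eye phantoms are exact horizontal
# mirrors, so the downstream mirroring stage is exactly invertible.

# Rendering constants shared by the map renderer and the decoder. The color
# square is blended with the stated opacity over a uniform red-free gray --
# the overlay destroys the underlying vasculature on real device reports,
# so nothing structured is drawn beneath it.
MAP_ALPHA <- 0.85
MAP_UNDER_GRAY <- 110
MAP_SQUARE_FRAC <- 0.30

#' Default thickness color scale
#'
#' Piecewise-linear stops over 0-500 um in the clinical ordering:
#' violet/blue (thin) -> green (normal) -> yellow -> orange -> red -> white
#' (progressively thicker). The device's true breakpoints are not public;
#' these are configurable via [thicknessColorScale()].
#'
#' @return A [ThicknessColorScale-class].
#' @export
defaultColorScale <- function() {
  thicknessColorScale(data.frame(
    thickness = c(0, 100, 225, 300, 350, 425, 500),
    r = c(148,   0,   0, 255, 255, 255, 255),
    g = c(  0,   0, 255, 255, 165,   0, 255),
    b = c(211, 255,   0,   0,   0,   0, 255)
  ))
}

#' Construct a thickness color scale
#'
#' @param stops data.frame with `thickness` (um, strictly increasing,
#'   starting at 0) and 8-bit `r`, `g`, `b` columns.
#' @return A [ThicknessColorScale-class].
#' @export
thicknessColorScale <- function(stops) {
  new("ThicknessColorScale", stops = stops,
      maxThickness = utils::tail(stops$thickness, 1))
}

#' Map thickness values to RGB through a color scale
#'
#' Linear interpolation between stops; values above the top stop clip to
#' the top color.
#'
#' @param thickness numeric vector/matrix in um.
#' @param scale a [ThicknessColorScale-class].
#' @return numeric matrix `n x 3` of 8-bit colors (unrounded).
#' @export
scaleColors <- function(thickness, scale) {
  s <- scale@stops
  t <- pmin(pmax(as.numeric(thickness), 0), scale@maxThickness)
  cbind(
    stats::approx(s$thickness, s$r, t, rule = 2)$y,
    stats::approx(s$thickness, s$g, t, rule = 2)$y,
    stats::approx(s$thickness, s$b, t, rule = 2)$y
  )
}

#' Construct phantom parameters
#'
#' Defaults place phantoms in the green-to-red bands of the 0-500 um scale:
#' baseline thickness 250 um with edema amplitudes in 50-250 um.
#'
#' @param canvasSize canvas side in px (>= 64).
#' @param vesselDepth branching recursion depth.
#' @param vesselWidth trunk width in px.
#' @param fazRadius FAZ disc radius in px.
#' @param nMicroaneurysms number of bright dots (leaking dots sit at the
#'   edema centers; any surplus dots do not leak).
#' @param leakageMode `"none"`, `"focal"` or `"diffuse"`.
#' @param edemaCenters n x 2 matrix of `(x, y)` centers (canonical right-eye
#'   coordinates); leakage halos share these centers exactly.
#' @param edemaAmplitudes bump heights in um.
#' @param edemaRadii bump radii (Gaussian sd) in px.
#' @param laterality `"left"` or `"right"`.
#' @param noiseSd additive noise sd.
#' @param seed integer seed.
#' @return A [PhantomParams-class].
#' @export
phantomParams <- function(canvasSize = 128,
                          vesselDepth = 4,
                          vesselWidth = max(1.5, canvasSize / 110),
                          fazRadius = round(0.06 * canvasSize),
                          nMicroaneurysms = 0,
                          leakageMode = "none",
                          edemaCenters = matrix(numeric(0), 0, 2),
                          edemaAmplitudes = numeric(0),
                          edemaRadii = numeric(0),
                          laterality = "right",
                          noiseSd = 4,
                          seed = 1L) {
  if (canvasSize < 64) rf_error("parameterError", "canvasSize must be >= 64")
  if (length(edemaAmplitudes) && any(edemaAmplitudes < 0)) {
    rf_error("parameterError", "edema amplitudes must be >= 0")
  }
  new("PhantomParams", canvasSize = canvasSize, vesselDepth = vesselDepth,
      vesselWidth = vesselWidth, fazRadius = fazRadius,
      nMicroaneurysms = nMicroaneurysms, leakageMode = leakageMode,
      edemaCenters = edemaCenters, edemaAmplitudes = edemaAmplitudes,
      edemaRadii = edemaRadii, laterality = laterality,
      noiseSd = noiseSd, seed = seed)
}

# squared distance of every grid pixel to (x, y); 0-based coordinates
grid_dist2 <- function(S, x, y) {
  dx <- (0:(S - 1)) - x
  dy <- (0:(S - 1)) - y
  outer(dy^2, dx^2, `+`)  # rows = y, cols = x
}

#' Generate a retinal thickness field
#'
#' Smooth baseline (250 um) plus Gaussian edema bumps at the configured
#' centers and a smooth low-frequency perturbation scaled by `noiseSd`.
#' Deterministic for a fixed seed. The field is defined in canonical
#' right-eye coordinates; the fovea sits at the canvas center.
#'
#' @param params a [PhantomParams-class].
#' @param foveaCenter `(x, y)`; defaults to the canvas center.
#' @param gradeLabel ETDRS grade tag attached to the field.
#' @param baseline baseline thickness in um.
#' @return A [ThicknessField-class].
#' @export
generateThicknessField <- function(params, foveaCenter = NULL,
                                   gradeLabel = "no_DR", baseline = 250) {
  S <- params@canvasSize
  if (is.null(foveaCenter)) foveaCenter <- c((S - 1) / 2, (S - 1) / 2)
  v <- matrix(baseline, S, S)
  nb <- nrow(params@edemaCenters)
  if (nb > 0) {
    for (i in seq_len(nb)) {
      d2 <- grid_dist2(S, params@edemaCenters[i, 1], params@edemaCenters[i, 2])
      v <- v + params@edemaAmplitudes[i] * exp(-d2 / (2 * params@edemaRadii[i]^2))
    }
  }
  if (params@noiseSd > 0) {
    v <- v + withr::with_seed(as.integer(params@seed), {
      coarse <- matrix(stats::rnorm(64, sd = params@noiseSd), 8, 8)
      up <- EBImage::resize(EBImage::Image(coarse), w = S, h = S)
      EBImage::imageData(up)
    })
  }
  # foveal dip: the real macula thins toward the foveal pit
  v <- v - 30 * exp(-grid_dist2(S, foveaCenter[1], foveaCenter[2]) /
                      (2 * (1.2 * params@fazRadius)^2))
  v[v < 0] <- 0
  new("ThicknessField", values = v, foveaCenter = foveaCenter,
      gradeLabel = gradeLabel)
}

# stamp a filled soft-edged disc of the given value onto a matrix
stamp_disc <- function(m, x, y, r, value, soft = 1) {
  S <- nrow(m)
  x0 <- max(0, floor(x - r - soft - 1)); x1 <- min(S - 1, ceiling(x + r + soft + 1))
  y0 <- max(0, floor(y - r - soft - 1)); y1 <- min(S - 1, ceiling(y + r + soft + 1))
  if (x0 > x1 || y0 > y1) return(m)
  xs <- x0:x1; ys <- y0:y1
  d <- sqrt(outer((ys - y)^2, (xs - x)^2, `+`))
  w <- pmin(1, pmax(0, (r + soft - d) / soft))
  sub <- m[ys + 1, xs + 1, drop = FALSE]
  m[ys + 1, xs + 1] <- sub * (1 - w) + value * w
  m
}

stamp_segment <- function(m, p0, p1, width, value, soft = 0.8) {
  S <- nrow(m)
  r <- width / 2
  pad <- r + soft + 1
  x0 <- max(0, floor(min(p0[1], p1[1]) - pad))
  x1 <- min(S - 1, ceiling(max(p0[1], p1[1]) + pad))
  y0 <- max(0, floor(min(p0[2], p1[2]) - pad))
  y1 <- min(S - 1, ceiling(max(p0[2], p1[2]) + pad))
  if (x0 > x1 || y0 > y1) return(m)
  xs <- x0:x1; ys <- y0:y1
  v <- p1 - p0
  vv <- sum(v^2)
  gx <- matrix(xs, length(ys), length(xs), byrow = TRUE)
  gy <- matrix(ys, length(ys), length(xs))
  t <- if (vv > 0) ((gx - p0[1]) * v[1] + (gy - p0[2]) * v[2]) / vv else 0
  t[t < 0] <- 0; t[t > 1] <- 1
  d <- sqrt((gx - (p0[1] + t * v[1]))^2 + (gy - (p0[2] + t * v[2]))^2)
  w <- (r + soft - d) / soft
  w[w < 0] <- 0; w[w > 1] <- 1
  sub <- m[ys + 1, xs + 1, drop = FALSE]
  m[ys + 1, xs + 1] <- sub * (1 - w) + value * w
  m
}

# recursive midpoint-displacement branching tree; purely cosmetic
draw_vessel_tree <- function(m, S, depth, width, value) {
  branch <- function(m, p, angle, len, w, d) {
    ang <- angle + stats::runif(1, -0.15, 0.15)
    mid <- p + (len / 2) * c(cos(ang), sin(ang)) +
      stats::runif(2, -len * 0.08, len * 0.08)
    q <- p + len * c(cos(ang), sin(ang))
    m <- stamp_segment(m, p, mid, w, value)
    m <- stamp_segment(m, mid, q, w, value)
    if (d > 0) {
      spread <- stats::runif(1, 0.35, 0.6)
      m <- branch(m, q, ang - spread, len * 0.72, w * 0.75, d - 1)
      m <- branch(m, q, ang + spread, len * 0.72, w * 0.75, d - 1)
    }
    m
  }
  root <- c(0.02 * S, 0.5 * S)  # vessels enter at the nasal edge
  m <- branch(m, root, -0.55, 0.3 * S, width, depth)
  m <- branch(m, root, +0.55, 0.3 * S, width, depth)
  m
}

flip_h <- function(pix) {
  # mirror around the vertical axis (reverse columns)
  pix[, rev(seq_len(dim(pix)[2])), , drop = FALSE]
}

#' Render a mid-phase FA frame phantom
#'
#' Grayscale frame: bright perfused background with a branching vessel
#' tree, a dark disc at the fovea (the FAZ), bright microaneurysm dots,
#' and -- when `leakageMode` is not `"none"` -- hyperfluorescent leakage
#' halos centered exactly on the edema centers of the paired thickness
#' field. Left-eye phantoms are horizontal mirrors of the right-eye render.
#'
#' @param field a [ThicknessField-class] (provides the fovea center).
#' @param params a [PhantomParams-class]; requires
#'   `fazRadius < canvasSize / 4`.
#' @return A grayscale [RasterImage-class].
#' @export
renderFaFrame <- function(field, params) {
  S <- params@canvasSize
  if (params@fazRadius >= S / 4) {
    rf_error("parameterError", "fazRadius must be < canvasSize / 4")
  }
  fx <- field@foveaCenter[1]; fy <- field@foveaCenter[2]
  m <- withr::with_seed(as.integer(params@seed), {
    d2 <- grid_dist2(S, (S - 1) / 2, (S - 1) / 2)
    m <- matrix(140, S, S) - 18 * d2 / max(d2)  # mild vignette
    m <- draw_vessel_tree(m, S, params@vesselDepth, params@vesselWidth, 195)
    # leakage halos (before dots so dots stay visible on top)
    if (params@leakageMode != "none" && nrow(params@edemaCenters) > 0) {
      amp <- if (params@leakageMode == "focal") 60 else 80
      widen <- if (params@leakageMode == "focal") 1 else 1.6
      for (i in seq_len(nrow(params@edemaCenters))) {
        d2h <- grid_dist2(S, params@edemaCenters[i, 1], params@edemaCenters[i, 2])
        m <- m + amp * exp(-d2h / (2 * (widen * params@edemaRadii[i])^2))
      }
    }
    # FAZ: dark capillary-free disc at the fovea
    m <- stamp_disc(m, fx, fy, params@fazRadius, 45, soft = 2)
    # microaneurysm dots: leaking ones sit at the edema centers
    dots <- params@edemaCenters
    nExtra <- max(0, params@nMicroaneurysms - nrow(dots))
    if (nExtra > 0) {
      ang <- stats::runif(nExtra, 0, 2 * pi)
      rad <- stats::runif(nExtra, 2.2 * params@fazRadius, 0.32 * S)
      dots <- rbind(dots, cbind(fx + rad * cos(ang), fy + rad * sin(ang)))
    }
    for (i in seq_len(nrow(dots))) {
      m <- stamp_disc(m, dots[i, 1], dots[i, 2], max(1.2, 0.008 * S), 238, soft = 0.8)
    }
    if (params@noiseSd > 0) m <- m + matrix(stats::rnorm(S * S, sd = params@noiseSd), S, S)
    m
  })
  pix <- array(round(clamp255(m)), c(S, S, 1L))
  if (params@laterality == "left") pix <- flip_h(pix)
  rasterImage8(pix, "gray")
}

#' Render an OCT macular thickness map report phantom
#'
#' RGB report: red-free gray fundus with vessels, a color-coded thickness
#' square transparently overlaid centered at the fovea, and a vertical
#' color bar strip at the right margin. Thickness above the scale maximum
#' clips to the top color. Left-eye reports are horizontal mirrors.
#'
#' @param field a [ThicknessField-class].
#' @param scale a [ThicknessColorScale-class].
#' @param params a [PhantomParams-class] (geometry, seed, laterality).
#' @return An RGB [RasterImage-class].
#' @export
renderThicknessMap <- function(field, scale = defaultColorScale(),
                               params = phantomParams(canvasSize = ncol(field@values))) {
  S <- params@canvasSize
  stopifnot(all(dim(field@values) == S))
  bg <- withr::with_seed(as.integer(params@seed) + 1L, {
    m <- matrix(120, S, S)
    m <- draw_vessel_tree(m, S, params@vesselDepth, params@vesselWidth, 98)
    if (params@noiseSd > 0) m <- m + matrix(stats::rnorm(S * S, sd = params@noiseSd), S, S)
    m
  })
  pix <- array(rep(clamp255(bg), 3L), c(S, S, 3L))

  # color-coded square centered at the (canonical) fovea
  side <- round(MAP_SQUARE_FRAC * S)
  x0 <- round(field@foveaCenter[1]) - side %/% 2
  y0 <- round(field@foveaCenter[2]) - side %/% 2
  rows <- (y0 + 1):(y0 + side); cols <- (x0 + 1):(x0 + side)
  sub <- field@values[rows, cols]
  cc <- scaleColors(sub, scale)
  for (ch in 1:3) {
    pix[rows, cols, ch] <- MAP_ALPHA * matrix(cc[, ch], side, side) +
      (1 - MAP_ALPHA) * MAP_UNDER_GRAY
  }

  # vertical color bar at the right margin (outside any central scan window)
  barW <- max(3L, round(0.035 * S))
  barRows <- (round(0.1 * S) + 1):(round(0.9 * S))
  barCols <- (S - barW + 1):S
  tbar <- seq(scale@maxThickness, 0, length.out = length(barRows))
  cbar <- scaleColors(tbar, scale)
  for (ch in 1:3) pix[barRows, barCols, ch] <- cbar[, ch]

  pix <- round(clamp255(pix))
  if (params@laterality == "left") pix <- flip_h(pix)
  rasterImage8(pix, "RGB")
}

#' Decode thickness from a rendered (or synthesized) map
#'
#' Inverts the color scale by nearest-neighbor lookup against a finely
#' sampled version of the scale, after un-blending the known overlay
#' opacity. On rendered phantoms this recovers the field within one
#' quantization step (1 um lookup grid) everywhere inside the square.
#'
#' @param img an RGB [RasterImage-class] (a map crop or a full render).
#' @param scale the [ThicknessColorScale-class] used for rendering.
#' @param alpha,background overlay constants used by [renderThicknessMap()].
#' @param step lookup grid resolution in um.
#' @return numeric matrix of decoded thickness (um), same H x W as `img`.
#' @export
decodeThickness <- function(img, scale = defaultColorScale(),
                            alpha = MAP_ALPHA, background = MAP_UNDER_GRAY,
                            step = 0.5) {
  stopifnot(imgChannels(img) == 3L)
  p <- img@pixels
  n <- dim(p)[1] * dim(p)[2]
  flat <- cbind(as.numeric(p[, , 1]), as.numeric(p[, , 2]), as.numeric(p[, , 3]))
  flat <- (flat - (1 - alpha) * background) / alpha
  tg <- seq(0, scale@maxThickness, by = step)
  lut <- scaleColors(tg, scale)
  lut2 <- rowSums(lut^2)
  out <- numeric(n)
  block <- 20000L
  for (s in seq(1L, n, by = block)) {
    e <- min(n, s + block - 1L)
    cross <- flat[s:e, , drop = FALSE] %*% t(lut)
    d2 <- matrix(lut2, e - s + 1L, length(tg), byrow = TRUE) - 2 * cross
    out[s:e] <- tg[max.col(-d2, ties.method = "first")]
  }
  matrix(out, dim(p)[1], dim(p)[2])
}

#' Generate a diagrammatic virtual FA drawing
#'
#' Abstract right-macula diagram: a central dark presumed FAZ and bright
#' dots (virtual microaneurysms) placed on concentric rings at equal radial
#' spacing. `mode` controls the surrounding hyperfluorescence: `"dots"`
#' adds no halo, `"focal"` adds a tight halo per dot, `"diffuse"` adds wide
#' confluent halos. The three modes produce three canonical, deterministic
#' diagrams.
#'
#' @param mode `"dots"`, `"focal"` or `"diffuse"`.
#' @param canvasSize canvas side in px.
#' @return A grayscale [RasterImage-class].
#' @export
generateVirtualFA <- function(mode = c("dots", "focal", "diffuse"),
                              canvasSize = 512) {
  if (!is.character(mode) || !mode[1] %in% c("dots", "focal", "diffuse")) {
    rf_error("parameterError", "mode must be dots, focal or diffuse")
  }
  mode <- mode[1]
  S <- canvasSize
  cx <- (S - 1) / 2; cy <- (S - 1) / 2
  m <- matrix(120, S, S)
  ringStep <- 0.11 * S
  radii <- ringStep * (1:3)
  dots <- do.call(rbind, lapply(seq_along(radii), function(k) {
    nk <- 8L
    ang <- 2 * pi * (0:(nk - 1)) / nk + (k - 1) * pi / 8
    cbind(cx + radii[k] * cos(ang), cy + radii[k] * sin(ang))
  }))
  if (mode != "dots") {
    amp <- 70
    sd <- if (mode == "focal") 0.030 * S else 0.085 * S
    for (i in seq_len(nrow(dots))) {
      m <- m + amp * exp(-grid_dist2(S, dots[i, 1], dots[i, 2]) / (2 * sd^2))
    }
  }
  m <- stamp_disc(m, cx, cy, 0.05 * S, 40, soft = 2)
  for (i in seq_len(nrow(dots))) {
    m <- stamp_disc(m, dots[i, 1], dots[i, 2], max(1.5, 0.010 * S), 240, soft = 0.8)
  }
  rasterImage8(array(round(clamp255(m)), c(S, S, 1L)), "gray")
}

grade_recipe <- function(grade, S, fx, fy) {
  # lesion load scales with ETDRS stage; leakage halos and edema bumps are
  # co-located so FA leakage predicts OCT thickening
  spreadMax <- 0.4 * MAP_SQUARE_FRAC * S  # keep edema inside the map square
  place <- function(n, rmin, rmax) {
    ang <- stats::runif(n, 0, 2 * pi)
    rad <- stats::runif(n, rmin, rmax)
    cbind(fx + rad * cos(ang), fy + rad * sin(ang))
  }
  switch(grade,
    no_DR = list(nMA = 0, leak = "none", centers = matrix(numeric(0), 0, 2),
                 amps = numeric(0), radii = numeric(0)),
    mild_NPDR = list(nMA = 3, leak = "none", centers = matrix(numeric(0), 0, 2),
                     amps = numeric(0), radii = numeric(0)),
    moderate_NPDR = {
      n <- 2
      list(nMA = 5, leak = "focal", centers = place(n, 0.3 * spreadMax, spreadMax),
           amps = stats::runif(n, 50, 120), radii = stats::runif(n, 0.035, 0.05) * S)
    },
    severe_NPDR = {
      n <- 3
      list(nMA = 8, leak = "focal", centers = place(n, 0.3 * spreadMax, spreadMax),
           amps = stats::runif(n, 100, 180), radii = stats::runif(n, 0.04, 0.06) * S)
    },
    PDR = {
      n <- 4
      list(nMA = 10, leak = "diffuse", centers = place(n, 0.2 * spreadMax, spreadMax),
           amps = stats::runif(n, 150, 250), radii = stats::runif(n, 0.055, 0.08) * S)
    })
}

#' Generate a seeded phantom dataset
#'
#' Produces `nPairs` raw (un-preprocessed) report-style image pairs with
#' randomized fovea position, laterality and ETDRS grade (uniform over the
#' five stages by default), the stand-in for a clinical paired FA/OCT
#' collection. Each element carries the ground-truth field and parameters,
#' which downstream tests use as the co-registration reference.
#'
#' @param nPairs number of pairs (>= 1).
#' @param paramsDistribution named list of overrides: `canvasSize`,
#'   `noiseSd`, `gradeLevels` (subset of stages to sample from).
#' @param seed integer seed; the run is reproducible from it alone.
#' @return A list of length `nPairs`; each element is a list with `id`,
#'   `fa`, `oct` ([RasterImage-class]), `laterality`, `gradeLabel`,
#'   `field` ([ThicknessField-class]) and `params` ([PhantomParams-class]).
#' @export
generateDataset <- function(nPairs, paramsDistribution = list(), seed = 1L) {
  if (nPairs < 1) rf_error("parameterError", "nPairs must be >= 1")
  S <- paramsDistribution$canvasSize %||% 128
  noiseSd <- paramsDistribution$noiseSd %||% 4
  gradeLevels <- paramsDistribution$gradeLevels %||% GRADE_LEVELS
  scale <- defaultColorScale()
  withr::with_seed(as.integer(seed), {
    seeds <- sample.int(.Machine$integer.max - 1L, nPairs)
    lapply(seq_len(nPairs), function(i) {
      withr::with_seed(seeds[i], {
        grade <- sample(gradeLevels, 1)
        lat <- sample(c("left", "right"), 1)
        fx <- (S - 1) / 2 + stats::runif(1, -0.03, 0.03) * S
        fy <- (S - 1) / 2 + stats::runif(1, -0.03, 0.03) * S
        rec <- grade_recipe(grade, S, fx, fy)
        params <- phantomParams(
          canvasSize = S, nMicroaneurysms = rec$nMA, leakageMode = rec$leak,
          edemaCenters = rec$centers, edemaAmplitudes = rec$amps,
          edemaRadii = rec$radii, laterality = lat, noiseSd = noiseSd,
          seed = sample.int(.Machine$integer.max - 1L, 1))
        field <- generateThicknessField(params, foveaCenter = c(fx, fy),
                                        gradeLabel = grade)
        list(id = sprintf("%04d", i),
             fa = renderFaFrame(field, params),
             oct = renderThicknessMap(field, scale, params),
             laterality = lat, gradeLabel = grade,
             field = field, params = params)
      })
    })
  })
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write phantom parameters to a flat YAML file
#'
#' Flat key-value form of every [PhantomParams-class] field (edema centers
#' as parallel `edema_x` / `edema_y` lists).
#'
#' @param params a [PhantomParams-class].
#' @param path destination YAML.
#' @return `path`, invisibly.
#' @export
writePhantomParams <- function(params, path) {
  yaml::write_yaml(list(
    canvas_size = params@canvasSize, vessel_depth = params@vesselDepth,
    vessel_width = params@vesselWidth, faz_radius = params@fazRadius,
    n_microaneurysms = params@nMicroaneurysms,
    leakage_mode = params@leakageMode,
    edema_x = as.numeric(params@edemaCenters[, 1]),
    edema_y = as.numeric(params@edemaCenters[, 2]),
    edema_amplitudes = params@edemaAmplitudes,
    edema_radii = params@edemaRadii, laterality = params@laterality,
    noise_sd = params@noiseSd, seed = params@seed), path)
  invisible(path)
}

#' Read phantom parameters from a flat YAML file
#'
#' @param path YAML file written by [writePhantomParams()] (missing keys
#'   take the [phantomParams()] defaults).
#' @return A [PhantomParams-class].
#' @export
readPhantomParams <- function(path) {
  y <- yaml::read_yaml(path)
  base <- phantomParams(canvasSize = y$canvas_size %||% 128)
  phantomParams(
    canvasSize = y$canvas_size %||% 128,
    vesselDepth = y$vessel_depth %||% base@vesselDepth,
    vesselWidth = y$vessel_width %||% base@vesselWidth,
    fazRadius = y$faz_radius %||% base@fazRadius,
    nMicroaneurysms = y$n_microaneurysms %||% 0,
    leakageMode = y$leakage_mode %||% "none",
    edemaCenters = cbind(as.numeric(y$edema_x %||% numeric(0)),
                         as.numeric(y$edema_y %||% numeric(0))),
    edemaAmplitudes = as.numeric(y$edema_amplitudes %||% numeric(0)),
    edemaRadii = as.numeric(y$edema_radii %||% numeric(0)),
    laterality = y$laterality %||% "right",
    noiseSd = y$noise_sd %||% 4,
    seed = y$seed %||% 1L)
}
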