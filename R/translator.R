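# pix2pix conditional GAN: U-Net generator with skip connections joining
# mirrored resolutions, patch-based discriminator judging (source,
# candidate) pairs on a spatial grid, and the composite objective
# generator loss = adversarial loss + lambda * L1 loss (lambda = 100).
# Self-contained CPU implementation; all convolutions are 4x4 with pad 1.

#' Composite loss breakdown
#'
#' The components of one generator/discriminator update. The invariant
#' `generatorLoss == adversarialLoss + lambdaL1 * l1Loss` holds exactly.
#'
#' @slot adversarialLoss BCE of the discriminator's patch scores on the
#'   fake, judged against "real".
#' @slot l1Loss mean absolute pixel difference between the generated
#'   translation and the target.
#' @slot generatorLoss the lambda-weighted composite.
#' @slot discriminatorLoss discriminator objective (NA outside training).
#' @export
setClass("LossBreakdown",
  representation(adversarialLoss = "numeric", l1Loss = "numeric",
                 generatorLoss = "numeric", discriminatorLoss = "numeric"),
  validity = function(object) {
    if (object@adversarialLoss < 0 || object@l1Loss < 0) {
      return("loss components must be >= 0")
    }
    TRUE
  }
)

#' Construct a training configuration
#'
#' Full-scale defaults: 512 px images, 200 epochs, a snapshot every 10
#' epochs (20 checkpoints), lambda = 100, Adam at learning rate 2e-4 with
#' beta1 = 0.5, batch size 1. Desk-scale runs shrink `imageSize`, `ngf`,
#' `ndf` and `epochs`; the architecture stays valid because the U-Net
#' depth is log2(imageSize) with the innermost layer at 1 x 1.
#'
#' @param imageSize power of two >= 32.
#' @param epochs training epochs.
#' @param checkpointInterval epochs between generator snapshots.
#' @param lambdaL1 L1 weight in the composite generator loss.
#' @param batchSize images per update.
#' @param learningRate,adamBeta1 Adam settings.
#' @param ngf,ndf base channel widths (generator / discriminator).
#' @param seed integer seed covering init and data order.
#' @param direction `"fa_to_oct"` or `"oct_to_fa"`.
#' @return A [TrainConfig-class].
#' @export
trainConfig <- function(imageSize = 512, epochs = 200, checkpointInterval = 10,
                        lambdaL1 = 100, batchSize = 1, learningRate = 2e-4,
                        adamBeta1 = 0.5, ngf = 64, ndf = 64, seed = 1L,
                        direction = "fa_to_oct") {
  new("TrainConfig", imageSize = imageSize, epochs = epochs,
      checkpointInterval = checkpointInterval, lambdaL1 = lambdaL1,
      batchSize = batchSize, learningRate = learningRate,
      adamBeta1 = adamBeta1, ngf = ngf, ndf = ndf, seed = seed,
      direction = direction)
}

gen_arch <- function(config) {
  n <- as.integer(round(log2(config@imageSize)))
  encCh <- pmin(config@ngf * 2^(0:(n - 1)), 8 * config@ngf)
  list(n = n, encCh = encCh, size = config@imageSize)
}

#' Build a U-Net generator
#'
#' Encoder-decoder with skip connections joining mirrored resolutions;
#' maps a 3-channel `imageSize^2` image to a 3-channel image of the same
#' size with a tanh output (bounded to `[-1, 1]`). Weights are drawn from
#' N(0, 0.02) under the config seed. Instance normalization everywhere
#' except the first encoder layer, the 1 x 1 innermost layer and the
#' output layer.
#'
#' @param config a [TrainConfig-class].
#' @return A generator object (list with `arch` and `params`).
#' @export
buildGenerator <- function(config) {
  arch <- gen_arch(config)
  n <- arch$n; ch <- arch$encCh
  withr::with_seed(as.integer(config@seed), {
    P <- list()
    for (i in 1:n) {
      cin <- if (i == 1) 3L else ch[i - 1]
      P[[paste0("e", i, "_w")]] <- init_conv_w(ch[i], cin)
      P[[paste0("e", i, "_b")]] <- numeric(ch[i])
      if (i >= 2 && i <= n - 1) {
        P[[paste0("en", i, "_g")]] <- rep(1, ch[i])
        P[[paste0("en", i, "_bt")]] <- numeric(ch[i])
      }
    }
    for (i in n:1) {
      cin <- if (i == n) ch[n] else 2L * ch[i]
      cout <- if (i == 1) 3L else ch[i - 1]
      P[[paste0("d", i, "_u")]] <- init_tconv_u(cin, cout)
      P[[paste0("d", i, "_b")]] <- numeric(cout)
      if (i >= 2) {
        P[[paste0("dn", i, "_g")]] <- rep(1, cout)
        P[[paste0("dn", i, "_bt")]] <- numeric(cout)
      }
    }
    list(arch = arch, params = P)
  })
}

gen_forward <- function(gen, x, keepCache = TRUE) {
  n <- gen$arch$n; P <- gen$params
  e <- encIn <- encNorm <- vector("list", n)
  for (i in 1:n) {
    inp <- if (i == 1) x else lrelu_fw(e[[i - 1]])
    encIn[[i]] <- inp
    h <- conv_fw(inp, P[[paste0("e", i, "_w")]], P[[paste0("e", i, "_b")]])
    if (i >= 2 && i <= n - 1) {
      nc <- inorm_fw(h, P[[paste0("en", i, "_g")]], P[[paste0("en", i, "_bt")]])
      encNorm[[i]] <- nc
      h <- nc$y
    }
    e[[i]] <- h
  }
  decIn <- decRelu <- decNorm <- vector("list", n)
  h <- e[[n]]
  y <- NULL
  for (i in n:1) {
    inp <- if (i == n) h else concat_ch(h, e[[i]])
    decIn[[i]] <- inp
    r <- relu_fw(inp)
    decRelu[[i]] <- r
    t <- tconv_fw(r, P[[paste0("d", i, "_u")]], P[[paste0("d", i, "_b")]])
    if (i >= 2) {
      nc <- inorm_fw(t, P[[paste0("dn", i, "_g")]], P[[paste0("dn", i, "_bt")]])
      decNorm[[i]] <- nc
      h <- nc$y
    } else {
      y <- tanh(t)
    }
  }
  cache <- if (keepCache) {
    list(e = e, encIn = encIn, encNorm = encNorm, decIn = decIn,
         decRelu = decRelu, decNorm = decNorm, y = y)
  }
  list(y = y, cache = cache)
}

gen_backward <- function(gen, cache, gy) {
  n <- gen$arch$n; P <- gen$params
  ch <- gen$arch$encCh
  G <- list()
  skipGrad <- vector("list", n)
  gh <- NULL
  for (i in 1:n) {
    gt <- if (i == 1) {
      gy * (1 - cache$y^2)
    } else {
      nb <- inorm_bw(cache$decNorm[[i]], P[[paste0("dn", i, "_g")]], gh)
      G[[paste0("dn", i, "_g")]] <- nb$ggamma
      G[[paste0("dn", i, "_bt")]] <- nb$gbeta
      nb$gx
    }
    bw <- tconv_bw(cache$decRelu[[i]], P[[paste0("d", i, "_u")]], gt)
    G[[paste0("d", i, "_u")]] <- bw$gu
    G[[paste0("d", i, "_b")]] <- bw$gb
    ginp <- relu_bw(cache$decIn[[i]], bw$gx)
    if (i == n) {
      gh <- NULL
      geTop <- ginp
    } else {
      gh <- ginp[, , seq_len(ch[i]), drop = FALSE]
      skipGrad[[i]] <- ginp[, , ch[i] + seq_len(ch[i]), drop = FALSE]
    }
  }
  ge <- geTop
  for (i in n:1) {
    gout <- ge
    if (i < n && !is.null(skipGrad[[i]])) gout <- gout + skipGrad[[i]]
    gconv <- if (i >= 2 && i <= n - 1) {
      nb <- inorm_bw(cache$encNorm[[i]], P[[paste0("en", i, "_g")]], gout)
      G[[paste0("en", i, "_g")]] <- nb$ggamma
      G[[paste0("en", i, "_bt")]] <- nb$gbeta
      nb$gx
    } else gout
    bw <- conv_bw(cache$encIn[[i]], P[[paste0("e", i, "_w")]], gconv)
    G[[paste0("e", i, "_w")]] <- bw$gw
    G[[paste0("e", i, "_b")]] <- bw$gb
    if (i > 1) ge <- lrelu_bw(cache$e[[i - 1]], bw$gx)
  }
  G[names(P)]
}

disc_layers <- function(config) {
  ndf <- config@ndf
  list(
    list(cin = 6L, cout = ndf, s = 2L, norm = FALSE, act = TRUE),
    list(cin = ndf, cout = 2L * ndf, s = 2L, norm = TRUE, act = TRUE),
    list(cin = 2L * ndf, cout = 4L * ndf, s = 2L, norm = TRUE, act = TRUE),
    list(cin = 4L * ndf, cout = 8L * ndf, s = 1L, norm = TRUE, act = TRUE),
    list(cin = 8L * ndf, cout = 1L, s = 1L, norm = FALSE, act = FALSE)
  )
}

#' Build a patch-based discriminator
#'
#' Consumes the channel-wise concatenation of (source, candidate) and
#' emits a spatial grid of real/fake logits: each grid cell judges one
#' overlapping receptive-field patch (70 x 70 px at full resolution). For
#' a 256 px input with the default 4x-downsampling patch head the grid is
#' 30 x 30.
#'
#' @param config a [TrainConfig-class].
#' @return A discriminator object (list with `layers` and `params`).
#' @export
buildDiscriminator <- function(config) {
  layers <- disc_layers(config)
  withr::with_seed(as.integer(config@seed) + 1L, {
    P <- list()
    for (j in seq_along(layers)) {
      L <- layers[[j]]
      P[[paste0("c", j, "_w")]] <- init_conv_w(L$cout, L$cin)
      P[[paste0("c", j, "_b")]] <- numeric(L$cout)
      if (L$norm) {
        P[[paste0("cn", j, "_g")]] <- rep(1, L$cout)
        P[[paste0("cn", j, "_bt")]] <- numeric(L$cout)
      }
    }
    list(layers = layers, params = P)
  })
}

disc_forward <- function(disc, src, cand, keepCache = TRUE) {
  if (!identical(dim(src), dim(cand))) {
    rf_error("parameterError", "source and candidate dims must match")
  }
  x <- concat_ch(src, cand)
  L <- disc$layers; P <- disc$params
  convIn <- norms <- pre <- vector("list", length(L))
  h <- x
  for (j in seq_along(L)) {
    convIn[[j]] <- h
    h <- conv_fw(h, P[[paste0("c", j, "_w")]], P[[paste0("c", j, "_b")]],
                 s = L[[j]]$s)
    if (L[[j]]$norm) {
      nc <- inorm_fw(h, P[[paste0("cn", j, "_g")]], P[[paste0("cn", j, "_bt")]])
      norms[[j]] <- nc
      h <- nc$y
    }
    pre[[j]] <- h
    if (L[[j]]$act) h <- lrelu_fw(h)
  }
  cache <- if (keepCache) list(convIn = convIn, norms = norms, pre = pre)
  list(logits = h, cache = cache)
}

disc_backward <- function(disc, cache, glog) {
  L <- disc$layers; P <- disc$params
  G <- list()
  gh <- glog
  for (j in rev(seq_along(L))) {
    if (L[[j]]$act) gh <- lrelu_bw(cache$pre[[j]], gh)
    if (L[[j]]$norm) {
      nb <- inorm_bw(cache$norms[[j]], P[[paste0("cn", j, "_g")]], gh)
      G[[paste0("cn", j, "_g")]] <- nb$ggamma
      G[[paste0("cn", j, "_bt")]] <- nb$gbeta
      gh <- nb$gx
    }
    bw <- conv_bw(cache$convIn[[j]], P[[paste0("c", j, "_w")]], gh,
                  s = L[[j]]$s)
    G[[paste0("c", j, "_w")]] <- bw$gw
    G[[paste0("c", j, "_b")]] <- bw$gb
    gh <- bw$gx
  }
  list(grads = G[names(P)], gx = gh)
}

#' Discriminator patch scores
#'
#' Forward pass returning the spatial logit grid for a (source, candidate)
#' pair of [RasterImage-class]s.
#'
#' @param disc a discriminator from [buildDiscriminator()].
#' @param src,cand [RasterImage-class]s of identical dimensions.
#' @return numeric matrix of patch logits.
#' @export
discriminatorScores <- function(disc, src, cand) {
  out <- disc_forward(disc, img_to_unit(src), img_to_unit(cand),
                      keepCache = FALSE)
  out$logits[, , 1]
}

#' Compose the generator objective
#'
#' `generator loss = adversarial loss + lambda * L1 loss`.
#'
#' @param adversarialLoss,l1Loss nonnegative components.
#' @param lambdaL1 the L1 weight (100 by default).
#' @param discriminatorLoss optional discriminator objective to record.
#' @return A [LossBreakdown-class].
#' @export
compositeGeneratorLoss <- function(adversarialLoss, l1Loss, lambdaL1 = 100,
                                   discriminatorLoss = NA_real_) {
  if (adversarialLoss < 0 || l1Loss < 0) {
    rf_error("parameterError", "loss components must be >= 0")
  }
  new("LossBreakdown", adversarialLoss = adversarialLoss, l1Loss = l1Loss,
      generatorLoss = adversarialLoss + lambdaL1 * l1Loss,
      discriminatorLoss = discriminatorLoss)
}

img_to_unit <- function(img) {
  img <- toRGB(img)
  img@pixels / 127.5 - 1
}

unit_to_img <- function(x) {
  rasterImage8(round(clamp255((x + 1) * 127.5)), "RGB")
}

pair_tensors <- function(pairs, direction, imageSize) {
  lapply(pairs, function(s) {
    if (imgWidth(s@faCrop) != imageSize || imgHeight(s@faCrop) != imageSize) {
      rf_error("parameterError", "pair crops must match config imageSize")
    }
    if (direction == "fa_to_oct") {
      list(src = img_to_unit(s@faCrop), tgt = img_to_unit(s@octCrop))
    } else {
      list(src = img_to_unit(s@octCrop), tgt = img_to_unit(s@faCrop))
    }
  })
}

#' Train a pix2pix translator
#'
#' Alternating discriminator/generator updates over the paired set, batch
#' size 1, with a generator snapshot saved every `checkpointInterval`
#' epochs (`floor(epochs / interval)` snapshots in total; 20 under the
#' default full-scale schedule of 200 epochs saved each 10). `direction`
#' selects
#' which half of each pair is source vs target. Fully seeded: two runs
#' with the same data and config produce identical loss histories on a
#' single-threaded CPU.
#'
#' @param pairs nonempty list of [PairedSample-class].
#' @param config a [TrainConfig-class].
#' @param verbose print per-epoch losses.
#' @return list with `checkpoints` (a [CheckpointSet-class]), `history`
#'   (per-epoch data.frame of mean adversarial, L1, generator and
#'   discriminator losses), `generator` and `discriminator` (final
#'   states).
#' @export
trainPix2pix <- function(pairs, config, verbose = FALSE) {
  if (length(pairs) < 1) rf_error("parameterError", "need at least one pair")
  tensors <- pair_tensors(pairs, config@direction, config@imageSize)
  G <- buildGenerator(config)
  D <- buildDiscriminator(config)
  optG <- adam_init(G$params)
  optD <- adam_init(D$params)
  lam <- config@lambdaL1
  ckEpochs <- integer(0)
  ckGens <- list()
  hist <- data.frame()
  withr::with_seed(as.integer(config@seed) + 2L, {
    for (ep in seq_len(config@epochs)) {
      ord <- sample.int(length(tensors))
      advs <- l1s <- gls <- dls <- numeric(length(ord))
      for (k in seq_along(ord)) {
        tp <- tensors[[ord[k]]]
        fake <- gen_forward(G, tp$src)

        # discriminator update: real pair vs generated pair
        fr <- disc_forward(D, tp$src, tp$tgt)
        ff <- disc_forward(D, tp$src, fake$y)
        dloss <- 0.5 * (bce_logits(fr$logits, 1) + bce_logits(ff$logits, 0))
        br <- disc_backward(D, fr$cache, 0.5 * bce_logits_grad(fr$logits, 1))
        bf <- disc_backward(D, ff$cache, 0.5 * bce_logits_grad(ff$logits, 0))
        gD <- mapply(`+`, br$grads, bf$grads, SIMPLIFY = FALSE)
        optD <- adam_step(D$params, gD, optD, config@learningRate,
                          config@adamBeta1)

        # generator update against the updated discriminator
        fg <- disc_forward(D, tp$src, fake$y)
        adv <- bce_logits(fg$logits, 1)
        l1 <- mean(abs(fake$y - tp$tgt))
        bg <- disc_backward(D, fg$cache, bce_logits_grad(fg$logits, 1))
        gyAdv <- bg$gx[, , 4:6, drop = FALSE]
        gyL1 <- lam * sign(fake$y - tp$tgt) / length(tp$tgt)
        gG <- gen_backward(G, fake$cache, gyAdv + gyL1)
        optG <- adam_step(G$params, gG, optG, config@learningRate,
                          config@adamBeta1)

        advs[k] <- adv; l1s[k] <- l1
        gls[k] <- adv + lam * l1; dls[k] <- dloss
      }
      hist <- rbind(hist, data.frame(
        epoch = ep, adversarial_loss = mean(advs), l1_loss = mean(l1s),
        generator_loss = mean(gls), discriminator_loss = mean(dls)))
      if (verbose) {
        message(sprintf("epoch %3d | G %.3f (adv %.3f, L1 %.4f) | D %.3f",
                        ep, mean(gls), mean(advs), mean(l1s), mean(dls)))
      }
      if (ep %% config@checkpointInterval == 0) {
        ckEpochs <- c(ckEpochs, ep)
        # deep copy: the optimizer updates parameter buffers in place
        ckGens[[length(ckGens) + 1L]] <- list(arch = G$arch,
                                              params = deep_copy_params(G$params))
      }
    }
  })
  list(
    checkpoints = new("CheckpointSet", epochs = ckEpochs,
                      generators = ckGens, direction = config@direction),
    history = hist, generator = G, discriminator = D)
}

#' Translate an image with a generator
#'
#' Deterministic inference: the instance-normalization statistics depend
#' only on the input, so repeated calls with the same weights and input
#' are bit-identical. The output is mapped back from the tanh range to an
#' 8-bit RGB image.
#'
#' @param generator a generator (from [buildGenerator()], a training run,
#'   or a [CheckpointSet-class] element).
#' @param source a [RasterImage-class] with sides equal to the generator's
#'   image size.
#' @return An RGB [RasterImage-class] of identical dimensions.
#' @export
translateImage <- function(generator, source) {
  if (imgWidth(source) != generator$arch$size ||
      imgHeight(source) != generator$arch$size) {
    rf_error("parameterError", "source dims must equal the generator image size")
  }
  out <- gen_forward(generator, img_to_unit(source), keepCache = FALSE)
  unit_to_img(out$y)
}

#' Save generator checkpoints to disk
#'
#' One weight file per snapshot, named `g_<direction>_<epoch>.rds`, plus a
#' sidecar JSON manifest (epochs, direction, seed, image size, interval,
#' lambda).
#'
#' @param checkpoints a [CheckpointSet-class].
#' @param dir destination directory.
#' @param config the [TrainConfig-class] that produced them.
#' @return `dir`, invisibly.
#' @export
saveCheckpointSet <- function(checkpoints, dir, config) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (i in seq_along(checkpoints@epochs)) {
    saveRDS(checkpoints@generators[[i]],
            file.path(dir, sprintf("g_%s_%d.rds", checkpoints@direction,
                                   checkpoints@epochs[i])))
  }
  manifest <- list(direction = checkpoints@direction,
                   epochs = checkpoints@epochs, seed = config@seed,
                   imageSize = config@imageSize,
                   checkpointInterval = config@checkpointInterval,
                   lambdaL1 = config@lambdaL1)
  jsonlite::write_json(manifest, file.path(dir, sprintf(
    "manifest_%s.json", checkpoints@direction)), auto_unbox = TRUE)
  invisible(dir)
}

#' Load generator checkpoints from disk
#'
#' @param dir directory written by [saveCheckpointSet()].
#' @param direction which direction's manifest to read.
#' @return A [CheckpointSet-class].
#' @export
loadCheckpointSet <- function(dir, direction) {
  mf <- jsonlite::read_json(file.path(dir, sprintf("manifest_%s.json",
                                                   direction)),
                            simplifyVector = TRUE)
  gens <- lapply(mf$epochs, function(ep) {
    readRDS(file.path(dir, sprintf("g_%s_%d.rds", direction, ep)))
  })
  new("CheckpointSet", epochs = as.numeric(mf$epochs), generators = gens,
      direction = direction)
}

setMethod("show", "LossBreakdown", function(object) {
  cat(sprintf("LossBreakdown: G %.4f = adv %.4f + lambda*L1 %.4f | D %.4f\n",
              object@generatorLoss, object@adversarialLoss,
              object@generatorLoss - object@adversarialLoss,
              object@discriminatorLoss))
})
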