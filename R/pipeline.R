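# End-to-end study orchestration at configurable scale:
# simulate -> preprocess -> train (both directions) -> select best
# checkpoints by FID -> translate the test set -> evaluate, with logging,
# seeding and a single YAML config. Every stage writes its outputs under
# the run directory and can be skipped on re-runs, in which case its
# outputs are reloaded from disk.

#' Default run configuration
#'
#' Desk-scale profile: 40 phantom pairs on a 128 px canvas, 32 px training
#' crops, 20 epochs with a snapshot every 5. The full-scale profile
#' (`profile = "full"`) encodes 512 px crops, 200 epochs, interval 10,
#' lambda 100 and the 1195/110 split geometry.
#'
#' @param profile `"desk"` or `"full"`.
#' @return named list of stage sub-configs.
#' @export
runConfigDefaults <- function(profile = c("desk", "full")) {
  profile <- match.arg(profile)
  desk <- list(
    seed = 1L,
    out = "retfusion_run",
    phantom = list(n_pairs = 40L, canvas_size = 128L, noise_sd = 4),
    preprocess = list(out_size = 32L, n_test = 10L,
                      saturation_threshold = 30, faz_policy = "otsu",
                      mag_scale = 1.0),
    train = list(epochs = 20L, checkpoint_interval = 5L, lambda_l1 = 100,
                 ngf = 16L, ndf = 16L, learning_rate = 2e-4,
                 adam_beta1 = 0.5, batch_size = 1L,
                 directions = c("fa_to_oct", "oct_to_fa")),
    selection = list(extractor = "desk"),
    metrics = list()
  )
  if (profile == "desk") return(desk)
  full <- desk
  full$phantom$n_pairs <- 1195L
  full$preprocess$out_size <- 512L
  full$preprocess$n_test <- 110L
  full$train$epochs <- 200L
  full$train$checkpoint_interval <- 10L
  full$train$ngf <- 64L
  full$train$ndf <- 64L
  full
}

#' Read a run configuration from YAML
#'
#' Missing keys fall back to the desk-scale defaults.
#'
#' @param path YAML file with the sections of [runConfigDefaults()].
#' @return named list.
#' @export
readRunConfig <- function(path) {
  user <- yaml::read_yaml(path)
  modifyList(runConfigDefaults("desk"), user)
}

# free-width horizontal montage (source | truth | synthesized panels)
hconcat <- function(imgs) {
  imgs <- lapply(imgs, toRGB)
  H <- imgHeight(imgs[[1]])
  W <- sum(vapply(imgs, imgWidth, numeric(1)))
  out <- array(0, c(H, W, 3L))
  x <- 0L
  for (im in imgs) {
    w <- imgWidth(im)
    out[, (x + 1):(x + w), ] <- im@pixels
    x <- x + w
  }
  rasterImage8(out, "RGB")
}

log_line <- function(logPath, ...) {
  line <- sprintf("[%s] %s", format(Sys.time(), "%H:%M:%S"), sprintf(...))
  message(line)
  cat(line, "\n", file = logPath, append = TRUE)
}

stage_timer <- function(logPath, stage, expr) {
  t0 <- proc.time()[["elapsed"]]
  res <- force(expr)
  log_line(logPath, "stage %-10s done in %.1fs", stage,
           proc.time()[["elapsed"]] - t0)
  res
}

#' Run the full study
#'
#' Executes the requested stages in order, writing each stage's artifacts
#' under `config$out`: raw phantom reports (JPEG), preprocessed composites
#' and the manifest CSV, generator checkpoints per direction, FID curves
#' (CSV), translated test images with side-by-side panels, virtual-FA
#' translations with decoded mean thickness, and the metric report CSV
#' with distance maps. Stages omitted from `stages` are reloaded from the
#' run directory (e.g. leave out `"train"` to reuse existing checkpoints).
#' Idempotent per output directory; identical config and seed reproduce
#' identical reports.
#'
#' @param config list as returned by [readRunConfig()] /
#'   [runConfigDefaults()].
#' @param stages character subset of `c("simulate", "preprocess", "train",
#'   "select", "translate", "evaluate")`.
#' @return the run directory path, invisibly.
#' @export
runStudy <- function(config = runConfigDefaults("desk"),
                     stages = c("simulate", "preprocess", "train", "select",
                                "translate", "evaluate")) {
  out <- config$out
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  logPath <- file.path(out, "run.log")
  yaml::write_yaml(config, file.path(out, "config.yaml"))
  log_line(logPath, "run start | seed %d | stages: %s", config$seed,
           paste(stages, collapse = ", "))

  rawDir <- file.path(out, "raw")
  prepDir <- file.path(out, "preprocessed")
  ckDir <- file.path(out, "checkpoints")
  selDir <- file.path(out, "selection")
  trDir <- file.path(out, "translated")
  evDir <- file.path(out, "evaluation")

  fail <- function(stage, id, e) {
    log_line(logPath, "FAILED at stage %s (sample %s): %s", stage, id,
             conditionMessage(e))
    stop(e)
  }

  # ---- simulate -----------------------------------------------------
  raw <- if ("simulate" %in% stages) {
    stage_timer(logPath, "simulate", {
      dir.create(rawDir, showWarnings = FALSE)
      raw <- generateDataset(config$phantom$n_pairs,
                             list(canvasSize = config$phantom$canvas_size,
                                  noiseSd = config$phantom$noise_sd),
                             seed = config$seed)
      for (s in raw) {
        writeRasterImage(s$fa, file.path(rawDir, paste0(s$id, "_fa.jpg")))
        writeRasterImage(s$oct, file.path(rawDir, paste0(s$id, "_oct.jpg")))
      }
      utils::write.csv(data.frame(
        id = vapply(raw, `[[`, "", "id"),
        laterality = vapply(raw, `[[`, "", "laterality"),
        grade_label = vapply(raw, `[[`, "", "gradeLabel")),
        file.path(rawDir, "raw_manifest.csv"), row.names = FALSE)
      log_line(logPath, "simulate: %d pairs", length(raw))
      raw
    })
  } else {
    mf <- utils::read.csv(file.path(rawDir, "raw_manifest.csv"),
                          colClasses = "character")
    lapply(seq_len(nrow(mf)), function(i) {
      list(id = mf$id[i],
           fa = readRasterImage(file.path(rawDir, paste0(mf$id[i], "_fa.jpg"))),
           oct = readRasterImage(file.path(rawDir, paste0(mf$id[i], "_oct.jpg"))),
           laterality = mf$laterality[i], gradeLabel = mf$grade_label[i])
    })
  }

  # ---- preprocess ---------------------------------------------------
  pc <- config$preprocess
  prep <- if ("preprocess" %in% stages) {
    stage_timer(logPath, "preprocess", {
      dir.create(prepDir, showWarnings = FALSE)
      prep <- tryCatch(
        preprocessDataset(raw, nTest = pc$n_test, seed = config$seed,
                          outSize = pc$out_size,
                          saturationThreshold = pc$saturation_threshold,
                          fazPolicy = pc$faz_policy, magScale = pc$mag_scale),
        error = function(e) fail("preprocess", "?", e))
      for (s in prep$samples) {
        writeRasterImage(s@composite,
                         file.path(prepDir, paste0(s@id, ".jpg")))
      }
      utils::write.csv(prep$manifest, file.path(prepDir, "manifest.csv"),
                       row.names = FALSE)
      log_line(logPath, "preprocess: %d auto, %d manual, %d train / %d test",
               length(prep$samples),
               sum(prep$manifest$qc_status == "manual"),
               length(prep$split$train), length(prep$split$test))
      prep
    })
  } else {
    mf <- utils::read.csv(file.path(prepDir, "manifest.csv"))
    ok <- mf$qc_status == "auto"
    samples <- lapply(which(ok), function(i) {
      comp <- readRasterImage(file.path(prepDir, paste0(
        sprintf("%04d", as.integer(mf$id[i])), ".jpg")))
      halves <- splitComposite(comp)
      new("PairedSample", faCrop = halves$fa, octCrop = halves$oct,
          composite = comp, gradeLabel = mf$grade_label[i],
          id = sprintf("%04d", as.integer(mf$id[i])))
    })
    split <- list(
      train = which(mf$split[ok] == "train"),
      test = which(mf$split[ok] == "test"))
    list(samples = samples, manifest = mf, split = split)
  }
  trainPairs <- prep$samples[prep$split$train]
  testPairs <- prep$samples[prep$split$test]

  # ---- train --------------------------------------------------------
  tc <- config$train
  mkConfig <- function(direction) {
    trainConfig(imageSize = pc$out_size, epochs = tc$epochs,
                checkpointInterval = tc$checkpoint_interval,
                lambdaL1 = tc$lambda_l1, batchSize = tc$batch_size %||% 1L,
                learningRate = tc$learning_rate, adamBeta1 = tc$adam_beta1,
                ngf = tc$ngf, ndf = tc$ndf, seed = config$seed,
                direction = direction)
  }
  checkpoints <- list()
  for (direction in tc$directions) {
    checkpoints[[direction]] <- if ("train" %in% stages) {
      stage_timer(logPath, paste0("train:", direction), {
        run <- tryCatch(trainPix2pix(trainPairs, mkConfig(direction)),
                        error = function(e) fail("train", direction, e))
        saveCheckpointSet(run$checkpoints, ckDir, mkConfig(direction))
        utils::write.csv(run$history,
                         file.path(ckDir, paste0("history_", direction, ".csv")),
                         row.names = FALSE)
        log_line(logPath, "train %s: %d checkpoints over %d epochs",
                 direction, length(run$checkpoints@epochs), tc$epochs)
        run$checkpoints
      })
    } else {
      loadCheckpointSet(ckDir, direction)
    }
  }

  # ---- select -------------------------------------------------------
  extractor <- deskExtractor()
  best <- list()
  curves <- list()
  for (direction in tc$directions) {
    srcFun <- if (direction == "fa_to_oct") function(s) s@faCrop else function(s) s@octCrop
    tgtFun <- if (direction == "fa_to_oct") function(s) s@octCrop else function(s) s@faCrop
    curves[[direction]] <- if ("select" %in% stages) {
      stage_timer(logPath, paste0("select:", direction), {
        dir.create(selDir, showWarnings = FALSE)
        curve <- selectBestCheckpoint(checkpoints[[direction]],
                                      lapply(testPairs, tgtFun),
                                      lapply(testPairs, srcFun), extractor)
        writeFidCurve(curve, file.path(selDir, paste0("fid_", direction, ".csv")))
        log_line(logPath, "select %s: best epoch %d (FID %.4f)", direction,
                 curve@epochs[curve@bestIndex], curve@fid[curve@bestIndex])
        curve
      })
    } else {
      cc <- utils::read.csv(file.path(selDir, paste0("fid_", direction, ".csv")))
      new("FIDCurve", epochs = cc$epoch, fid = cc$fid,
          bestIndex = which.min(cc$fid))
    }
    best[[direction]] <-
      checkpoints[[direction]]@generators[[curves[[direction]]@bestIndex]]
  }

  # ---- translate ----------------------------------------------------
  translations <- list()
  if ("translate" %in% stages) {
    stage_timer(logPath, "translate", {
      dir.create(trDir, showWarnings = FALSE)
      for (direction in tc$directions) {
        srcFun <- if (direction == "fa_to_oct") function(s) s@faCrop else function(s) s@octCrop
        tgtFun <- if (direction == "fa_to_oct") function(s) s@octCrop else function(s) s@faCrop
        dd <- file.path(trDir, direction)
        dir.create(dd, showWarnings = FALSE)
        translations[[direction]] <- lapply(testPairs, function(s) {
          synth <- translateImage(best[[direction]], srcFun(s))
          writeRasterImage(synth, file.path(dd, paste0(s@id, "_synth.png")))
          panel <- hconcat(list(srcFun(s), tgtFun(s), synth))
          writeRasterImage(panel, file.path(dd, paste0(s@id, "_panel.png")))
          synth
        })
      }
      # virtual-FA diagrams through the FA -> OCT generator
      if ("fa_to_oct" %in% tc$directions) {
        vf <- virtualFaResponse(best[["fa_to_oct"]],
                                canvasSize = config$phantom$canvas_size,
                                outSize = pc$out_size, outDir = trDir)
        utils::write.csv(vf, file.path(trDir, "virtual_fa_summary.csv"),
                         row.names = FALSE)
        log_line(logPath, "virtual FA decoded mean thickness: %s",
                 paste(sprintf("%s=%.0f", vf$mode, vf$mean_thickness_um),
                       collapse = ", "))
      }
    })
  } else {
    for (direction in tc$directions) {
      dd <- file.path(trDir, direction)
      translations[[direction]] <- lapply(testPairs, function(s) {
        readRasterImage(file.path(dd, paste0(s@id, "_synth.png")))
      })
    }
  }

  # ---- evaluate -----------------------------------------------------
  if ("evaluate" %in% stages) {
    stage_timer(logPath, "evaluate", {
      dir.create(evDir, showWarnings = FALSE)
      backbone <- deskBackbone()
      for (direction in tc$directions) {
        tgtFun <- if (direction == "fa_to_oct") function(s) s@octCrop else function(s) s@faCrop
        truth <- lapply(testPairs, tgtFun)
        report <- evaluatePairs(truth, translations[[direction]],
                                ids = vapply(testPairs, function(s) s@id, ""),
                                backbone = backbone)
        writeMetricReport(report,
                          file.path(evDir, paste0("metrics_", direction, ".csv")))
        mapDir <- file.path(evDir, paste0("maps_", direction))
        dir.create(mapDir, showWarnings = FALSE)
        for (i in seq_along(truth)) {
          fd <- featureDistance(truth[[i]], translations[[direction]][[i]],
                                backbone)
          writeRasterImage(distanceMapImage(fd$map),
                           file.path(mapDir, paste0(testPairs[[i]]@id, "_map.png")))
        }
        log_line(logPath, "evaluate %s: SSIM %.3f, PSNR %.2f dB", direction,
                 report@aggregate$mean[report@aggregate$metric == "ssim"],
                 report@aggregate$mean[report@aggregate$metric == "psnr_db"])
      }
    })
  }

  log_line(logPath, "run complete: %s", out)
  invisible(out)
}

#' Translate the virtual-FA diagrams and decode their thickness
#'
#' Prepares the three diagrammatic virtual-FA drawings with the same
#' cropping steps as the dataset (FAZ segmentation, fovea-centered crop of
#' the map-square side, resize), feeds them to an FA -> OCT generator, and
#' decodes the mean retinal thickness of each synthesized map through the
#' color scale. A trained model is expected to decode more thickening
#' from diffuse leakage than from bare microaneurysm dots.
#'
#' @param generator an FA -> OCT generator.
#' @param canvasSize diagram canvas (match the training phantom canvas).
#' @param outSize the generator's image size.
#' @param outDir optional directory for diagram/synthesis panels.
#' @param scale color scale for decoding.
#' @return data.frame with `mode` and `mean_thickness_um`.
#' @export
virtualFaResponse <- function(generator, canvasSize = 128, outSize = 32,
                              outDir = NULL, scale = defaultColorScale()) {
  modes <- c("dots", "focal", "diffuse")
  side <- round(MAP_SQUARE_FRAC * canvasSize)
  res <- lapply(modes, function(mode) {
    diagram <- generateVirtualFA(mode, canvasSize)
    seg <- segmentFAZ(diagram)
    crop <- finalizeCrop(cropFoveaCentered(diagram, seg@centroid, side),
                         outSize)
    synth <- translateImage(generator, crop)
    if (!is.null(outDir)) {
      writeRasterImage(concatenatePair(crop, synth),
                       file.path(outDir, paste0("virtual_fa_", mode, ".png")))
    }
    data.frame(mode = mode,
               mean_thickness_um = mean(decodeThickness(synth, scale)))
  })
  do.call(rbind, res)
}
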