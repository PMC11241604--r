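## End-to-end orchestration: preprocess -> segment -> features -> select ->
## classify -> risk screen, with one global seed deterministically fanned
## out to every stage (see deriveSeed), so a full run is bit-reproducible.

#' Default pipeline configuration
#'
#' @param seed global seed; all stage seeds derive from it.
#' @param nTrain,nEval phantom corpus sizes for demo mode (balanced
#'   normal/abnormal).
#' @param outDir optional output directory for predictions.csv and
#'   report.json.
#' @param tauRisk risk-screen intensity threshold.
#' @return nested list with per-stage configs (\code{preprocess},
#'   \code{segment}, \code{features}, \code{select}, \code{presnet}).
#' @export
pipelineConfig <- function(seed = 1L, nTrain = 120L, nEval = 60L,
                           outDir = NULL, tauRisk = 0.8) {
  list(seed = as.integer(seed), nTrain = as.integer(nTrain),
       nEval = as.integer(nEval), outDir = outDir, tauRisk = tauRisk,
       preprocess = preprocessConfig(), segment = segmentConfig(),
       features = featureConfig(),
       select = list(e = 20L, rho = 1L, g = 0.05, alpha = NULL,
                     fallbackK = 10L),
       presnet = presnetConfig(nBlocks = 1L, kappa = 4L,
                               seed = deriveSeed(seed, 7L)))
}

#' Run one image through preprocessing, segmentation and feature extraction
#'
#' @param image raw raster in [0,1].
#' @param config pipeline configuration.
#' @param seed per-image seed for the segmentation search.
#' @return list with \code{pre} (preprocessing intermediates), \code{seg}
#'   (a [SegmentationResult-class]) and \code{features} (named vector of
#'   84).
#' @export
processImage <- function(image, config = pipelineConfig(), seed = 1L) {
  pre <- preprocessImage(image, config$preprocess)
  seg <- segmentLungs(pre$enhanced, pre$mask, config$segment, seed)
  feats <- extractFeatures(seg, pre$enhanced, config$features,
                           reference = pre$denoised)
  list(pre = pre, seg = seg, features = feats)
}

.featureMatrix <- function(images, config, seedStage, globalSeed) {
  rows <- lapply(seq_along(images), function(i)
    processImage(images[[i]], config, deriveSeed(globalSeed, seedStage, i)))
  list(x = do.call(rbind, lapply(rows, `[[`, "features")), rows = rows)
}

.demoCorpus <- function(n, seedStage, globalSeed) {
  lapply(seq_len(n), function(i)
    generatePhantom(randomPhantomSpec(deriveSeed(globalSeed, seedStage, i),
                                      abnormal = i %% 2L == 0L)))
}

#' Run the screening pipeline
#'
#' \describe{
#'   \item{demo}{generates a seeded phantom corpus (\code{nTrain} training
#'     and \code{nEval} evaluation phantoms, half abnormal), trains, then
#'     predicts and screens the evaluation set and reports classification
#'     metrics, risk accuracy, lung-field Dice and denoising PSNR gain.}
#'   \item{train}{trains on the supplied \code{images} (list of rasters)
#'     and \code{labels}; returns the model and the selection.}
#'   \item{predict}{applies a trained \code{model} to \code{images}.}
#' }
#'
#' Two runs with the same config are byte-identical (the predictions CSV
#' included). When \code{config$outDir} is set, predictions.csv and
#' report.json are written there.
#'
#' @param mode \code{"demo"}, \code{"train"} or \code{"predict"}.
#' @param images list of rasters (train/predict modes).
#' @param labels class labels (train mode).
#' @param model a trained [PresnetModel-class] (predict mode).
#' @param config see [pipelineConfig()].
#' @return list with (depending on mode) \code{predictions},
#'   \code{report}, \code{model}, \code{selection}, \code{history}.
#' @export
runPipeline <- function(mode = c("demo", "train", "predict"), images = NULL,
                        labels = NULL, model = NULL,
                        config = pipelineConfig()) {
  mode <- match.arg(mode)
  seed <- config$seed
  if (mode == "predict") {
    if (is.null(model)) stop("predict mode needs a trained model checkpoint")
    if (is.null(images)) stop("predict mode needs images")
    fm <- .featureMatrix(images, config, 12L, seed)
    pred <- predictPresnet(model, fm$x)
    pred <- riskScreen(pred, fm$x, config$tauRisk)
    return(list(predictions = pred))
  }
  if (mode == "train") {
    if (is.null(images) || is.null(labels))
      stop("train mode needs images and labels")
    fm <- .featureMatrix(images, config, 11L, seed)
    sel <- selectFeatures(fm$x, labels, e = config$select$e,
                          rho = config$select$rho, g = config$select$g,
                          alpha = config$select$alpha,
                          fallbackK = config$select$fallbackK)
    ## feed the net every quadrant copy of each family with a selected
    ## column, family-major so the 4 quadrant values sit adjacent: with the
    ## stride-4 pooling the net can take per-family maxima over quadrants
    ## ("any quadrant abnormal"), which is the screening semantics
    fams <- unique(sub("^q[1-4]_", "", colnames(fm$x)[selectedFeatures(sel)]))
    cols <- as.vector(vapply(fams, function(f) paste0("q", 1:4, "_", f),
                             character(4)))
    xs <- fm$x[, cols, drop = FALSE]
    net <- buildPresnet(config$presnet, ncol(xs))
    tr <- trainPresnet(net, xs, labels)
    return(list(model = tr$model, history = tr$history, selection = sel))
  }

  ## demo: phantom corpus -> train -> evaluate
  trainPh <- .demoCorpus(config$nTrain, 3L, seed)
  evalPh <- .demoCorpus(config$nEval, 4L, seed)
  trLabels <- vapply(trainPh, function(p) p@truth@classLabel, character(1))
  tr <- runPipeline("train", images = lapply(trainPh, phantomImage),
                    labels = trLabels, config = config)
  evFm <- .featureMatrix(lapply(evalPh, phantomImage), config, 12L, seed)
  pred <- predictPresnet(tr$model, evFm$x)
  pred <- riskScreen(pred, evFm$x, config$tauRisk)
  truthClass <- vapply(evalPh, function(p) p@truth@classLabel, character(1))
  truthRisk <- vapply(evalPh, function(p) p@truth@riskLabel, character(1))
  pred <- data.frame(id = sprintf("phantom_%03d", seq_along(evalPh)),
                     pred, truthClass = truthClass, truthRisk = truthRisk,
                     stringsAsFactors = FALSE)
  cc <- confusionCounts(pred$classLabel, truthClass)
  metrics <- confusionMetrics(cc["TP"], cc["FP"], cc["TN"], cc["FN"])
  dice <- mean(vapply(seq_along(evalPh), function(i)
    diceScore(evFm$rows[[i]]$pre$mask, evalPh[[i]]@truth@lungMask), numeric(1)))
  ## denoising PSNR gain on a handful of evaluation phantoms vs their
  ## noise-free twins
  gains <- vapply(seq_len(min(5L, length(evalPh))), function(i) {
    sp <- evalPh[[i]]@spec
    clean <- phantomImage(generatePhantom(phantomSpec(
      height = sp@height, width = sp@width, nRibs = sp@nRibs,
      nVessels = sp@nVessels, nodules = sp@nodules, noise = "none",
      seed = sp@seed)))
    noisy <- phantomImage(evalPh[[i]])
    den <- evFm$rows[[i]]$pre$denoised
    msePsnr(clean, den)["psnr"] - msePsnr(clean, noisy)["psnr"]
  }, numeric(1))
  report <- list(
    n_train = config$nTrain, n_eval = config$nEval,
    confusion = as.list(cc), metrics = as.list(metrics),
    risk_accuracy = mean(pred$riskLabel == truthRisk),
    lung_dice = dice, psnr_gain_db = mean(gains),
    n_selected = length(selectedFeatures(tr$selection)))
  if (!is.null(config$outDir)) {
    dir.create(config$outDir, recursive = TRUE, showWarnings = FALSE)
    utils::write.csv(pred, file.path(config$outDir, "predictions.csv"),
                     row.names = FALSE)
    jsonlite::write_json(report, file.path(config$outDir, "report.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  list(predictions = pred, report = report, model = tr$model,
       selection = tr$selection, history = tr$history)
}
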