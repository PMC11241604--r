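#' @import methods
NULL

#' Specification of a synthetic chest phantom
#'
#' Describes the geometry, lesions and noise of one synthetic chest-like
#' image: two elliptical lung fields on a brighter thorax, curved bright rib
#' bands, thin bright vessel lines, and optional bright nodule blobs placed
#' on a rib, on a vessel, or free in the parenchyma.
#'
#' @slot height,width image size in pixels (each at least 64).
#' @slot nRibs number of rib bands per lung.
#' @slot nVessels number of vessel lines per lung.
#' @slot nodules list of nodule descriptors as produced by [noduleSpec()].
#' @slot noiseModel list with element \code{kind} in \code{"none"},
#'   \code{"gaussian"} (element \code{sigma}) or \code{"poisson"}
#'   (element \code{scale}).
#' @slot seed integer RNG seed; the phantom is a pure function of the spec.
#' @seealso [phantomSpec()], [generatePhantom()]
#' @export
setClass("PhantomSpec",
  representation(height = "integer", width = "integer", nRibs = "integer",
                 nVessels = "integer", nodules = "list", noiseModel = "list",
                 seed = "integer"))

setValidity("PhantomSpec", function(object) {
  msg <- character(0)
  if (object@height < 64L || object@width < 64L)
    msg <- c(msg, "height and width must be >= 64")
  if (object@nRibs < 0L || object@nVessels < 0L)
    msg <- c(msg, "nRibs and nVessels must be non-negative")
  for (nd in object@nodules) {
    if (!is.list(nd) || is.null(nd$radius) || is.null(nd$placement))
      msg <- c(msg, "each nodule needs radius and placement")
    else {
      if (nd$radius < 2) msg <- c(msg, "nodule radii must be >= 2 px")
      if (!nd$placement %in% c("on_rib", "on_vessel", "free"))
        msg <- c(msg, "placement must be on_rib, on_vessel or free")
    }
  }
  kind <- object@noiseModel$kind
  if (is.null(kind) || !kind %in% c("none", "gaussian", "poisson"))
    msg <- c(msg, "noiseModel$kind must be none, gaussian or poisson")
  else if (kind == "gaussian" && (is.null(object@noiseModel$sigma) ||
                                  object@noiseModel$sigma < 0))
    msg <- c(msg, "gaussian noise needs sigma >= 0")
  else if (kind == "poisson" && (is.null(object@noiseModel$scale) ||
                                 object@noiseModel$scale <= 0))
    msg <- c(msg, "poisson noise needs scale > 0")
  if (length(msg)) msg else TRUE
})

#' Ground truth accompanying a generated phantom
#'
#' @slot lungMask,ribMask,vesselMask logical rasters of the rendered
#'   structures (lung fields are the full ellipses, before brighter
#'   structures are painted over them).
#' @slot noduleMasks list of logical rasters, one per nodule.
#' @slot classLabel \code{"Normal"} or \code{"Abnormal"} (abnormal iff at
#'   least one nodule).
#' @slot riskLabel \code{"none"} for normal phantoms, else \code{"low"} or
#'   \code{"high"} (high iff any nodule is on a rib or at least the risk
#'   radius, default 8 px).
#' @export
setClass("PhantomTruth",
  representation(lungMask = "matrix", ribMask = "matrix",
                 vesselMask = "matrix", noduleMasks = "list",
                 classLabel = "character", riskLabel = "character"))

setValidity("PhantomTruth", function(object) {
  msg <- character(0)
  d <- dim(object@lungMask)
  if (!identical(dim(object@ribMask), d) || !identical(dim(object@vesselMask), d))
    msg <- c(msg, "all masks must share one shape")
  for (m in object@noduleMasks)
    if (!identical(dim(m), d)) msg <- c(msg, "nodule masks must match shape")
  abnormal <- length(object@noduleMasks) > 0L
  if (abnormal != (object@classLabel == "Abnormal"))
    msg <- c(msg, "classLabel must be Abnormal iff nodules present")
  if ((object@riskLabel == "none") != (object@classLabel == "Normal"))
    msg <- c(msg, "riskLabel is none iff classLabel is Normal")
  if (length(msg)) msg else TRUE
})

#' A rendered phantom: image plus ground truth
#'
#' @slot image numeric raster in [0,1].
#' @slot truth a [PhantomTruth-class] object.
#' @slot spec the generating [PhantomSpec-class].
#' @export
setClass("ChestPhantom",
  representation(image = "matrix", truth = "PhantomTruth", spec = "PhantomSpec"))

#' Four-part segmentation of a lung field
#'
#' @slot seeds 4x2 integer matrix of (row, col) seed points in quadrant
#'   order TL, TR, BL, BR.
#' @slot masks list of 4 logical rasters, one grown region per quadrant.
#' @slot thresholds numeric vector of the 4 region-growing thresholds.
#' @slot lungMask the lung-field mask the regions were grown within.
#' @export
setClass("SegmentationResult",
  representation(seeds = "matrix", masks = "list", thresholds = "numeric",
                 lungMask = "matrix"))

setValidity("SegmentationResult", function(object) {
  msg <- character(0)
  if (nrow(object@seeds) != 4L || ncol(object@seeds) != 2L)
    msg <- c(msg, "seeds must be a 4x2 matrix")
  if (length(object@masks) != 4L) msg <- c(msg, "exactly 4 masks required")
  for (q in seq_len(min(4L, length(object@masks)))) {
    m <- object@masks[[q]]
    if (any(m & !object@lungMask)) msg <- c(msg, "masks must lie within the lung mask")
    s <- object@seeds[q, ]
    if (sum(m) > 0L && !m[s[1], s[2]])
      msg <- c(msg, sprintf("seed %d must lie inside its mask", q))
  }
  if (length(msg)) msg else TRUE
})

#' Result of chi-square feature selection
#'
#' @slot scores per-feature chi-square scores.
#' @slot rank the binomially derived significance rank R used as the test's
#'   significance level.
#' @slot criticalValue chi-square critical value at 1 - R with 1 df.
#' @slot selected integer indices of the kept features, in descending
#'   score order.
#' @export
setClass("SelectionResult",
  representation(scores = "numeric", rank = "numeric",
                 criticalValue = "numeric", selected = "integer"))

setValidity("SelectionResult", function(object) {
  msg <- character(0)
  if (any(object@selected < 1L | object@selected > length(object@scores)))
    msg <- c(msg, "selected indices out of range")
  if (is.unsorted(rev(object@scores[object@selected])))
    msg <- c(msg, "selected must be in descending score order")
  if (length(msg)) msg else TRUE
})

#' A parametric-ReLU residual network model
#'
#' Small residual network: a convolution stem, \code{nBlocks} residual
#' blocks (conv, p-ReLU, conv, identity skip), max pooling with stride
#' \code{kappa}, and a fully connected head with 2 logits
#' (Normal / Abnormal).
#'
#' @slot config list of hyperparameters (see [presnetConfig()]).
#' @slot params named list of parameter arrays.
#' @slot inputDim length of the input feature vector (or c(H, W) in
#'   image mode).
#' @slot featureNames names of the features the model was trained on
#'   (used to align prediction inputs), possibly empty.
#' @export
setClass("PresnetModel",
  representation(config = "list", params = "list", inputDim = "integer",
                 featureNames = "character"))

## ---- show methods -------------------------------------------------------

setMethod("show", "PhantomSpec", function(object) {
  cat(sprintf("PhantomSpec %dx%d | %d ribs, %d vessels per lung | %d nodule(s) | noise: %s | seed %d\n",
              object@height, object@width, object@nRibs, object@nVessels,
              length(object@nodules), object@noiseModel$kind, object@seed))
})

setMethod("show", "ChestPhantom", function(object) {
  cat(sprintf("ChestPhantom %dx%d | class %s | risk %s\n",
              nrow(object@image), ncol(object@image),
              object@truth@classLabel, object@truth@riskLabel))
})

setMethod("show", "SegmentationResult", function(object) {
  cat("SegmentationResult: 4 regions (TL, TR, BL, BR)\n")
  for (q in 1:4)
    cat(sprintf("  seed (%d,%d) threshold %.4f size %d\n",
                object@seeds[q, 1], object@seeds[q, 2],
                object@thresholds[q], sum(object@masks[[q]])))
})

setMethod("show", "SelectionResult", function(object) {
  cat(sprintf("SelectionResult: %d/%d features kept (R = %.4f, critical = %.4f)\n",
              length(object@selected), length(object@scores),
              object@rank, object@criticalValue))
})

setMethod("show", "PresnetModel", function(object) {
  cat(sprintf("PresnetModel (%s mode): input %s, %d blocks, width %d, J init %.3g\n",
              object@config$mode, paste(object@inputDim, collapse = "x"),
              object@config$nBlocks, object@config$width, object@config$jInit))
})

## ---- accessors ----------------------------------------------------------

#' @describeIn ChestPhantom-class the rendered image raster.
#' @param object a \code{ChestPhantom}.
#' @export
phantomImage <- function(object) object@image

#' @describeIn ChestPhantom-class the ground truth.
#' @export
phantomTruth <- function(object) object@truth

#' Accessors for segmentation results
#'
#' @param object a [SegmentationResult-class].
#' @return \code{segSeeds}: 4x2 matrix of seed points; \code{segMasks}: list
#'   of 4 logical masks; \code{segThresholds}: numeric vector of 4.
#' @export
segSeeds <- function(object) object@seeds

#' @rdname segSeeds
#' @export
segMasks <- function(object) object@masks

#' @rdname segSeeds
#' @export
segThresholds <- function(object) object@thresholds

#' Accessors for selection results
#'
#' @param object a [SelectionResult-class].
#' @export
selectedFeatures <- function(object) object@selected

#' @rdname selectedFeatures
#' @export
featureScores <- function(object) object@scores
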