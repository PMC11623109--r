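#' @import methods
NULL

#' Model configuration for the attention-gated MultiRes U-Net
#'
#' Declarative description of the network: input geometry, the per-level
#' filter schedule of the five-level encoder, the attention-gate projection
#' width, the block variant used for parameter accounting, the upsampling
#' mode and the weight-initialisation seed.
#'
#' @slot inputHeight,inputWidth input spatial dims in pixels; each must be
#'   divisible by 16 (the encoder applies four exact 2x2 poolings).
#' @slot inputChannels number of input channels (1 for B-mode grayscale).
#' @slot filterSchedule integer vector of 5 strictly increasing filter counts,
#'   one per encoder level.
#' @slot attentionInter number of channels of the attention gates' 1x1
#'   projection.
#' @slot blockVariant `"canonical"` (three serial 3x3 convolutions plus a 1x1
#'   residual, each with batch normalisation) or `"table_audit"` (a single
#'   3x3 convolution per block, the reading under which the reference layer
#'   table's printed parameter counts are arithmetic).
#' @slot upsampleMode `"bilinear"` (parameter-free) or `"transpose"`
#'   (reserved; only bilinear is executable).
#' @slot seed integer seed for weight initialisation.
#' @export
setClass("ModelConfig",
  representation(
    inputHeight = "integer", inputWidth = "integer", inputChannels = "integer",
    filterSchedule = "integer", attentionInter = "integer",
    blockVariant = "character", upsampleMode = "character", seed = "integer"
  )
)

setValidity("ModelConfig", function(object) {
  msg <- character()
  if (object@inputHeight %% 16L != 0L)
    msg <- c(msg, sprintf("inputHeight %d is not divisible by 16", object@inputHeight))
  if (object@inputWidth %% 16L != 0L)
    msg <- c(msg, sprintf("inputWidth %d is not divisible by 16", object@inputWidth))
  fs <- object@filterSchedule
  if (length(fs) != 5L) msg <- c(msg, "filterSchedule must have 5 entries")
  if (any(diff(fs) <= 0L)) msg <- c(msg, "filterSchedule must be strictly increasing")
  if (any(fs < 3L)) msg <- c(msg, "filterSchedule entries must be >= 3")
  if (!object@blockVariant %in% c("canonical", "table_audit"))
    msg <- c(msg, "blockVariant must be 'canonical' or 'table_audit'")
  if (!object@upsampleMode %in% c("bilinear", "transpose"))
    msg <- c(msg, "upsampleMode must be 'bilinear' or 'transpose'")
  if (length(msg)) msg else TRUE
})

#' Assembled network graph
#'
#' Ordered block table plus the skip wiring produced by [assembleModel()].
#' `blocks` has one row per layer-table row (kind, channels, output dims and
#' parameter counts under both interpretations); `skips` pairs each encoder
#' stage 1-4 with the decoder block whose attention gate consumes it.
#'
#' @slot config the [ModelConfig-class] the graph was assembled from.
#' @slot blocks data.frame of block specifications.
#' @slot skips data.frame with columns `encoderStage`, `decoderBlock`.
#' @export
setClass("ModelGraph",
  representation(config = "ModelConfig", blocks = "data.frame", skips = "data.frame")
)

setValidity("ModelGraph", function(object) {
  b <- object@blocks
  need <- c("block", "name", "kind", "inChannels", "outChannels",
            "outHeight", "outWidth", "paramsAudit", "paramsCanonical")
  if (!all(need %in% names(b))) return("blocks is missing required columns")
  out <- b[b$kind == "output_conv", ]
  if (nrow(out) != 1L || out$outChannels != 1L)
    return("graph must end in a single 1-channel output convolution")
  if (out$outHeight != object@config@inputHeight ||
      out$outWidth != object@config@inputWidth)
    return("output block must restore the input spatial dims")
  if (!identical(sort(object@skips$encoderStage), 1:4))
    return("every encoder stage 1..4 must have exactly one skip consumer")
  TRUE
})

#' Simulation controls for the ultrasound phantom
#'
#' Parameters of the synthetic B-mode phantom: lesion geometry, echogenicity
#' contrast, speckle statistics, calcifications and posterior shadowing.
#'
#' @slot height,width image dims in pixels.
#' @slot lesionCountRange integer interval for the number of lesions.
#' @slot lesionRadiusRange radius interval in pixels.
#' @slot boundaryIrregularity amplitude of the sinusoidal radial perturbation,
#'   as a fraction of the radius (0 = exact ellipse).
#' @slot lesionContrast fractional intensity drop inside the lesion (hypoechoic).
#' @slot speckleShape shape of the multiplicative gamma speckle (mean 1,
#'   variance 1/shape); larger = smoother.
#' @slot calcificationCountRange integer interval for bright punctate deposits.
#' @slot shadowProbability probability of a posterior acoustic shadow per lesion.
#' @slot classLabel `"normal"`, `"benign"` or `"malignant"`.
#' @slot seed integer; all phantom output is a pure function of (params, seed).
#' @export
setClass("PhantomParams",
  representation(
    height = "integer", width = "integer",
    lesionCountRange = "integer", lesionRadiusRange = "numeric",
    boundaryIrregularity = "numeric", lesionContrast = "numeric",
    speckleShape = "numeric", calcificationCountRange = "integer",
    shadowProbability = "numeric", classLabel = "character", seed = "integer"
  )
)

setValidity("PhantomParams", function(object) {
  msg <- character()
  if (object@height < 16L || object@width < 16L) msg <- c(msg, "frame too small")
  if (!object@classLabel %in% c("normal", "benign", "malignant"))
    msg <- c(msg, "classLabel must be normal/benign/malignant")
  if (object@classLabel == "normal" && any(object@lesionCountRange != 0L))
    msg <- c(msg, "normal class forces lesion count 0")
  if (object@boundaryIrregularity < 0) msg <- c(msg, "boundaryIrregularity must be >= 0")
  if (object@lesionContrast < 0 || object@lesionContrast > 1)
    msg <- c(msg, "lesionContrast must be in [0,1]")
  if (object@speckleShape <= 0) msg <- c(msg, "speckleShape must be > 0")
  if (object@shadowProbability < 0 || object@shadowProbability > 1)
    msg <- c(msg, "shadowProbability must be in [0,1]")
  if (any(diff(object@lesionCountRange) < 0) || any(object@lesionCountRange < 0L))
    msg <- c(msg, "lesionCountRange must be a non-negative interval")
  if (length(msg)) msg else TRUE
})

#' A phantom or loaded ultrasound sample
#'
#' @slot image grayscale matrix in `[0,1]` (rows = height).
#' @slot mask binary matrix of the same dims ({0,1}).
#' @slot label class label.
#' @slot seed the seed the sample was generated from (NA for loaded data).
#' @export
setClass("UltrasoundSample",
  representation(image = "matrix", mask = "matrix", label = "character",
                 seed = "integer")
)

setValidity("UltrasoundSample", function(object) {
  if (!identical(dim(object@image), dim(object@mask)))
    return("image and mask dims differ")
  if (!all(object@mask %in% c(0, 1))) return("mask must be exactly binary")
  if (object@label == "normal" && any(object@mask == 1))
    return("normal samples must have an empty mask")
  TRUE
})

#' Geometric augmentation specification
#'
#' One random transform (rotation, flips, isotropic scaling, crop-and-resize)
#' applied identically to an image (bilinear) and its mask (nearest
#' neighbour).
#'
#' @slot rotationDegrees interval the rotation angle is drawn from.
#' @slot flipHorizontal,flipVertical flip probabilities.
#' @slot scaleFactor interval the isotropic scale is drawn from.
#' @slot cropFraction side length of the crop window as a fraction of the
#'   image side, in (0, 1]; the window is resized back to the full frame.
#' @slot seed integer seed making the drawn transform deterministic.
#' @export
setClass("AugmentSpec",
  representation(rotationDegrees = "numeric", flipHorizontal = "numeric",
                 flipVertical = "numeric", scaleFactor = "numeric",
                 cropFraction = "numeric", seed = "integer")
)

setValidity("AugmentSpec", function(object) {
  msg <- character()
  p <- c(object@flipHorizontal, object@flipVertical)
  if (any(p < 0 | p > 1)) msg <- c(msg, "flip probabilities must be in [0,1]")
  if (any(object@scaleFactor <= 0)) msg <- c(msg, "scale bounds must be positive")
  if (object@cropFraction <= 0 || object@cropFraction > 1)
    msg <- c(msg, "cropFraction must be in (0,1]")
  if (length(msg)) msg else TRUE
})

#' Training hyperparameters
#'
#' @slot learningRate initial Adam learning rate.
#' @slot batchSize minibatch size.
#' @slot epochs number of training epochs.
#' @slot plateauPatience epochs without validation-loss improvement before the
#'   learning rate is reduced.
#' @slot plateauFactor multiplicative reduction factor in (0,1).
#' @slot minLr learning-rate floor.
#' @slot seed seed controlling shuffling, augmentation and initialisation.
#' @export
setClass("Hyperparams",
  representation(learningRate = "numeric", batchSize = "integer",
                 epochs = "integer", plateauPatience = "integer",
                 plateauFactor = "numeric", minLr = "numeric", seed = "integer")
)

setValidity("Hyperparams", function(object) {
  msg <- character()
  if (object@learningRate <= 0) msg <- c(msg, "learningRate must be positive")
  if (object@batchSize < 1L) msg <- c(msg, "batchSize must be positive")
  if (object@epochs < 1L) msg <- c(msg, "epochs must be positive")
  if (object@plateauFactor <= 0 || object@plateauFactor >= 1)
    msg <- c(msg, "plateauFactor must be in (0,1)")
  if (object@minLr <= 0) msg <- c(msg, "minLr must be positive")
  if (length(msg)) msg else TRUE
})

#' Per-epoch training trace
#'
#' @slot epochs data.frame with one row per completed epoch: `epoch`,
#'   `trainLoss`, `valLoss`, `valDice`, `lr`.
#' @export
setClass("TrainHistory", representation(epochs = "data.frame"))

setValidity("TrainHistory", function(object) {
  e <- object@epochs
  need <- c("epoch", "trainLoss", "valLoss", "valDice", "lr")
  if (!all(need %in% names(e))) return("missing history columns")
  if (nrow(e) > 1 && any(diff(e$lr) > 1e-12)) return("lr must be non-increasing")
  TRUE
})

#' Pixelwise confusion counts
#'
#' @slot tp,tn,fp,fn non-negative pixel tallies.
#' @export
setClass("ConfusionCounts",
  representation(tp = "numeric", tn = "numeric", fp = "numeric", fn = "numeric")
)

setValidity("ConfusionCounts", function(object) {
  v <- c(object@tp, object@tn, object@fp, object@fn)
  if (any(v < 0)) return("counts must be non-negative")
  TRUE
})

#' Segmentation metric report with fold aggregation
#'
#' @slot perFold data.frame with one row per fold and columns `fold`, `acc`,
#'   `sen`, `spe`, `pre`, `f1`, `dice`, `auc`.
#' @slot mean,sd named numeric vectors: unweighted fold mean and sample
#'   standard deviation per metric.
#' @slot nFolds number of folds aggregated.
#' @export
setClass("MetricReport",
  representation(perFold = "data.frame", mean = "numeric", sd = "numeric",
                 nFolds = "integer")
)

setValidity("MetricReport", function(object) {
  m <- as.matrix(object@perFold[, metricNames(), drop = FALSE])
  if (any(!is.na(m) & (m < -1e-9 | m > 1 + 1e-9)))
    return("all metrics must lie in [0,1]")
  if (any(object@sd < -1e-12, na.rm = TRUE)) return("sd must be >= 0")
  TRUE
})

#' Index of a BUSI-style PNG dataset tree
#'
#' @slot root source directory.
#' @slot records data.frame with columns `image` (path), `label`, `nMasks`.
#' @slot maskPaths list of character vectors, one per record (may be empty:
#'   an explicit empty-mask marker).
#' @export
setClass("DatasetIndex",
  representation(root = "character", records = "data.frame", maskPaths = "list")
)

setValidity("DatasetIndex", function(object) {
  if (nrow(object@records) != length(object@maskPaths))
    return("records and maskPaths disagree")
  if (nrow(object@records) &&
      !all(object@records$label %in% c("normal", "benign", "malignant")))
    return("labels must be normal/benign/malignant")
  TRUE
})

#' K-fold assignment plan
#'
#' @slot k number of folds.
#' @slot assignment integer vector mapping sample index to fold id 1..k.
#' @export
setClass("FoldPlan", representation(k = "integer", assignment = "integer"))

setValidity("FoldPlan", function(object) {
  sz <- tabulate(object@assignment, nbins = object@k)
  if (sum(sz) != length(object@assignment)) return("folds must partition the index set")
  if (max(sz) - min(sz) > 1L) return("fold sizes must differ by at most 1")
  TRUE
})
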