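#' @useDynLib hrdq, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @import methods
NULL

#' OCTVolume: a 3-D OCT intensity grid with physical geometry
#'
#' Voxels are stored as a numeric array in index order (b, z, x) =
#' (b-scan index, axial depth, lateral position), with intensities in
#' [0, 1]. \code{spacingUm} holds the physical voxel spacing in micrometres
#' in the same order: (inter-slice, axial, lateral). Axial depth z increases
#' from the inner retina downward. Indexing is 1-based in R; physical
#' coordinates refer to voxel centers.
#'
#' @slot voxels numeric 3-D array, dim (n_bscans, n_axial, n_lateral),
#'   finite and non-negative.
#' @slot spacingUm numeric(3), strictly positive, micrometres.
#' @slot originMm numeric(3), physical coordinate of voxel (1,1,1), mm.
#' @export
setClass("OCTVolume",
  representation(voxels = "array", spacingUm = "numeric", originMm = "numeric"),
  prototype(originMm = c(0, 0, 0))
)

setValidity("OCTVolume", function(object) {
  msg <- character()
  if (length(dim(object@voxels)) != 3L)
    msg <- c(msg, "voxels must be a 3-D array (b, z, x)")
  if (any(dim(object@voxels) < 1L))
    msg <- c(msg, "all grid dimensions must be >= 1")
  if (length(object@spacingUm) != 3L || any(!is.finite(object@spacingUm)) ||
      any(object@spacingUm <= 0))
    msg <- c(msg, "spacingUm must be three strictly positive finite values")
  if (any(!is.finite(object@voxels)))
    msg <- c(msg, "voxel intensities must be finite")
  else if (any(object@voxels < 0))
    msg <- c(msg, "voxel intensities must be non-negative")
  if (length(object@originMm) != 3L)
    msg <- c(msg, "originMm must have length 3")
  if (length(msg)) msg else TRUE
})

#' Construct an OCTVolume
#'
#' @param voxels numeric 3-D array in (b, z, x) order.
#' @param spacingUm numeric(3) spacing (inter-slice, axial, lateral) in um.
#' @param originMm numeric(3) physical origin in mm.
#' @return An \linkS4class{OCTVolume}.
#' @examples
#' v <- OCTVolume(array(0, c(2, 8, 8)), spacingUm = c(46.875, 2.2599, 11.71875))
#' spacingUm(v)
#' @export
OCTVolume <- function(voxels, spacingUm, originMm = c(0, 0, 0)) {
  new("OCTVolume", voxels = voxels, spacingUm = as.numeric(spacingUm),
      originMm = as.numeric(originMm))
}

#' LabelMask: per-voxel HRD class labels aligned to an OCTVolume
#'
#' Integer labels over {0 = background, 1 = hard exudate, 2 = small HRD},
#' same (b, z, x) grid and spacing as the paired volume.
#'
#' @slot labels integer 3-D array.
#' @slot spacingUm numeric(3), micrometres.
#' @export
setClass("LabelMask",
  representation(labels = "array", spacingUm = "numeric")
)

setValidity("LabelMask", function(object) {
  msg <- character()
  if (length(dim(object@labels)) != 3L)
    msg <- c(msg, "labels must be a 3-D array (b, z, x)")
  if (!all(object@labels %in% c(0L, 1L, 2L)))
    msg <- c(msg, "labels must be from {0, 1, 2}")
  if (length(object@spacingUm) != 3L || any(object@spacingUm <= 0))
    msg <- c(msg, "spacingUm must be three strictly positive values")
  if (length(msg)) msg else TRUE
})

#' Construct a LabelMask
#'
#' @param labels integer 3-D array in (b, z, x) order with values in {0,1,2}.
#' @param spacingUm numeric(3) spacing in um.
#' @return A \linkS4class{LabelMask}.
#' @export
LabelMask <- function(labels, spacingUm) {
  storage.mode(labels) <- "integer"
  new("LabelMask", labels = labels, spacingUm = as.numeric(spacingUm))
}

#' @describeIn OCTVolume-accessors voxel array of a volume
#' @export
setGeneric("voxels", function(x) standardGeneric("voxels"))
#' @describeIn OCTVolume-accessors label array of a mask
#' @export
setGeneric("labels3d", function(x) standardGeneric("labels3d"))
#' @describeIn OCTVolume-accessors physical spacing in micrometres
#' @export
setGeneric("spacingUm", function(x) standardGeneric("spacingUm"))

#' Accessors for OCT grid objects
#'
#' @param x an \linkS4class{OCTVolume} or \linkS4class{LabelMask}.
#' @name OCTVolume-accessors
#' @aliases voxels labels3d spacingUm
NULL

#' @export
setMethod("voxels", "OCTVolume", function(x) x@voxels)
#' @export
setMethod("labels3d", "LabelMask", function(x) x@labels)
#' @export
setMethod("spacingUm", "OCTVolume", function(x) x@spacingUm)
#' @export
setMethod("spacingUm", "LabelMask", function(x) x@spacingUm)
#' @export
setMethod("dim", "OCTVolume", function(x) dim(x@voxels))
#' @export
setMethod("dim", "LabelMask", function(x) dim(x@labels))

setMethod("show", "OCTVolume", function(object) {
  d <- dim(object)
  s <- object@spacingUm
  cat(sprintf("OCTVolume: %d b-scans x %d axial x %d lateral\n", d[1], d[2], d[3]))
  cat(sprintf("  spacing (um): inter-slice %.4g, axial %.4g, lateral %.4g\n",
              s[1], s[2], s[3]))
  cat(sprintf("  extent (mm): %.3g x %.3g x %.3g\n",
              d[1] * s[1] / 1000, d[2] * s[2] / 1000, d[3] * s[3] / 1000))
  cat(sprintf("  intensity range: [%.3g, %.3g]\n",
              min(object@voxels), max(object@voxels)))
})

setMethod("show", "LabelMask", function(object) {
  d <- dim(object)
  tab <- tabulate(object@labels + 1L, nbins = 3L)
  cat(sprintf("LabelMask: %d b-scans x %d axial x %d lateral\n", d[1], d[2], d[3]))
  cat(sprintf("  voxels: %d hard exudate, %d small HRD, %d background\n",
              tab[2], tab[3], tab[1]))
})

#' Parameters of the deterministic back-shadow test
#'
#' A candidate component casts a back shadow when the mean intensity of the
#' column band directly beneath it (from the component bottom down to the
#' estimated RPE depth) falls below \code{tau} times the mean intensity of
#' two flanking bands at the same depths.
#'
#' @slot tau attenuation ratio threshold in (0,1); default 0.75.
#' @slot flankFactor lateral offset of the flank bands, as a multiple of the
#'   component width; default 2.
#' @slot minWindowPx minimum usable depth-window height in pixels; shorter
#'   windows yield shadow = FALSE with a "window_too_short" flag. Default 10.
#' @export
setClass("ShadowParams",
  representation(tau = "numeric", flankFactor = "numeric", minWindowPx = "numeric"),
  prototype(tau = 0.75, flankFactor = 2, minWindowPx = 10)
)

setValidity("ShadowParams", function(object) {
  msg <- character()
  if (object@tau <= 0 || object@tau >= 1) msg <- c(msg, "tau must be in (0,1)")
  if (object@flankFactor <= 0) msg <- c(msg, "flankFactor must be positive")
  if (object@minWindowPx <= 0) msg <- c(msg, "minWindowPx must be positive")
  if (length(msg)) msg else TRUE
})

#' @rdname ShadowParams-class
#' @param tau,flankFactor,minWindowPx see slot documentation.
#' @return A \linkS4class{ShadowParams} object.
#' @export
ShadowParams <- function(tau = 0.75, flankFactor = 2, minWindowPx = 10) {
  new("ShadowParams", tau = tau, flankFactor = flankFactor,
      minWindowPx = minWindowPx)
}

#' Specification of a layered-retina OCT phantom
#'
#' Defines the grid, geometry, layer model, speckle level, and lesion plan of
#' a synthetic b-scan stack. Bright lesions are rendered as ellipses in the
#' (z, x) plane of single b-scans: hard exudates at RPE-like reflectivity
#' with an attenuated column ("back shadow") rendered beneath them, small
#' HRDs at NFL-like reflectivity without shadow, and sub-threshold noise
#' dots that appear in the image but not in the ground-truth mask.
#'
#' @slot shape integer(3): (n_bscans, n_axial, n_lateral).
#' @slot spacingUm numeric(3): (inter-slice, axial, lateral) in um.
#' @slot layers named numeric vector of layer reflectivities and depth
#'   fractions (see prototype for the fields).
#' @slot speckleVar variance of the multiplicative gamma speckle (mean 1).
#' @slot nHardExudate,nSmallHrd,nNoise lesion counts per volume.
#' @slot hardDiamUm,smallDiamUm,noiseDiamUm target physical diameter ranges
#'   in um; defaults 45-150, 20-40, 8-18.
#' @slot shadowFactor multiplicative attenuation of the rendered back
#'   shadow; default 0.4.
#' @slot seed integer random seed.
#' @export
setClass("PhantomSpec",
  representation(shape = "integer", spacingUm = "numeric", layers = "numeric",
                 speckleVar = "numeric", nHardExudate = "integer",
                 nSmallHrd = "integer", nNoise = "integer",
                 hardDiamUm = "numeric", smallDiamUm = "numeric",
                 noiseDiamUm = "numeric", shadowFactor = "numeric",
                 seed = "integer"),
  prototype(shape = c(4L, 256L, 256L),
            spacingUm = c(46.875, 2.2599, 11.71875),
            layers = c(vitreous = 0.03, nfl = 0.55, mid = 0.10, rpe = 0.85,
                       below = 0.05,
                       nfl_top = 0.15, nfl_bot = 0.20, rpe_top = 0.76,
                       rpe_bot = 0.80),
            speckleVar = 0.05, nHardExudate = 3L, nSmallHrd = 5L, nNoise = 2L,
            hardDiamUm = c(45, 150), smallDiamUm = c(20, 40),
            noiseDiamUm = c(8, 18), shadowFactor = 0.4, seed = 1L)
)

setValidity("PhantomSpec", function(object) {
  msg <- character()
  if (length(object@shape) != 3L || any(object@shape < 1L))
    msg <- c(msg, "shape must be three positive integers (b, z, x)")
  if (any(object@spacingUm <= 0)) msg <- c(msg, "spacingUm must be positive")
  if (object@speckleVar < 0) msg <- c(msg, "speckleVar must be >= 0")
  if (object@shadowFactor <= 0 || object@shadowFactor >= 1)
    msg <- c(msg, "shadowFactor must be in (0,1)")
  if (any(c(object@nHardExudate, object@nSmallHrd, object@nNoise) < 0L))
    msg <- c(msg, "lesion counts must be >= 0")
  # ranges must be consistent with the 20/40 um classification thresholds so
  # that every rendered lesion has an unambiguous ground-truth class
  if (object@hardDiamUm[1] <= 40)
    msg <- c(msg, "hard-exudate diameters must exceed 40 um")
  if (object@smallDiamUm[1] < 20 || object@smallDiamUm[2] > 40)
    msg <- c(msg, "small-HRD diameters must lie in [20, 40] um")
  if (object@noiseDiamUm[2] >= 20)
    msg <- c(msg, "noise-dot diameters must stay below 20 um")
  if (length(msg)) msg else TRUE
})

#' @rdname PhantomSpec-class
#' @param shape,spacingUm,layers,speckleVar,nHardExudate,nSmallHrd,nNoise
#'   see slot documentation.
#' @param hardDiamUm,smallDiamUm,noiseDiamUm,shadowFactor,seed see slots.
#' @return A \linkS4class{PhantomSpec}.
#' @export
PhantomSpec <- function(shape = c(4L, 256L, 256L),
                        spacingUm = c(46.875, 2.2599, 11.71875),
                        layers = NULL, speckleVar = 0.05,
                        nHardExudate = 3L, nSmallHrd = 5L, nNoise = 2L,
                        hardDiamUm = c(45, 150), smallDiamUm = c(20, 40),
                        noiseDiamUm = c(8, 18), shadowFactor = 0.4,
                        seed = 1L) {
  proto <- new("PhantomSpec")
  if (is.null(layers)) layers <- proto@layers
  new("PhantomSpec", shape = as.integer(shape), spacingUm = as.numeric(spacingUm),
      layers = layers, speckleVar = speckleVar,
      nHardExudate = as.integer(nHardExudate), nSmallHrd = as.integer(nSmallHrd),
      nNoise = as.integer(nNoise), hardDiamUm = hardDiamUm,
      smallDiamUm = smallDiamUm, noiseDiamUm = noiseDiamUm,
      shadowFactor = shadowFactor, seed = as.integer(seed))
}

#' Second-rater perturbation model
#'
#' Emulates inter-rater disagreement: each ground-truth component is
#' independently dropped, class-flipped, or morphologically jittered
#' (dilated or eroded by up to \code{jitterPx} pixels).
#'
#' @slot jitterPx maximum boundary dilation/erosion radius in pixels.
#' @slot dropProb probability a component is omitted entirely.
#' @slot flipProb probability a component's class is swapped (1 <-> 2).
#' @slot seed integer random seed.
#' @export
setClass("RaterNoiseSpec",
  representation(jitterPx = "numeric", dropProb = "numeric",
                 flipProb = "numeric", seed = "integer"),
  prototype(jitterPx = 1, dropProb = 0.05, flipProb = 0.05, seed = 1L)
)

setValidity("RaterNoiseSpec", function(object) {
  msg <- character()
  if (object@jitterPx < 0) msg <- c(msg, "jitterPx must be >= 0")
  if (object@dropProb < 0 || object@dropProb > 1)
    msg <- c(msg, "dropProb must be in [0,1]")
  if (object@flipProb < 0 || object@flipProb > 1)
    msg <- c(msg, "flipProb must be in [0,1]")
  if (length(msg)) msg else TRUE
})

#' @rdname RaterNoiseSpec-class
#' @param jitterPx,dropProb,flipProb,seed see slot documentation.
#' @return A \linkS4class{RaterNoiseSpec}.
#' @export
RaterNoiseSpec <- function(jitterPx = 1, dropProb = 0.05, flipProb = 0.05,
                           seed = 1L) {
  new("RaterNoiseSpec", jitterPx = jitterPx, dropProb = dropProb,
      flipProb = flipProb, seed = as.integer(seed))
}

#' Architecture of the improved U-shaped segmentation network
#'
#' Three down/upsampling steps; every encoder stage is a multi-scale
#' convolution module (MSCM: parallel 3x3 convolutions at dilation rates
#' 1, 2 and 3, concatenated and fused by a 1x1 convolution); the two deepest
#' encoder stages additionally carry a channel attention module (CAM:
#' global average pooling followed by a fully connected bottleneck whose
#' sigmoid output gates the channels).
#'
#' @slot levels number of down/upsampling steps (fixed at 3).
#' @slot dilations dilation rates of the parallel MSCM branches.
#' @slot baseChannels channel width of the first encoder stage; 16 by
#'   default, 8 for the CPU-friendly tiny preset.
#' @slot inChannels,outChannels input channels (1) and output classes (2:
#'   background / HRD foreground).
#' @slot camReduction bottleneck reduction ratio of the CAM; default 4.
#' @export
setClass("NetConfig",
  representation(levels = "integer", dilations = "integer",
                 baseChannels = "integer", inChannels = "integer",
                 outChannels = "integer", camReduction = "integer"),
  prototype(levels = 3L, dilations = c(1L, 2L, 3L), baseChannels = 16L,
            inChannels = 1L, outChannels = 2L, camReduction = 4L)
)

setValidity("NetConfig", function(object) {
  msg <- character()
  if (object@levels != 3L) msg <- c(msg, "levels is fixed at 3")
  if (!identical(object@dilations, c(1L, 2L, 3L)))
    msg <- c(msg, "dilations must be exactly (1, 2, 3)")
  if (object@baseChannels < 4L) msg <- c(msg, "baseChannels must be >= 4")
  if (length(msg)) msg else TRUE
})

#' @rdname NetConfig-class
#' @param baseChannels,camReduction see slot documentation.
#' @return A \linkS4class{NetConfig}.
#' @export
NetConfig <- function(baseChannels = 16L, camReduction = 4L) {
  new("NetConfig", baseChannels = as.integer(baseChannels),
      camReduction = as.integer(camReduction))
}

#' Training protocol for the segmentation network
#'
#' Defaults follow the published protocol: SGD with initial learning rate
#' 0.01, momentum 0.9, weight decay 0.0001, batch size 2, 60 epochs, and
#' online augmentation drawing 2-4 distinct operations per sample from
#' {left-right flip, up-down flip, random rotation, additive Gaussian
#' noise}.
#'
#' @slot learningRate,momentum,weightDecay SGD hyperparameters.
#' @slot batchSize,epochs loop sizes.
#' @slot augment logical: apply online augmentation.
#' @slot seed integer random seed.
#' @export
setClass("TrainConfig",
  representation(learningRate = "numeric", momentum = "numeric",
                 weightDecay = "numeric", batchSize = "integer",
                 epochs = "integer", augment = "logical", seed = "integer"),
  prototype(learningRate = 0.01, momentum = 0.9, weightDecay = 1e-4,
            batchSize = 2L, epochs = 60L, augment = TRUE, seed = 1L)
)

setValidity("TrainConfig", function(object) {
  msg <- character()
  if (object@learningRate <= 0) msg <- c(msg, "learningRate must be positive")
  if (object@momentum < 0 || object@momentum >= 1)
    msg <- c(msg, "momentum must be in [0,1)")
  if (object@epochs < 0L) msg <- c(msg, "epochs must be >= 0")
  if (object@batchSize < 1L) msg <- c(msg, "batchSize must be >= 1")
  if (length(msg)) msg else TRUE
})

#' @rdname TrainConfig-class
#' @param learningRate,momentum,weightDecay,batchSize,epochs,augment,seed
#'   see slot documentation.
#' @return A \linkS4class{TrainConfig}.
#' @export
TrainConfig <- function(learningRate = 0.01, momentum = 0.9,
                        weightDecay = 1e-4, batchSize = 2L, epochs = 60L,
                        augment = TRUE, seed = 1L) {
  new("TrainConfig", learningRate = learningRate, momentum = momentum,
      weightDecay = weightDecay, batchSize = as.integer(batchSize),
      epochs = as.integer(epochs), augment = augment, seed = as.integer(seed))
}
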