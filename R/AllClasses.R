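#' @import methods
NULL

#' Lesion shape specification
#'
#' Describes one synthetic lesion as a star-shaped radial contour
#' \eqn{r(\theta)} around a centre point. The base shape is a circle of
#' radius \code{baseRadius} (as a fraction of the image side) perturbed by
#' low-order radial harmonics; malignant lesions additionally carry narrow
#' radial spikes (spicules) that produce the spiculated, angulated margins
#' typical of malignancy, while benign lesions are smooth perturbed
#' ellipses.
#'
#' @slot kind \code{"benign"} or \code{"malignant"}.
#' @slot center numeric length 2, fractional (x, y) image coordinates.
#' @slot baseRadius base contour radius, fraction of the image side;
#'   must lie in (0.05, 0.35).
#' @slot harmonics numeric matrix with columns \code{order},
#'   \code{amplitude}, \code{phase}; amplitudes are in the same radius
#'   units as \code{baseRadius}. Benign amplitudes are capped at
#'   \code{0.08 * baseRadius}.
#' @slot nSpicules integer, number of spicules (malignant only, >= 4).
#' @slot spiculeLength spicule height as a fraction of \code{baseRadius}.
#' @slot seed integer seed controlling spicule placement.
#' @export
setClass("LesionSpec",
  representation(kind = "character", center = "numeric",
                 baseRadius = "numeric", harmonics = "matrix",
                 nSpicules = "integer", spiculeLength = "numeric",
                 seed = "integer"))

setValidity("LesionSpec", function(object) {
  k <- object@kind
  if (!k %in% c("benign", "malignant"))
    return("kind must be 'benign' or 'malignant'")
  r0 <- object@baseRadius
  if (!(r0 > 0.05 && r0 < 0.35))
    return(sprintf("baseRadius %.3f outside (0.05, 0.35)", r0))
  if (length(object@center) != 2L || any(!is.finite(object@center)))
    return("center must be two finite fractional coordinates")
  h <- object@harmonics
  if (ncol(h) != 3L) return("harmonics must have columns order, amplitude, phase")
  amps <- if (nrow(h)) h[, 2L] else numeric()
  if (any(amps < 0)) return("harmonic amplitudes must be non-negative")
  if (k == "benign") {
    if (object@nSpicules != 0L)
      return("benign lesions must have nSpicules = 0")
    if (any(amps > 0.08 * r0 + 1e-12))
      return(sprintf("benign harmonic amplitude exceeds 0.08*baseRadius = %.4f",
                     0.08 * r0))
  } else {
    if (object@nSpicules < 4L)
      return("malignant lesions require at least 4 spicules")
    if (object@spiculeLength <= 0)
      return("malignant spiculeLength must be positive")
  }
  rmax <- r0 + sum(amps) +
    (if (k == "malignant") object@spiculeLength * r0 else 0)
  if (sum(amps) >= r0)
    return("total harmonic amplitude must be below baseRadius (contour r > 0)")
  margin <- min(object@center, 1 - object@center)
  if (rmax >= margin)
    return(sprintf("lesion of maximal radius %.3f does not fit inside image (margin %.3f)",
                   rmax, margin))
  TRUE
})

#' Speckle rendering parameters
#'
#' Parameters of the ultrasound-like rendering: the lesion-to-background
#' intensity ratio (\code{contrast < 1} makes the lesion hypoechoic, i.e.
#' darker than its surroundings), the dispersion of the multiplicative
#' gamma speckle (mean 1, shape \code{1/speckleScale^2}), and a Gaussian
#' point-spread blur.
#'
#' @slot contrast lesion/background mean intensity ratio in (0, 1).
#' @slot speckleScale multiplicative speckle dispersion, >= 0
#'   (0 is the noise-free limit).
#' @slot blurSigma Gaussian blur standard deviation in pixels, >= 0.
#' @slot seed integer seed for the noise fields.
#' @export
setClass("SpeckleParams",
  representation(contrast = "numeric", speckleScale = "numeric",
                 blurSigma = "numeric", seed = "integer"))

setValidity("SpeckleParams", function(object) {
  if (!(object@contrast > 0 && object@contrast < 1))
    return("contrast must lie in (0, 1): the lesion is hypoechoic")
  if (object@speckleScale < 0) return("speckleScale must be >= 0")
  if (object@blurSigma < 0) return("blurSigma must be >= 0")
  TRUE
})

#' Pixel confusion counts
#'
#' True/false positive/negative pixel tallies for one prediction/gold mask
#' pair (or pooled over several), with label 1 = lesion as the positive
#' class.
#'
#' @slot TP,FP,FN,TN non-negative pixel counts.
#' @export
setClass("ConfusionCounts",
  representation(TP = "numeric", FP = "numeric", FN = "numeric", TN = "numeric"))

setValidity("ConfusionCounts", function(object) {
  v <- c(object@TP, object@FP, object@FN, object@TN)
  if (any(v < 0) || any(!is.finite(v))) return("counts must be finite and >= 0")
  if (any(v != round(v))) return("counts must be whole numbers")
  TRUE
})

#' Per-image segmentation metric report
#'
#' The full metric suite for one prediction/gold pair: global and mean
#' per-class accuracy, per-class and mean IoU, class-proportion-weighted
#' IoU, Dice coefficient and boundary-F1 score. Metrics whose denominator
#' is empty (e.g. mean accuracy when the gold mask has no lesion) are
#' flagged as \code{NA} rather than forced to 0 or 1.
#'
#' @slot globalAccuracy,meanAccuracy,iouLesion,iouBackground,meanIoU,weightedIoU,dice,bfScore numeric in [0, 1] or NA.
#' @slot lesionWeight,backgroundWeight gold-mask class proportions, summing to 1.
#' @export
setClass("SegMetrics",
  representation(globalAccuracy = "numeric", meanAccuracy = "numeric",
                 iouLesion = "numeric", iouBackground = "numeric",
                 meanIoU = "numeric", weightedIoU = "numeric",
                 dice = "numeric", bfScore = "numeric",
                 lesionWeight = "numeric", backgroundWeight = "numeric"))

setValidity("SegMetrics", function(object) {
  vals <- c(object@globalAccuracy, object@meanAccuracy, object@iouLesion,
            object@iouBackground, object@meanIoU, object@weightedIoU,
            object@dice, object@bfScore)
  ok <- is.na(vals) | (vals >= -1e-12 & vals <= 1 + 1e-12)
  if (!all(ok)) return("all metrics must lie in [0, 1] or be NA")
  w <- object@lesionWeight + object@backgroundWeight
  if (!is.na(w) && abs(w - 1) > 1e-9) return("class weights must sum to 1")
  TRUE
})

#' CNN layer graph
#'
#' A directed acyclic graph of typed processing layers (conv, batchnorm,
#' relu, maxpool, deconv, dropout, concat, softmax, pixel-classification)
#' plus one data-input source. \code{CNN1} is a series graph (single
#' input-to-sink path); \code{CNN2} and \code{CNN3} are DAG variants whose
#' skip branches aggregate early-layer spatial detail into the decoder.
#'
#' @slot variant \code{"CNN1"}, \code{"CNN2"} or \code{"CNN3"}.
#' @slot inputSide input image side in pixels (divisible by 8).
#' @slot width number of feature maps of the main-path convolutions.
#' @slot layers named list of layer descriptors.
#' @slot edges data.frame with character columns \code{from}, \code{to}.
#' @export
setClass("LayerGraph",
  representation(variant = "character", inputSide = "integer",
                 width = "integer", layers = "list", edges = "data.frame"))

setValidity("LayerGraph", function(object) {
  if (length(object@layers) == 0L) return(TRUE)  # degenerate empty graph
  kinds <- vapply(object@layers, `[[`, "", "kind")
  if (sum(kinds == "input") != 1L) return("graph must have exactly one input layer")
  if (sum(kinds == "pixelclass") != 1L)
    return("graph must have exactly one pixel-classification sink")
  ord <- tryCatch(topoSort(object), error = function(e) NULL)
  if (is.null(ord)) return("graph has a cycle")
  TRUE
})

#' Training configuration
#'
#' Hyperparameters of stochastic gradient descent with momentum:
#' \eqn{\theta_{l+1} = \theta_l - \alpha \nabla E(\theta_l) +
#' \gamma(\theta_l - \theta_{l-1})}. Defaults: learning rate
#' \eqn{\alpha = 0.001}, momentum \eqn{\gamma = 0.9}, mini-batch size 5,
#' 150 epochs, dropout ratio 0.5.
#'
#' @slot learningRate positive step size \eqn{\alpha}.
#' @slot momentum \eqn{\gamma} in [0, 1).
#' @slot batchSize mini-batch size, >= 1.
#' @slot maxEpochs number of epochs (the stop condition), >= 1.
#' @slot dropout dropout ratio of the dropout layer in [0, 1).
#' @slot seed integer seed for shuffling and dropout masks.
#' @export
setClass("TrainConfig",
  representation(learningRate = "numeric", momentum = "numeric",
                 batchSize = "integer", maxEpochs = "integer",
                 dropout = "numeric", seed = "integer"))

setValidity("TrainConfig", function(object) {
  if (object@learningRate <= 0) return("learningRate must be > 0")
  if (object@momentum < 0 || object@momentum >= 1)
    return("momentum must lie in [0, 1)")
  if (object@batchSize < 1L) return("batchSize must be >= 1")
  if (object@maxEpochs < 1L) return("maxEpochs must be >= 1")
  if (object@dropout < 0 || object@dropout >= 1)
    return("dropout must lie in [0, 1)")
  TRUE
})

#' Two-sample t-test result
#'
#' Pooled-variance (Student) two-sample comparison with a two-tailed
#' decision against the critical value \eqn{t_c}: the null hypothesis is
#' rejected when \eqn{t \ge t_c} or \eqn{t \le -t_c}.
#'
#' @slot statistic the t value.
#' @slot df degrees of freedom, \eqn{n_1 + n_2 - 2}.
#' @slot confidence confidence level in (0, 1).
#' @slot tCritical two-tailed critical value at \code{confidence}.
#' @slot significant logical.
#' @slot direction \code{"higher"}, \code{"lower"} or \code{"none"}:
#'   whether the first sample is significantly higher/lower.
#' @export
setClass("TTestResult",
  representation(statistic = "numeric", df = "integer",
                 confidence = "numeric", tCritical = "numeric",
                 significant = "logical", direction = "character"))

setValidity("TTestResult", function(object) {
  if (object@df < 1L) return("df must be >= 1")
  if (!object@direction %in% c("higher", "lower", "none"))
    return("direction must be 'higher', 'lower' or 'none'")
  TRUE
})
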