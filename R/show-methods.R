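#' @describeIn lesionSpec display method
#' @param object a `LesionSpec`.
#' @export
setMethod("show", "LesionSpec", function(object) {
  cat(sprintf("LesionSpec: %s lesion, centre (%.2f, %.2f), base radius %.3f\n",
              object@kind, object@center[1L], object@center[2L],
              object@baseRadius))
  cat(sprintf("  %d harmonic term(s)", nrow(object@harmonics)))
  if (object@nSpicules > 0L)
    cat(sprintf(", %d spicules of relative length %.2f",
                object@nSpicules, object@spiculeLength))
  cat(sprintf(", seed %d\n", object@seed))
})

#' @describeIn speckleParams display method
#' @param object a `SpeckleParams`.
#' @export
setMethod("show", "SpeckleParams", function(object) {
  cat(sprintf(
    "SpeckleParams: contrast %.2f (hypoechoic), speckle scale %.2f, blur sigma %.1f px, seed %d\n",
    object@contrast, object@speckleScale, object@blurSigma, object@seed))
})

#' @describeIn confusionCounts display method
#' @param object a `ConfusionCounts`.
#' @export
setMethod("show", "ConfusionCounts", function(object) {
  cat(sprintf("ConfusionCounts (label 1 = lesion): TP %g  FP %g  FN %g  TN %g  (total %g)\n",
              object@TP, object@FP, object@FN, object@TN,
              object@TP + object@FP + object@FN + object@TN))
})

#' @describeIn segMetrics display method
#' @param object a `SegMetrics`.
#' @export
setMethod("show", "SegMetrics", function(object) {
  df <- as.data.frame(object)
  cat("SegMetrics report:\n")
  print(round(df, 4))
})

#' @describeIn buildNetwork display method
#' @param object a `LayerGraph`.
#' @export
setMethod("show", "LayerGraph", function(object) {
  cat(sprintf("LayerGraph %s: input %dx%d, width %d, %d processing layers, %g input-to-sink path(s)\n",
              object@variant, object@inputSide, object@inputSide,
              object@width, countLayers(object), countPaths(object)))
})

#' @describeIn trainConfig display method
#' @param object a `TrainConfig`.
#' @export
setMethod("show", "TrainConfig", function(object) {
  cat(sprintf(
    "TrainConfig: lr %.4g, momentum %.2f, batch %d, %d epochs, dropout %.2f, seed %d\n",
    object@learningRate, object@momentum, object@batchSize,
    object@maxEpochs, object@dropout, object@seed))
})

#' @describeIn twoSampleT display method
#' @param object a `TTestResult`.
#' @export
setMethod("show", "TTestResult", function(object) {
  cat(sprintf("Two-sample t test (pooled variance): t = %.3f, df = %d\n",
              object@statistic, object@df))
  cat(sprintf("  %.0f%% critical value %.3f -> %s%s\n",
              100 * object@confidence, object@tCritical,
              if (object@significant) "significant" else "not significant",
              if (object@direction == "none") ""
              else sprintf(" (first sample %s)", object@direction)))
})
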