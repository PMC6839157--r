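# Segmentation metric suite: pixel confusion counts, global/per-class
# accuracy, per-class/mean/weighted IoU, Dice, boundary-F1, the
# FP/FN colour overlay, and per-set aggregation.

#' Pixel confusion counts for a prediction/gold mask pair
#'
#' Label 1 (lesion) is the positive class: TP are lesion pixels correctly
#' classified as lesion, FP background pixels misclassified as lesion, FN
#' lesion pixels missed, TN background pixels correctly classified.
#'
#' @param pred,gold binary masks of identical shape with labels in \{0, 1\}.
#' @return a [ConfusionCounts-class].
#' @examples
#' g <- matrix(0L, 4, 4); g[2:3, 2:3] <- 1L
#' confusionCounts(g, g)
#' @export
confusionCounts <- function(pred, gold) {
  if (!identical(dim(pred), dim(gold)))
    stop("pred and gold must have the same shape")
  checkBinaryMask(pred, "pred")
  checkBinaryMask(gold, "gold")
  p <- pred == 1
  g <- gold == 1
  new("ConfusionCounts",
      TP = sum(p & g), FP = sum(p & !g),
      FN = sum(!p & g), TN = sum(!p & !g))
}

#' Global and mean per-class accuracy
#'
#' Global accuracy is the fraction of all pixels correctly classified,
#' `(TP + TN) / (TP + TN + FP + FN)`; mean accuracy averages the two
#' class recalls, `((TP/(TP+FN)) + (TN/(TN+FP))) / 2`. When a class is
#' absent its recall is undefined and mean accuracy is flagged `NA`.
#'
#' @param cc a [ConfusionCounts-class].
#' @return named numeric vector `globalAccuracy`, `meanAccuracy`.
#' @export
accuracyMetrics <- function(cc) {
  tot <- cc@TP + cc@TN + cc@FP + cc@FN
  if (tot <= 0) stop("no pixels evaluated")
  ga <- (cc@TP + cc@TN) / tot
  ma <- if (cc@TP + cc@FN > 0 && cc@TN + cc@FP > 0)
    (cc@TP / (cc@TP + cc@FN) + cc@TN / (cc@TN + cc@FP)) / 2 else NA_real_
  c(globalAccuracy = ga, meanAccuracy = ma)
}

#' Per-class, mean and weighted intersection-over-union
#'
#' Lesion IoU is `TP/(TP+FN+FP)`, background IoU `TN/(TN+FN+FP)`, mean
#' IoU their average. Class weights are the gold-mask class proportions
#' (lesion weight `(TP+FN)/total`), and the weighted IoU mixes the two
#' class IoUs by those proportions.
#'
#' @param cc a [ConfusionCounts-class].
#' @return named numeric vector `iouLesion`, `iouBackground`, `meanIoU`,
#'   `weightedIoU`, `lesionWeight`, `backgroundWeight`.
#' @export
iouMetrics <- function(cc) {
  tot <- cc@TP + cc@TN + cc@FP + cc@FN
  dl <- cc@TP + cc@FN + cc@FP
  db <- cc@TN + cc@FN + cc@FP
  il <- if (dl > 0) cc@TP / dl else NA_real_
  ib <- if (db > 0) cc@TN / db else NA_real_
  lw <- (cc@TP + cc@FN) / tot
  bw <- (cc@TN + cc@FP) / tot
  c(iouLesion = il, iouBackground = ib,
    meanIoU = (il + ib) / 2,
    weightedIoU = lw * il + bw * ib,
    lesionWeight = lw, backgroundWeight = bw)
}

#' Dice similarity coefficient
#'
#' `2TP / (2TP + FN + FP)`; a monotone transform of the lesion IoU
#' (`dice = 2 iou / (1 + iou)`). Flagged `NA` when both masks are empty.
#'
#' @param cc a [ConfusionCounts-class].
#' @return the Dice coefficient in [0, 1], or NA.
#' @export
diceCoefficient <- function(cc) {
  d <- 2 * cc@TP + cc@FN + cc@FP
  if (d <= 0) return(NA_real_)
  2 * cc@TP / d
}

#' Boundary pixels of a binary mask
#'
#' Lesion pixels that are 4-adjacent to a background pixel or lie on the
#' image border.
#'
#' @param mask binary mask.
#' @return two-column matrix of (row, col) boundary coordinates.
#' @export
maskBoundary <- function(mask) {
  checkBinaryMask(mask)
  h <- nrow(mask); w <- ncol(mask)
  pad <- matrix(0L, h + 2L, w + 2L)
  pad[2:(h + 1L), 2:(w + 1L)] <- mask
  core <- pad[2:(h + 1L), 2:(w + 1L)]
  nb <- pad[1:h, 2:(w + 1L)] & pad[3:(h + 2L), 2:(w + 1L)] &
        pad[2:(h + 1L), 1:w] & pad[2:(h + 1L), 3:(w + 2L)]
  which(core == 1L & !nb, arr.ind = TRUE)
}

#' Default boundary-match tolerance
#'
#' `ceiling(0.0075 * image diagonal)` pixels, the conventional default
#' for the boundary-F1 score.
#'
#' @param dims mask dimensions (length 2).
#' @return tolerance in pixels.
#' @export
bfTolerance <- function(dims) {
  as.integer(ceiling(0.0075 * sqrt(sum(as.numeric(dims)^2))))
}

#' Boundary F1 (BF) score
#'
#' Precision is the fraction of predicted-boundary pixels lying within
#' `tolerancePx` (Euclidean) of some gold-boundary pixel; recall is the
#' symmetric quantity; the score is their harmonic mean
#' `2PR/(P+R)`, defined as 0 when `P + R = 0`. If both boundaries are
#' empty the score is flagged `NA`.
#'
#' @param pred,gold binary masks of identical shape.
#' @param tolerancePx match tolerance in pixels; default
#'   [bfTolerance()] of the image diagonal.
#' @return the BF score in [0, 1], or NA.
#' @export
bfScore <- function(pred, gold, tolerancePx = NULL) {
  if (!identical(dim(pred), dim(gold)))
    stop("pred and gold must have the same shape")
  if (is.null(tolerancePx)) tolerancePx <- bfTolerance(dim(gold))
  if (tolerancePx < 0) stop("tolerancePx must be >= 0")
  bp <- maskBoundary(pred)
  bg <- maskBoundary(gold)
  if (nrow(bp) == 0L && nrow(bg) == 0L) return(NA_real_)
  if (nrow(bp) == 0L || nrow(bg) == 0L) return(0)
  d2 <- outer(bp[, 1L], bg[, 1L], `-`)^2 + outer(bp[, 2L], bg[, 2L], `-`)^2
  tol2 <- tolerancePx^2
  precision <- mean(apply(d2, 1L, min) <= tol2)
  recall <- mean(apply(d2, 2L, min) <= tol2)
  if (precision + recall == 0) return(0)
  2 * precision * recall / (precision + recall)
}

#' Full per-image metric report
#'
#' @param pred,gold binary masks of identical shape.
#' @param tolerancePx BF-score tolerance; see [bfScore()].
#' @return a [SegMetrics-class].
#' @export
segMetrics <- function(pred, gold, tolerancePx = NULL) {
  cc <- confusionCounts(pred, gold)
  acc <- accuracyMetrics(cc)
  iou <- iouMetrics(cc)
  new("SegMetrics",
      globalAccuracy = unname(acc["globalAccuracy"]),
      meanAccuracy = unname(acc["meanAccuracy"]),
      iouLesion = unname(iou["iouLesion"]),
      iouBackground = unname(iou["iouBackground"]),
      meanIoU = unname(iou["meanIoU"]),
      weightedIoU = unname(iou["weightedIoU"]),
      dice = diceCoefficient(cc),
      bfScore = bfScore(pred, gold, tolerancePx),
      lesionWeight = unname(iou["lesionWeight"]),
      backgroundWeight = unname(iou["backgroundWeight"]))
}

#' @describeIn segMetrics coerce a report to a one-row data.frame.
#' @param x a `SegMetrics` object.
#' @param row.names,optional,... passed for S3 compatibility, unused.
#' @export
as.data.frame.SegMetrics <- function(x, row.names = NULL, optional = FALSE, ...) {
  data.frame(globalAccuracy = x@globalAccuracy, meanAccuracy = x@meanAccuracy,
             iouLesion = x@iouLesion, iouBackground = x@iouBackground,
             meanIoU = x@meanIoU, weightedIoU = x@weightedIoU,
             dice = x@dice, bfScore = x@bfScore,
             lesionWeight = x@lesionWeight,
             backgroundWeight = x@backgroundWeight)
}

#' False-positive / false-negative colour overlay
#'
#' Renders the error structure of a prediction: false positives pink,
#' false negatives green, true positives white, true negatives black.
#'
#' @param pred,gold binary masks of identical shape.
#' @return an `H x W x 3` RGB array in [0, 1].
#' @export
overlayErrors <- function(pred, gold) {
  if (!identical(dim(pred), dim(gold)))
    stop("pred and gold must have the same shape")
  checkBinaryMask(pred, "pred")
  checkBinaryMask(gold, "gold")
  pink <- c(1, 0.45, 0.75)
  green <- c(0, 1, 0)
  white <- c(1, 1, 1)
  out <- array(0, c(dim(gold), 3L))
  fp <- pred == 1 & gold == 0
  fn <- pred == 0 & gold == 1
  tp <- pred == 1 & gold == 1
  for (ch in 1:3) {
    plane <- matrix(0, nrow(gold), ncol(gold))
    plane[fp] <- pink[ch]
    plane[fn] <- green[ch]
    plane[tp] <- white[ch]
    out[, , ch] <- plane
  }
  out
}

#' Evaluate a set of prediction/gold pairs
#'
#' Computes the per-image metric reports, then the per-metric mean and
#' sample standard deviation over images, skipping flagged-missing
#' values (an `NA` per-image metric does not drag the set mean).
#'
#' @param pairs non-empty list; each element a list with components
#'   `pred` and `gold`.
#' @param tolerancePx BF-score tolerance; see [bfScore()].
#' @return list with `perImage` (one row per image) and `summary`
#'   (columns `metric`, `mean`, `sd`, `n`).
#' @export
evaluateSet <- function(pairs, tolerancePx = NULL) {
  if (length(pairs) == 0L) stop("pairs must be a non-empty list")
  perImage <- do.call(rbind, lapply(pairs, function(p)
    as.data.frame(segMetrics(p$pred, p$gold, tolerancePx))))
  cols <- c("globalAccuracy", "meanAccuracy", "iouLesion", "iouBackground",
            "meanIoU", "weightedIoU", "dice", "bfScore")
  summary <- do.call(rbind, lapply(cols, function(m) {
    v <- perImage[[m]]
    v <- v[!is.na(v)]
    data.frame(metric = m,
               mean = if (length(v)) mean(v) else NA_real_,
               sd = if (length(v) > 1L) stats::sd(v) else NA_real_,
               n = length(v), stringsAsFactors = FALSE)
  }))
  list(perImage = perImage, summary = summary)
}
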