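# Independent brute-force oracles used to cross-check the vectorized /
# compiled implementations.

# per-pixel double-loop confusion tally
bruteConfusion <- function(pred, gold) {
  tp <- fp <- fn <- tn <- 0
  for (i in seq_len(nrow(pred)))
    for (j in seq_len(ncol(pred))) {
      p <- pred[i, j]; g <- gold[i, j]
      if (p == 1 && g == 1) tp <- tp + 1
      else if (p == 1 && g == 0) fp <- fp + 1
      else if (p == 0 && g == 1) fn <- fn + 1
      else tn <- tn + 1
    }
  c(TP = tp, FP = fp, FN = fn, TN = tn)
}

# metric formulas computed directly from a brute-force tally
bruteMetrics <- function(pred, gold) {
  cc <- bruteConfusion(pred, gold)
  tot <- sum(cc)
  il <- cc["TP"] / (cc["TP"] + cc["FN"] + cc["FP"])
  ib <- cc["TN"] / (cc["TN"] + cc["FN"] + cc["FP"])
  lw <- (cc["TP"] + cc["FN"]) / tot
  unname(c(global = (cc["TP"] + cc["TN"]) / tot,
           iouLesion = il, iouBackground = ib, meanIoU = (il + ib) / 2,
           weightedIoU = lw * il + (1 - lw) * ib,
           dice = 2 * cc["TP"] / (2 * cc["TP"] + cc["FN"] + cc["FP"])))
}

# boundary pixels by explicit neighbour inspection
bruteBoundary <- function(mask) {
  out <- NULL
  h <- nrow(mask); w <- ncol(mask)
  for (i in seq_len(h))
    for (j in seq_len(w)) {
      if (mask[i, j] != 1) next
      edge <- i == 1 || i == h || j == 1 || j == w
      if (!edge) {
        edge <- mask[i - 1, j] == 0 || mask[i + 1, j] == 0 ||
          mask[i, j - 1] == 0 || mask[i, j + 1] == 0
      }
      if (edge) out <- rbind(out, c(i, j))
    }
  out
}

# boundary-F1 by exhaustive pairwise distance matching
bruteBF <- function(pred, gold, tol) {
  bp <- bruteBoundary(pred)
  bg <- bruteBoundary(gold)
  if (is.null(bp) && is.null(bg)) return(NA_real_)
  if (is.null(bp) || is.null(bg)) return(0)
  near <- function(a, bset) {
    ok <- logical(nrow(a))
    for (i in seq_len(nrow(a))) {
      dmin <- Inf
      for (j in seq_len(nrow(bset)))
        dmin <- min(dmin, sqrt(sum((a[i, ] - bset[j, ])^2)))
      ok[i] <- dmin <= tol
    }
    mean(ok)
  }
  p <- near(bp, bg)
  r <- near(bg, bp)
  if (p + r == 0) return(0)
  2 * p * r / (p + r)
}

# direct-summation 2-d convolution (stride 1) for a single channel pair
bruteConv2d <- function(x, w, pad) {
  k <- nrow(w)
  h <- nrow(x); wd <- ncol(x)
  xp <- matrix(0, h + 2 * pad, wd + 2 * pad)
  xp[pad + seq_len(h), pad + seq_len(wd)] <- x
  out <- matrix(0, h + 2 * pad - k + 1, wd + 2 * pad - k + 1)
  for (i in seq_len(nrow(out)))
    for (j in seq_len(ncol(out)))
      out[i, j] <- sum(xp[i:(i + k - 1), j:(j + k - 1)] * w)
  out
}

randomMask <- function(side, p = 0.3) {
  matrix(as.integer(stats::runif(side * side) < p), side, side)
}

# square lesion mask helper
squareMask <- function(side, r0, r1, c0, c1) {
  m <- matrix(0L, side, side)
  m[r0:r1, c0:c1] <- 1L
  m
}
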