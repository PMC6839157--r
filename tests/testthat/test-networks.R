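# Architecture construction: layer counts, DAG structure, shape
# propagation, initialization, forward semantics.

test_that("the three variants count 52, 61 and 68 processing layers", {
  expect_identical(countLayers(buildNetwork("CNN1", 160L)), 52L)
  expect_identical(countLayers(buildNetwork("CNN2", 160L)), 61L)
  expect_identical(countLayers(buildNetwork("CNN3", 160L)), 68L)
})

test_that("layer counts are independent of width and empty graphs count zero", {
  for (v in c("CNN1", "CNN2", "CNN3"))
    expect_identical(countLayers(buildNetwork(v, 160L, width = 8L)),
                     countLayers(buildNetwork(v, 160L, width = 64L)))
  expect_identical(countLayers(new("LayerGraph")), 0L)
})

test_that("the CNN2 skip branch accounts exactly for the extra layers", {
  g1 <- buildNetwork("CNN1", 160L)
  g2 <- buildNetwork("CNN2", 160L)
  skipLayers <- setdiff(names(g2@layers), names(g1@layers))
  expect_identical(countLayers(g2) - countLayers(g1), length(skipLayers))
  expect_identical(length(skipLayers), 9L)
})

test_that("series and DAG variants have the expected path multiplicity", {
  expect_equal(countPaths(buildNetwork("CNN1", 160L)), 1)
  expect_equal(countPaths(buildNetwork("CNN2", 160L)), 2)
  expect_gte(countPaths(buildNetwork("CNN3", 160L)), 4)
})

test_that("shapes are conserved input-to-output for all variants and sides", {
  for (v in c("CNN1", "CNN2", "CNN3"))
    for (side in c(160L, 320L)) {
      g <- buildNetwork(v, side, width = 4L)
      sh <- inferShapes(g)   # also asserts concat inputs agree spatially
      expect_identical(sh[["pixelclass"]][1L], side)
      expect_identical(sh[["pixelclass"]][2L], 2L)
    }
})

test_that("the encoder bottleneck of a 160-pixel input is 20x20", {
  sh <- inferShapes(buildNetwork("CNN1", 160L))
  expect_identical(sh[["bott_2_relu"]][1L], 20L)
})

test_that("invalid build arguments are rejected", {
  expect_error(buildNetwork("CNN1", 150L), "multiple of 8")
  expect_error(buildNetwork("CNN1", 160L, width = 1L), "width")
  expect_error(buildNetwork("CNN9", 160L))
})

test_that("initialization is zero-bias Gaussian with sd 0.01, seeded", {
  g <- buildNetwork("CNN1", 160L)   # width 64: tens of thousands of weights
  p <- initParameters(g, seed = 7L)
  ws <- unlist(lapply(p, function(q) q$W))
  bs <- unlist(lapply(p, function(q) q$b))
  expect_gt(length(ws), 1e4)
  expect_true(all(bs == 0))
  expect_gt(stats::sd(ws), 0.009)
  expect_lt(stats::sd(ws), 0.011)
  expect_lt(abs(mean(ws)), 1e-3)
  expect_identical(p, initParameters(g, seed = 7L))
  expect_false(identical(p, initParameters(g, seed = 8L)))
})

test_that("forward pass yields per-pixel probabilities at input size", {
  g <- buildNetwork("CNN1", 160L, width = 2L)
  p <- initParameters(g, 1L)
  x <- matrix(stats::runif(160 * 160), 160L)
  pr <- forwardPass(g, p, x)
  expect_identical(dim(pr), c(160L, 160L, 2L, 1L))
  expect_lt(max(abs(pr[, , 1L, ] + pr[, , 2L, ] - 1)), 1e-6)
  expect_error(forwardPass(g, p, matrix(0, 64, 64)), "side")
})

test_that("the convolution kernel reproduces a hand-computed oracle", {
  set.seed(9)
  x <- matrix(stats::rnorm(16), 4, 4)
  w <- matrix(stats::rnorm(9), 3, 3)
  got <- BUSseg:::cpp_conv_fwd(array(x, c(4, 4, 1, 1)),
                               array(w, c(3, 3, 1, 1)), 0, 1L, 1L, FALSE)$y
  expect_equal(got[, , 1, 1], bruteConv2d(x, w, 1L), tolerance = 1e-12)

  # two-channel sum and bias
  x2 <- array(stats::rnorm(32), c(4, 4, 2, 1))
  w2 <- array(stats::rnorm(18), c(3, 3, 2, 1))
  got2 <- BUSseg:::cpp_conv_fwd(x2, w2, 0.5, 1L, 1L, FALSE)$y
  want2 <- bruteConv2d(x2[, , 1, 1], w2[, , 1, 1], 1L) +
    bruteConv2d(x2[, , 2, 1], w2[, , 2, 1], 1L) + 0.5
  expect_equal(got2[, , 1, 1], want2, tolerance = 1e-12)
})

test_that("the transposed convolution doubles size and inverts the conv geometry", {
  set.seed(10)
  x <- array(stats::rnorm(16), c(4, 4, 1, 1))
  w <- array(stats::rnorm(16), c(4, 4, 1, 1))
  y <- BUSseg:::cpp_deconv_fwd(x, w, 0, 2L, 1L)
  expect_identical(dim(y), c(8L, 8L, 1L, 1L))
  # oracle: scatter each input pixel times the kernel at stride-2 offsets
  want <- matrix(0, 10, 10)   # padded output then trimmed by pad = 1
  for (i in 1:4)
    for (j in 1:4)
      want[(2 * i - 1):(2 * i + 2), (2 * j - 1):(2 * j + 2)] <-
        want[(2 * i - 1):(2 * i + 2), (2 * j - 1):(2 * j + 2)] + x[i, j, 1, 1] * w[, , 1, 1]
  expect_equal(y[, , 1, 1], want[2:9, 2:9], tolerance = 1e-12)
})

test_that("graphs serialize to a versioned JSON description", {
  g <- buildNetwork("CNN3", 160L, width = 4L)
  js <- serializeGraph(g)
  obj <- jsonlite::fromJSON(js, simplifyVector = FALSE)
  expect_identical(obj$variant, "CNN3")
  expect_identical(obj$version, 1L)
  expect_identical(length(obj$layers), 69L)   # 68 + input
  path <- withr::local_tempfile(fileext = ".json")
  serializeGraph(g, path)
  expect_identical(jsonlite::fromJSON(readLines(path),
                                      simplifyVector = FALSE)$variant, "CNN3")
})

test_that("backpropagated gradients match finite differences on a toy net", {
  g <- buildNetwork("CNN1", 16L, width = 4L)
  g@layers[["dec1_drop"]]$ratio <- 0   # deterministic loss for differencing
  p <- initParameters(g, 3L)
  set.seed(12)
  x <- matrix(stats::runif(256), 16L)
  tgt <- squareMask(16L, 5, 11, 6, 12)
  lossAt <- function(par) {
    fw <- forwardPass(g, par, x, train = TRUE, returnCache = TRUE)
    BUSseg:::lossAndLogitGrad(fw$probs, tgt)$loss
  }
  fw <- forwardPass(g, p, x, train = TRUE, returnCache = TRUE)
  lg <- BUSseg:::lossAndLogitGrad(fw$probs, tgt)
  grads <- BUSseg:::backwardPass(g, p, fw, lg$dlogits)
  convs <- names(Filter(function(q) !is.null(q$W), grads))
  set.seed(13)
  h <- 1e-5
  for (i in 1:10) {
    nm <- sample(convs, 1L)
    idx <- sample(length(p[[nm]]$W), 1L)
    pp <- p; pp[[nm]]$W[idx] <- pp[[nm]]$W[idx] + h
    pm <- p; pm[[nm]]$W[idx] <- pm[[nm]]$W[idx] - h
    fd <- (lossAt(pp) - lossAt(pm)) / (2 * h)
    bp <- grads[[nm]]$W[idx]
    expect_lt(abs(fd - bp) / max(abs(fd), abs(bp), 1e-8), 1e-3)
  }
})
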