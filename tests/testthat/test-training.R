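# SGDM update rule, splitting protocols, the training loop and
# prediction semantics.

test_that("the SGDM update follows theta - lr*grad + momentum*(theta - prev)", {
  cfg <- trainConfig()
  expect_equal(sgdmStep(1.0, 0.9, 2.0, cfg), 1.088)
  expect_equal(sgdmStep(0.5, 0.5, 0, cfg), 0.5)        # fixed point
  cfg0 <- trainConfig(momentum = 0)
  expect_equal(sgdmStep(1.0, 0.3, 2.0, cfg0), 1.0 - 0.001 * 2)  # plain GD
  # nested list structures update elementwise
  th <- list(a = c(1, 2), b = list(W = matrix(1, 2, 2)))
  up <- sgdmStep(th, th, list(a = c(1, 1), b = list(W = matrix(0, 2, 2))), cfg)
  expect_equal(up$a, c(1, 2) - 0.001)
  expect_equal(up$b$W, matrix(1, 2, 2))
  expect_error(sgdmStep(1, c(1, 2), 1, cfg), "congruent")
})

test_that("SGDM drives a convex quadratic to its minimum", {
  cfg <- trainConfig()   # default learning rate and momentum
  th <- 1; prev <- 1
  for (i in 1:2000) {
    nxt <- sgdmStep(th, prev, th, cfg)   # E = theta^2/2, grad = theta
    prev <- th; th <- nxt
    if (abs(th) < 1e-3) break
  }
  expect_lt(abs(th), 1e-3)
})

test_that("stratified 60/20/20 split reproduces the published subset sizes", {
  labsA <- rep(c("benign", "malignant"), c(208L, 179L))
  spA <- stratifiedSplit(labsA, seed = 5L)
  expect_identical(lengths(spA)[c("train", "val", "test")],
                   c(train = 233L, val = 77L, test = 77L))
  # class proportions carried into each subset within one item
  for (s in spA) {
    nm <- sum(labsA[s] == "malignant")
    expect_lte(abs(nm - length(s) * 179 / 387), 1)
  }

  labsB <- rep(c("benign", "malignant"), c(110L, 53L))
  spB <- stratifiedSplit(labsB, seed = 5L)
  expect_identical(lengths(spB)[c("train", "val", "test")],
                   c(train = 97L, val = 33L, test = 33L))

  sp10 <- stratifiedSplit(rep(c("a", "b"), each = 5L), seed = 1L)
  expect_identical(lengths(sp10)[c("train", "val", "test")],
                   c(train = 6L, val = 2L, test = 2L))
  labs10 <- rep(c("a", "b"), each = 5L)
  expect_identical(as.integer(table(labs10[sp10$val])), c(1L, 1L))
  expect_identical(as.integer(table(labs10[sp10$test])), c(1L, 1L))
})

test_that("splits partition the indices proportionally for any n and seed", {
  set.seed(2)
  for (rep in 1:10) {
    n <- sample(25:200, 1L)
    labs <- sample(c("benign", "malignant"), n, replace = TRUE,
                   prob = c(0.6, 0.4))
    if (min(table(labs)) < 3L) next
    sp <- stratifiedSplit(labs, seed = rep)
    all_ <- c(sp$train, sp$val, sp$test)
    expect_identical(sort(all_), seq_len(n))
    for (cl in unique(labs)) {
      fr <- mean(labs == cl)
      for (s in sp)
        expect_lte(abs(sum(labs[s] == cl) - length(s) * fr), 1 + 1e-9)
    }
  }
})

test_that("stratified k-fold partitions are balanced and deterministic", {
  labs <- rep(c("benign", "malignant"), each = 5L)
  f <- kfoldSplit(labs, k = 5L, seed = 3L)
  expect_identical(length(f), 5L)
  sizes <- vapply(f, function(x) length(x$test), 0L)
  expect_true(all(sizes == 2L))
  expect_identical(sort(unlist(lapply(f, `[[`, "test"))), 1:10)
  for (fold in f)
    expect_identical(sort(c(fold$train, fold$test)), 1:10)
  expect_identical(kfoldSplit(labs, 5L, seed = 3L), f)
  expect_error(kfoldSplit(labs[1:3], k = 5L), "at least k")

  labs2 <- sample(rep(c("b", "m"), c(23L, 19L)))
  f2 <- kfoldSplit(labs2, k = 5L, seed = 9L)
  sizes2 <- vapply(f2, function(x) length(x$test), 0L)
  expect_lte(diff(range(sizes2)), 1L)
})

test_that("the training loop iterates, records losses and is reproducible", {
  ds <- generateDataset(10, side = 16L, masterSeed = 31L)
  g <- buildNetwork("CNN1", 16L, width = 2L)
  p <- initParameters(g, 1L)
  cfg <- trainConfig(maxEpochs = 1L, seed = 11L)
  fit <- trainNetwork(g, p, ds, cfg)
  expect_identical(nrow(fit$trace), 2L)   # 10 images / batch 5
  expect_identical(fit$trace$iteration, 1:2)
  expect_true(all(is.finite(fit$trace$loss)))

  fit2 <- trainNetwork(g, p, ds, cfg)
  expect_identical(fit$trace, fit2$trace)
  expect_identical(fit$params, fit2$params)

  fit3 <- trainNetwork(g, p, ds, trainConfig(maxEpochs = 1L, seed = 12L))
  expect_false(identical(fit$trace$loss, fit3$trace$loss))
})

test_that("the single-precision engine agrees with the reference path", {
  ds <- generateDataset(10, side = 16L, masterSeed = 41L)
  g <- buildNetwork("CNN2", 16L, width = 4L)
  p <- initParameters(g, 2L)
  # dropout off so both paths see the same deterministic loss surface
  cfg <- trainConfig(maxEpochs = 2L, seed = 21L, dropout = 0)
  fa <- trainNetwork(g, p, ds, cfg, engine = "single")
  fr <- trainNetwork(g, p, ds, cfg, engine = "reference")
  expect_equal(fa$trace$loss, fr$trace$loss, tolerance = 1e-4)
  wA <- unlist(lapply(fa$params, function(q) q$W))
  wR <- unlist(lapply(fr$params, function(q) q$W))
  expect_lt(max(abs(wA - wR)), 5e-4)   # float accumulation over 4 updates
})

test_that("a small series network learns the phantom task", {
  ds <- generateDataset(20, side = 64L, masterSeed = 55L)
  g <- buildNetwork("CNN1", 64L, width = 8L)
  p <- initParameters(g, 5L)
  fit <- trainNetwork(g, p, ds, trainConfig(maxEpochs = 15L, seed = 5L))
  tr <- fit$trace$loss
  expect_lt(mean(utils::tail(tr, 5L)), mean(utils::head(tr, 5L)))
})

test_that("prediction takes the per-pixel argmax with ties to background", {
  g <- buildNetwork("CNN1", 16L, width = 2L)
  p <- initParameters(g, 1L)
  # zero out the classifying convolution: both logits equal -> all ties
  p$final_conv$W[] <- 0
  p$final_conv$b[] <- 0
  img <- matrix(stats::runif(256), 16L)
  pred <- predictMask(g, p, img)
  expect_true(all(pred == 0L))
  expect_identical(dim(pred), dim(img))
})

test_that("dataset geometry mismatches abort training", {
  ds <- generateDataset(4, side = 16L, masterSeed = 1L)
  ds[[2L]]$mask <- ds[[2L]]$mask[1:8, 1:8]
  g <- buildNetwork("CNN1", 16L, width = 2L)
  expect_error(trainNetwork(g, initParameters(g, 1L), ds, trainConfig(maxEpochs = 1L)),
               "shapes differ")
  g24 <- buildNetwork("CNN1", 24L, width = 2L)
  ds2 <- generateDataset(4, side = 16L, masterSeed = 1L)
  expect_error(trainNetwork(g24, initParameters(g24, 1L), ds2,
                            trainConfig(maxEpochs = 1L)),
               "expects 24x24")
})
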