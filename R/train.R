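# SGDM optimization, stratified splitting, k-fold cross-validation and
# the mini-batch training loop.

#' Create a training configuration
#'
#' Defaults are the study conditions: learning rate 0.001, momentum 0.9,
#' mini-batch size 5, 150 epochs, dropout ratio 0.5.
#'
#' @param learningRate step size, > 0.
#' @param momentum momentum coefficient in [0, 1).
#' @param batchSize mini-batch size.
#' @param maxEpochs number of training epochs (the stop condition).
#' @param dropout dropout ratio.
#' @param seed integer seed for shuffling and dropout.
#' @return a validated [TrainConfig-class].
#' @export
trainConfig <- function(learningRate = 0.001, momentum = 0.9, batchSize = 5L,
                        maxEpochs = 150L, dropout = 0.5, seed = 1L) {
  new("TrainConfig", learningRate = learningRate, momentum = momentum,
      batchSize = as.integer(batchSize), maxEpochs = as.integer(maxEpochs),
      dropout = dropout, seed = as.integer(seed))
}

#' One SGDM parameter update
#'
#' Applies \eqn{\theta_{l+1} = \theta_l - \alpha \nabla E(\theta_l) +
#' \gamma(\theta_l - \theta_{l-1})} elementwise. All three arguments may
#' be numeric vectors/arrays or (nested) lists thereof with congruent
#' shapes; the first step of an optimization passes
#' `thetaPrev = theta`.
#'
#' @param theta current parameters \eqn{\theta_l}.
#' @param thetaPrev previous parameters \eqn{\theta_{l-1}}.
#' @param grad gradient \eqn{\nabla E(\theta_l)}.
#' @param cfg a [TrainConfig-class] supplying \eqn{\alpha} and
#'   \eqn{\gamma}.
#' @return updated parameters \eqn{\theta_{l+1}}, same structure as
#'   `theta`.
#' @examples
#' sgdmStep(1.0, 0.9, 2.0, trainConfig())  # 1 - 0.002 + 0.09 = 1.088
#' @export
sgdmStep <- function(theta, thetaPrev, grad, cfg) {
  if (is.list(theta)) {
    if (!is.list(thetaPrev) || !is.list(grad) ||
        length(thetaPrev) != length(theta) || length(grad) != length(theta))
      stop("theta, thetaPrev and grad must have congruent structure")
    return(mapply(sgdmStep, theta, thetaPrev, grad,
                  MoreArgs = list(cfg = cfg), SIMPLIFY = FALSE))
  }
  if (length(thetaPrev) != length(theta) || length(grad) != length(theta))
    stop("theta, thetaPrev and grad must have congruent shapes")
  theta - cfg@learningRate * grad + cfg@momentum * (theta - thetaPrev)
}

# allocate class counts to a target total by largest remainder
largestRemainder <- function(targets, total) {
  base <- floor(targets)
  rem <- total - sum(base)
  if (rem > 0) {
    extra <- order(targets - base, decreasing = TRUE)[seq_len(rem)]
    base[extra] <- base[extra] + 1
  } else if (rem < 0) {
    take <- order(targets - base)[seq_len(-rem)]
    base[take] <- base[take] - 1
  }
  as.integer(base)
}

#' Stratified train/validation/test split
#'
#' Splits indices `1..length(labels)` so that validation and test sizes
#' are `round(f * n)` (train takes the remainder) and each class is
#' represented in every subset within one item of its global proportion.
#' With the default 60/20/20 fractions, n = 387 gives 233/77/77 and
#' n = 163 gives 97/33/33.
#'
#' @param labels class label per item (character or factor).
#' @param fractions train/validation/test fractions summing to 1.
#' @param seed shuffling seed.
#' @return list with integer index vectors `train`, `val`, `test`.
#' @export
stratifiedSplit <- function(labels, fractions = c(0.6, 0.2, 0.2), seed = 1L) {
  n <- length(labels)
  if (n < 5L) stop("need at least 5 items to split")
  if (abs(sum(fractions) - 1) > 1e-9) stop("fractions must sum to 1")
  labels <- as.character(labels)
  tab <- table(labels)
  if (any(tab < 3L))
    warning("a class has fewer than 3 items; making a best-effort assignment")
  nVal <- round(fractions[2L] * n)
  nTest <- round(fractions[3L] * n)
  classes <- names(tab)
  nc <- as.numeric(tab)
  valCounts <- largestRemainder(nc * fractions[2L], nVal)
  testCounts <- largestRemainder(nc * fractions[3L], nTest)
  # best effort for tiny classes: never draw more than the class holds
  over <- valCounts + testCounts > nc
  if (any(over)) testCounts[over] <- pmax(nc[over] - valCounts[over], 0L)
  val <- integer(0); test <- integer(0); train <- integer(0)
  withSeed(seed, {
    for (i in seq_along(classes)) {
      idx <- sample(which(labels == classes[i]))
      v <- valCounts[i]; t <- testCounts[i]
      val <- c(val, idx[seq_len(v)])
      test <- c(test, idx[v + seq_len(t)])
      train <- c(train, idx[setdiff(seq_along(idx), seq_len(v + t))])
    }
  })
  list(train = sort(train), val = sort(val), test = sort(test))
}

#' Stratified k-fold partition
#'
#' Partitions indices into k folds of sizes differing by at most one,
#' stratified by label, deterministic per seed. Each element pairs the
#' held-out `test` fold with the complementary `train` set.
#'
#' @param labels class label per item.
#' @param k number of folds (default 5).
#' @param seed shuffling seed.
#' @return list of k lists with components `train` and `test`.
#' @export
kfoldSplit <- function(labels, k = 5L, seed = 1L) {
  n <- length(labels)
  if (n < k) stop(sprintf("need at least k = %d items, got %d", k, n))
  labels <- as.character(labels)
  ord <- withSeed(seed, {
    out <- integer(0)
    for (cl in sample(unique(labels)))
      out <- c(out, sample(which(labels == cl)))
    out
  })
  foldId <- integer(n)
  foldId[ord] <- rep(seq_len(k), length.out = n)
  lapply(seq_len(k), function(f)
    list(train = which(foldId != f), test = which(foldId == f)))
}

#' Train a network with SGDM
#'
#' Runs `cfg@maxEpochs` epochs over seeded mini-batches of
#' `cfg@batchSize`, recording the mean cross-entropy of every mini-batch
#' (the loss trace). The mini-batch order is reshuffled each epoch with
#' a per-epoch seed derived from `cfg@seed`; identical seeds and data
#' reproduce the identical trace. Training aborts with a diagnostic if
#' the loss becomes non-finite.
#'
#' @param g a [LayerGraph-class].
#' @param params initial parameters from [initParameters()].
#' @param dataset list of records with `image` and `mask` matrices
#'   matching the graph's input side.
#' @param cfg a [TrainConfig-class].
#' @param engine `"single"` (default) runs the whole step in the
#'   single-precision C++ engine, the customary precision for CNN
#'   optimization; `"reference"` uses the double-precision layer-by-layer
#'   R path (slower; used for verification).
#' @param verbose print a line per epoch.
#' @return list with `params` (trained) and `trace`
#'   (data.frame `iteration`, `loss`).
#' @export
trainNetwork <- function(g, params, dataset, cfg = trainConfig(),
                         engine = c("single", "reference"),
                         verbose = FALSE) {
  engine <- match.arg(engine)
  validObject(cfg)
  if (length(dataset) == 0L) stop("dataset is empty")
  for (it in dataset) {
    if (!identical(dim(it$image), dim(it$mask)))
      stop("image and mask shapes differ in the dataset")
    if (!all(dim(it$image) == g@inputSide))
      stop(sprintf("dataset images are %dx%d but the graph expects %dx%d",
                   nrow(it$image), ncol(it$image), g@inputSide, g@inputSide))
  }
  # the configured dropout ratio governs the graph's dropout layers
  for (nm in names(g@layers))
    if (g@layers[[nm]]$kind == "dropout") g@layers[[nm]]$ratio <- cfg@dropout
  fast <- if (engine == "single") makeEngine(g, params, cfg) else NULL
  trainable <- trainableParams(params)
  prev <- trainable
  iteration <- 0L
  traceIter <- integer(0)
  traceLoss <- numeric(0)
  for (epoch in seq_len(cfg@maxEpochs)) {
    ord <- withSeed(deriveSeed(cfg@seed, epoch, 3L), sample(length(dataset)))
    batches <- split(ord, ceiling(seq_along(ord) / cfg@batchSize))
    for (b in batches) {
      iteration <- iteration + 1L
      x <- stackImages(lapply(dataset[b], `[[`, "image"))
      dropSeed <- deriveSeed(cfg@seed, iteration, 5L)
      if (!is.null(fast)) {
        tgt <- vapply(dataset[b], function(it) as.numeric(it$mask),
                      numeric(length(dataset[[b[1L]]]$mask)))
        loss <- cpp_engine_step(fast$ptr, x, tgt, dropSeed)
        if (!is.finite(loss))
          stop(sprintf("non-finite loss at iteration %d", iteration))
        traceIter[iteration] <- iteration
        traceLoss[iteration] <- loss
      } else {
        tgt <- stackImages(lapply(dataset[b], `[[`, "mask"))[, , 1L, , drop = FALSE]
        fw <- forwardPass(g, params, x, train = TRUE, returnCache = TRUE,
                          dropoutSeed = dropSeed)
        params <- fw$params  # batchnorm running statistics advance
        lg <- lossAndLogitGrad(fw$probs, tgt)
        if (!is.finite(lg$loss))
          stop(sprintf("non-finite loss at iteration %d", iteration))
        traceIter[iteration] <- iteration
        traceLoss[iteration] <- lg$loss
        grads <- backwardPass(g, params, fw, lg$dlogits)
        cur <- trainableParams(params)
        upd <- sgdmStep(cur, prev, alignGrads(cur, grads), cfg)
        prev <- cur
        params <- mergeTrainable(params, upd)
      }
    }
    if (verbose)
      message(sprintf("epoch %3d  mean loss %.4f", epoch,
                      mean(utils::tail(traceLoss, length(batches)))))
  }
  if (!is.null(fast)) params <- extractEngineParams(fast, params)
  list(params = params,
       trace = data.frame(iteration = traceIter, loss = traceLoss))
}

# trainable view of the parameter store (weights, biases, batchnorm
# scale/offset; running statistics are not gradient-updated)
trainableParams <- function(params) {
  lapply(params, function(p) p[intersect(names(p), c("W", "b", "gamma", "beta"))])
}

alignGrads <- function(trainable, grads) {
  out <- trainable
  for (nm in names(out))
    for (f in names(out[[nm]])) {
      gr <- grads[[nm]][[f]]
      out[[nm]][[f]] <- if (is.null(gr)) out[[nm]][[f]] * 0 else gr
    }
  out
}

mergeTrainable <- function(params, upd) {
  for (nm in names(upd))
    for (f in names(upd[[nm]])) {
      v <- upd[[nm]][[f]]
      dim(v) <- dim(params[[nm]][[f]])
      params[[nm]][[f]] <- v
    }
  params
}

#' Predict a binary lesion mask
#'
#' Runs the network in inference mode and takes the per-pixel argmax
#' over the two class probabilities; exact 0.5/0.5 ties go to the
#' background class.
#'
#' @param g a [LayerGraph-class].
#' @param params trained parameters.
#' @param image matrix matching the graph's input side.
#' @return integer binary mask of the image's shape.
#' @export
predictMask <- function(g, params, image) {
  probs <- forwardPass(g, params, image)
  matrix(as.integer(probs[, , 2L, 1L] > probs[, , 1L, 1L]),
         nrow(image), ncol(image))
}

#' Stratified k-fold cross-validation of one architecture
#'
#' For each fold: initialize, train on the fold's training items, then
#' evaluate the full metric suite on the held-out items.
#'
#' @param variant architecture name passed to [buildNetwork()].
#' @param dataset list of records with `image`, `mask`, `label`.
#' @param k number of folds.
#' @param cfg a [TrainConfig-class].
#' @param width network width.
#' @param tolerancePx BF-score tolerance.
#' @param keepParams also return each fold's trained parameters (as
#'   element `params` of the fold entry); off by default to save memory.
#' @return list with `perFold` (list of [evaluateSet()] results, plus
#'   the fold's loss trace and optionally parameters) and `foldSummary`
#'   (data.frame of per-fold metric means).
#' @export
crossValidate <- function(variant, dataset, k = 5L, cfg = trainConfig(),
                          width = 64L, tolerancePx = NULL,
                          keepParams = FALSE) {
  labels <- vapply(dataset, `[[`, "", "label")
  folds <- kfoldSplit(labels, k, seed = cfg@seed)
  side <- nrow(dataset[[1L]]$image)
  g <- buildNetwork(variant, side, width)
  perFold <- vector("list", k)
  rows <- vector("list", k)
  for (f in seq_len(k)) {
    foldCfg <- cfg
    foldCfg@seed <- deriveSeed(cfg@seed, f, 7L)
    params <- initParameters(g, seed = foldCfg@seed)
    fit <- trainNetwork(g, params, dataset[folds[[f]]$train], foldCfg)
    pairs <- lapply(dataset[folds[[f]]$test], function(it)
      list(pred = predictMask(g, fit$params, it$image), gold = it$mask))
    ev <- evaluateSet(pairs, tolerancePx)
    ev$trace <- fit$trace
    if (keepParams) ev$params <- fit$params
    perFold[[f]] <- ev
    means <- stats::setNames(ev$summary$mean, ev$summary$metric)
    rows[[f]] <- data.frame(fold = f, t(means))
  }
  list(perFold = perFold, foldSummary = do.call(rbind, rows))
}
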