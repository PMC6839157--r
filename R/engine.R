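# Forward and backward execution of a layer graph over (H, W, C, N)
# tensors. Heavy kernels (conv, deconv, pooling, batchnorm, relu) are
# implemented in C++ (src/kernels.cpp); the graph walk, dropout, softmax
# and the cross-entropy loss live here.

BN_EPS <- 1e-5
BN_MOMENTUM <- 0.1   # running-statistics update rate

#' Initialize network parameters
#'
#' Convolution and deconvolution weights are drawn i.i.d. from a Gaussian
#' with mean 0 and standard deviation 0.01; biases start at zero;
#' batchnorm scales at 1 and offsets at 0 with running mean 0 / variance
#' 1. Deterministic per seed.
#'
#' @param g a [LayerGraph-class].
#' @param seed integer seed.
#' @return named list of per-layer parameter lists.
#' @export
initParameters <- function(g, seed = 1L) {
  withSeed(seed, {
    params <- list()
    for (ly in g@layers) {
      params[[ly$name]] <- switch(ly$kind,
        conv = ,
        deconv = list(
          W = array(stats::rnorm(ly$k * ly$k * ly$inCh * ly$outCh, 0, 0.01),
                    c(ly$k, ly$k, ly$inCh, ly$outCh)),
          b = numeric(ly$outCh)),
        batchnorm = list(gamma = rep(1, ly$ch), beta = numeric(ly$ch),
                         rmean = numeric(ly$ch), rvar = rep(1, ly$ch)),
        NULL)
    }
    params[!vapply(params, is.null, TRUE)]
  })
}

softmaxProbs <- function(logits) {
  # stable 2-channel softmax over the channel dimension
  d <- dim(logits)
  a <- logits[, , 1L, , drop = FALSE]
  b <- logits[, , 2L, , drop = FALSE]
  m <- pmax(a, b)
  ea <- exp(a - m)
  eb <- exp(b - m)
  s <- ea + eb
  out <- array(0, d)
  out[, , 1L, ] <- ea / s
  out[, , 2L, ] <- eb / s
  out
}

concatChannels <- function(tensors) {
  d1 <- dim(tensors[[1L]])
  chs <- vapply(tensors, function(t) dim(t)[3L], 0)
  out <- array(0, c(d1[1L], d1[2L], sum(chs), d1[4L]))
  at <- 0L
  for (t in tensors) {
    ch <- dim(t)[3L]
    out[, , (at + 1L):(at + ch), ] <- t
    at <- at + ch
  }
  out
}

#' Run a forward pass through a layer graph
#'
#' In inference mode (`train = FALSE`) dropout is disabled and batchnorm
#' uses its running statistics, so the output is deterministic. The
#' output has the input's spatial size with 2 channels of per-pixel class
#' probabilities summing to 1.
#'
#' @param g a [LayerGraph-class].
#' @param params parameter store from [initParameters()] (possibly
#'   trained).
#' @param x input batch: a matrix, an `(H, W, N)` stack, or an
#'   `(H, W, 1, N)` array with side equal to `g@inputSide`.
#' @param train logical; training mode enables dropout and batch
#'   statistics.
#' @param returnCache logical; also return per-layer activations and the
#'   updated batchnorm running statistics (used by the training loop).
#' @param dropoutSeed integer seed for the dropout masks in training
#'   mode.
#' @return probability array `(H, W, 2, N)`; with `returnCache = TRUE`, a
#'   list `(probs, acts, cache, params)`.
#' @export
forwardPass <- function(g, params, x, train = FALSE, returnCache = FALSE,
                        dropoutSeed = 1L) {
  x <- asBatch(x)
  d <- dim(x)
  if (d[1L] != g@inputSide || d[2L] != g@inputSide)
    stop(sprintf("input side %dx%d does not match graph input side %d",
                 d[1L], d[2L], g@inputSide))
  if (d[3L] != 1L) stop("expected a single intensity channel")
  ord <- topoSort(g)
  acts <- list(input = x)
  cache <- list()
  if (train) dropRng <- deriveSeed(dropoutSeed, 977L)
  for (nd in ord) {
    if (nd == "input") next
    ly <- g@layers[[nd]]
    pre <- predecessors(g, nd)
    xin <- if (ly$kind == "concat") acts[ly$inputs] else acts[[pre[1L]]]
    p <- params[[nd]]
    acts[[nd]] <- switch(ly$kind,
      conv = {
        r <- cpp_conv_fwd(xin, p$W, p$b, ly$stride, ly$pad, keepCols = train)
        if (train) cache[[nd]] <- list(cols = r$cols)
        r$y
      },
      deconv = cpp_deconv_fwd(xin, p$W, p$b, ly$stride, ly$pad),
      batchnorm = {
        if (train) {
          r <- cpp_bn_fwd(xin, p$gamma, p$beta, BN_EPS)
          cache[[nd]] <- list(mean = r$mean, invstd = r$invstd)
          params[[nd]]$rmean <- (1 - BN_MOMENTUM) * p$rmean + BN_MOMENTUM * r$mean
          params[[nd]]$rvar <- (1 - BN_MOMENTUM) * p$rvar + BN_MOMENTUM * r$var
          r$y
        } else {
          cpp_bn_infer(xin, p$gamma, p$beta, p$rmean, p$rvar, BN_EPS)
        }
      },
      relu = cpp_relu_fwd(xin),
      maxpool = {
        r <- cpp_maxpool_fwd(xin, ly$stride)
        cache[[nd]] <- list(idx = r$idx, xdim = dim(xin))
        r$y
      },
      dropout = {
        if (train && ly$ratio > 0) {
          keep <- 1 - ly$ratio
          mask <- withSeed(dropRng, array((stats::runif(length(xin)) < keep) / keep,
                                          dim(xin)))
          dropRng <- deriveSeed(dropRng, 1L)
          cache[[nd]] <- list(mask = mask)
          xin * mask
        } else xin
      },
      concat = concatChannels(xin),
      softmax = softmaxProbs(xin),
      pixelclass = xin,
      stop(sprintf("unknown layer kind '%s'", ly$kind)))
  }
  probs <- acts[["pixelclass"]]
  if (!returnCache) return(probs)
  list(probs = probs, acts = acts, cache = cache, params = params)
}

# mean per-pixel cross-entropy of the softmax probabilities against a
# binary target stack (H, W, N); returns loss and the gradient at the
# softmax *input* (logits), already divided by the pixel count
lossAndLogitGrad <- function(probs, targets) {
  d <- dim(probs)
  npix <- d[1L] * d[2L] * d[4L]
  tgt <- asBatch(targets)  # (H, W, 1, N)
  pl <- probs[, , 2L, , drop = FALSE]
  pb <- probs[, , 1L, , drop = FALSE]
  eps <- 1e-12
  loss <- -sum(tgt * log(pl + eps) + (1 - tgt) * log(pb + eps)) / npix
  dlogits <- array(0, d)
  dlogits[, , 1L, ] <- (pb - (1 - tgt)) / npix
  dlogits[, , 2L, ] <- (pl - tgt) / npix
  list(loss = loss, dlogits = dlogits)
}

# Backward pass. `fw` is the list returned by forwardPass(returnCache =
# TRUE); `dlogits` is the gradient at the softmax input. Returns a
# parameter-gradient store congruent with the trainable entries of
# `params`.
backwardPass <- function(g, params, fw, dlogits) {
  ord <- rev(topoSort(g))
  grads <- list()
  dacts <- list()
  addGrad <- function(name, d) {
    if (is.null(dacts[[name]])) dacts[[name]] <<- d
    else dacts[[name]] <<- dacts[[name]] + d
  }
  dacts[["softmax"]] <- dlogits   # combined softmax + cross-entropy grad
  for (nd in ord) {
    if (nd %in% c("input", "pixelclass")) next
    ly <- g@layers[[nd]]
    dy <- dacts[[nd]]
    if (is.null(dy)) next
    pre <- predecessors(g, nd)
    xin <- if (ly$kind == "concat") NULL else fw$acts[[pre[1L]]]
    p <- params[[nd]]
    switch(ly$kind,
      conv = {
        cols <- fw$cache[[nd]]$cols
        r <- cpp_conv_bwd(xin, p$W, dy, ly$stride, ly$pad, cols)
        grads[[nd]] <- list(W = r$dw, b = r$db)
        addGrad(pre[1L], r$dx)
      },
      deconv = {
        r <- cpp_deconv_bwd(xin, p$W, dy, ly$stride, ly$pad)
        grads[[nd]] <- list(W = r$dw, b = r$db)
        addGrad(pre[1L], r$dx)
      },
      batchnorm = {
        cb <- fw$cache[[nd]]
        r <- cpp_bn_bwd(xin, p$gamma, cb$mean, cb$invstd, dy)
        grads[[nd]] <- list(gamma = r$dgamma, beta = r$dbeta)
        addGrad(pre[1L], r$dx)
      },
      relu = addGrad(pre[1L], cpp_relu_bwd(xin, dy)),
      maxpool = {
        cb <- fw$cache[[nd]]
        addGrad(pre[1L], cpp_maxpool_bwd(cb$idx, dy, cb$xdim))
      },
      dropout = {
        cb <- fw$cache[[nd]]
        addGrad(pre[1L], if (is.null(cb)) dy else dy * cb$mask)
      },
      concat = {
        at <- 0L
        for (src in ly$inputs) {
          ch <- dim(fw$acts[[src]])[3L]
          addGrad(src, dy[, , (at + 1L):(at + ch), , drop = FALSE])
          at <- at + ch
        }
      },
      softmax = addGrad(pre[1L], dy),  # dy already w.r.t. logits
      stop(sprintf("no backward rule for layer kind '%s'", ly$kind)))
    dacts[[nd]] <- NULL  # free as we go
  }
  grads
}

# Compile a LayerGraph into the compact integer descriptor interpreted by
# the single-precision C++ training engine. Slot 0 is the input; each
# processing layer writes one activation slot. The softmax and
# pixel-classification layers are not materialized: the engine computes
# softmax + cross-entropy jointly on the logits slot (the layer feeding
# softmax), which is both faster and numerically safer.
engineDesc <- function(g) {
  ord <- topoSort(g)
  kinds <- vapply(g@layers, `[[`, "", "kind")
  keep <- ord[!(kinds[ord] %in% c("input", "softmax", "pixelclass"))]
  slot <- stats::setNames(seq_along(keep), keep)
  slot[["input"]] <- 0L
  code <- c(conv = 1L, deconv = 2L, batchnorm = 3L, relu = 4L,
            maxpool = 5L, dropout = 6L, concat = 7L)
  layers <- lapply(keep, function(nm) {
    ly <- g@layers[[nm]]
    ins <- if (ly$kind == "concat") ly$inputs else predecessors(g, nm)[1L]
    fld <- function(f, def) if (is.null(ly[[f]])) def else ly[[f]]
    list(kind = unname(code[ly$kind]),
         in_ = unname(slot[ins]),
         out = unname(slot[nm]),
         k = fld("k", 0L), stride = fld("stride", 0L), pad = fld("pad", 0L),
         inCh = fld("inCh", 0L), outCh = fld("outCh", 0L),
         ratio = fld("ratio", 0))
  })
  layers <- lapply(layers, function(l) {
    names(l)[names(l) == "in_"] <- "in"
    l
  })
  logits <- predecessors(g, "softmax")[1L]
  list(layers = layers, names = keep, nSlots = length(keep) + 1L,
       side = g@inputSide, logitsSlot = unname(slot[logits]))
}

makeEngine <- function(g, params, cfg) {
  desc <- engineDesc(g)
  pars <- lapply(desc$names, function(nm) params[[nm]])
  ptr <- cpp_engine_create(desc, pars, cfg@learningRate, cfg@momentum,
                           BN_MOMENTUM, BN_EPS)
  list(ptr = ptr, desc = desc)
}

# pull trained parameters out of the engine back into the R store,
# restoring array dimensions
extractEngineParams <- function(eng, params) {
  flat <- cpp_engine_params(eng$ptr)
  for (i in seq_along(eng$desc$names)) {
    nm <- eng$desc$names[i]
    p <- flat[[i]]
    if (is.null(p)) next
    for (f in names(p)) {
      v <- p[[f]]
      dim(v) <- dim(params[[nm]][[f]])
      params[[nm]][[f]] <- v
    }
  }
  params
}
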