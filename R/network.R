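# Layer-graph construction for the three segmentation architectures.
#
# CNN1 (series): (Conv-BN-ReLU x2 - MaxPool) x3  ->  Conv-BN-ReLU x2  ->
#   Deconv-BN-ReLU-Conv-BN-ReLU-Dropout  ->  (Deconv-BN-ReLU-Conv-BN-ReLU) x2
#   ->  MaxPool(stride 1, size-preserving)  ->  Conv2(1x1)-BN-ReLU  ->
#   Softmax  ->  PixelClassification.
# All 3x3 convolutions use stride 1 / padding 1 and `width` feature maps;
# the last convolution is 1x1 with 2 feature maps (background, lesion).
# Deconvolutions are 4x4, stride 2, each exactly doubling the spatial size.
#
# CNN2 adds one skip path tapping the first encoder module after its second
# ReLU, down-sampled by two MaxPool + Conv-BN-ReLU steps to the resolution
# after the first deconvolution, where it is depth-concatenated into the
# main path (9 extra layers: 61 total).
#
# CNN3 adds three skip paths tapping each encoder module after its second
# conv's ReLU, resampled to full resolution (a Deconv followed by
# Conv-BN-ReLU per 2x step; a Conv-BN-ReLU adapter for the native-scale
# branch) and depth-concatenated just before the final 1x1 convolution
# (16 extra layers: 68 total).

convLayer <- function(name, k, inCh, outCh) {
  list(name = name, kind = "conv", k = as.integer(k),
       stride = 1L, pad = as.integer((k - 1) / 2),
       inCh = as.integer(inCh), outCh = as.integer(outCh))
}
deconvLayer <- function(name, inCh, outCh)
  list(name = name, kind = "deconv", k = 4L, stride = 2L, pad = 1L,
       inCh = as.integer(inCh), outCh = as.integer(outCh))
bnLayer <- function(name, ch)
  list(name = name, kind = "batchnorm", ch = as.integer(ch))
reluLayer <- function(name) list(name = name, kind = "relu")
poolLayer <- function(name, stride)
  list(name = name, kind = "maxpool", k = 2L, stride = as.integer(stride))
dropLayer <- function(name, ratio = 0.5)
  list(name = name, kind = "dropout", ratio = ratio)
concatLayer <- function(name, inputs)
  list(name = name, kind = "concat", inputs = inputs)

# append a chain of layers connected in series after `after`; returns the
# builder state
chain <- function(st, layers, after = NULL) {
  prev <- if (is.null(after)) st$tail else after
  for (ly in layers) {
    st$layers[[ly$name]] <- ly
    st$edges <- rbind(st$edges,
                      data.frame(from = prev, to = ly$name,
                                 stringsAsFactors = FALSE))
    prev <- ly$name
  }
  st$tail <- prev
  st
}

convBlock <- function(prefix, inCh, outCh, w) {
  list(convLayer(paste0(prefix, "_conv"), 3L, inCh, outCh),
       bnLayer(paste0(prefix, "_bn"), outCh),
       reluLayer(paste0(prefix, "_relu")))
}

#' Build one of the three segmentation architectures
#'
#' Constructs the layer graph of the series architecture `CNN1` or the
#' DAG architectures `CNN2` / `CNN3` (skip aggregation by depth
#' concatenation) for a square single-channel input.
#'
#' @param variant `"CNN1"`, `"CNN2"` or `"CNN3"`.
#' @param inputSide input image side in pixels, divisible by 8 (the
#'   encoder halves the resolution three times; 160 maps to a 20x20
#'   bottleneck).
#' @param width number of feature maps of the main-path convolutions
#'   (default 64; >= 2).
#' @return a validated [LayerGraph-class].
#' @examples
#' g <- buildNetwork("CNN1", 160)
#' countLayers(g)  # 52
#' @export
buildNetwork <- function(variant = c("CNN1", "CNN2", "CNN3"),
                         inputSide, width = 64L) {
  variant <- match.arg(variant)
  if (!isCount(inputSide) || inputSide <= 0 || inputSide %% 8 != 0)
    stop("inputSide must be a positive multiple of 8")
  if (!isCount(width) || width < 2) stop("width must be an integer >= 2")
  w <- as.integer(width)

  st <- list(layers = list(input = list(name = "input", kind = "input", ch = 1L)),
             edges = data.frame(from = character(), to = character(),
                                stringsAsFactors = FALSE),
             tail = "input")

  # encoder: three sub-sampling modules
  for (m in 1:3) {
    inCh <- if (m == 1L) 1L else w
    st <- chain(st, convBlock(sprintf("enc%d_1", m), inCh, w, w))
    st <- chain(st, convBlock(sprintf("enc%d_2", m), w, w, w))
    st <- chain(st, list(poolLayer(sprintf("enc%d_pool", m), 2L)))
  }
  # bottleneck convolutions
  st <- chain(st, convBlock("bott_1", w, w, w))
  st <- chain(st, convBlock("bott_2", w, w, w))

  # decoder: three up-sampling modules; dropout after the first pair
  dec1ConvIn <- if (variant == "CNN2") 2L * w else w
  st <- chain(st, list(deconvLayer("dec1_deconv", w, w),
                       bnLayer("dec1_bnd", w), reluLayer("dec1_relud")))
  if (variant == "CNN2") {
    # skip branch: tap after the first module's second ReLU, two
    # MaxPool + Conv-BN-ReLU steps down to the post-deconv resolution
    st <- chain(st, list(poolLayer("skip_pool1", 2L)), after = "enc1_2_relu")
    st <- chain(st, convBlock("skip_1", w, w, w))
    st <- chain(st, list(poolLayer("skip_pool2", 2L)))
    st <- chain(st, convBlock("skip_2", w, w, w))
    cc <- concatLayer("skip_concat", c("dec1_relud", "skip_2_relu"))
    st$layers[[cc$name]] <- cc
    st$edges <- rbind(st$edges,
                      data.frame(from = cc$inputs, to = cc$name,
                                 stringsAsFactors = FALSE))
    st$tail <- cc$name
  }
  st <- chain(st, list(convLayer("dec1_conv", 3L, dec1ConvIn, w),
                       bnLayer("dec1_bnc", w), reluLayer("dec1_reluc"),
                       dropLayer("dec1_drop")))
  for (m in 2:3) {
    st <- chain(st, list(deconvLayer(sprintf("dec%d_deconv", m), w, w),
                         bnLayer(sprintf("dec%d_bnd", m), w),
                         reluLayer(sprintf("dec%d_relud", m)),
                         convLayer(sprintf("dec%d_conv", m), 3L, w, w),
                         bnLayer(sprintf("dec%d_bnc", m), w),
                         reluLayer(sprintf("dec%d_reluc", m))))
  }

  # final size-preserving pooling
  st <- chain(st, list(poolLayer("final_pool", 1L)))

  finalConvIn <- w
  if (variant == "CNN3") {
    # three aggregation branches tapped after each encoder module's
    # second conv (its ReLU output), resampled to full resolution
    st <- chain(st, convBlock("agg1", w, w, w), after = "enc1_2_relu")
    st <- chain(st, list(deconvLayer("agg2_deconv", w, w)), after = "enc2_2_relu")
    st <- chain(st, convBlock("agg2", w, w, w))
    st <- chain(st, list(deconvLayer("agg3_deconv1", w, w)), after = "enc3_2_relu")
    st <- chain(st, convBlock("agg3_1", w, w, w))
    st <- chain(st, list(deconvLayer("agg3_deconv2", w, w)))
    st <- chain(st, convBlock("agg3_2", w, w, w))
    cc <- concatLayer("agg_concat",
                      c("final_pool", "agg1_relu", "agg2_relu", "agg3_2_relu"))
    st$layers[[cc$name]] <- cc
    st$edges <- rbind(st$edges,
                      data.frame(from = cc$inputs, to = cc$name,
                                 stringsAsFactors = FALSE))
    st$tail <- cc$name
    finalConvIn <- 4L * w
  }

  st <- chain(st, list(convLayer("final_conv", 1L, finalConvIn, 2L),
                       bnLayer("final_bn", 2L), reluLayer("final_relu"),
                       list(name = "softmax", kind = "softmax"),
                       list(name = "pixelclass", kind = "pixelclass")))

  g <- new("LayerGraph", variant = variant, inputSide = as.integer(inputSide),
           width = w, layers = st$layers, edges = st$edges)
  inferShapes(g)  # raises if any aggregation inputs disagree in size
  g
}

#' Count processing layers of a graph
#'
#' Counts every processing layer (conv, batchnorm, relu, maxpool, deconv,
#' dropout, concat, softmax, pixel-classification), excluding the data
#' input layer. The three stock variants count 52, 61 and 68 layers.
#'
#' @param g a [LayerGraph-class].
#' @return integer layer count.
#' @export
countLayers <- function(g) {
  if (length(g@layers) == 0L) return(0L)
  kinds <- vapply(g@layers, `[[`, "", "kind")
  sum(kinds != "input")
}

# topological order of layer names; errors on cycles
topoSort <- function(g) {
  names_ <- names(g@layers)
  indeg <- stats::setNames(integer(length(names_)), names_)
  for (to in g@edges$to) indeg[to] <- indeg[to] + 1L
  out <- character(0)
  ready <- names_[indeg == 0L]
  edges <- g@edges
  while (length(ready)) {
    nd <- ready[1L]
    ready <- ready[-1L]
    out <- c(out, nd)
    succ <- edges$to[edges$from == nd]
    for (s in succ) {
      indeg[s] <- indeg[s] - 1L
      if (indeg[s] == 0L) ready <- c(ready, s)
    }
  }
  if (length(out) != length(names_)) stop("graph has a cycle")
  out
}

predecessors <- function(g, name) g@edges$from[g@edges$to == name]

#' Count distinct input-to-sink paths
#'
#' A series graph has exactly one; the DAG variants have several
#' (CNN2: 2, CNN3: 4).
#'
#' @param g a [LayerGraph-class].
#' @return number of distinct directed paths from the input layer to the
#'   pixel-classification sink.
#' @export
countPaths <- function(g) {
  ord <- topoSort(g)
  npath <- stats::setNames(numeric(length(ord)), ord)
  npath["input"] <- 1
  for (nd in ord) {
    if (nd == "input") next
    pre <- predecessors(g, nd)
    npath[nd] <- sum(npath[pre])
  }
  unname(npath["pixelclass"])
}

#' Symbolic shape propagation
#'
#' Propagates (side, channels) from the input through the graph,
#' checking that every concatenation joins inputs of identical spatial
#' size and that the output side equals the input side.
#'
#' @param g a [LayerGraph-class].
#' @return named list mapping layer name to `c(side, channels)`.
#' @export
inferShapes <- function(g) {
  ord <- topoSort(g)
  shapes <- list(input = c(g@inputSide, 1L))
  for (nd in ord) {
    if (nd == "input") next
    ly <- g@layers[[nd]]
    pre <- predecessors(g, nd)
    ins <- shapes[pre]
    s <- ins[[1L]]
    shapes[[nd]] <- switch(ly$kind,
      conv = {
        if (s[2L] != ly$inCh)
          stop(sprintf("layer %s: expected %d input channels, got %d",
                       nd, ly$inCh, s[2L]))
        c(s[1L], ly$outCh)
      },
      deconv = {
        if (s[2L] != ly$inCh)
          stop(sprintf("layer %s: expected %d input channels, got %d",
                       nd, ly$inCh, s[2L]))
        c(2L * s[1L], ly$outCh)
      },
      maxpool = if (ly$stride == 2L) c(s[1L] %/% 2L, s[2L]) else s,
      concat = {
        sides <- vapply(ins, `[[`, 0L, 1L)
        if (length(unique(sides)) != 1L)
          stop(sprintf("concat %s joins inputs of unequal spatial size (%s)",
                       nd, paste(sides, collapse = ", ")))
        # honour the declared input order
        ins <- shapes[ly$inputs]
        c(unname(sides[1L]), sum(vapply(ins, `[[`, 0L, 2L)))
      },
      s)  # batchnorm, relu, dropout, softmax, pixelclass preserve shape
  }
  if (shapes[["pixelclass"]][1L] != g@inputSide)
    stop("output spatial size does not match the input")
  shapes
}

#' Serialize a layer graph to JSON
#'
#' Versioned plain-text description (layers, edges, hyperparameters)
#' suitable for archiving a run.
#'
#' @param g a [LayerGraph-class].
#' @param path optional file to write to.
#' @return the JSON string, invisibly when `path` is given.
#' @export
serializeGraph <- function(g, path = NULL) {
  obj <- list(format = "busseg-graph", version = 1L,
              variant = g@variant, inputSide = g@inputSide, width = g@width,
              layers = unname(g@layers), edges = g@edges)
  js <- jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  if (!is.null(path)) {
    writeLines(js, path)
    return(invisible(js))
  }
  js
}

#' Tabular description of a graph
#'
#' @param g a [LayerGraph-class].
#' @return data.frame with one row per layer in topological order.
#' @export
describeNetwork <- function(g) {
  ord <- topoSort(g)
  shapes <- inferShapes(g)
  do.call(rbind, lapply(ord, function(nm) {
    ly <- g@layers[[nm]]
    data.frame(name = nm, kind = ly$kind,
               kernel = if (is.null(ly[["k"]])) NA_integer_ else ly[["k"]],
               stride = if (is.null(ly[["stride"]])) NA_integer_ else ly[["stride"]],
               outSide = shapes[[nm]][1L], outChannels = shapes[[nm]][2L],
               stringsAsFactors = FALSE)
  }))
}
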