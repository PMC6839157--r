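# internal helpers shared across modules

# Run code with a temporary RNG state seeded at `seed`; the caller's
# .Random.seed is restored afterwards so library calls never perturb
# user-level reproducibility.
withSeed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(code)
}

# Splitmix-style per-item seed derivation: decorrelates item streams from a
# single master seed, independent of generation order. Kept below 2^31 so
# the result is always a valid R integer seed.
deriveSeed <- function(masterSeed, index, stream = 0L) {
  m <- 2147483629
  s <- (as.numeric(masterSeed) %% m)
  x <- (s * 48271 + as.numeric(index) * 2654435761 + as.numeric(stream) * 40503) %% m
  as.integer((x * 69621 + 12345) %% m)
}

# promote a matrix / 3-d array to the engine's (H, W, C, N) layout
asBatch <- function(x) {
  if (is.matrix(x)) {
    dim(x) <- c(dim(x), 1L, 1L)
    return(x)
  }
  d <- dim(x)
  if (length(d) == 3L) {     # (H, W, N) single-channel stack
    dim(x) <- c(d[1L], d[2L], 1L, d[3L])
    return(x)
  }
  if (length(d) == 4L) return(x)
  stop("expected a matrix or a 3-/4-d array")
}

# stack a list of equally-sized matrices into (H, W, 1, N)
stackImages <- function(imgs) {
  d <- dim(imgs[[1L]])
  out <- array(0, c(d[1L], d[2L], 1L, length(imgs)))
  for (i in seq_along(imgs)) out[, , 1L, i] <- imgs[[i]]
  out
}

checkBinaryMask <- function(m, arg = "mask") {
  if (!all(dim(m) > 0L)) stop(sprintf("%s has zero extent", arg))
  v <- unique(as.vector(m))
  if (!all(v %in% c(0, 1)))
    stop(sprintf("%s contains labels outside {0, 1}", arg))
  invisible(TRUE)
}

isCount <- function(x) length(x) == 1L && is.numeric(x) && is.finite(x) &&
  x == round(x)
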