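# Synthetic breast-ultrasound phantom generator.
#
# Real BUS images show hypoechoic (darker-than-background) lesions embedded
# in multiplicative speckle; benign lesions present smooth elliptical
# outlines while malignant ones show irregular, spiculated, angulated
# margins. The generator emulates exactly that morphological contrast so
# the segmentation pipeline can be exercised end to end without clinical
# data.

#' Create a lesion specification
#'
#' Convenience constructor for [LesionSpec-class]. When `harmonics` is
#' `NULL`, a mild order-2 perturbation (an ellipse-like elongation) is
#' used.
#'
#' @param kind `"benign"` or `"malignant"`.
#' @param center fractional (x, y) centre coordinates.
#' @param baseRadius base radius as a fraction of the image side, in
#'   (0.05, 0.35).
#' @param harmonics matrix (or vector coercible to a 3-column matrix) of
#'   radial perturbation terms `(order, amplitude, phase)`.
#' @param nSpicules number of spicules; malignant lesions require >= 4,
#'   benign must have 0.
#' @param spiculeLength spicule height as a fraction of `baseRadius`.
#' @param seed integer seed controlling spicule placement.
#' @return a validated [LesionSpec-class] object.
#' @examples
#' lesionSpec("malignant", nSpicules = 6, spiculeLength = 0.5)
#' @export
lesionSpec <- function(kind = c("benign", "malignant"),
                       center = c(0.5, 0.5), baseRadius = 0.15,
                       harmonics = NULL,
                       nSpicules = if (kind == "malignant") 6L else 0L,
                       spiculeLength = 0.5, seed = 1L) {
  kind <- match.arg(kind)
  if (is.null(harmonics))
    harmonics <- matrix(c(2, 0.05 * baseRadius, 0), nrow = 1L)
  if (!is.matrix(harmonics)) harmonics <- matrix(harmonics, ncol = 3L, byrow = TRUE)
  colnames(harmonics) <- c("order", "amplitude", "phase")
  new("LesionSpec", kind = kind, center = as.numeric(center),
      baseRadius = as.numeric(baseRadius), harmonics = harmonics,
      nSpicules = as.integer(nSpicules),
      spiculeLength = as.numeric(spiculeLength), seed = as.integer(seed))
}

#' Create speckle rendering parameters
#'
#' @param contrast lesion-to-background mean intensity ratio in (0, 1).
#' @param speckleScale multiplicative speckle dispersion (>= 0; 0 gives a
#'   noise-free two-level image).
#' @param blurSigma Gaussian blur sigma in pixels.
#' @param seed integer noise seed.
#' @return a validated [SpeckleParams-class] object.
#' @export
speckleParams <- function(contrast = 0.5, speckleScale = 0.3,
                          blurSigma = 1, seed = 1L) {
  new("SpeckleParams", contrast = as.numeric(contrast),
      speckleScale = as.numeric(speckleScale),
      blurSigma = as.numeric(blurSigma), seed = as.integer(seed))
}

# angular width (radians) of a spicule bump; narrow so spikes rasterize as
# thin radial projections that cut the mask's solidity
SPICULE_SIGMA <- 0.07

# Gaussian blur whose brush never exceeds the image extent (EBImage
# requires filter dimensions <= image dimensions)
gblurSafe <- function(x, sigma) {
  radius <- 2L * as.integer(ceiling(3 * sigma)) + 1L
  cap <- min(dim(x))
  if (radius > cap) radius <- cap - (1L - cap %% 2L)  # largest odd <= cap
  EBImage::gblur(x, sigma = sigma, radius = radius)
}

#' Sample a closed lesion contour
#'
#' Evaluates the radial contour \eqn{r(\theta) = r_0 + \sum_j a_j
#' \cos(k_j\theta + \phi_j) + r_0\,s\sum_m \exp(-\Delta_m(\theta)^2 /
#' 2\sigma^2)} on a dense angle grid including both endpoints, so
#' `r[1] == r[length(r)]` (periodicity). Spicule angles are drawn from the
#' spec's seed; the same spec always yields the identical contour.
#'
#' @param spec a [LesionSpec-class].
#' @param nTheta number of angular intervals (the grid has `nTheta + 1`
#'   samples spanning \eqn{[0, 2\pi]}).
#' @return list with `theta`, `radius`, and fractional image coordinates
#'   `x`, `y`.
#' @export
makeLesionContour <- function(spec, nTheta = 720L) {
  validObject(spec)
  theta <- seq(0, 2 * pi, length.out = nTheta + 1L)
  r <- rep(spec@baseRadius, length(theta))
  h <- spec@harmonics
  for (i in seq_len(nrow(h)))
    r <- r + h[i, 2L] * cos(h[i, 1L] * theta + h[i, 3L])
  if (spec@nSpicules > 0L) {
    ang <- withSeed(spec@seed, sort(stats::runif(spec@nSpicules, 0, 2 * pi)))
    amp <- spec@spiculeLength * spec@baseRadius
    for (a in ang) {
      d <- abs(theta - a)
      d <- pmin(d, 2 * pi - d)          # wrap-around angular distance
      r <- r + amp * exp(-0.5 * (d / SPICULE_SIGMA)^2)
    }
  }
  if (any(r <= 0)) stop("contour radius must stay positive")
  list(theta = theta,
       radius = r,
       x = spec@center[1L] + r * cos(theta),
       y = spec@center[2L] + r * sin(theta))
}

#' Rasterize a contour into a binary mask
#'
#' The contour is star-shaped around its centre, so a pixel is inside iff
#' its distance to the centre is below the (interpolated) contour radius
#' at its angle. Pixel centres sit at `(i - 0.5)/side` in fractional
#' coordinates; rows index y and columns x.
#'
#' @param contour output of [makeLesionContour()].
#' @param side image side in pixels (a positive even integer; the study
#'   sides are 160 and 320).
#' @return an integer `side x side` matrix over \{0, 1\}.
#' @export
rasterizeMask <- function(contour, side) {
  stopifnot(isCount(side), side > 0, side %% 2 == 0)
  if (min(contour$x) < 0 || max(contour$x) > 1 ||
      min(contour$y) < 0 || max(contour$y) > 1)
    stop("contour extends outside the image bounds")
  # recover the generating centre exactly from the first contour sample
  cx <- contour$x[1L] - contour$radius[1L] * cos(contour$theta[1L])
  cy <- contour$y[1L] - contour$radius[1L] * sin(contour$theta[1L])
  px <- (matrix(rep(seq_len(side), each = side), side) - 0.5) / side  # columns -> x
  py <- (matrix(rep(seq_len(side), times = side), side) - 0.5) / side # rows -> y
  dx <- px - cx
  dy <- py - cy
  ang <- atan2(dy, dx) %% (2 * pi)
  rad <- stats::approx(contour$theta, contour$radius, xout = ang,
                       rule = 2)$y
  mask <- matrix(as.integer(sqrt(dx * dx + dy * dy) < rad), side, side)
  if (sum(mask) == 0L)
    stop("degenerate contour: rasterization produced an empty mask")
  mask
}

#' Render a speckled ultrasound-like image from a mask
#'
#' Builds a piecewise-constant scene (background level 0.55, lesion level
#' `0.55 * contrast`, hence hypoechoic), adds a Gaussian-blurred
#' background texture whose amplitude scales with `speckleScale`,
#' multiplies by gamma-distributed speckle with mean 1 and shape
#' `1/speckleScale^2` (the fully-developed-speckle approximation), applies
#' Gaussian blur and clips to [0, 1]. With `speckleScale = 0` and
#' `blurSigma = 0` the output is exactly the two-level clean scene.
#'
#' @param mask binary lesion mask.
#' @param sp a [SpeckleParams-class].
#' @return numeric matrix in [0, 1] of the same shape as `mask`.
#' @export
renderImage <- function(mask, sp) {
  validObject(sp)
  checkBinaryMask(mask)
  bg <- 0.55
  clean <- matrix(bg, nrow(mask), ncol(mask))
  clean[mask == 1L] <- bg * sp@contrast
  img <- withSeed(sp@seed, {
    out <- clean
    if (sp@speckleScale > 0) {
      # coarse background texture (tissue inhomogeneity), then speckle
      tex <- matrix(stats::rnorm(length(mask)), nrow(mask))
      tex <- gblurSafe(tex, sigma = 3)
      tex <- tex / max(stats::sd(tex), 1e-12)
      out <- out * (1 + 0.2 * sp@speckleScale * tex)
      shape <- 1 / sp@speckleScale^2
      noise <- matrix(stats::rgamma(length(mask), shape = shape, rate = shape),
                      nrow(mask))
      out <- out * noise
    }
    out
  })
  if (sp@blurSigma > 0) img <- gblurSafe(img, sigma = sp@blurSigma)
  img[img < 0] <- 0
  img[img > 1] <- 1
  unname(img)
}

#' Solidity of a binary mask
#'
#' Area divided by convex-hull area of the lesion pixels. Spiculated
#' (malignant-like) shapes have lower solidity than smooth elliptical
#' (benign-like) ones.
#'
#' @param mask binary mask with at least 3 lesion pixels.
#' @return solidity in (0, 1].
#' @export
maskSolidity <- function(mask) {
  checkBinaryMask(mask)
  idx <- which(mask == 1L, arr.ind = TRUE)
  if (nrow(idx) < 3L) stop("mask needs at least 3 lesion pixels")
  pts <- cbind(idx[, 2L], idx[, 1L])  # (x, y)
  hull <- grDevices::chull(pts)
  hx <- pts[hull, 1L]; hy <- pts[hull, 2L]
  n <- length(hull)
  area <- abs(sum(hx * hy[c(2:n, 1L)] - hx[c(2:n, 1L)] * hy)) / 2
  # hull through pixel centres slightly undercuts the pixelated region;
  # guard against solidity marginally above 1 for convex shapes
  min(nrow(idx) / max(area, 1), 1)
}

# Draw per-item lesion/speckle parameters from a derived seed. Defaults
# (documented in the methods vignette) emulate mid-sized lesions covering
# roughly 3-10% of the image.
randomLesionSpec <- function(kind, seed) {
  withSeed(seed, {
    center <- stats::runif(2, 0.42, 0.58)
    r0 <- stats::runif(1, 0.10, 0.18)
    if (kind == "benign") {
      h <- rbind(c(2, stats::runif(1, 0.02, 0.08) * r0, stats::runif(1, 0, 2 * pi)),
                 c(3, stats::runif(1, 0, 0.02) * r0, stats::runif(1, 0, 2 * pi)))
      lesionSpec("benign", center = center, baseRadius = r0, harmonics = h,
                 seed = seed)
    } else {
      orders <- sample(5:9, 3L)
      h <- rbind(c(2, stats::runif(1, 0.03, 0.10) * r0, stats::runif(1, 0, 2 * pi)),
                 cbind(orders, stats::runif(3, 0.02, 0.06) * r0,
                       stats::runif(3, 0, 2 * pi)))
      lesionSpec("malignant", center = center, baseRadius = r0, harmonics = h,
                 nSpicules = sample(4:8, 1L),
                 spiculeLength = stats::runif(1, 0.3, 0.6), seed = seed)
    }
  })
}

#' Generate a seeded synthetic BUS dataset
#'
#' Produces `n` image/mask/label records with a benign:malignant mix set
#' by `malignantFraction` (default 179/387, the class balance of a
#' representative clinical BUS collection). Per-item seeds are derived
#' deterministically from `masterSeed`, so the same call always
#' reproduces the same dataset, item by item.
#'
#' @param n number of items (>= 2).
#' @param malignantFraction fraction of malignant items in [0, 1];
#'   exactly `round(n * malignantFraction)` items are malignant.
#' @param side image side in pixels.
#' @param masterSeed integer master seed.
#' @param contrast,speckleScale,blurSigma rendering parameters passed to
#'   [speckleParams()].
#' @return list of records, each with elements `image`, `mask`, `label`,
#'   `spec`, `seed`.
#' @examples
#' ds <- generateDataset(4, side = 64, masterSeed = 7)
#' table(vapply(ds, `[[`, "", "label"))
#' @export
generateDataset <- function(n, malignantFraction = 179 / 387, side = 160L,
                            masterSeed = 1L, contrast = 0.5,
                            speckleScale = 0.3, blurSigma = 1) {
  if (!isCount(n) || n < 2) stop("n must be an integer >= 2")
  if (malignantFraction < 0 || malignantFraction > 1)
    stop("malignantFraction must lie in [0, 1]")
  nMal <- round(n * malignantFraction)
  labels <- c(rep("malignant", nMal), rep("benign", n - nMal))
  labels <- withSeed(deriveSeed(masterSeed, 0L), sample(labels))
  lapply(seq_len(n), function(i) {
    itemSeed <- deriveSeed(masterSeed, i)
    spec <- randomLesionSpec(labels[i], itemSeed)
    mask <- rasterizeMask(makeLesionContour(spec), side)
    img <- renderImage(mask, speckleParams(contrast, speckleScale, blurSigma,
                                           seed = deriveSeed(masterSeed, i, 1L)))
    list(image = img, mask = mask, label = labels[i], spec = spec,
         seed = itemSeed)
  })
}

#' Write a dataset to disk as PNG pairs plus a CSV manifest
#'
#' Images and masks are written as 8-bit grayscale PNGs
#' (`img_00001.png`, `msk_00001.png`, ...); masks store lesion pixels as
#' 255. The manifest lists filenames, labels, seeds and lesion
#' parameters.
#'
#' @param dataset output of [generateDataset()].
#' @param dir output directory (created if needed).
#' @return the manifest data.frame, invisibly.
#' @export
writeDataset <- function(dataset, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(dir)) stop(sprintf("cannot create output directory '%s'", dir))
  rows <- lapply(seq_along(dataset), function(i) {
    it <- dataset[[i]]
    imgFile <- sprintf("img_%05d.png", i)
    mskFile <- sprintf("msk_%05d.png", i)
    writeGrayPNG(it$image, file.path(dir, imgFile))
    writeGrayPNG(it$mask, file.path(dir, mskFile))
    s <- it$spec
    data.frame(image = imgFile, mask = mskFile, label = it$label,
               seed = it$seed, center_x = s@center[1L], center_y = s@center[2L],
               base_radius = s@baseRadius, n_spicules = s@nSpicules,
               spicule_length = s@spiculeLength, stringsAsFactors = FALSE)
  })
  manifest <- do.call(rbind, rows)
  utils::write.csv(manifest, file.path(dir, "manifest.csv"), row.names = FALSE)
  invisible(manifest)
}
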