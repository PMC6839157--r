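# Image/mask I/O, resizing, and run-artifact persistence.
#
# Conventions: pixels are row-major with rows indexing y; masks are
# stored as 8-bit PNG with 255 = lesion and any nonzero value is read
# back as lesion, which is robust to external annotation conventions.

# EBImage stores images (x, y) = (width, height); the package works in
# matrix (row, col) = (y, x) order, so reads and writes transpose.
ebToMatrix <- function(img) {
  d <- EBImage::imageData(img)
  if (length(dim(d)) == 3L) d <- apply(d, c(1L, 2L), mean)  # collapse channels
  t(d)
}

matrixToEb <- function(m) EBImage::Image(t(m))

writeGrayPNG <- function(m, path) {
  EBImage::writeImage(matrixToEb(pmin(pmax(m, 0), 1)), path, type = "png",
                      bits.per.sample = 8L)
}

#' Load and resize an image/mask pair
#'
#' The image is resized with bilinear interpolation and rescaled to
#' [0, 1]; the mask is thresholded at > 0 and resized with
#' nearest-neighbour interpolation so labels stay binary. When the input
#' is already at the target side the mask passes through pixel-identical.
#'
#' @param imagePath grayscale image file (PNG/TIFF).
#' @param maskPath binary mask file (any nonzero pixel = lesion).
#' @param side target side in pixels (the study uses 160 or 320).
#' @param centerCrop optional fraction in (0, 1]: before resizing, keep
#'   only the central `centerCrop` portion of each dimension (both image
#'   and mask). Useful for external images whose borders carry burnt-in
#'   annotations.
#' @return list with `image` (numeric matrix in [0, 1]) and `mask`
#'   (integer matrix over \{0, 1\}), both `side x side`.
#' @export
loadAndResize <- function(imagePath, maskPath, side, centerCrop = NULL) {
  if (!file.exists(imagePath)) stop(sprintf("image file '%s' not found", imagePath))
  if (!file.exists(maskPath)) stop(sprintf("mask file '%s' not found", maskPath))
  img <- ebToMatrix(EBImage::readImage(imagePath))
  msk <- ebToMatrix(EBImage::readImage(maskPath))
  if (!is.null(centerCrop)) {
    if (centerCrop <= 0 || centerCrop > 1) stop("centerCrop must lie in (0, 1]")
    cropIdx <- function(n) {
      keep <- max(1L, round(n * centerCrop))
      off <- (n - keep) %/% 2L
      off + seq_len(keep)
    }
    img <- img[cropIdx(nrow(img)), cropIdx(ncol(img)), drop = FALSE]
    msk <- msk[cropIdx(nrow(msk)), cropIdx(ncol(msk)), drop = FALSE]
  }
  if (max(img) > 1) img <- img / max(img)
  img[img < 0] <- 0
  msk <- (msk > 0) + 0L
  if (sum(msk) == 0L) stop(sprintf("mask '%s' is empty after thresholding", maskPath))
  if (!all(dim(img) == side)) {
    img <- ebToMatrix(EBImage::resize(matrixToEb(img), w = side, h = side))
    img <- pmin(pmax(img, 0), 1)
  }
  if (!all(dim(msk) == side)) {
    msk <- ebToMatrix(EBImage::resize(matrixToEb(msk), w = side, h = side,
                                      filter = "none"))
    msk <- (msk > 0) + 0L
  }
  storage.mode(msk) <- "integer"
  list(image = img, mask = msk)
}

#' Persist the artifacts of a run
#'
#' Writes the dataset manifest, the resolved configuration, metric
#' reports, loss traces and a plain-text log (seeds, versions) into a
#' run directory. Re-running with the same configuration and seeds
#' reproduces all CSV numbers byte for byte.
#'
#' @param runDir output directory (created if needed).
#' @param manifest data.frame dataset manifest (or NULL).
#' @param config named list of resolved settings (written as YAML).
#' @param reports named list of data.frames, written as
#'   `report_<name>.csv`.
#' @param traces named list of loss-trace data.frames, written as
#'   `trace_<name>.csv`.
#' @param seeds named integer vector recorded in the log.
#' @return the run directory, invisibly.
#' @export
writeRunArtifacts <- function(runDir, manifest = NULL, config = list(),
                              reports = list(), traces = list(),
                              seeds = integer()) {
  dir.create(runDir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(runDir) || file.access(runDir, mode = 2L) != 0L)
    stop(sprintf("run directory '%s' is not writable", runDir))
  if (!is.null(manifest))
    utils::write.csv(manifest, file.path(runDir, "manifest.csv"),
                     row.names = FALSE)
  yaml::write_yaml(config, file.path(runDir, "config.yaml"))
  for (nm in names(reports))
    utils::write.csv(reports[[nm]],
                     file.path(runDir, sprintf("report_%s.csv", nm)),
                     row.names = FALSE)
  for (nm in names(traces))
    utils::write.csv(traces[[nm]],
                     file.path(runDir, sprintf("trace_%s.csv", nm)),
                     row.names = FALSE)
  writeLines(c(sprintf("package: BUSseg %s",
                       as.character(utils::packageVersion("BUSseg"))),
               sprintf("R: %s", R.version.string),
               sprintf("date: %s", format(Sys.time(), "%Y-%m-%d %H:%M:%S")),
               if (length(seeds)) paste0("seed ", names(seeds), ": ", seeds)),
             file.path(runDir, "log.txt"))
  invisible(runDir)
}
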