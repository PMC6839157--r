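# Synthetic phantom generator: contours, rasterization, speckle
# rendering, dataset assembly.

test_that("zero-perturbation contour is a circle and contours are periodic", {
  spec <- lesionSpec("benign", baseRadius = 0.2,
                     harmonics = matrix(c(2, 0, 0), 1))
  ct <- makeLesionContour(spec)
  expect_true(all(abs(ct$radius - 0.2) < 1e-12))
  expect_equal(ct$radius[1L], ct$radius[length(ct$radius)])

  spiky <- lesionSpec("malignant", nSpicules = 6L, spiculeLength = 0.4,
                      seed = 11L)
  cs <- makeLesionContour(spiky)
  expect_gt(min(cs$radius), 0)
  expect_equal(cs$radius[1L], cs$radius[length(cs$radius)], tolerance = 1e-9)
})

test_that("contours are deterministic per spec and seed", {
  spec <- lesionSpec("malignant", nSpicules = 5L, seed = 42L)
  expect_identical(makeLesionContour(spec), makeLesionContour(spec))
})

test_that("invalid lesion specifications are rejected with the violated bound", {
  expect_error(lesionSpec("benign", baseRadius = 0.4), "baseRadius")
  expect_error(lesionSpec("benign", baseRadius = 0.04), "baseRadius")
  expect_error(lesionSpec("malignant", nSpicules = 2L), "4 spicules")
  expect_error(lesionSpec("benign",
                          harmonics = matrix(c(2, 0.05, 0), 1),
                          baseRadius = 0.1),
               "0.08")
  # a lesion whose maximal radius crosses the border
  expect_error(lesionSpec("benign", center = c(0.9, 0.5), baseRadius = 0.2),
               "fit inside")
})

test_that("spiculated contours are less solid than their smooth base shape", {
  base <- matrix(c(2, 0.08 * 0.2, 0), 1)
  ben <- lesionSpec("benign", baseRadius = 0.2, harmonics = base)
  mal <- lesionSpec("malignant", baseRadius = 0.2, harmonics = base,
                    nSpicules = 6L, spiculeLength = 0.5, seed = 5L)
  mb <- rasterizeMask(makeLesionContour(ben), 160L)
  mm <- rasterizeMask(makeLesionContour(mal), 160L)
  expect_lt(maskSolidity(mm), maskSolidity(mb))
})

test_that("rasterized circle area matches the analytic area", {
  spec <- lesionSpec("benign", baseRadius = 0.25,
                     harmonics = matrix(c(2, 0, 0), 1))
  ct <- makeLesionContour(spec)
  for (side in c(160L, 320L)) {
    frac <- sum(rasterizeMask(ct, side)) / side^2
    expect_equal(frac, pi * 0.25^2, tolerance = 0.05)
  }
  # scale consistency between the two study sides
  f160 <- sum(rasterizeMask(ct, 160L)) / 160^2
  f320 <- sum(rasterizeMask(ct, 320L)) / 320^2
  expect_lt(abs(f160 - f320) / f320, 0.02)
})

test_that("rasterization area tracks the analytic contour area generally", {
  for (seed in 1:5) {
    spec <- BUSseg:::randomLesionSpec(if (seed %% 2) "benign" else "malignant",
                                      seed * 17L)
    ct <- makeLesionContour(spec)
    # polygon area from the radial samples
    analytic <- sum(diff(ct$theta) * (ct$radius[-1]^2 + ct$radius[-length(ct$radius)]^2) / 4)
    frac <- sum(rasterizeMask(ct, 160L)) / 160^2
    expect_lt(abs(frac - analytic) / analytic, 0.2)
  }
})

test_that("degenerate and out-of-bounds contours raise errors", {
  tiny <- list(theta = seq(0, 2 * pi, length.out = 91),
               radius = rep(1e-4, 91))
  tiny$x <- 0.5 + tiny$radius * cos(tiny$theta)
  tiny$y <- 0.5 + tiny$radius * sin(tiny$theta)
  expect_error(rasterizeMask(tiny, 64L), "empty")
  off <- list(theta = seq(0, 2 * pi, length.out = 91),
              radius = rep(0.3, 91))
  off$x <- 0.9 + off$radius * cos(off$theta)
  off$y <- 0.5 + off$radius * sin(off$theta)
  expect_error(rasterizeMask(off, 64L), "outside")
})

test_that("noise-free rendering is exactly two-level and hypoechoic", {
  spec <- lesionSpec("benign", baseRadius = 0.2)
  mask <- rasterizeMask(makeLesionContour(spec), 64L)
  img <- renderImage(mask, speckleParams(contrast = 0.5, speckleScale = 0,
                                         blurSigma = 0))
  expect_identical(length(unique(as.vector(img))), 2L)
  expect_lt(mean(img[mask == 1]), mean(img[mask == 0]))
})

test_that("speckled rendering stays hypoechoic across seeds", {
  spec <- lesionSpec("benign", baseRadius = 0.2)   # ~12% of pixels
  mask <- rasterizeMask(makeLesionContour(spec), 160L)
  ok <- vapply(1:20, function(s) {
    img <- renderImage(mask, speckleParams(contrast = 0.5, speckleScale = 0.3,
                                           blurSigma = 1, seed = s))
    mean(img[mask == 1]) < mean(img[mask == 0])
  }, TRUE)
  expect_true(all(ok))
})

test_that("rendering is deterministic per seed", {
  spec <- lesionSpec("benign", baseRadius = 0.15)
  mask <- rasterizeMask(makeLesionContour(spec), 64L)
  sp <- speckleParams(seed = 9L)
  expect_identical(renderImage(mask, sp), renderImage(mask, sp))
})

test_that("generateDataset reproduces the clinical class mix and is seeded", {
  ds <- generateDataset(387, malignantFraction = 179 / 387, side = 64L,
                        masterSeed = 3L)
  labs <- vapply(ds, `[[`, "", "label")
  expect_identical(sum(labs == "malignant"), 179L)
  expect_identical(sum(labs == "benign"), 208L)
  expect_true(all(vapply(ds, function(d) sum(d$mask) > 0, TRUE)))

  ds0 <- generateDataset(10, malignantFraction = 0, side = 64L, masterSeed = 1L)
  expect_true(all(vapply(ds0, `[[`, "", "label") == "benign"))

  a <- generateDataset(6, side = 64L, masterSeed = 5L)
  b <- generateDataset(6, side = 64L, masterSeed = 5L)
  expect_identical(vapply(a, `[[`, "", "label"), vapply(b, `[[`, "", "label"))
  expect_identical(a[[1L]]$image, b[[1L]]$image)

  expect_error(generateDataset(1), "n must be")
})

test_that("benign and malignant populations are morphologically separated", {
  ds <- generateDataset(100, malignantFraction = 0.5, side = 96L,
                        masterSeed = 77L, speckleScale = 0)
  sol <- vapply(ds, function(d) maskSolidity(d$mask), 0)
  labs <- vapply(ds, `[[`, "", "label")
  gap <- mean(sol[labs == "benign"]) - mean(sol[labs == "malignant"])
  expect_gte(gap, 0.05)
})

test_that("lesions darker than background in nearly all seeds at contrast 0.7", {
  ds <- generateDataset(50, malignantFraction = 0.5, side = 64L,
                        masterSeed = 13L, contrast = 0.7)
  ok <- vapply(ds, function(d) {
    mean(d$image[d$mask == 1]) < mean(d$image[d$mask == 0])
  }, TRUE)
  expect_gte(sum(ok), 49L)
})

test_that("writeDataset persists PNG pairs and a readable manifest", {
  dir <- withr::local_tempdir()
  ds <- generateDataset(3, side = 64L, masterSeed = 2L)
  man <- writeDataset(ds, dir)
  expect_true(all(file.exists(file.path(dir, man$image))))
  expect_true(all(file.exists(file.path(dir, man$mask))))
  back <- utils::read.csv(file.path(dir, "manifest.csv"))
  expect_identical(back$label, man$label)
  lr <- loadAndResize(file.path(dir, man$image[1]), file.path(dir, man$mask[1]),
                      64L)
  expect_identical(lr$mask, ds[[1L]]$mask)
})
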