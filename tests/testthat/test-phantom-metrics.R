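# Phantom generators, two-plane scenes and the gauge-fixed metrics.

test_that("phantoms honour their specifications", {
  uni <- makePhantom(phantomSpec("uniform", size = 32L))
  expect_equal(uni@phase, matrix(0, 32, 32))
  expect_equal(uni@absorption, matrix(0, 32, 32))

  # two points at the requested center distance, transparent on an
  # absorbing background
  dx <- 0.65 / 4
  tp <- makePhantom(phantomSpec("two_point", size = 64L,
                                featureScale = 0.9, pixelSize = dx))
  holes <- which(tp@absorption == 0, arr.ind = TRUE)
  expect_identical(nrow(holes), 2L)
  expect_identical(unique(holes[, "row"]), 33L)
  expect_equal(diff(sort(holes[, "col"])) * dx, round(0.9 / dx) * dx)

  for (kind in c("tissue", "star", "bars")) {
    a <- makePhantom(phantomSpec(kind, size = 32L, seed = 4L))
    b <- makePhantom(phantomSpec(kind, size = 32L, seed = 4L))
    expect_identical(a@absorption, b@absorption)
    expect_true(all(a@absorption >= 0) && all(a@absorption <= 1.5))
    expect_true(all(a@phase >= 0) && all(a@phase <= 1.5))
  }

  expect_error(makePhantom(phantomSpec("two_point", featureScale = 0.01)),
               "pixel")
})

test_that("two-plane simulation reduces and matches its oracle", {
  cfg <- tinyConfig()
  n <- hrShape(cfg)
  tisA <- randomComplexObject(n, hrPixelSize(cfg), 21)
  zero <- matrix(0, n, n)

  # transparent occluder: frame-exact reduction to the single-plane model
  transp <- complexObject(zero, zero, hrPixelSize(cfg))
  twoT <- simulateTwoPlaneStack(twoPlaneScene(tisA, transp, 150), cfg,
                                zFocus = 4)
  one <- simulateStack(tisA, cfg, z = 4)
  expect_lt(max(abs(twoT@images - one@images)) / max(one@images), 1e-12)

  # vanishing separation: pointwise product of the two transmittances
  occ <- randomComplexObject(n, hrPixelSize(cfg), 22)
  two0 <- simulateTwoPlaneStack(twoPlaneScene(tisA, occ, 1e-10), cfg)
  prod <- complexObject(tisA@phase + occ@phase,
                        tisA@absorption + occ@absorption, hrPixelSize(cfg))
  oneP <- simulateStack(prod, cfg)
  expect_lt(max(abs(two0@images - oneP@images)) / max(oneP@images), 1e-8)

  # direct-sum propagation oracle on the toy grid
  scene <- twoPlaneScene(tisA, occ, 37)
  stack <- simulateTwoPlaneStack(scene, cfg, zFocus = 12)
  p <- makePupil(cfg)
  hImg <- defocusKernel(cfg, 12 - 37)@values
  hSep <- fpmicro:::defocusKernelValues(n, hrPixelSize(cfg),
                                        cfg@wavelength, 37)
  for (i in c(1L, 30L, 169L)) {
    want <- oracleTwoPlaneCapture(objectField(tisA), objectField(occ),
                                  wavevectors(stack@illumination)[i, ],
                                  p@values, hImg, hSep, 1, kStep(cfg))
    expect_lt(relErr(frame(stack, i), want), 1e-10)
  }

  badDim <- randomComplexObject(n * 2L, hrPixelSize(cfg), 23)
  expect_error(twoPlaneScene(tisA, badDim, 50), "grid")
})

test_that("metrics are gauge-fixed and symmetric where promised", {
  a <- matrix(stats::runif(64, 0.2, 1), 8, 8)
  expect_identical(amplitudeRmse(a, a), 0)
  expect_equal(phaseCorrelation(a, a), 1, tolerance = 1e-12)
  # global intensity scale is gauge
  expect_lt(amplitudeRmse(2 * a, a), 1e-12)
  # piston is gauge for the phase
  expect_equal(phaseCorrelation(a + 1.3, a), 1, tolerance = 1e-12)
  # constant against constant correlates perfectly; mixed is an error
  k <- matrix(1, 8, 8)
  expect_identical(phaseCorrelation(k, 2 * k), 1)
  expect_error(phaseCorrelation(k, a), "constant")

  # unit-variance perturbation on a strong field reads out as RMSE ~ 1
  set.seed(8)
  truth <- matrix(10, 128, 128)
  noisy <- truth + matrix(stats::rnorm(128^2), 128, 128)
  expect_equal(amplitudeRmse(noisy, truth), 1, tolerance = 0.05)
})

test_that("the two-point dip criterion reads profiles correctly", {
  n <- 64L
  img <- matrix(0, n, n)
  c0 <- n / 2 + 1
  # two clear peaks with a deep valley: resolved
  img[c0, c0 - 4] <- 1; img[c0, c0 + 4] <- 0.9
  expect_true(fpmicro:::twoPointResolved(img, 8 * 0.1, 0.1))
  # filled valley: unresolved
  img2 <- img
  img2[c0, (c0 - 3):(c0 + 3)] <- 0.95
  expect_false(fpmicro:::twoPointResolved(img2, 8 * 0.1, 0.1))
  # sub-pixel separation cannot be resolved
  expect_false(fpmicro:::twoPointResolved(img, 0.1, 0.1))

  expect_warning(
    out <- resolutionProbe(list(img), list(img2), 0.8, 0.1, 0.1),
    "resolved")
  expect_identical(unname(out), c(0.8, Inf))
})

test_that("occluder strokes are opaque, thin and reproducible", {
  occ <- makeOccluder(64L, strokeWidth = 1.5, seed = 5L)
  expect_identical(occ@absorption,
                   makeOccluder(64L, strokeWidth = 1.5, seed = 5L)@absorption)
  expect_setequal(unique(as.vector(occ@absorption)), c(0, 3))
  frac <- mean(occ@absorption > 0)
  expect_gt(frac, 0.02); expect_lt(frac, 0.6)
  expect_equal(max(occ@phase), 0)
  sc <- twoPlaneScene(makePhantom(phantomSpec("uniform", size = 64L)),
                      occ, 150)
  expect_equal(sc@maskFraction, frac)
})
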