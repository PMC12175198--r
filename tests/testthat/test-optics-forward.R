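# Forward model: illumination geometry, pupil, defocus kernel, capture
# equation, stack simulation.

test_that("LED wavevectors follow the array trigonometry", {
  cfg <- opticalConfig()
  illum <- ledWavevectors(cfg)
  k <- wavevectors(illum)

  expect_equal(nrow(k), 169L)
  expect_identical(illum@centralIndex, 1L)
  expect_identical(k[1, ], c(kx = 0, ky = 0))

  # LED six columns out: dx = 24 mm at h = 52 mm
  i <- which(illum@ledIndices[, "col"] == 6L & illum@ledIndices[, "row"] == 0L)
  sinx <- 24 / sqrt(24^2 + 52^2)
  expect_equal(unname(k[i, "kx"]) * cfg@wavelength, sinx, tolerance = 1e-12)
  expect_equal(unname(k[i, "ky"]), 0)

  # direction sines are physical and |lambda k| grows with lateral offset
  sines <- cfg@wavelength * sqrt(rowSums(k^2))
  expect_true(all(sines < 1))
  offset <- sqrt(rowSums(illum@ledIndices^2))
  expect_true(all(diff(sines[order(offset)]) > -1e-12))

  # spiral ordering: ring index is non-decreasing along the sequence
  ring <- pmax(abs(illum@ledIndices[, 1]), abs(illum@ledIndices[, 2]))
  expect_true(all(diff(ring) >= 0))
})

test_that("even LED grids need an explicit central override", {
  cfg <- opticalConfig(ledGrid = c(12L, 12L))
  expect_error(ledWavevectors(cfg), "central")
  illum <- ledWavevectors(cfg, centralOverride = c(6L, 6L))
  expect_identical(wavevectors(illum)[1, ], c(kx = 0, ky = 0))
})

test_that("Noll indexing matches the classical Zernike table", {
  want <- list(c(0, 0), c(1, 1), c(1, -1), c(2, 0), c(2, -2), c(2, 2),
               c(3, -1), c(3, 1), c(3, -3), c(3, 3), c(4, 0), c(4, 2),
               c(4, -2), c(4, 4), c(4, -4))
  got <- lapply(1:15, function(j) unname(fpmicro:::nollToNm(j)))
  expect_equal(got, lapply(want, as.integer))
})

test_that("pupil is the NA disk with Zernike phase", {
  cfg <- opticalConfig()
  p <- makePupil(cfg)
  expect_equal(p@cutoff, 0.3 / 0.523, tolerance = 1e-12)
  # piston initialisation: |P| is the plain disk
  expect_equal(Mod(p@values)[p@support], rep(1, sum(p@support)))
  expect_true(all(Mod(p@values)[!p@support] == 0))
  # piston-only and all-zero coefficients give identical |P|
  p0 <- makePupil(cfg, rep(0, 15))
  expect_equal(Mod(p0@values), Mod(p@values))
  # piston is a constant phase on the support
  ph <- Arg(p@values)[p@support]
  expect_equal(max(ph) - min(ph), 0, tolerance = 1e-12)
})

test_that("undersampled captures are rejected", {
  cfg <- opticalConfig(magnification = 2)   # object pixel 3.25 um
  expect_error(makePupil(cfg), "Nyquist")
})

test_that("defocus kernel is the angular-spectrum propagator", {
  cfg <- smallConfig()
  n <- cfg@lrShape[1]
  z <- 12.5
  k <- defocusKernel(cfg, z)
  # on-axis frequency: plain phase delay exp(i 2 pi z / lambda)
  c0 <- n / 2 + 1
  expect_equal(k@values[c0, c0], exp(1i * 2 * pi * z / cfg@wavelength),
               tolerance = 1e-12)
  # |H| = 1 on propagating frequencies
  expect_equal(Mod(k@values), matrix(1, n, n), tolerance = 1e-12)
  # z = 0 is the identity everywhere
  expect_equal(defocusKernel(cfg, 0)@values, matrix(1 + 0i, n, n))
  # conjugate symmetry in z
  expect_equal(k@values * defocusKernel(cfg, -z)@values,
               matrix(1 + 0i, n, n), tolerance = 1e-12)
})

test_that("uniform object images at gamma and scales linearly", {
  cfg <- tinyConfig()
  obj <- makePhantom(phantomSpec("uniform", size = hrShape(cfg),
                                 pixelSize = hrPixelSize(cfg)))
  spec <- objectSpectrum(obj)
  p <- makePupil(cfg)
  h <- defocusKernel(cfg, 0)
  fr <- forwardCapture(spec, c(0, 0), p, h, gamma = 2)
  expect_equal(fr, matrix(2, 8, 8), tolerance = 1e-12)
  expect_equal(forwardCapture(spec, c(0, 0), p, h, gamma = 0),
               matrix(0, 8, 8))
})

test_that("out-of-band windows raise an error naming the LED", {
  cfg <- tinyConfig()
  obj <- randomComplexObject(hrShape(cfg), hrPixelSize(cfg), 1)
  spec <- objectSpectrum(obj)
  p <- makePupil(cfg)
  h <- defocusKernel(cfg, 0)
  kBig <- c(10 * kStep(cfg), 0)
  expect_error(forwardCapture(spec, kBig, p, h, ledIndex = 42L), "LED 42")
})

test_that("Parseval holds for the centered unitary transforms", {
  for (seed in 1:5) {
    obj <- randomComplexObject(16L, 0.1625, seed)
    f <- objectField(obj)
    expect_equal(sum(Mod(objectSpectrum(obj)@values)^2), sum(Mod(f)^2),
                 tolerance = 1e-10)
    # round trip
    expect_equal(fpmicro:::ifft2c(objectSpectrum(obj)@values), f,
                 tolerance = 1e-12)
  }
})

test_that("capture equation matches the brute-force transform oracle", {
  cfg <- tinyConfig()
  illum <- ledWavevectors(cfg)
  dk <- kStep(cfg)
  set.seed(99)
  for (draw in 1:20) {
    obj <- randomComplexObject(hrShape(cfg), hrPixelSize(cfg), draw)
    z <- stats::runif(1, -20, 20)
    gamma <- stats::runif(1, 0.5, 2)
    i <- sample(nrow(wavevectors(illum)), 1)
    coeffs <- c(1, stats::rnorm(5, 0, 0.3))
    p <- makePupil(cfg, coeffs)
    h <- defocusKernel(cfg, z)
    got <- forwardCapture(objectSpectrum(obj), wavevectors(illum)[i, ],
                          p, h, gamma)
    want <- oracleCapture(objectField(obj), wavevectors(illum)[i, ],
                          p@values, h@values, gamma, dk)
    expect_lt(relErr(got, want), 1e-10)
  }
})

test_that("defocused capture reduces to the ideal model at z = 0", {
  cfg <- tinyConfig()
  obj <- randomComplexObject(hrShape(cfg), hrPixelSize(cfg), 7)
  spec <- objectSpectrum(obj)
  p <- makePupil(cfg)
  illum <- ledWavevectors(cfg)
  h0 <- defocusKernel(cfg, 0)
  for (i in c(1L, 5L, 100L)) {
    withH <- forwardCapture(spec, wavevectors(illum)[i, ], p, h0, 1)
    # ideal model: no kernel term at all
    ideal <- forwardCapture(spec, wavevectors(illum)[i, ], p,
                            methods::new("DefocusKernel", z = 0,
                                         values = matrix(1 + 0i, 8, 8)), 1)
    expect_identical(withH, ideal)
  }
})

test_that("stack simulation composes frames deterministically", {
  cfg <- tinyConfig()
  obj <- randomComplexObject(hrShape(cfg), hrPixelSize(cfg), 11)
  stack <- simulateStack(obj, cfg)
  expect_equal(nFrames(stack), 169L)

  # frame-for-frame equality with direct forward captures
  spec <- objectSpectrum(obj)
  p <- makePupil(cfg)
  h <- defocusKernel(cfg, 0)
  for (i in c(1L, 17L, 169L))
    expect_identical(frame(stack, i),
                     forwardCapture(spec, wavevectors(stack@illumination)[i, ],
                                    p, h, 1))

  # same seed, bit-identical; noise draws also reproducible
  ns <- noiseSpec(photons = 1e4, readSigma = 1e-3)
  s1 <- simulateStack(obj, cfg, noise = ns, seed = 5L)
  s2 <- simulateStack(obj, cfg, noise = ns, seed = 5L)
  expect_identical(s1@images, s2@images)
  expect_false(identical(s1@images, stack@images))
  expect_true(all(s1@images >= 0))

  expect_error(simulateStack(obj, cfg, gammas = -1), "positive")
})
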