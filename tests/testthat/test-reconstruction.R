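# Joint reconstruction: initialisation, objective, optimisation
# contracts, object extraction.

test_that("initial state follows the stated initialisation", {
  stack <- smallStack()
  st <- initializeState(stack)
  expect_identical(st@z, 0)
  expect_equal(st@zernikeCoeffs, c(1, rep(0, 14)))
  expect_equal(st@gammas, rep(1, 169))
  expect_identical(dim(st@spectrum), c(64L, 64L))   # 4 x 16 upsampling

  # uniform object: initial amplitude uniform, central frame fits
  cfg <- tinyConfig()
  uni <- makePhantom(phantomSpec("uniform", size = hrShape(cfg),
                                 pixelSize = hrPixelSize(cfg)))
  ustack <- simulateStack(uni, cfg)
  ust <- initializeState(ustack)
  amp <- Mod(fpmicro:::ifft2c(ust@spectrum))
  expect_equal(amp, matrix(1, 16, 16), tolerance = 1e-10)
  expect_lt(objective(ust, ustack, batch = 1L), 1e-12)
})

test_that("objective is zero at the generating parameters and has the
           stated closed forms", {
  cfg <- smallConfig()
  obj <- smallTissue()
  set.seed(3)
  gam <- stats::runif(169, 0.8, 1.2)
  stack <- simulateStack(obj, cfg, z = 7, gammas = gam)
  truth <- initializeState(stack)
  truth@spectrum <- objectSpectrum(obj)@values
  truth@z <- 7
  truth@gammas <- gam
  expect_identical(objective(truth, stack, lossKind = "L1"), 0)
  expect_identical(objective(truth, stack, lossKind = "L2"), 0)

  # I_pred = 0 against I_gt = c: L1 -> c, L2 -> c^2 (per-pixel means)
  const <- 0.7
  zeroState <- initializeState(stack)
  zeroState@spectrum[] <- 0 + 0i
  cstack <- stack
  cstack@images[] <- const
  expect_equal(objective(zeroState, cstack, lossKind = "L1"), const)
  expect_equal(objective(zeroState, cstack, lossKind = "L2"), const^2)
})

test_that("loss descends and the recovered object matches the phantom", {
  st <- smallRecon()
  expect_lt(utils::tail(lossHistory(st), 1), 0.1 * lossHistory(st)[1])
  ex <- extractObject(st)
  expect_lt(amplitudeRmse(ex$object, smallTissue()), 0.05)
  expect_gt(phaseCorrelation(ex$object, smallTissue()), 0.98)
  expect_lt(abs(defocus(st)), 1)       # simulated in focus
})

test_that("extraction removes the piston and bounds the phase", {
  ex <- extractObject(smallRecon())
  expect_lte(max(abs(ex$phase)), pi)
  expect_equal(ex$intensity, Mod(fpmicro:::ifft2c(smallRecon()@spectrum))^2)

  # zero-phase initialisation extracts an identically zero phase map
  st0 <- initializeState(smallStack())
  ex0 <- extractObject(st0)
  expect_equal(ex0$phase, matrix(0, 64, 64), tolerance = 1e-10)
})

test_that("frozen parameter groups stay bit-identical", {
  stack <- smallStack()
  spec <- optimizerSpec(epochs = 3L,
                        freeze = c("spectrum", "pupil", "z", "gamma"))
  st0 <- initializeState(stack)
  st <- reconstruct(stack, spec, state = st0)
  expect_identical(st@spectrum, st0@spectrum)
  expect_identical(st@zernikeCoeffs, st0@zernikeCoeffs)
  expect_identical(st@z, st0@z)
  expect_identical(st@gammas, st0@gammas)

  # partial freeze: z pinned, the rest moves
  spec2 <- optimizerSpec(epochs = 3L, freeze = "z")
  st2 <- reconstruct(stack, spec2, state = st0)
  expect_identical(st2@z, st0@z)
  expect_false(identical(st2@spectrum, st0@spectrum))
})

test_that("identical seeds give identical runs", {
  stack <- smallStack()
  a <- reconstruct(stack, optimizerSpec(epochs = 4L, seed = 9L))
  b <- reconstruct(stack, optimizerSpec(epochs = 4L, seed = 9L))
  expect_identical(lossHistory(a), lossHistory(b))
  expect_identical(a@spectrum, b@spectrum)
  c <- reconstruct(stack, optimizerSpec(epochs = 4L, seed = 10L))
  expect_false(identical(lossHistory(a), lossHistory(c)))
})

test_that("divergence raises an informative error", {
  stack <- smallStack()
  spec <- optimizerSpec(epochs = 2L,
                        learningRates = c(spectrum = 1e-2, pupil = 1e-3,
                                          z = 1e-1, gamma = 1e6),
                        lrSchedule = "constant")
  expect_error(reconstruct(stack, spec), "epoch")
})

test_that("pupil aberrations are recovered when z is pinned", {
  cfg <- smallConfig()
  obj <- smallTissue()
  coeffsTrue <- c(1, 0, 0, 0.4, -0.3, 0.2, rep(0, 9))
  stack <- simulateStack(obj, cfg, pupil = makePupil(cfg, coeffsTrue))
  st <- reconstruct(stack, optimizerSpec(epochs = 80L, freeze = "z"))
  # piston is a pure gauge; compare the aberration coefficients
  expect_equal(st@zernikeCoeffs[4:6], coeffsTrue[4:6], tolerance = 0.1)
})
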