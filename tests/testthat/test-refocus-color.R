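# Digital refocusing, occluder suppression plumbing, RGB assembly and
# phase display.

test_that("sweep refocus finds the simulated defocus", {
  cfg <- smallConfig()
  stack25 <- simulateStack(smallTissue(), cfg, z = 25)
  res <- refocus(stack25, "sweep", zRange = c(-50, 50), nCandidates = 21L,
                 spec = optimizerSpec(epochs = 10L))
  expect_s4_class(res, "RefocusResult")
  expect_true(res@zStar %in% c(20, 25, 30))
  expect_identical(length(res@scoreCurve), 21L)
  # correct-sign focus scores better than its mirror image
  expect_lt(res@scoreCurve[res@zGrid == 25],
            res@scoreCurve[res@zGrid == -25])
  expect_false(res@atBoundary)

  # a too-narrow range is flagged
  expect_warning(
    resN <- refocus(stack25, "sweep", zRange = c(-6, 6), nCandidates = 5L,
                    spec = optimizerSpec(epochs = 5L)),
    "endpoint")
  expect_true(resN@atBoundary)
})

test_that("joint refocus refines to within a micron on an in-focus stack", {
  res <- refocus(smallStack(), "joint_opt", zRange = c(-30, 30),
                 spec = optimizerSpec(epochs = 40L))
  expect_lt(abs(res@zStar), 1)
  expect_identical(res@method, "joint_opt")
})

test_that("suppression at a focal plane equals a plain frozen-z
           reconstruction when there is no occluder", {
  stack <- smallStack()
  spec <- optimizerSpec(epochs = 10L)
  sup <- suppressOccluder(stack, 0, spec)
  spec2 <- optimizerSpec(epochs = 10L, freeze = "z")
  plain <- reconstruct(stack, spec2)
  expect_identical(sup$state@spectrum, plain@spectrum)
  expect_identical(sup$state@z, 0)
})

test_that("RGB assembly orders channels by wavelength and normalises", {
  m <- matrix(stats::runif(64, 0, 4), 8, 8)
  # identical maps in capture order (523, 470, 623 nm) -> gray image
  rgb <- assembleRgb(list(m, m, m), wavelengths = c(523, 470, 623))
  expect_equal(rgb@channels[, , 1], rgb@channels[, , 2])
  expect_equal(rgb@channels[, , 2], rgb@channels[, , 3])
  expect_true(all(rgb@channels >= 0 & rgb@channels <= 1))
  expect_equal(rgb@wavelengths, c(0.623, 0.523, 0.470))

  # distinct maps land on their nominal channels regardless of order
  maps <- list(g = m, b = 2 * m, r = 3 * m)
  rgb2 <- assembleRgb(maps, wavelengths = c(0.523, 0.470, 0.623))
  expect_equal(rgb2@normalization,
               as.numeric(stats::quantile(3 * m, 0.99)) *
                 c(1, 1 / 3, 2 / 3), tolerance = 1e-10)
  # permuting then un-permuting the inputs is the identity
  rgb3 <- assembleRgb(maps[c(3, 1, 2)], wavelengths = c(623, 523, 470))
  expect_identical(rgb2@channels, rgb3@channels)

  expect_error(assembleRgb(list(m, m, m[1:4, 1:4])), "shape")
  expect_error(assembleRgb(list(m, m, m), wavelengths = c(523, 523, 470)),
               "nm")
})

test_that("phase display rescales without altering radians", {
  ramp <- matrix(seq(0, 1, length.out = 64), 8, 8)
  d <- phaseToDisplay(ramp)
  expect_equal(c(d$min, d$max), c(0, 1))
  expect_equal(d$image * (d$max - d$min) + d$min, ramp)

  flat <- phaseToDisplay(matrix(0.3, 4, 4))
  expect_equal(flat$image, matrix(0, 4, 4))
  expect_equal(flat$min, 0.3)

  # wrapped values at +-pi pass through unmodified
  wrapped <- matrix(c(-pi, pi, 0, 0.5), 2, 2)
  dw <- phaseToDisplay(wrapped)
  expect_equal(dw$image * (dw$max - dw$min) + dw$min, wrapped)
})
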