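# The reconstructor's analytic Wirtinger gradients against forward
# finite differences, for both loss kinds and every parameter group.

test_that("analytic gradients match finite differences", {
  cfg <- tinyConfig()
  obj <- makePhantom(phantomSpec("tissue", size = hrShape(cfg), seed = 3L,
                                 pixelSize = hrPixelSize(cfg),
                                 featureScale = 1))
  set.seed(42)
  stack <- simulateStack(obj, cfg, z = 5,
                         gammas = stats::runif(169, 0.8, 1.2))
  coeffs <- c(1, 0.05, -0.03, 0.02, 0, 0.01)
  zt <- 2
  loggam <- log(stats::runif(169, 0.9, 1.1))
  O <- initializeState(stack, J = 6L)@spectrum +
    matrix(complex(real = stats::rnorm(256, 0, 0.1),
                   imaginary = stats::rnorm(256, 0, 0.1)), 16, 16)
  ctx <- fpmicro:::reconContext(stack, 6L)
  batch <- c(1L, 5L, 40L)
  h <- 1e-6

  for (lk in c("L1", "L2")) {
    g <- fpmicro:::batchGradients(O, coeffs, zt, loggam, stack, ctx,
                                  batch, lk)
    f <- function(O2 = O, c2 = coeffs, z2 = zt, lg2 = loggam)
      fpmicro:::batchGradients(O2, c2, z2, lg2, stack, ctx, batch, lk)$loss

    fd <- c(); an <- c()
    for (idx in c(7L + 16L * 7L, 3L + 16L * 9L)) {
      O2 <- O; O2[idx] <- O2[idx] + h
      fd <- c(fd, (f(O2) - g$loss) / h); an <- c(an, 2 * Re(g$gO[idx]))
      O2 <- O; O2[idx] <- O2[idx] + 1i * h
      fd <- c(fd, (f(O2) - g$loss) / h); an <- c(an, 2 * Im(g$gO[idx]))
    }
    for (j in c(2L, 4L)) {
      c2 <- coeffs; c2[j] <- c2[j] + h
      fd <- c(fd, (f(c2 = c2) - g$loss) / h); an <- c(an, g$gC[j])
    }
    fd <- c(fd, (f(z2 = zt + h) - g$loss) / h); an <- c(an, g$gZ)
    lg2 <- loggam; lg2[5] <- lg2[5] + h
    fd <- c(fd, (f(lg2 = lg2) - g$loss) / h); an <- c(an, g$gG[5])

    expect_equal(fd, an, tolerance = 1e-5)
  }
})
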