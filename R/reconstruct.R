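#' @include forward.R metrics.R
NULL

#' Construct optimiser settings
#'
#' Defaults are the package's pinned reconstruction settings: L1 data
#' misfit, 200 epochs of Adam over mini-batches of 13 LEDs, per-group
#' step sizes `spectrum = 1e-2`, `pupil = 1e-3`, `z = 1e-1` (um) and
#' `gamma = 3e-3`, seed 0.  All overridable; `freeze` removes whole
#' parameter groups from the optimisation (their values stay
#' bit-identical across epochs).
#'
#' @param lossKind `"L1"` or `"L2"`.
#' @param learningRates Named numeric for `spectrum`, `pupil`, `z`,
#'   `gamma`.
#' @param epochs Passes over the LED set.
#' @param batchSize LEDs per mini-batch.
#' @param seed Integer seed (controls batch shuffling only).
#' @param freeze Character subset of the parameter-group names.
#' @param lrSchedule `"cosine"` (anneal step sizes to zero over the epoch
#'   budget) or `"constant"`.  Annealing removes the stochastic-step
#'   jitter floor on noiseless data, which is what makes the dim
#'   high-angle captures' intensity factors identifiable.
#' @return An [OptimizerSpec-class].
#' @export
optimizerSpec <- function(lossKind = "L1",
                          learningRates = c(spectrum = 1e-2, pupil = 1e-3,
                                            z = 1e-1, gamma = 3e-3),
                          epochs = 200L, batchSize = 13L, seed = 0L,
                          freeze = character(), lrSchedule = "cosine") {
  methods::new("OptimizerSpec",
    lossKind = lossKind, learningRates = learningRates,
    epochs = as.integer(epochs), batchSize = as.integer(batchSize),
    seed = as.integer(seed), freeze = freeze, lrSchedule = lrSchedule)
}

#' Initialise a reconstruction state from a capture stack
#'
#' The recovered amplitude starts from the central-LED capture: its
#' square root is replicated onto the HR grid (zero initial phase) and
#' transformed into the initial object spectrum.  The defocus starts at
#' zero, the pupil at the unaberrated Zernike initialisation
#' `(1, 0, ..., 0)`, and all intensity factors at one.
#'
#' @param stack A [CaptureStack-class].
#' @param J Number of pupil Zernike coefficients carried (default 15).
#' @return A [ReconstructionState-class].
#' @export
initializeState <- function(stack, J = 15L) {
  stopifnot(methods::is(stack, "CaptureStack"))
  cfg <- stack@config
  up <- cfg@hrUpsample
  amp_lr <- sqrt(centralFrame(stack))
  amp_hr <- kronecker(amp_lr, matrix(1, up, up))
  methods::new("ReconstructionState",
    spectrum = fft2c(amp_hr),
    zernikeCoeffs = c(1, rep(0, J - 1L)),
    z = 0,
    gammas = rep(1, nFrames(stack)),
    lossHistory = numeric(),
    epoch = 0L,
    config = cfg,
    illumination = stack@illumination)
}

#' @rdname accessors
#' @export
setMethod("gammas", "ReconstructionState", function(x) x@gammas)

#' @rdname accessors
#' @export
setMethod("defocus", "ReconstructionState", function(x) x@z)

#' @rdname accessors
#' @export
setMethod("lossHistory", "ReconstructionState", function(x) x@lossHistory)

setMethod("show", "ReconstructionState", function(object) {
  cat(sprintf(
    "ReconstructionState: %d^2 spectrum, z = %.3f um, %d epochs run%s\n",
    nrow(object@spectrum), object@z, object@epoch,
    if (length(object@lossHistory))
      sprintf(", last loss %.4g", utils::tail(object@lossHistory, 1))
    else ""))
})

# ---------------------------------------------------------------------------
# Shared per-reconstruction precomputation

reconContext <- function(stack, J) {
  cfg <- stack@config
  n_lr <- cfg@lrShape[1]
  n_hr <- hrShape(cfg)
  dx_lr <- lrPixelSize(cfg)
  dk <- kStep(cfg)
  cutoff <- cfg@objectiveNa / cfg@wavelength
  support <- matrix(sqrt(freqRadiusSq(n_lr, dx_lr)) <= cutoff, n_lr, n_lr)
  basis <- zernikeBasis(n_lr, dx_lr, cutoff, J)
  arg <- 1 - cfg@wavelength^2 * freqRadiusSq(n_lr, dx_lr)
  sqrtRad <- sqrt(pmax(arg, 0))       # 0 on any evanescent corner
  N <- nFrames(stack)
  windows <- vector("list", N)
  for (i in seq_len(N)) {
    m <- pixelShift(stack@illumination@wavevectors[i, ], dk)
    w <- windowIndices(n_hr, n_lr, m)
    if (!w$ok)
      stop(sprintf("LED %d: spectrum window out of the HR band", i))
    windows[[i]] <- w
  }
  list(cfg = cfg, n_lr = n_lr, n_hr = n_hr, scale = n_lr / n_hr,
       support = support, basis = basis, sqrtRad = sqrtRad,
       kappa = 2 * pi / cfg@wavelength, windows = windows, N = N)
}

pupilFromCoeffs <- function(ctx, coeffs) {
  phase <- matrix(as.vector(ctx$basis %*% coeffs), ctx$n_lr, ctx$n_lr)
  ifelse(ctx$support, exp(1i * phase), 0 + 0i)
}

kernelFromZ <- function(ctx, z) {
  defocusKernelValues(ctx$n_lr, lrPixelSize(ctx$cfg), ctx$cfg@wavelength, z)
}

# ---------------------------------------------------------------------------
# Objective

#' Data-misfit objective of a reconstruction state
#'
#' Mean over the batch of the per-pixel mean misfit between predicted and
#' observed captures: `mean(|I_pred - I_gt|)` for L1,
#' `mean((I_pred - I_gt)^2)` for L2.  Zero exactly when the state's
#' forward predictions reproduce the observations on the batch.
#'
#' @param state A [ReconstructionState-class].
#' @param stack The observed [CaptureStack-class].
#' @param batch Nonempty integer vector of frame indices (default all).
#' @param lossKind `"L1"` or `"L2"`.
#' @return Nonnegative scalar.
#' @export
objective <- function(state, stack, batch = seq_len(nFrames(stack)),
                      lossKind = "L1") {
  stopifnot(length(batch) >= 1L, lossKind %in% c("L1", "L2"))
  ctx <- reconContext(stack, length(state@zernikeCoeffs))
  P <- pupilFromCoeffs(ctx, state@zernikeCoeffs)
  H <- kernelFromZ(ctx, state@z)
  PH <- P * H
  total <- 0
  for (i in batch) {
    w <- ctx$windows[[i]]
    E <- ifft2c(state@spectrum[w$rows, w$cols] * PH) * ctx$scale
    R <- state@gammas[i] * Mod(E)^2 - stack@images[, , i]
    total <- total + if (lossKind == "L1") mean(abs(R)) else mean(R^2)
  }
  total / length(batch)
}

# ---------------------------------------------------------------------------
# Adam

adamInit <- function(dim) list(m = array(0, dim), v = array(0, dim), t = 0L)

adamStep <- function(stateA, grad, lr, b1 = 0.9, b2 = 0.999, eps = 1e-8) {
  stateA$t <- stateA$t + 1L
  stateA$m <- b1 * stateA$m + (1 - b1) * grad
  stateA$v <- b2 * stateA$v + (1 - b2) * grad^2
  mhat <- stateA$m / (1 - b1^stateA$t)
  vhat <- stateA$v / (1 - b2^stateA$t)
  stateA$delta <- lr * mhat / (sqrt(vhat) + eps)
  stateA
}

# ---------------------------------------------------------------------------
# Gradients of the batch objective (Wirtinger calculus; finite-difference
# tested).  Returns the objective value plus gradients for every group:
#   gO  : d L / d conj(O)        (complex HR matrix; dL/dRe = 2 Re, etc.)
#   gC  : d L / d coeffs         (real J)
#   gZ  : d L / d z              (real scalar)
#   gG  : d L / d log(gamma_i)   (real N, nonzero on the batch only)
batchGradients <- function(O, coeffs, z, loggam, stack, ctx, batch,
                           lossKind) {
  P <- pupilFromCoeffs(ctx, coeffs)
  H <- kernelFromZ(ctx, z)
  PH <- P * H
  dHdz_fac <- 1i * ctx$kappa * ctx$sqrtRad * H   # dH/dz elementwise
  B <- length(batch)
  npix <- ctx$n_lr^2

  gO <- matrix(0 + 0i, ctx$n_hr, ctx$n_hr)
  gC <- numeric(length(coeffs))
  gZ <- 0
  gG <- numeric(ctx$N)
  loss <- 0

  for (i in batch) {
    w <- ctx$windows[[i]]
    A <- O[w$rows, w$cols]
    T <- A * PH
    E <- ifft2c(T) * ctx$scale
    gam <- exp(loggam[i])
    Ipred <- gam * Mod(E)^2
    R <- Ipred - stack@images[, , i]
    if (lossKind == "L1") {
      loss <- loss + mean(abs(R))
      W <- sign(R) / (B * npix)
    } else {
      loss <- loss + mean(R^2)
      W <- 2 * R / (B * npix)
    }
    gE <- gam * W * E
    gT <- ctx$scale * fft2c(gE)
    gO[w$rows, w$cols] <- gO[w$rows, w$cols] + gT * Conj(PH)
    gP <- gT * Conj(A * H)
    gC <- gC + 2 * Re(as.vector(crossprod(ctx$basis,
                                          as.vector(Conj(gP) * 1i * P))))
    gH <- gT * Conj(A * P)
    gZ <- gZ + 2 * Re(sum(Conj(gH) * dHdz_fac))
    gG[i] <- sum(W * Ipred)
  }
  list(loss = loss / B, gO = gO, gC = gC, gZ = gZ, gG = gG)
}

# ---------------------------------------------------------------------------
# Reconstruction driver

#' Joint gradient-based FPM reconstruction
#'
#' Minimises the capture misfit jointly over the HR object spectrum, the
#' pupil Zernike coefficients, the defocus distance and the per-capture
#' intensity factors, using Adam on analytic Wirtinger gradients of the
#' forward model.  Intensity factors are optimised as `exp(g)` so they
#' stay positive.  Mini-batches of LEDs are shuffled each epoch with the
#' spec's seed; runs are deterministic given identical inputs.
#'
#' @param stack The observed [CaptureStack-class].
#' @param spec An [OptimizerSpec-class].
#' @param state Optional warm-start [ReconstructionState-class]
#'   (default [initializeState()]); use this to pin `z` to a chosen focal
#'   plane together with `freeze = "z"`.
#' @return The final [ReconstructionState-class] with `lossHistory`
#'   filled per epoch.
#' @seealso [extractObject()] to turn the state into images.
#' @export
reconstruct <- function(stack, spec = optimizerSpec(), state = NULL) {
  stopifnot(methods::is(stack, "CaptureStack"),
            methods::is(spec, "OptimizerSpec"))
  if (is.null(state)) state <- initializeState(stack)
  ctx <- reconContext(stack, length(state@zernikeCoeffs))
  if (spec@batchSize > ctx$N)
    stop("batchSize exceeds the number of captures")

  O <- state@spectrum
  coeffs <- state@zernikeCoeffs
  z <- state@z
  loggam <- log(state@gammas)

  lr <- spec@learningRates
  frozen <- spec@freeze
  adO_re <- adamInit(dim(O)); adO_im <- adamInit(dim(O))
  adC <- adamInit(length(coeffs))
  adZ <- adamInit(1L)
  adG <- adamInit(ctx$N)

  set.seed(spec@seed)
  lossHist <- numeric(spec@epochs)
  for (ep in seq_len(spec@epochs)) {
    fac <- if (spec@lrSchedule == "cosine")
      0.5 * (1 + cos(pi * (ep - 1) / spec@epochs)) else 1
    lr <- spec@learningRates * fac
    order_ep <- sample.int(ctx$N)
    starts <- seq(1L, ctx$N, by = spec@batchSize)
    epochLoss <- 0
    for (s in starts) {
      batch <- order_ep[s:min(s + spec@batchSize - 1L, ctx$N)]
      g <- batchGradients(O, coeffs, z, loggam, stack, ctx, batch,
                          spec@lossKind)
      if (!is.finite(g$loss))
        stop(sprintf(
          "reconstruction diverged at epoch %d (non-finite loss); learning rates: spectrum %g, pupil %g, z %g, gamma %g",
          ep, lr[["spectrum"]], lr[["pupil"]], lr[["z"]], lr[["gamma"]]))
      epochLoss <- epochLoss + g$loss

      if (!"spectrum" %in% frozen) {
        adO_re <- adamStep(adO_re, 2 * Re(g$gO), lr[["spectrum"]])
        adO_im <- adamStep(adO_im, 2 * Im(g$gO), lr[["spectrum"]])
        O <- O - adO_re$delta - 1i * adO_im$delta
      }
      if (!"pupil" %in% frozen) {
        adC <- adamStep(adC, g$gC, lr[["pupil"]])
        coeffs <- coeffs - adC$delta
      }
      if (!"z" %in% frozen) {
        adZ <- adamStep(adZ, g$gZ, lr[["z"]])
        z <- z - as.numeric(adZ$delta)
      }
      if (!"gamma" %in% frozen) {
        # shorter second-moment memory: early epochs give the dim frames
        # large noisy gradients whose long-memory vhat would otherwise
        # suppress the genuine late-run signal
        adG <- adamStep(adG, g$gG, lr[["gamma"]], b2 = 0.99)
        loggam <- loggam - adG$delta
      }
    }
    lossHist[ep] <- epochLoss / length(starts)
  }

  methods::new("ReconstructionState",
    spectrum = O, zernikeCoeffs = as.numeric(coeffs), z = as.numeric(z),
    gammas = as.numeric(exp(loggam)),
    lossHistory = c(state@lossHistory, lossHist),
    epoch = state@epoch + spec@epochs,
    config = stack@config, illumination = stack@illumination)
}
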