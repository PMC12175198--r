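#' @include phantom.R
NULL

#' Construct a two-plane scene
#'
#' @param tissue [ComplexObject-class] at the focal plane (z = 0).
#' @param occluder [ComplexObject-class] at `separation` um above the
#'   tissue, towards the objective.
#' @param separation Nonzero axial separation (um).
#' @return A [TwoPlaneScene-class]; the occluder mask area fraction
#'   (absorption above half its maximum) is recorded.
#' @export
twoPlaneScene <- function(tissue, occluder, separation) {
  mx <- max(occluder@absorption)
  maskFraction <- if (mx > 0) mean(occluder@absorption > mx / 2) else 0
  methods::new("TwoPlaneScene",
    tissue = tissue, occluder = occluder,
    separation = separation, maskFraction = maskFraction)
}

#' Simulate a capture stack through two axial planes
#'
#' Sequential coherent propagation: the tilted illumination traverses the
#' tissue, the field is propagated by `separation` with the HR
#' angular-spectrum kernel, modulated by the occluder, and imaged through
#' the pupil focused at `zFocus` relative to the tissue plane (so the
#' occluder-plane content carries a residual defocus of
#' `zFocus - separation`).  With a transparent occluder the result reduces
#' exactly to [simulateStack()] of the tissue alone at `z = zFocus`.
#'
#' @param scene A [TwoPlaneScene-class] on the HR grid of `config`.
#' @param config An [OpticalConfig-class].
#' @param zFocus Focal plane of the acquisition relative to the tissue
#'   plane (um); 0 focuses the tissue.
#' @param gammas Positive scalar or length-N intensity factors.
#' @param noise A [noiseSpec()] or NULL.
#' @param seed Integer seed for the noise draws.
#' @return A [CaptureStack-class].
#' @export
simulateTwoPlaneStack <- function(scene, config, zFocus = 0, gammas = 1,
                                  noise = NULL, seed = 0L) {
  stopifnot(methods::is(scene, "TwoPlaneScene"),
            methods::is(config, "OpticalConfig"))
  n_hr <- hrShape(config)
  if (nrow(scene@tissue@phase) != n_hr)
    stop(sprintf("scene grid %d does not match config HR grid %d",
                 nrow(scene@tissue@phase), n_hr))

  illum <- ledWavevectors(config)
  N <- nrow(illum@wavevectors)
  if (length(gammas) == 1L) gammas <- rep(gammas, N)
  if (length(gammas) != N) stop("gammas must be scalar or length ", N)
  if (any(gammas <= 0)) stop("gammas must be positive")
  pupil <- makePupil(config)
  kernel_img <- defocusKernel(config, zFocus - scene@separation)

  dk <- kStep(config)
  dx_hr <- hrPixelSize(config)
  O1 <- fft2c(objectField(scene@tissue))
  o2 <- objectField(scene@occluder)
  H_sep <- defocusKernelValues(n_hr, dx_hr, config@wavelength,
                               scene@separation)

  n_lr <- config@lrShape[1]
  scale <- n_lr / n_hr
  images <- array(0, dim = c(n_lr, n_lr, N))
  if (!is.null(noise)) set.seed(seed)
  for (i in seq_len(N)) {
    m <- pixelShift(illum@wavevectors[i, ], dk)
    w <- windowIndices(n_hr, n_lr, m)
    if (!w$ok)
      stop(sprintf("LED %d: spectrum window out of the HR band", i))
    # circular-shift theorem: multiplying the tissue by the tilt phase
    # shifts its spectrum by the integer pixel offset
    Psi <- H_sep * rollMatrix(O1, m)
    field2 <- o2 * ifft2c(Psi)
    S2 <- fft2c(field2)
    w0 <- windowIndices(n_hr, n_lr, c(0L, 0L))
    E <- ifft2c(S2[w0$rows, w0$cols] *
                  (pupil@values * kernel_img@values)) * scale
    fr <- gammas[i] * Mod(E)^2
    if (!is.null(noise)) fr <- applyNoise(fr, noise)
    images[, , i] <- fr
  }
  methods::new("CaptureStack",
    images = images, gammas = as.numeric(gammas), config = config,
    illumination = illum,
    metadata = list(z = zFocus, separation = scene@separation,
                    seed = as.integer(seed), noise = noise,
                    maskFraction = scene@maskFraction, ordering = "spiral"))
}

# Circular shift implementing roll(X, m)[u] = X[u - m] on centered indices.
rollMatrix <- function(x, m) {
  n1 <- nrow(x); n2 <- ncol(x)
  ri <- ((seq_len(n1) - 1 - m[1]) %% n1) + 1
  ci <- ((seq_len(n2) - 1 - m[2]) %% n2) + 1
  x[ri, ci]
}
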