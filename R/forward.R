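#' @include defocus.R pupil.R illumination.R optical-config.R
NULL

#' DC-centered object spectrum
#'
#' Holds the unitary Fourier transform of a complex object field on the
#' high-resolution grid; `values` is DC-centered and `kStep` is the
#' frequency sampling (1/um), identical for the HR and LR grids because
#' both span the same field of view.
#'
#' @slot values Complex DC-centered HR spectrum.
#' @slot kStep Frequency sampling step (1/um).
#' @export
setClass("ObjectSpectrum",
  representation(values = "matrix", kStep = "numeric"))

#' Construct a complex object
#'
#' @param phase Real matrix, phase in radians.
#' @param absorption Real nonnegative matrix of the same shape.
#' @param pixelSize Object-plane pixel pitch (um).
#' @return A [ComplexObject-class].
#' @export
complexObject <- function(phase, absorption, pixelSize) {
  methods::new("ComplexObject", phase = phase, absorption = absorption,
               pixelSize = pixelSize)
}

#' Complex field and spectrum of an object
#'
#' `objectField()` evaluates `o(r) = exp(i*phase - absorption)`;
#' `objectSpectrum()` returns its unitary DC-centered transform.
#'
#' @param object A [ComplexObject-class].
#' @return A complex matrix, or an [ObjectSpectrum-class].
#' @export
objectField <- function(object) {
  exp(1i * object@phase - object@absorption)
}

#' @rdname objectField
#' @export
objectSpectrum <- function(object) {
  n <- nrow(object@phase)
  methods::new("ObjectSpectrum",
    values = fft2c(objectField(object)),
    kStep = 1 / (n * object@pixelSize))
}

#' @rdname accessors
#' @export
setMethod("pixelSize", "ComplexObject", function(x) x@pixelSize)

#' @rdname accessors
#' @export
setMethod("phaseMap", "ComplexObject", function(x) x@phase)

#' @rdname accessors
#' @export
setMethod("absorptionMap", "ComplexObject", function(x) x@absorption)

setMethod("show", "ComplexObject", function(object) {
  cat(sprintf(
    "ComplexObject: %d x %d grid, pixel %.4f um, phase [%.3f, %.3f] rad, absorption [%.3f, %.3f]\n",
    nrow(object@phase), ncol(object@phase), object@pixelSize,
    min(object@phase), max(object@phase),
    min(object@absorption), max(object@absorption)))
})

# ---------------------------------------------------------------------------
# Spectrum window bookkeeping

# Row/column indices of the LR-sized window implementing the substitution
# S[u] = O[u - m]: the portion of the HR spectrum centered at pixel offset
# -m from DC.  m = (m_row, m_col) is the integer pixel shift of the
# illumination wavevector (rows ~ ky, cols ~ kx).
windowIndices <- function(n_hr, n_lr, m) {
  c_h <- n_hr / 2 + 1
  start <- c_h - n_lr / 2 - m
  list(rows = start[1]:(start[1] + n_lr - 1),
       cols = start[2]:(start[2] + n_lr - 1),
       ok = all(start >= 1) && all(start + n_lr - 1 <= n_hr))
}

# Integer pixel shift (m_row, m_col) of a wavevector k_m = (kx, ky).
pixelShift <- function(k_m, kStep) {
  c(round(k_m[2] / kStep), round(k_m[1] / kStep))
}

#' One low-resolution capture from the forward model
#'
#' Implements the defocused FPM capture equation: the LR-sized window of
#' the HR object spectrum centered at the illumination shift `k_m`
#' (nearest-pixel centering) is filtered by the pupil and the defocus
#' kernel, inverse-transformed, and squared:
#' `I = gamma * |IFFT( O(k - k_m) P(k) H(k, z) )|^2`.
#' Energy bookkeeping uses unitary transforms with an `n_lr / n_hr` field
#' scale so that a unit-transmittance object yields a unit-intensity frame.
#'
#' @param spectrum An [ObjectSpectrum-class] on the HR grid.
#' @param k_m Length-2 wavevector `(kx, ky)` in 1/um.
#' @param pupil A [Pupil-class] on the LR grid.
#' @param kernel A [DefocusKernel-class] on the LR grid.
#' @param gamma Nonnegative intensity factor of the capture.
#' @param ledIndex Optional integer used in the out-of-band error message.
#' @return Real nonnegative LR matrix.
#' @export
forwardCapture <- function(spectrum, k_m, pupil, kernel, gamma = 1,
                           ledIndex = NA_integer_) {
  n_hr <- nrow(spectrum@values)
  n_lr <- nrow(pupil@values)
  m <- pixelShift(k_m, spectrum@kStep)
  w <- windowIndices(n_hr, n_lr, m)
  if (!w$ok)
    stop(sprintf(
      "LED %s: spectrum window at pixel shift (%d, %d) extends beyond the %d^2 HR spectrum",
      ifelse(is.na(ledIndex), "?", as.character(ledIndex)), m[1], m[2], n_hr))
  # grouping (P * H) first matches the reconstruction objective exactly
  field <- ifft2c(spectrum@values[w$rows, w$cols] *
                    (pupil@values * kernel@values)) * (n_lr / n_hr)
  gamma * Mod(field)^2
}

# ---------------------------------------------------------------------------
# Noise model and full-stack simulation

#' Capture noise specification
#'
#' Optional Poisson shot noise at a stated photon budget plus additive
#' Gaussian read noise, both in the normalised intensity units of the
#' simulator (a unit-transmittance object images at intensity 1).
#'
#' @param photons Expected photons per unit intensity per pixel
#'   (NULL disables shot noise).
#' @param readSigma Standard deviation of additive read noise (counts in
#'   normalised intensity units; 0 disables).
#' @return A list of class `fpm_noise`.
#' @export
noiseSpec <- function(photons = NULL, readSigma = 0) {
  stopifnot(is.null(photons) || photons > 0, readSigma >= 0)
  structure(list(photons = photons, readSigma = readSigma),
            class = "fpm_noise")
}

applyNoise <- function(frame, noise) {
  if (!is.null(noise$photons)) {
    frame <- matrix(
      stats::rpois(length(frame), frame * noise$photons) / noise$photons,
      nrow(frame), ncol(frame))
  }
  if (noise$readSigma > 0) {
    frame <- frame + matrix(stats::rnorm(length(frame), 0, noise$readSigma),
                            nrow(frame), ncol(frame))
  }
  pmax(frame, 0)
}

#' Simulate a full FPM capture stack
#'
#' Drives [forwardCapture()] over every LED of the array, optionally at a
#' common defocus `z`, with per-capture intensity factors and optional
#' shot/read noise.  Deterministic for a given `seed`.
#'
#' @param object A [ComplexObject-class] on the HR grid of `config`.
#' @param config An [OpticalConfig-class].
#' @param z Defocus distance of the acquisition (um).
#' @param gammas Positive scalar or length-N vector of intensity factors.
#' @param noise A [noiseSpec()] or NULL for noiseless captures.
#' @param seed Integer seed used for the noise draws.
#' @param pupil Optional [Pupil-class] overriding the unaberrated default
#'   (e.g. to simulate aberrated acquisitions).
#' @return A [CaptureStack-class].
#' @examples
#' obj <- makePhantom(phantomSpec("uniform", size = 64L))
#' stack <- simulateStack(obj, opticalConfig(lrShape = c(16L, 16L)))
#' nFrames(stack)   # 169
#' @export
simulateStack <- function(object, config, z = 0, gammas = 1, noise = NULL,
                          seed = 0L, pupil = NULL) {
  stopifnot(methods::is(object, "ComplexObject"),
            methods::is(config, "OpticalConfig"))
  n_hr <- hrShape(config)
  if (nrow(object@phase) != n_hr)
    stop(sprintf("object grid %d does not match config HR grid %d",
                 nrow(object@phase), n_hr))
  illum <- ledWavevectors(config)
  N <- nrow(illum@wavevectors)
  if (length(gammas) == 1L) gammas <- rep(gammas, N)
  if (length(gammas) != N)
    stop("gammas must be scalar or length ", N)
  if (any(gammas <= 0)) stop("gammas must be positive")
  if (is.null(pupil)) pupil <- makePupil(config)
  kernel <- defocusKernel(config, z)
  spec <- objectSpectrum(object)

  n_lr <- config@lrShape[1]
  images <- array(0, dim = c(n_lr, n_lr, N))
  if (!is.null(noise)) set.seed(seed)
  for (i in seq_len(N)) {
    frame <- forwardCapture(spec, illum@wavevectors[i, ], pupil, kernel,
                            gammas[i], ledIndex = i)
    if (!is.null(noise)) frame <- applyNoise(frame, noise)
    images[, , i] <- frame
  }
  methods::new("CaptureStack",
    images = images, gammas = as.numeric(gammas), config = config,
    illumination = illum,
    metadata = list(z = z, seed = as.integer(seed),
                    noise = noise, ordering = "spiral"))
}

#' @rdname accessors
#' @export
setMethod("gammas", "CaptureStack", function(x) x@gammas)

#' @rdname accessors
#' @export
setMethod("nFrames", "CaptureStack", function(x) dim(x@images)[3])

#' Extract one frame of a capture stack
#'
#' @param stack A [CaptureStack-class].
#' @param i Frame index in the stack's LED ordering.
#' @return Real LR matrix.
#' @export
frame <- function(stack, i) stack@images[, , i]

#' Central-LED frame of a capture stack
#'
#' @param stack A [CaptureStack-class].
#' @return Real LR matrix captured under on-axis illumination.
#' @export
centralFrame <- function(stack) {
  frame(stack, stack@illumination@centralIndex)
}

setMethod("show", "CaptureStack", function(object) {
  d <- dim(object@images)
  cat(sprintf(
    "CaptureStack: %d frames of %d x %d, lambda %.3f um, z %.1f um\n",
    d[3], d[1], d[2], object@config@wavelength,
    if (is.null(object@metadata$z)) NA_real_ else object@metadata$z))
})
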