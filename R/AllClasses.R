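#' @include AllGenerics.R
NULL

# ---------------------------------------------------------------------------
# OpticalConfig

#' Optical configuration of an FPM acquisition
#'
#' Describes the microscope and LED-array geometry of a Fourier
#' ptychographic capture: illumination wavelength, objective NA and
#' magnification, camera pixel pitch, LED grid layout and stand-off height,
#' and the sampling of the reconstruction grids.  Lengths are micrometres
#' except `ledPitch` and `ledHeight`, which follow the field's convention of
#' millimetres.
#'
#' The object-plane pixel of a capture is `cameraPixel / magnification`;
#' the high-resolution grid refines it by the integer factor `hrUpsample`
#' over the same field of view.
#'
#' @slot wavelength Illumination wavelength (um).
#' @slot objectiveNa Objective numerical aperture, in (0, 1).
#' @slot magnification Objective magnification (> 0).
#' @slot cameraPixel Camera pixel pitch at the sensor plane (um).
#' @slot ledGrid Integer pair (rows, cols) of the LED array.
#' @slot ledPitch Center-to-center LED spacing (mm).
#' @slot ledHeight Sample-to-array distance (mm).
#' @slot hrUpsample Integer >= 2; high-resolution oversampling factor.
#' @slot lrShape Integer pair: pixels per low-resolution capture.
#'
#' @seealso [opticalConfig()] for the user constructor.
#' @export
setClass("OpticalConfig",
  representation(
    wavelength = "numeric",
    objectiveNa = "numeric",
    magnification = "numeric",
    cameraPixel = "numeric",
    ledGrid = "integer",
    ledPitch = "numeric",
    ledHeight = "numeric",
    hrUpsample = "integer",
    lrShape = "integer"
  )
)

setValidity("OpticalConfig", function(object) {
  msg <- character()
  if (length(object@wavelength) != 1L || object@wavelength <= 0)
    msg <- c(msg, "wavelength must be a single positive length (um)")
  if (length(object@objectiveNa) != 1L ||
      object@objectiveNa <= 0 || object@objectiveNa >= 1)
    msg <- c(msg, "objectiveNa must lie strictly in (0, 1)")
  if (length(object@magnification) != 1L || object@magnification <= 0)
    msg <- c(msg, "magnification must be positive")
  if (length(object@cameraPixel) != 1L || object@cameraPixel <= 0)
    msg <- c(msg, "cameraPixel must be positive (um)")
  if (length(object@ledGrid) != 2L || any(object@ledGrid < 1L))
    msg <- c(msg, "ledGrid must be two positive integers")
  if (length(object@ledHeight) != 1L || object@ledHeight <= 0)
    msg <- c(msg, "ledHeight must be positive (mm)")
  if (length(object@ledPitch) != 1L || object@ledPitch <= 0)
    msg <- c(msg, "ledPitch must be positive (mm)")
  if (length(object@hrUpsample) != 1L || object@hrUpsample < 2L)
    msg <- c(msg, "hrUpsample must be an integer >= 2")
  if (length(object@lrShape) != 2L || any(object@lrShape < 4L))
    msg <- c(msg, "lrShape must be two integers >= 4")
  if (length(object@lrShape) == 2L &&
      (object@lrShape[1] != object@lrShape[2] || object@lrShape[1] %% 2L != 0L))
    msg <- c(msg, "lrShape must be square with an even side")
  if (length(msg)) msg else TRUE
})

# ---------------------------------------------------------------------------
# ComplexObject

#' Complex transmission of a thin sample
#'
#' The sample is the thin complex transmittance
#' `o(r) = exp(i*phase(r) - absorption(r))` on a square, even-sided
#' high-resolution grid: `phase` is the optical path delay in radians and
#' `absorption` the (nonnegative) attenuation exponent, so the amplitude
#' `|o| = exp(-absorption)` lies in (0, 1].
#'
#' @slot phase Real matrix, phase in radians.
#' @slot absorption Real nonnegative matrix, attenuation exponent.
#' @slot pixelSize Object-plane pixel pitch (um).
#' @export
setClass("ComplexObject",
  representation(
    phase = "matrix",
    absorption = "matrix",
    pixelSize = "numeric"
  )
)

setValidity("ComplexObject", function(object) {
  msg <- character()
  d <- dim(object@phase)
  if (!identical(d, dim(object@absorption)))
    msg <- c(msg, "phase and absorption must share dimensions")
  if (d[1] != d[2] || d[1] %% 2L != 0L)
    msg <- c(msg, "grid must be square with an even side length")
  if (any(object@absorption < 0))
    msg <- c(msg, "absorption must be nonnegative")
  if (length(object@pixelSize) != 1L || object@pixelSize <= 0)
    msg <- c(msg, "pixelSize must be a single positive length (um)")
  if (length(msg)) msg else TRUE
})

# ---------------------------------------------------------------------------
# IlluminationSet

#' Per-LED illumination wavevectors
#'
#' Spectral shifts `k_m = (sin(theta_x)/lambda, sin(theta_y)/lambda)` for
#' every LED, ordered center-outward so index 1 is the on-axis LED.
#'
#' @slot wavevectors N x 2 matrix of spectral shifts (1/um).
#' @slot ledIndices N x 2 integer matrix of signed (row, col) grid offsets
#'   from the central LED.
#' @slot centralIndex Index of the on-axis LED (always 1 for the package's
#'   spiral ordering).
#' @slot wavelength Wavelength used to scale the shifts (um).
#' @export
setClass("IlluminationSet",
  representation(
    wavevectors = "matrix",
    ledIndices = "matrix",
    centralIndex = "integer",
    wavelength = "numeric"
  )
)

setValidity("IlluminationSet", function(object) {
  msg <- character()
  if (ncol(object@wavevectors) != 2L) msg <- c(msg, "wavevectors must be N x 2")
  if (nrow(object@wavevectors) != nrow(object@ledIndices))
    msg <- c(msg, "wavevectors and ledIndices must have equal rows")
  ci <- object@centralIndex
  if (length(ci) != 1L || ci < 1L || ci > nrow(object@wavevectors))
    msg <- c(msg, "centralIndex out of range")
  else if (any(object@wavevectors[ci, ] != 0))
    msg <- c(msg, "central LED must have an exactly zero wavevector")
  sines <- object@wavelength * sqrt(rowSums(object@wavevectors^2))
  if (any(sines > 1 + 1e-12))
    msg <- c(msg, "|lambda * k_m| must not exceed 1 (non-physical tilt)")
  if (length(msg)) msg else TRUE
})

# ---------------------------------------------------------------------------
# Pupil

#' Coherent transfer function of the objective
#'
#' NA-limited support disk with a Zernike-parameterised phase:
#' `P(k) = support(k) * exp(i * sum_j c_j Z_j(k))`, with Noll-indexed
#' Zernike polynomials evaluated on the disk normalised to the cutoff
#' frequency `NA / lambda`.
#'
#' @slot support Logical matrix, the NA disk on the LR frequency grid.
#' @slot zernikeCoeffs Real vector of Noll-indexed coefficients (radians).
#' @slot values Complex matrix `P(k)`.
#' @slot cutoff Cutoff frequency `NA / lambda` (1/um).
#' @slot kStep Frequency sampling step of the grid (1/um).
#' @export
setClass("Pupil",
  representation(
    support = "matrix",
    zernikeCoeffs = "numeric",
    values = "matrix",
    cutoff = "numeric",
    kStep = "numeric"
  )
)

setValidity("Pupil", function(object) {
  msg <- character()
  if (!identical(dim(object@support), dim(object@values)))
    msg <- c(msg, "support and values must share dimensions")
  if (any(Mod(object@values[!object@support]) != 0))
    msg <- c(msg, "P(k) must vanish outside the support disk")
  if (length(msg)) msg else TRUE
})

# ---------------------------------------------------------------------------
# DefocusKernel

#' Angular-spectrum defocus kernel
#'
#' `H(k, z) = exp(i * (2*pi/lambda) * z * sqrt(1 - (lambda kx)^2 -
#' (lambda ky)^2))` on the LR frequency grid; evanescent frequencies
#' (negative radicand) decay exponentially with `|z|`.
#'
#' @slot z Signed defocus distance (um).
#' @slot values Complex matrix `H(k, z)`.
#' @export
setClass("DefocusKernel",
  representation(z = "numeric", values = "matrix")
)

# ---------------------------------------------------------------------------
# CaptureStack

#' Stack of low-resolution intensity captures
#'
#' The N intensity frames of one FPM acquisition together with their
#' per-capture intensity factors and the acquisition geometry.
#'
#' @slot images Numeric array `n x n x N` of nonnegative intensities.
#' @slot gammas Positive numeric vector of length N.
#' @slot config The [OpticalConfig-class] of the acquisition.
#' @slot illumination The matching [IlluminationSet-class].
#' @slot metadata List of free-form provenance (defocus used in simulation,
#'   seed, noise specification, ...).
#' @export
setClass("CaptureStack",
  representation(
    images = "array",
    gammas = "numeric",
    config = "OpticalConfig",
    illumination = "IlluminationSet",
    metadata = "list"
  )
)

setValidity("CaptureStack", function(object) {
  msg <- character()
  d <- dim(object@images)
  if (length(d) != 3L) msg <- c(msg, "images must be an n x n x N array")
  else {
    if (d[3] != length(object@gammas))
      msg <- c(msg, "length(gammas) must equal the number of frames")
    if (d[3] != nrow(object@illumination@wavevectors))
      msg <- c(msg, "frame count must match the illumination set")
    if (!identical(as.integer(d[1:2]), as.integer(object@config@lrShape)))
      msg <- c(msg, "frame shape must match config lrShape")
  }
  if (any(object@images < 0)) msg <- c(msg, "intensities must be nonnegative")
  if (any(object@gammas <= 0)) msg <- c(msg, "gammas must be positive")
  if (length(msg)) msg else TRUE
})

# ---------------------------------------------------------------------------
# ReconstructionState

#' State of a joint FPM reconstruction
#'
#' Carries the current estimates of every jointly optimised parameter
#' group: the DC-centered high-resolution object spectrum, the pupil
#' Zernike coefficients, the defocus distance, the per-capture intensity
#' factors, plus the per-epoch loss trace.
#'
#' @slot spectrum Complex HR matrix, DC-centered object spectrum estimate.
#' @slot zernikeCoeffs Real vector of pupil coefficients (radians).
#' @slot z Defocus estimate (um).
#' @slot gammas Positive vector of per-capture intensity factors.
#' @slot lossHistory Nonnegative per-epoch objective values.
#' @slot epoch Number of completed epochs.
#' @slot config Acquisition [OpticalConfig-class].
#' @slot illumination Acquisition [IlluminationSet-class].
#' @export
setClass("ReconstructionState",
  representation(
    spectrum = "matrix",
    zernikeCoeffs = "numeric",
    z = "numeric",
    gammas = "numeric",
    lossHistory = "numeric",
    epoch = "integer",
    config = "OpticalConfig",
    illumination = "IlluminationSet"
  )
)

setValidity("ReconstructionState", function(object) {
  msg <- character()
  n_hr <- as.integer(object@config@lrShape[1] * object@config@hrUpsample)
  if (!identical(as.integer(dim(object@spectrum)), c(n_hr, n_hr)))
    msg <- c(msg, "spectrum grid must be hrUpsample * lrShape")
  if (any(object@gammas <= 0)) msg <- c(msg, "gammas must stay positive")
  if (any(object@lossHistory < 0)) msg <- c(msg, "loss history must be >= 0")
  if (length(msg)) msg else TRUE
})

# ---------------------------------------------------------------------------
# OptimizerSpec

#' Optimiser settings for joint reconstruction
#'
#' @slot lossKind `"L1"` (default, robust data misfit) or `"L2"`.
#' @slot learningRates Named positive numerics for the parameter groups
#'   `spectrum`, `pupil`, `z`, `gamma` (Adam step sizes; `z` in um).
#' @slot epochs Number of passes over the LED set.
#' @slot batchSize LEDs per mini-batch.
#' @slot seed Integer seed controlling batch shuffling (and nothing else).
#' @slot freeze Character subset of the group names to exclude from
#'   optimisation.
#' @slot lrSchedule `"cosine"` (default: step sizes anneal to zero over
#'   the epoch budget, letting the fit settle to the noise floor) or
#'   `"constant"`.
#' @export
setClass("OptimizerSpec",
  representation(
    lossKind = "character",
    learningRates = "numeric",
    epochs = "integer",
    batchSize = "integer",
    seed = "integer",
    freeze = "character",
    lrSchedule = "character"
  )
)

setValidity("OptimizerSpec", function(object) {
  msg <- character()
  if (!object@lossKind %in% c("L1", "L2"))
    msg <- c(msg, "lossKind must be 'L1' or 'L2'")
  need <- c("spectrum", "pupil", "z", "gamma")
  if (!all(need %in% names(object@learningRates)))
    msg <- c(msg, "learningRates must name spectrum, pupil, z and gamma")
  else if (any(object@learningRates[need] <= 0))
    msg <- c(msg, "learning rates must be positive")
  if (object@epochs < 1L) msg <- c(msg, "epochs must be >= 1")
  if (object@batchSize < 1L) msg <- c(msg, "batchSize must be >= 1")
  if (!all(object@freeze %in% need))
    msg <- c(msg, "freeze may only name spectrum, pupil, z, gamma")
  if (!object@lrSchedule %in% c("cosine", "constant"))
    msg <- c(msg, "lrSchedule must be 'cosine' or 'constant'")
  if (length(msg)) msg else TRUE
})

# ---------------------------------------------------------------------------
# Synthetic-data classes

#' Specification of a synthetic phantom
#'
#' @slot kind One of `"tissue"`, `"two_point"`, `"star"`, `"bars"`,
#'   `"uniform"`.
#' @slot size High-resolution grid side (even integer).
#' @slot muRange Absorption bounds, nonnegative length-2.
#' @slot phiRange Phase bounds in radians, length-2.
#' @slot featureScale Characteristic feature size (um); for `two_point`
#'   this is the center-to-center separation.
#' @slot pixelSize HR pixel pitch (um).
#' @slot seed Integer seed for reproducible generation.
#' @export
setClass("PhantomSpec",
  representation(
    kind = "character",
    size = "integer",
    muRange = "numeric",
    phiRange = "numeric",
    featureScale = "numeric",
    pixelSize = "numeric",
    seed = "integer"
  )
)

setValidity("PhantomSpec", function(object) {
  msg <- character()
  if (!object@kind %in% c("tissue", "two_point", "star", "bars", "uniform"))
    msg <- c(msg, "unknown phantom kind")
  if (object@size < 8L || object@size %% 2L != 0L)
    msg <- c(msg, "size must be an even integer >= 8")
  if (any(object@muRange < 0) || diff(object@muRange) < 0)
    msg <- c(msg, "muRange must be nonnegative and nondecreasing")
  if (diff(object@phiRange) < 0) msg <- c(msg, "phiRange must be nondecreasing")
  if (object@pixelSize <= 0) msg <- c(msg, "pixelSize must be positive")
  if (length(msg)) msg else TRUE
})

#' Two-plane scene: tissue plus an out-of-plane occluder
#'
#' A tissue object at the focal plane `z = 0` and an occluding object
#' (e.g. opaque marker strokes) a distance `separation` above it, towards
#' the objective.  In reconstruction coordinates the occluder plane renders
#' sharp at defocus `-separation`.
#'
#' @slot tissue [ComplexObject-class] at the focal plane.
#' @slot occluder [ComplexObject-class] at the occluder plane.
#' @slot separation Axial plane separation (um), nonzero.
#' @slot maskFraction Fraction of the field covered by the occluder
#'   (absorption > half its maximum).
#' @export
setClass("TwoPlaneScene",
  representation(
    tissue = "ComplexObject",
    occluder = "ComplexObject",
    separation = "numeric",
    maskFraction = "numeric"
  )
)

setValidity("TwoPlaneScene", function(object) {
  msg <- character()
  if (!identical(dim(object@tissue@phase), dim(object@occluder@phase)))
    msg <- c(msg, "tissue and occluder must share grids")
  if (object@separation == 0) msg <- c(msg, "separation must be nonzero")
  if (length(msg)) msg else TRUE
})

# ---------------------------------------------------------------------------
# Refocus / RGB results

#' Result of a digital refocus search
#'
#' @slot zStar Best defocus estimate (um).
#' @slot zGrid Candidate defocuses evaluated (empty for joint mode).
#' @slot scoreCurve Focus score per candidate (final reconstruction loss).
#' @slot method `"joint_opt"` or `"sweep"`.
#' @slot atBoundary TRUE when the sweep argmin sits on an endpoint of the
#'   search range (range likely too narrow).
#' @export
setClass("RefocusResult",
  representation(
    zStar = "numeric",
    zGrid = "numeric",
    scoreCurve = "numeric",
    method = "character",
    atBoundary = "logical"
  )
)

setValidity("RefocusResult", function(object) {
  msg <- character()
  if (length(object@zGrid) != length(object@scoreCurve))
    msg <- c(msg, "scoreCurve must match zGrid in length")
  if (object@method == "sweep" && length(object@zGrid) &&
      !any(object@zGrid == object@zStar))
    msg <- c(msg, "sweep zStar must be a grid point")
  if (length(msg)) msg else TRUE
})

#' Tri-wavelength RGB assembly
#'
#' @slot channels Array `n x n x 3`, channel order (R, G, B) from
#'   wavelengths (623, 523, 470) nm, each normalised to [0, 1].
#' @slot normalization Per-channel scale divisor applied (the recorded
#'   percentile value), length 3.
#' @slot wavelengths Wavelengths (um) in channel order.
#' @export
setClass("RgbImage",
  representation(
    channels = "array",
    normalization = "numeric",
    wavelengths = "numeric"
  )
)

setValidity("RgbImage", function(object) {
  msg <- character()
  d <- dim(object@channels)
  if (length(d) != 3L || d[3] != 3L)
    msg <- c(msg, "channels must be n x n x 3")
  if (any(object@channels < 0) || any(object@channels > 1))
    msg <- c(msg, "channel values must lie in [0, 1]")
  if (length(msg)) msg else TRUE
})
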