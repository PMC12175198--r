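#' @include AllClasses.R
NULL

#' Build the objective's pupil function
#'
#' The coherent transfer function on the LR frequency grid: a binary disk
#' of radius `NA / lambda` carrying a Zernike-parameterised phase,
#' `P(k) = disk(k) * exp(i * sum_j c_j Z_j(k))` with Noll-indexed Z_j on
#' the disk normalised to the cutoff radius.  Coefficients are radians;
#' the first (piston) coefficient only sets a global phase and never
#' affects intensities.
#'
#' @param config An [OpticalConfig-class].
#' @param zernikeCoeffs Real coefficient vector; default the unaberrated
#'   initialisation `c(1, 0, ..., 0)`.
#' @param J Basis size when `zernikeCoeffs` is shorter (default 15).
#' @return A [Pupil-class].
#' @examples
#' p <- makePupil(opticalConfig())
#' p@cutoff   # 0.3 / 0.523 ~ 0.574 1/um
#' @export
makePupil <- function(config, zernikeCoeffs = NULL, J = 15L) {
  stopifnot(methods::is(config, "OpticalConfig"))
  n <- config@lrShape[1]
  dx <- lrPixelSize(config)
  cutoff <- config@objectiveNa / config@wavelength
  nyquist <- 1 / (2 * dx)
  if (cutoff > nyquist)
    stop(sprintf(
      "pupil cutoff %.4f 1/um exceeds the capture Nyquist frequency %.4f 1/um: the capture is undersampled",
      cutoff, nyquist))

  if (is.null(zernikeCoeffs)) {
    zernikeCoeffs <- c(1, rep(0, J - 1L))
  } else if (length(zernikeCoeffs) < J) {
    zernikeCoeffs <- c(zernikeCoeffs, rep(0, J - length(zernikeCoeffs)))
  }
  J <- length(zernikeCoeffs)

  support <- matrix(sqrt(freqRadiusSq(n, dx)) <= cutoff, n, n)
  basis <- zernikeBasis(n, dx, cutoff, J)
  phase <- matrix(as.vector(basis %*% zernikeCoeffs), n, n)
  values <- ifelse(support, exp(1i * phase), 0 + 0i)

  methods::new("Pupil",
    support = support, zernikeCoeffs = as.numeric(zernikeCoeffs),
    values = values, cutoff = cutoff, kStep = 1 / (n * dx))
}

setMethod("show", "Pupil", function(object) {
  cat(sprintf("Pupil: %d x %d grid, cutoff %.4f 1/um, %d Zernike coefficients\n",
              nrow(object@values), ncol(object@values), object@cutoff,
              length(object@zernikeCoeffs)))
})
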