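#' @include AllClasses.R
NULL

# sqrt(1 - (lambda kx)^2 - (lambda ky)^2) on the LR grid, 0 where
# evanescent.  Shared by the kernel and its z-derivative.
defocusRadicand <- function(n, dx, wavelength) {
  arg <- 1 - wavelength^2 * freqRadiusSq(n, dx)
  sqrt(pmax(arg, 0))
}

#' Angular-spectrum defocus kernel
#'
#' `H(k, z) = exp(i * (2*pi/lambda) * z * sqrt(1 - (lambda kx)^2 -
#' (lambda ky)^2))` on the LR frequency grid of `config`.  Evanescent
#' frequencies (negative radicand) decay exponentially with the
#' propagation distance, `exp(-(2*pi/lambda) * |z| * sqrt((lambda k)^2 -
#' 1))`, so they vanish over any realistic defocus yet survive the
#' zero-distance limit continuously.  `H(k, 0) = 1` and
#' `H(k, -z) = Conj(H(k, z))` everywhere (the evanescent factor is real).
#'
#' @param config An [OpticalConfig-class].
#' @param z Signed defocus distance (um); positive towards the objective.
#' @return A [DefocusKernel-class].
#' @export
defocusKernel <- function(config, z) {
  stopifnot(methods::is(config, "OpticalConfig"), length(z) == 1L,
            is.finite(z))
  n <- config@lrShape[1]
  dx <- lrPixelSize(config)
  values <- defocusKernelValues(n, dx, config@wavelength, z)
  methods::new("DefocusKernel", z = z, values = values)
}

# Raw kernel values on an arbitrary square grid (also used at HR for
# plane-to-plane propagation in two-plane scenes).
defocusKernelValues <- function(n, dx, wavelength, z) {
  if (z == 0) return(matrix(1 + 0i, n, n))   # exp(0) for every frequency
  arg <- 1 - wavelength^2 * freqRadiusSq(n, dx)
  prop <- arg >= 0
  values <- matrix(0 + 0i, n, n)
  values[prop] <- exp(1i * (2 * pi / wavelength) * z * sqrt(arg[prop]))
  # evanescent components decay exponentially with propagation distance
  # (|z| in both directions: back-propagation must not amplify them)
  values[!prop] <- exp(-(2 * pi / wavelength) * abs(z) * sqrt(-arg[!prop]))
  values
}

setMethod("defocus", "DefocusKernel", function(x) x@z)
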