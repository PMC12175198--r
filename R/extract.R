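#' @include reconstruct.R
NULL

#' Extract the recovered object from a reconstruction state
#'
#' Inverse-transforms the state's spectrum into the complex object
#' estimate and derives the display quantities: HR intensity `|o|^2`,
#' phase `arg(o)` with the global piston removed (circular mean phase set
#' to zero, result re-wrapped into (-pi, pi]) and absorption
#' `-log|o|` clipped below at zero.
#'
#' @param state A [ReconstructionState-class].
#' @return A list with elements `object` (a [ComplexObject-class]),
#'   `intensity`, `phase` (both HR matrices) and `clippedAbsorption`
#'   (count of pixels whose absorption was clipped to zero).
#' @export
extractObject <- function(state) {
  stopifnot(methods::is(state, "ReconstructionState"))
  o <- ifft2c(state@spectrum)
  intensity <- Mod(o)^2
  ph <- Arg(o)
  piston <- Arg(mean(exp(1i * ph)))
  phase <- Arg(exp(1i * (ph - piston)))
  mu <- -log(pmax(Mod(o), .Machine$double.eps))
  clipped <- sum(mu < 0)
  mu <- pmax(mu, 0)
  list(
    object = complexObject(phase, mu, hrPixelSize(state@config)),
    intensity = intensity,
    phase = phase,
    clippedAbsorption = clipped)
}
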