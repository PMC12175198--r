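#' @include AllClasses.R
NULL

#' Per-LED spectral shifts from array geometry
#'
#' Each LED at lateral offset `(dx, dy)` from the optical axis illuminates
#' the sample with a tilted plane wave whose direction sines are
#' `sin(theta_x) = dx / sqrt(dx^2 + dy^2 + h^2)` (and likewise for y) with
#' `h` the sample-to-array distance; the induced spectral shift is
#' `k_m = (sin(theta_x)/lambda, sin(theta_y)/lambda)`.
#'
#' LEDs are ordered by a deterministic center-outward spiral: ascending
#' ring number (Chebyshev distance from the central LED), and within a
#' ring ascending angle from the +x axis, counter-clockwise.  Index 1 is
#' always the on-axis LED, so low spatial frequencies are visited first.
#'
#' @param config An [OpticalConfig-class]; `ledGrid` must be odd x odd so
#'   a central LED exists, unless `centralOverride` names the (row, col)
#'   of the LED to treat as on-axis.
#' @param centralOverride Optional integer pair overriding the central
#'   LED position (1-based grid indices) for even-sided arrays.
#' @return An [IlluminationSet-class].
#' @examples
#' illum <- ledWavevectors(opticalConfig())
#' nrow(wavevectors(illum))   # 169 LEDs
#' @export
ledWavevectors <- function(config, centralOverride = NULL) {
  stopifnot(methods::is(config, "OpticalConfig"))
  rows <- config@ledGrid[1]; cols <- config@ledGrid[2]
  if (is.null(centralOverride)) {
    if (rows %% 2L == 0L || cols %% 2L == 0L)
      stop("ledGrid ", rows, " x ", cols, " has no central LED; ",
           "pass centralOverride = c(row, col) to resolve the ambiguity")
    center <- c((rows + 1L) %/% 2L, (cols + 1L) %/% 2L)
  } else {
    center <- as.integer(centralOverride)
    stopifnot(length(center) == 2L,
              center[1] >= 1L, center[1] <= rows,
              center[2] >= 1L, center[2] <= cols)
  }

  ij <- expand.grid(row = seq_len(rows), col = seq_len(cols))
  di <- ij$row - center[1]
  dj <- ij$col - center[2]
  ring <- pmax(abs(di), abs(dj))
  ang <- atan2(di, dj) %% (2 * pi)     # 0 on +x axis, CCW
  ord <- order(ring, ang, di, dj)

  di <- di[ord]; dj <- dj[ord]
  # lateral offsets in um; pitch is stored in mm
  dx <- dj * config@ledPitch * 1e3
  dy <- di * config@ledPitch * 1e3
  h <- config@ledHeight * 1e3
  hyp <- sqrt(dx^2 + dy^2 + h^2)
  kx <- (dx / hyp) / config@wavelength
  ky <- (dy / hyp) / config@wavelength

  methods::new("IlluminationSet",
    wavevectors = cbind(kx = kx, ky = ky),
    ledIndices = cbind(row = as.integer(di), col = as.integer(dj)),
    centralIndex = 1L,
    wavelength = config@wavelength
  )
}

#' Synthetic-aperture illumination NA of an LED set
#'
#' The largest direction sine over the set, `max |lambda * k_m|`; added to
#' the objective NA it bounds the reconstructible band.
#'
#' @param illumination An [IlluminationSet-class].
#' @return Numeric in [0, 1).
#' @export
illuminationNa <- function(illumination) {
  max(illumination@wavelength * sqrt(rowSums(illumination@wavevectors^2)))
}

#' @rdname accessors
#' @export
setMethod("wavevectors", "IlluminationSet", function(x) x@wavevectors)

setMethod("show", "IlluminationSet", function(object) {
  cat(sprintf("IlluminationSet: %d LEDs, lambda %.3f um, illumination NA %.3f\n",
              nrow(object@wavevectors), object@wavelength,
              illuminationNa(object)))
})
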