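#' @include AllClasses.R
NULL

#' Construct an optical configuration
#'
#' Defaults reproduce the package's reference acquisition geometry: a
#' 10x / 0.3 NA objective, 6.5 um camera pixels (0.65 um at the object
#' plane), a 13 x 13 LED array with 4 mm pitch at 52 mm below the sample,
#' green illumination at 523 nm, 64 x 64-pixel captures and a 4x
#' high-resolution grid.
#'
#' @param wavelength Illumination wavelength (um).
#' @param objectiveNa Objective numerical aperture.
#' @param magnification Objective magnification.
#' @param cameraPixel Camera pixel pitch at the sensor (um).
#' @param ledGrid Integer pair (rows, cols) of the LED array.
#' @param ledPitch LED spacing (mm).
#' @param ledHeight Sample-to-array distance (mm).
#' @param hrUpsample Integer >= 2: HR grid refinement factor.
#' @param lrShape Integer pair: pixels per capture (square, even).
#' @return An [OpticalConfig-class].
#' @examples
#' cfg <- opticalConfig()
#' lrPixelSize(cfg)   # 0.65 um at the object plane
#' @export
opticalConfig <- function(wavelength = 0.523,
                          objectiveNa = 0.3,
                          magnification = 10,
                          cameraPixel = 6.5,
                          ledGrid = c(13L, 13L),
                          ledPitch = 4,
                          ledHeight = 52,
                          hrUpsample = 4L,
                          lrShape = c(64L, 64L)) {
  methods::new("OpticalConfig",
    wavelength = wavelength,
    objectiveNa = objectiveNa,
    magnification = magnification,
    cameraPixel = cameraPixel,
    ledGrid = as.integer(ledGrid),
    ledPitch = ledPitch,
    ledHeight = ledHeight,
    hrUpsample = as.integer(hrUpsample),
    lrShape = as.integer(lrShape)
  )
}

#' Derived sampling quantities of a configuration
#'
#' `lrPixelSize()` is the object-plane pixel of a capture
#' (`cameraPixel / magnification`, um); `hrPixelSize()` refines it by
#' `hrUpsample`; `hrShape()` is the high-resolution grid side; `kStep()`
#' the common frequency sampling step of both grids (1/um), which is shared
#' because both grids span the same field of view.
#'
#' @param config An [OpticalConfig-class].
#' @return A single numeric (or integer for `hrShape`).
#' @export
lrPixelSize <- function(config) config@cameraPixel / config@magnification

#' @rdname lrPixelSize
#' @export
hrPixelSize <- function(config) lrPixelSize(config) / config@hrUpsample

#' @rdname lrPixelSize
#' @export
hrShape <- function(config) as.integer(config@lrShape[1] * config@hrUpsample)

#' @rdname lrPixelSize
#' @export
kStep <- function(config) 1 / (config@lrShape[1] * lrPixelSize(config))

setMethod("show", "OpticalConfig", function(object) {
  cat("OpticalConfig\n",
      sprintf("  wavelength: %.3f um, NA %.2f, magnification %gx\n",
              object@wavelength, object@objectiveNa, object@magnification),
      sprintf("  camera pixel: %.2f um (object plane %.3f um)\n",
              object@cameraPixel, lrPixelSize(object)),
      sprintf("  LED array: %d x %d, pitch %g mm, height %g mm\n",
              object@ledGrid[1], object@ledGrid[2],
              object@ledPitch, object@ledHeight),
      sprintf("  grids: LR %d^2, HR %d^2 (upsample %d)\n",
              object@lrShape[1], hrShape(object), object@hrUpsample),
      sep = "")
})
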