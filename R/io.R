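#' @include two-plane.R reconstruct.R
NULL

# Power-of-two normalisation keeps TIFF's [0,1] float range without any
# rounding: dividing and re-multiplying by 2^k is exact in binary
# floating point.
pow2Scale <- function(mx) {
  if (!is.finite(mx) || mx <= 1) 1 else 2^ceiling(log2(mx))
}

configToList <- function(cfg) {
  list(
    wavelength = cfg@wavelength,
    objective_na = cfg@objectiveNa,
    magnification = cfg@magnification,
    camera_pixel = cfg@cameraPixel,
    led_grid = as.integer(cfg@ledGrid),
    led_pitch = cfg@ledPitch,
    led_height = cfg@ledHeight,
    hr_upsample = as.integer(cfg@hrUpsample),
    lr_shape = as.integer(cfg@lrShape))
}

configFromList <- function(x) {
  known <- c("wavelength", "objective_na", "magnification", "camera_pixel",
             "led_grid", "led_pitch", "led_height", "hr_upsample",
             "lr_shape")
  unknown <- setdiff(names(x), known)
  if (length(unknown))
    stop("unknown optical config key: ", paste(unknown, collapse = ", "))
  opticalConfig(
    wavelength = x$wavelength, objectiveNa = x$objective_na,
    magnification = x$magnification, cameraPixel = x$camera_pixel,
    ledGrid = x$led_grid, ledPitch = x$led_pitch,
    ledHeight = x$led_height, hrUpsample = x$hr_upsample,
    lrShape = x$lr_shape)
}

#' Write / read a capture stack
#'
#' The on-disk dialect is a multi-page 32-bit-sample TIFF (one LR frame
#' per page, pages in the package's spiral LED order) plus a YAML sidecar
#' holding the full optical configuration, the LED ordering name, the
#' simulation defocus, the intensity factors, seed and noise spec, and
#' the power-of-two intensity scale applied before writing.  Lengths in
#' the sidecar are micrometres except `led_pitch` and `led_height`
#' (millimetres), stated in its `units` field.
#'
#' Frames are stored as 32-bit fixed-point samples of `image / scale` in
#' [0, 1], with `scale` an exact power of two, so the round trip is
#' faithful to an absolute precision of about `2e-10 * scale` — far
#' beyond the 16-bit dialect also accepted on read.  16-bit input pages
#' are promoted to the same floating representation with the sidecar's
#' recorded scale.
#'
#' @param stack A [CaptureStack-class].
#' @param path Base path (with or without `.tif`); `.tif` and `.yml`
#'   files are written next to each other.
#' @return `writeStack()` the base path invisibly; `readStack()` the
#'   [CaptureStack-class].
#' @export
writeStack <- function(stack, path) {
  stopifnot(methods::is(stack, "CaptureStack"))
  base <- sub("\\.tiff?$", "", path)
  scale <- pow2Scale(max(stack@images))
  frames <- lapply(seq_len(nFrames(stack)),
                   function(i) stack@images[, , i] / scale)
  tiff::writeTIFF(frames, paste0(base, ".tif"), bits.per.sample = 32L,
                  reduce = FALSE)
  meta <- stack@metadata
  side <- list(
    units = "lengths in um except led_pitch and led_height in mm",
    optical = configToList(stack@config),
    ordering = "spiral",
    z = if (is.null(meta$z)) 0 else meta$z,
    gammas = as.numeric(stack@gammas),
    seed = if (is.null(meta$seed)) 0L else meta$seed,
    noise = if (is.null(meta$noise)) NULL
            else list(photons = meta$noise$photons,
                      read_sigma = meta$noise$readSigma),
    intensity_scale = scale,
    dtype = "fixed32")
  yaml::write_yaml(side, paste0(base, ".yml"))
  invisible(base)
}

#' @rdname writeStack
#' @export
readStack <- function(path) {
  base <- sub("\\.tiff?$", "", path)
  tifPath <- paste0(base, ".tif")
  ymlPath <- paste0(base, ".yml")
  if (!file.exists(ymlPath))
    stop("missing sidecar config file: ", ymlPath)
  if (!file.exists(tifPath))
    stop("missing stack file: ", tifPath)
  side <- yaml::read_yaml(ymlPath)
  cfg <- configFromList(side$optical)
  illum <- ledWavevectors(cfg)
  N <- nrow(illum@wavevectors)
  pages <- tiff::readTIFF(tifPath, all = TRUE, as.is = FALSE)
  if (length(pages) != N)
    stop(sprintf("%s: expected %d pages (one per LED), found %d",
                 tifPath, N, length(pages)))
  scale <- if (is.null(side$intensity_scale)) 1 else side$intensity_scale
  n_lr <- cfg@lrShape[1]
  images <- array(0, dim = c(n_lr, n_lr, N))
  for (i in seq_len(N)) {
    pg <- pages[[i]]
    if (length(dim(pg)) == 3L) pg <- pg[, , 1]   # tolerate grayscale RGB
    images[, , i] <- pg * scale
  }
  noise <- if (is.null(side$noise)) NULL
           else noiseSpec(photons = side$noise$photons,
                          readSigma = side$noise$read_sigma %||% 0)
  methods::new("CaptureStack",
    images = images, gammas = as.numeric(side$gammas), config = cfg,
    illumination = illum,
    metadata = list(z = side$z, seed = side$seed, noise = noise,
                    ordering = side$ordering,
                    dtype = side$dtype %||% "fixed32",
                    intensity_scale = scale))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write / read a real-valued HR map as a float TIFF
#'
#' Maps with arbitrary range (phase is signed) are stored as
#' `(x - offset) / scale` with an exact power-of-two scale and the
#' (offset, scale) pair recorded in a YAML sidecar, so values are
#' recovered to an absolute precision of about `2e-10 * scale`
#' (32-bit fixed-point TIFF samples).
#'
#' @param x Real matrix.
#' @param path Base path for the `.tif` / `.yml` pair.
#' @param what Short content tag stored in the sidecar.
#' @return `writeFloatMap()` the base path invisibly; `readFloatMap()`
#'   the matrix.
#' @export
writeFloatMap <- function(x, path, what = "map") {
  base <- sub("\\.tiff?$", "", path)
  offset <- min(x)
  scale <- pow2Scale(max(x) - offset)
  tiff::writeTIFF((x - offset) / scale, paste0(base, ".tif"),
                  bits.per.sample = 32L, reduce = FALSE)
  yaml::write_yaml(list(what = what, offset = offset, scale = scale),
                   paste0(base, ".yml"))
  invisible(base)
}

#' @rdname writeFloatMap
#' @export
readFloatMap <- function(path) {
  base <- sub("\\.tiff?$", "", path)
  side <- yaml::read_yaml(paste0(base, ".yml"))
  img <- tiff::readTIFF(paste0(base, ".tif"))
  if (length(dim(img)) == 3L) img <- img[, , 1]
  img * side$scale + side$offset
}

#' Write an RGB assembly as an 8-bit PNG
#'
#' @param rgb An [RgbImage-class].
#' @param path Output `.png` path.
#' @return The path, invisibly.
#' @export
writeRgbPng <- function(rgb, path) {
  stopifnot(methods::is(rgb, "RgbImage"))
  png::writePNG(rgb@channels, path)
  invisible(path)
}
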