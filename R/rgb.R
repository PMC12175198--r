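#' @include extract.R
NULL

#' Assemble three single-wavelength reconstructions into an RGB image
#'
#' Stacks the per-wavelength HR intensity maps along the channel
#' dimension in (R, G, B) = (623, 523, 470) nm order, regardless of the
#' order they are supplied in, and normalises each channel by a stated
#' percentile (robust to hot pixels; the divisor is recorded so the
#' scaling is reversible).
#'
#' @param maps List of three same-shaped HR intensity matrices.
#' @param wavelengths Numeric length-3: wavelength of each map, in um or
#'   nm (auto-detected).  Must be a permutation of 623/523/470 nm.
#' @param percentile Normalisation percentile in (0, 1]; default 0.99.
#' @return An [RgbImage-class] with channels clipped to [0, 1].
#' @export
assembleRgb <- function(maps, wavelengths = c(0.623, 0.523, 0.470),
                        percentile = 0.99) {
  stopifnot(length(maps) == 3L, length(wavelengths) == 3L)
  d <- dim(maps[[1]])
  if (!all(vapply(maps, function(m) identical(dim(m), d), logical(1))))
    stop("the three channel maps must share the same shape")
  wl <- ifelse(wavelengths > 10, wavelengths / 1000, wavelengths)  # nm -> um
  target <- c(0.623, 0.523, 0.470)
  ord <- vapply(target, function(t) {
    i <- which(abs(wl - t) < 0.02)
    if (length(i) != 1L)
      stop(sprintf("need exactly one map near %.0f nm", t * 1000))
    i
  }, integer(1))

  channels <- array(0, dim = c(d, 3L))
  normalization <- numeric(3)
  for (c3 in 1:3) {
    m <- maps[[ord[c3]]]
    q <- stats::quantile(m, percentile, names = FALSE)
    if (q <= 0) q <- max(m, 1e-12)
    normalization[c3] <- q
    channels[, , c3] <- pmin(pmax(m / q, 0), 1)
  }
  methods::new("RgbImage",
    channels = channels, normalization = normalization,
    wavelengths = target)
}

#' Scale a phase map for display
#'
#' Linear rescale of a wrapped phase map to [0, 1] with the applied
#' (min, max) recorded; the radian values themselves are never altered
#' and no unwrapping is attempted.
#'
#' @param phase Real matrix of phase values (radians).
#' @return List with `image` (matrix in [0, 1]), `min`, `max` (radians).
#' @export
phaseToDisplay <- function(phase) {
  stopifnot(is.matrix(phase))
  lo <- min(phase); hi <- max(phase)
  img <- if (hi > lo) (phase - lo) / (hi - lo)
         else matrix(0, nrow(phase), ncol(phase))
  list(image = img, min = lo, max = hi)
}
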