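#' @include forward.R
NULL

#' Specify a synthetic phantom
#'
#' @param kind `"tissue"` (smoothed random blobs with correlated
#'   absorption and phase, nuclei as high-absorption/high-phase disks),
#'   `"two_point"` (two unit-amplitude points on an absorbing background,
#'   separated by `featureScale`), `"star"` (Siemens star),
#'   `"bars"` (bar pattern of period `featureScale`) or `"uniform"`.
#' @param size HR grid side (even integer).
#' @param muRange Absorption bounds; the defaults keep `|o|` in about
#'   [0.22, 1], within the weak-to-moderate modulation regime where the
#'   reconstruction converges without phase unwrapping.
#' @param phiRange Phase bounds (radians).
#' @param featureScale Characteristic feature size (um).
#' @param pixelSize HR pixel pitch (um); the default matches the
#'   reference configuration (0.65 / 4 um).
#' @param seed Integer seed; generation is reproducible.
#' @return A [PhantomSpec-class].
#' @export
phantomSpec <- function(kind = "tissue", size = 128L,
                        muRange = c(0, 1.5), phiRange = c(0, 1.5),
                        featureScale = 2, pixelSize = 0.65 / 4,
                        seed = 0L) {
  methods::new("PhantomSpec",
    kind = kind, size = as.integer(size), muRange = muRange,
    phiRange = phiRange, featureScale = featureScale,
    pixelSize = pixelSize, seed = as.integer(seed))
}

# Periodic Gaussian smoothing of a field, by Fourier multiplication.
gaussianSmooth <- function(x, sigma_px) {
  n <- nrow(x)
  f <- freqCoords(n, 1)                    # cycles per pixel
  g <- exp(-2 * pi^2 * sigma_px^2 * outer(f^2, f^2, `+`))
  Re(ifft2c(fft2c(x) * g))
}

rescaleTo <- function(x, range) {
  rng <- range(x)
  if (diff(rng) == 0) return(matrix(range[1], nrow(x), ncol(x)))
  range[1] + (x - rng[1]) / diff(rng) * diff(range)
}

#' Generate a synthetic phantom object
#'
#' Builds the [ComplexObject-class] described by a [PhantomSpec-class];
#' identical specs (including seed) yield identical fields.
#'
#' @param spec A [PhantomSpec-class].
#' @return A [ComplexObject-class].
#' @examples
#' obj <- makePhantom(phantomSpec("tissue", size = 64L, seed = 1L))
#' @export
makePhantom <- function(spec) {
  stopifnot(methods::is(spec, "PhantomSpec"))
  n <- spec@size
  dx <- spec@pixelSize
  if (spec@kind != "uniform" && spec@featureScale < dx)
    stop(sprintf("featureScale %.3f um is below the HR pixel %.3f um",
                 spec@featureScale, dx))
  set.seed(spec@seed)

  zero <- matrix(0, n, n)
  fields <- switch(spec@kind,
    uniform = list(mu = zero, phi = zero),
    tissue = phantomTissue(n, dx, spec),
    two_point = phantomTwoPoint(n, dx, spec),
    star = phantomStar(n, dx, spec),
    bars = phantomBars(n, dx, spec)
  )
  complexObject(fields$phi, fields$mu, dx)
}

phantomTissue <- function(n, dx, spec) {
  sigma_px <- max(spec@featureScale / dx / 2, 1)
  # stromal background: smoothed noise, mild absorption and phase
  bg <- gaussianSmooth(matrix(stats::rnorm(n * n), n, n), 2 * sigma_px)
  bg <- rescaleTo(bg, c(0, 0.35))
  # nuclei: correlated high-absorption, high-phase disks
  n_nuclei <- max(4L, as.integer(round((n * dx)^2 / (4 * spec@featureScale^2))))
  cx <- stats::runif(n_nuclei, 0.1 * n, 0.9 * n)
  cy <- stats::runif(n_nuclei, 0.1 * n, 0.9 * n)
  rad <- stats::runif(n_nuclei, 0.5, 1) * spec@featureScale / dx
  amp <- stats::runif(n_nuclei, 0.5, 1)
  xs <- matrix(seq_len(n), n, n, byrow = TRUE)
  ys <- matrix(seq_len(n), n, n)
  nuc <- matrix(0, n, n)
  for (i in seq_len(n_nuclei)) {
    d2 <- (xs - cx[i])^2 + (ys - cy[i])^2
    nuc <- nuc + amp[i] * exp(-d2 / (2 * (rad[i] / 1.5)^2))
  }
  nuc <- nuc / max(nuc)
  # sub-micron chromatin/stain granularity: stained tissue is spectrally
  # broadband, which is what gives darkfield (high-angle) captures their
  # signal in real acquisitions
  grain <- gaussianSmooth(matrix(stats::rnorm(n * n), n, n), 0.7)
  grain <- rescaleTo(grain, c(0, 0.25))
  mu <- spec@muRange[1] +
    pmin(bg + 0.55 * nuc + grain * (0.3 + nuc), 1) * diff(spec@muRange)
  # phase tracks absorption (stain raises both), plus independent texture
  tex <- gaussianSmooth(matrix(stats::rnorm(n * n), n, n), 3 * sigma_px)
  tex <- rescaleTo(tex, c(0, 0.2))
  phi_unit <- pmin(0.8 * (mu - spec@muRange[1]) /
                     max(diff(spec@muRange), .Machine$double.eps) + tex, 1)
  phi <- spec@phiRange[1] + phi_unit * diff(spec@phiRange)
  list(mu = mu, phi = phi)
}

phantomTwoPoint <- function(n, dx, spec) {
  sep_px <- round(spec@featureScale / dx)
  if (sep_px < 1) stop("separation below one HR pixel")
  mu <- matrix(spec@muRange[2], n, n)
  c0 <- n / 2 + 1
  off_l <- floor(sep_px / 2)
  off_r <- sep_px - off_l
  mu[c0, c0 - off_l] <- 0
  mu[c0, c0 + off_r] <- 0
  list(mu = mu, phi = matrix(0, n, n))
}

phantomStar <- function(n, dx, spec) {
  spokes <- 16L
  xs <- matrix(seq_len(n) - (n / 2 + 1), n, n, byrow = TRUE)
  ys <- matrix(seq_len(n) - (n / 2 + 1), n, n)
  theta <- atan2(ys, xs)
  r <- sqrt(xs^2 + ys^2)
  pattern <- (cos(spokes * theta) > 0) & (r <= 0.45 * n) & (r >= 2)
  mu <- ifelse(pattern, spec@muRange[2], spec@muRange[1])
  phi <- ifelse(pattern, spec@phiRange[2], spec@phiRange[1])
  list(mu = mu, phi = phi)
}

phantomBars <- function(n, dx, spec) {
  period_px <- max(2, round(spec@featureScale / dx))
  xs <- matrix(seq_len(n), n, n, byrow = TRUE)
  pattern <- (xs %/% (period_px / 2)) %% 2 == 0
  mu <- ifelse(pattern, spec@muRange[2], spec@muRange[1])
  phi <- ifelse(pattern, spec@phiRange[2], spec@phiRange[1])
  list(mu = mu, phi = phi)
}

#' Marker-stroke occluder object
#'
#' Opaque diagonal strokes (absorption `mu = 3`, about 95 percent
#' amplitude attenuation, near-zero phase) emulating marker-pen symbols on
#' a slide surface; transparent elsewhere.
#'
#' @param size HR grid side.
#' @param pixelSize HR pixel pitch (um).
#' @param strokeWidth Stroke width (um).
#' @param mu Absorption exponent of the strokes.
#' @param seed Integer seed for stroke placement.
#' @return A [ComplexObject-class]; the stroke mask is recoverable as
#'   `absorptionMap(x) > mu / 2`.
#' @export
makeOccluder <- function(size, pixelSize = 0.65 / 4, strokeWidth = 3,
                         mu = 3, seed = 0L) {
  n <- as.integer(size)
  set.seed(seed)
  w_px <- max(2, round(strokeWidth / pixelSize))
  xs <- matrix(seq_len(n), n, n, byrow = TRUE)
  ys <- matrix(seq_len(n), n, n)
  mask <- matrix(FALSE, n, n)
  # two crossing strokes through random interior anchors
  for (s in 1:2) {
    x0 <- stats::runif(1, 0.3 * n, 0.7 * n)
    y0 <- stats::runif(1, 0.3 * n, 0.7 * n)
    ang <- stats::runif(1, 0, pi)
    d <- abs(cos(ang) * (ys - y0) - sin(ang) * (xs - x0))
    mask <- mask | (d <= w_px / 2)
  }
  muF <- ifelse(mask, mu, 0)
  complexObject(matrix(0, n, n), muF, pixelSize)
}
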