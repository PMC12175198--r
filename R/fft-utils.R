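# Centered, unitary 2-D transforms and frequency-grid bookkeeping.
#
# All spectra in the package are DC-centered: the zero-frequency sample sits
# at matrix index (n/2 + 1, n/2 + 1) for an even side length n.  Grids are
# required to be square and even-sided, so fftshift is an involution and the
# centered transforms below are exact mutual inverses.

#' Swap quadrants so that the DC sample moves between corner and center
#'
#' For even-sided matrices `fftShift()` is its own inverse.
#'
#' @param x A matrix (real or complex) with even dimensions.
#' @return Matrix of the same shape with quadrants swapped.
#' @keywords internal
fftShift <- function(x) {
  n1 <- nrow(x); n2 <- ncol(x)
  stopifnot(n1 %% 2 == 0, n2 %% 2 == 0)
  x[c((n1 / 2 + 1):n1, 1:(n1 / 2)), c((n2 / 2 + 1):n2, 1:(n2 / 2))]
}

#' Centered unitary 2-D Fourier transform
#'
#' Maps a spatial field with its origin at the grid center to a DC-centered
#' spectrum, normalised by `1/sqrt(n_pixels)` so the transform is unitary
#' (Parseval holds exactly).
#'
#' @param x Square even-sided matrix.
#' @return Complex matrix, DC-centered spectrum.
#' @keywords internal
fft2c <- function(x) {
  fftShift(stats::fft(fftShift(x))) / sqrt(length(x))
}

#' Centered unitary inverse 2-D Fourier transform
#'
#' Exact inverse of [fft2c()].
#'
#' @param x DC-centered complex spectrum (square, even-sided).
#' @return Complex spatial field with origin at the grid center.
#' @keywords internal
ifft2c <- function(x) {
  fftShift(stats::fft(fftShift(x), inverse = TRUE)) / sqrt(length(x))
}

#' Centered frequency coordinates of an even-sided grid
#'
#' @param n Side length (even integer).
#' @param dx Pixel pitch (micrometres).
#' @return Numeric vector of length `n`: frequencies in 1/um, ordered to
#'   match DC-centered spectra (`0` at position `n/2 + 1`).
#' @keywords internal
freqCoords <- function(n, dx) {
  stopifnot(n %% 2 == 0)
  (seq_len(n) - (n / 2 + 1)) / (n * dx)
}

# Radial frequency-squared map |k|^2 on an n x n DC-centered grid (1/um^2).
freqRadiusSq <- function(n, dx) {
  f <- freqCoords(n, dx)
  outer(f^2, f^2, `+`)
}
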