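#' @include AllClasses.R
NULL

# Noll index -> (n, m).  Within radial order n the |m| sequence follows
# Noll's convention; even j carries the cosine (m >= 0) term, odd j the
# sine (m < 0) term.
nollToNm <- function(j) {
  stopifnot(j >= 1)
  n <- 0L
  while ((n + 1L) * (n + 2L) / 2 < j) n <- n + 1L
  k <- j - n * (n + 1L) / 2            # 1-based position within order n
  if (n %% 2L == 0L) m_abs <- 2L * (k %/% 2L)
  else m_abs <- 2L * ((k + 1L) %/% 2L) - 1L
  m <- if (m_abs == 0L) 0L else if (j %% 2L == 0L) m_abs else -m_abs
  c(n = n, m = m)
}

# Radial polynomial R_n^{|m|}(rho)
zernikeRadial <- function(n, m_abs, rho) {
  out <- 0
  for (s in 0:((n - m_abs) / 2)) {
    out <- out + (-1)^s * factorial(n - s) /
      (factorial(s) * factorial((n + m_abs) / 2 - s) *
         factorial((n - m_abs) / 2 - s)) * rho^(n - 2 * s)
  }
  out
}

#' Noll-indexed Zernike basis on a pupil disk
#'
#' Evaluates the first `J` Noll-indexed, Noll-normalised Zernike
#' polynomials on an LR frequency grid whose radial coordinate is
#' normalised to the pupil cutoff.  Values outside the support disk are
#' zero (the pupil vanishes there anyway).
#'
#' @param n Grid side (even integer).
#' @param dx Object-plane LR pixel (um), fixing the frequency grid.
#' @param cutoff Pupil cutoff frequency `NA / lambda` (1/um).
#' @param J Number of polynomials.
#' @return `n^2 x J` matrix; column j is Z_j flattened column-major.
#' @keywords internal
zernikeBasis <- function(n, dx, cutoff, J) {
  f <- freqCoords(n, dx)
  kx <- matrix(f, n, n, byrow = TRUE)   # column index -> kx
  ky <- matrix(f, n, n)                 # row index -> ky
  rho <- sqrt(kx^2 + ky^2) / cutoff
  theta <- atan2(ky, kx)
  inside <- rho <= 1
  rho_c <- pmin(rho, 1)
  out <- matrix(0, n * n, J)
  for (j in seq_len(J)) {
    nm <- nollToNm(j)
    n_ <- nm[["n"]]; m_ <- nm[["m"]]
    rad <- zernikeRadial(n_, abs(m_), rho_c)
    zj <- if (m_ == 0L) sqrt(n_ + 1) * rad
          else if (m_ > 0L) sqrt(2 * (n_ + 1)) * rad * cos(abs(m_) * theta)
          else sqrt(2 * (n_ + 1)) * rad * sin(abs(m_) * theta)
    zj[!inside] <- 0
    out[, j] <- as.vector(zj)
  }
  out
}
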