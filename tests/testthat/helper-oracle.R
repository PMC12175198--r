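# Brute-force discrete-transform oracle, written independently of the
# package's FFT path: centered unitary DFTs as explicit complex-exponential
# matrix products, window selection by index arithmetic from the defining
# substitution S[u] = O[u - m].

oracleDftMatrix <- function(n) {
  c0 <- n / 2 + 1
  idx <- seq_len(n) - c0
  exp(-2i * pi * outer(idx, idx) / n) / sqrt(n)
}

oracleFft2 <- function(x) {
  W <- oracleDftMatrix(nrow(x))
  W %*% x %*% t(W)
}

oracleIfft2 <- function(x) {
  W <- Conj(oracleDftMatrix(nrow(x)))
  W %*% x %*% t(W)
}

# One capture frame straight from the defining equations.
oracleCapture <- function(objField, k_m, pupilValues, kernelValues, gamma,
                          kstep) {
  n_hr <- nrow(objField)
  n_lr <- nrow(pupilValues)
  O <- oracleFft2(objField)
  m <- c(round(k_m[2] / kstep), round(k_m[1] / kstep))  # (row, col)
  S <- matrix(0 + 0i, n_lr, n_lr)
  ch <- n_hr / 2 + 1
  cl <- n_lr / 2 + 1
  for (u in seq_len(n_lr)) for (v in seq_len(n_lr)) {
    S[u, v] <- O[(u - cl) - m[1] + ch, (v - cl) - m[2] + ch]
  }
  E <- oracleIfft2(S * pupilValues * kernelValues) * (n_lr / n_hr)
  gamma * Mod(E)^2
}

# Two-plane capture: tilt the tissue spectrum, propagate by the plane
# separation at HR, modulate by the occluder, image the central window.
oracleTwoPlaneCapture <- function(field1, field2, k_m, pupilValues,
                                  kernelImg, kernelSep, gamma, kstep) {
  n_hr <- nrow(field1)
  n_lr <- nrow(pupilValues)
  O1 <- oracleFft2(field1)
  m <- c(round(k_m[2] / kstep), round(k_m[1] / kstep))
  roll <- matrix(0 + 0i, n_hr, n_hr)
  for (u in seq_len(n_hr)) for (v in seq_len(n_hr)) {
    roll[u, v] <- O1[((u - 1 - m[1]) %% n_hr) + 1, ((v - 1 - m[2]) %% n_hr) + 1]
  }
  S2 <- oracleFft2(field2 * oracleIfft2(kernelSep * roll))
  ch <- n_hr / 2 + 1
  cl <- n_lr / 2 + 1
  S <- S2[(ch - cl + 1):(ch - cl + n_lr), (ch - cl + 1):(ch - cl + n_lr)]
  E <- oracleIfft2(S * pupilValues * kernelImg) * (n_lr / n_hr)
  gamma * Mod(E)^2
}

relErr <- function(got, want) {
  denom <- max(abs(want), .Machine$double.eps)
  max(abs(got - want)) / denom
}
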