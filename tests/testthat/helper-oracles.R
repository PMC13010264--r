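# Independent oracles used across the suite.

# Closed-form competition model in the instantaneous-rebinding limit
# (k_on -> Inf, free enzyme always zero): the reversible pool R relaxes
# exponentially toward the substrate shares,
#   R13(t) = R * s13 * (1 - exp(-k_off t)),   R = (1 - E_i) E_T,
# and the cumulative glucose pools follow by quadrature of the bound
# pools. Entirely independent of the deSolve path in the package.
oracle_competition_G <- function(k_off, E_i, t, E_total = 0.83e-3,
                                 s13 = 0.5, kcat = 1) {
  I <- E_i * E_total
  R <- (1 - E_i) * E_total
  relax <- (1 - exp(-k_off * t)) / k_off
  G13 <- kcat * R * s13 * (t - relax)
  G12 <- kcat * ((I + R) * t - R * s13 * (t - relax))
  list(G12 = G12, G13 = G13)
}

# Interval isotope fractions from the closed-form pools.
oracle_competition_f12 <- function(k_off, E_i, times, ...) {
  tt <- c(0, times)
  G <- oracle_competition_G(k_off, E_i, tt, ...)
  d12 <- diff(G$G12); d13 <- diff(G$G13)
  d12 / (d12 + d13)
}

# Fourier translation of a periodic image by a (possibly subpixel) shift;
# used to create band-limited test images with exactly known shifts.
fourier_shift <- function(m, dr, dc) {
  n1 <- nrow(m); n2 <- ncol(m)
  k1 <- c(0:(ceiling(n1 / 2) - 1), -(floor(n1 / 2)):-1)
  k2 <- c(0:(ceiling(n2 / 2) - 1), -(floor(n2 / 2)):-1)
  ph <- exp(-2i * pi * (outer(k1 / n1 * dr, rep(1, n2)) +
                        outer(rep(1, n1), k2 / n2 * dc)))
  Re(stats::fft(stats::fft(m) * ph, inverse = TRUE)) / (n1 * n2)
}

# Band-limited random test image (smooth enough for subpixel work).
bandlimited_image <- function(n, seed = 1, cutoff = 0.15) {
  set.seed(seed)
  z <- matrix(stats::rnorm(n * n), n, n)
  k <- c(0:(n / 2), (n / 2 - 1):1)
  keep <- outer(k, k, function(a, b) sqrt(a^2 + b^2)) < cutoff * n
  Re(stats::fft(stats::fft(z) * keep, inverse = TRUE)) / n^2
}

# Build a leveled, masked map_frame from a vector of modulus values laid
# out on a square grid (fiber everywhere), for distribution statistics.
frame_from_values <- function(values, pixel_size = 2) {
  n <- ceiling(sqrt(length(values)))
  v <- c(values, rep(values[1], n * n - length(values)))
  mask <- matrix(c(rep(TRUE, length(values)),
                   rep(FALSE, n * n - length(values))), n, n)
  map_frame(height = matrix(10, n, n), modulus = matrix(v, n, n),
            pixel_size = pixel_size, fiber_mask = mask,
            background_mask = NULL)
}

# Small phantom so stack tests stay quick.
small_phantom <- function(...) {
  gen_fibril_phantom(length_nm = 600, margin_nm = 30, ...)
}
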