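# absolute-tolerance comparison (expect_equal's tolerance is relative)
expect_close <- function(x, y, tol) {
  expect_lt(max(abs(x - y)), tol)
}

# Reference geometries used throughout the suite
params_super <- function(D = 0.0030) net_params(D = D, ell = 0.4725)
params_sub <- function(D = 0.0338) net_params(D = D, ell = 0.3)
params_case_2d <- function(case, D = 0.1, alpha = 0.3, L = 3) {
  ratios <- c(1, 0.975, 0.95, 0.925, 0.9)
  R <- ratios[case] * L
  net_params(D = D, ell = alpha * R, R = R, L = L, dim = 2L)
}

# quadrature oracle for the 1D potential modes:
# (1/2L) int_{-R}^{R} V(x) cos(k pi x / L) dx
mode_1d_quadrature <- function(k, params) {
  f <- function(x) spring_potential(abs(x), params) * cos(k * pi * x / params$L)
  stats::integrate(f, -params$R, params$R, rel.tol = 1e-11,
                   abs.tol = 1e-13, subdivisions = 2000L)$value / (2 * params$L)
}

# radial quadrature oracle for the 2D modes: for a radial kernel the double
# integral collapses to a Hankel-type 1D integral with a J0 weight
mode_2d_quadrature <- function(k1, k2, params) {
  w <- pi * sqrt(k1^2 + k2^2) / params$L
  f <- function(r) spring_potential(r, params) * besselJ(w * r, 0) * r
  2 * pi * stats::integrate(f, 0, params$R, rel.tol = 1e-11,
                            subdivisions = 2000L)$value / (4 * params$L^2)
}

# truncated-series oracle for Struve H (coarser truncation than the
# implementation, summed in plain double arithmetic)
struve_series_oracle <- function(order, x, m_max = 60) {
  m <- 0:m_max
  sum((-1)^m / (gamma(m + 1.5) * gamma(m + order + 1.5)) * (x / 2)^(2 * m + order + 1))
}

# brute-force periodic convolution oracle
conv_oracle_1d <- function(values, kernel, dx) {
  n <- length(values)
  out <- numeric(n)
  for (i in seq_len(n)) {
    s <- 0
    for (m in seq_len(n)) {
      j <- ((i - m) %% n) + 1L
      s <- s + kernel[m] * values[j]
    }
    out[i] <- s * dx
  }
  out
}

count_peaks <- function(f) {
  g <- c(f[length(f)], f, f[1])
  sum(diff(sign(diff(g))) == -2)
}
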