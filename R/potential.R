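#' Compactly supported spring potential
#'
#' Net pairwise interaction potential of the fast-relinking limit: inside the
#' detection radius a quadratic spring well shifted so the potential is
#' continuous (equal to zero) at `|x| = R`, and identically zero beyond,
#' \deqn{V(r) = \frac{\kappa}{2}\left[(r-\ell)^2 - (R-\ell)^2\right], \quad r < R,}
#' with `V(r) = 0` for `r >= R`.  The scaled model uses `kappa = 2`, for which
#' the bracket is the potential itself.
#'
#' @param r Nonnegative distance(s).
#' @param params A [net_params()] object.
#' @return Potential value(s), same length as `r`.
#' @examples
#' p <- net_params(ell = 0.3, R = 0.75)
#' spring_potential(0, p)     # -0.1125
#' spring_potential(0.75, p)  # 0 at the support boundary
#' @export
spring_potential <- function(r, params) {
  if (any(r < 0)) stop("distance 'r' must be >= 0")
  ell <- params$ell; R <- params$R; hk <- params$kappa / 2
  ifelse(r < R, hk * ((r - ell)^2 - (R - ell)^2), 0)
}

#' Gradient of the spring potential
#'
#' Returns \eqn{\nabla V(x) = \kappa (|x| - \ell)\, x/|x|} for
#' `0 < |x| <= R` and the zero vector outside the (closed) support.  At
#' exactly zero separation the gradient is undefined when `ell > 0`; the zero
#' vector is returned, since coincident particles occur with probability zero
#' and any fixed direction would break isotropy.
#'
#' @param dx Displacement: a numeric vector of length `dim`, or a matrix with
#'   `dim` columns (one displacement per row).  Minimum-image reduction is the
#'   caller's responsibility.
#' @param params A [net_params()] object.
#' @return Gradient with the same shape as `dx`.
#' @export
spring_gradient <- function(dx, params) {
  ell <- params$ell; R <- params$R; kappa <- params$kappa
  if (is.matrix(dx)) {
    r <- sqrt(rowSums(dx^2))
    fac <- ifelse(r > 0 & r <= R, kappa * (r - ell) / pmax(r, .Machine$double.xmin), 0)
    dx * fac
  } else {
    r <- sqrt(sum(dx^2))
    if (r == 0 || r > R) return(dx * 0)
    kappa * (r - ell) * dx / r
  }
}

#' Struve function H of order 0 or 1
#'
#' Evaluated from the defining power series
#' \deqn{H_i(x) = \sum_{m \ge 0} \frac{(-1)^m}{\Gamma(m+3/2)\,\Gamma(m+i+3/2)}
#'   \left(\frac{x}{2}\right)^{2m+i+1},}
#' summed in terms of log-gamma with a relative tail bound of 1e-12.  For the
#' arguments arising here (`x = pi R sqrt(k1^2+k2^2) / L` with small mode
#' numbers, so `x` of order 10 or less) the series is numerically benign;
#' agreement with scipy's `struve` is at machine precision.
#'
#' @param order 0 or 1.
#' @param x Positive numeric vector.
#' @return `H_order(x)`.
#' @export
struve_h <- function(order, x) {
  if (!order %in% c(0, 1)) stop("'order' must be 0 or 1")
  if (any(x <= 0)) stop("'x' must be > 0")
  m <- 0:80
  vapply(x, function(xi) {
    lt <- (2 * m + order + 1) * log(xi / 2) - lgamma(m + 1.5) - lgamma(m + order + 1.5)
    sum((-1)^m * exp(lt))
  }, 0)
}

#' Fourier modes of the spring potential on the periodic box
#'
#' Coefficients of the expansion
#' \eqn{V(x) = \sum_k \hat V_k e^{i\pi k x / L}} with
#' \eqn{\hat V_k = (2L)^{-d} \int V e^{-i\pi k\cdot x/L} dx}.  In 1D the
#' closed form is
#' \deqn{\hat V_k = \frac{2R^3}{L}\left(-\frac{\sin z_k}{z_k^3}
#'   + (1-\alpha)\frac{\cos z_k}{z_k^2} + \frac{\alpha}{z_k^2}\right),
#'   \qquad z_k = \frac{\pi R |k|}{L},}
#' scaled by `kappa/2` for general spring constants.  The mean mode `k = 0`
#' is computed from the exact integral of `V` (the transform formula is
#' singular at `z = 0`); it never enters the stability analysis.
#'
#' @param k Integer mode index (vectorized).
#' @param params A [net_params()] object.
#' @return Real Fourier coefficient(s) \eqn{\hat V_k}; even in `k`.
#' @seealso [potential_mode_2d()] for the square box.
#' @examples
#' p <- net_params(ell = 0.4725)
#' -potential_mode_1d(1, p)   # critical noise for the first mode, ~0.0040
#' @export
potential_mode_1d <- function(k, params) {
  R <- params$R; L <- params$L; a <- params$alpha; hk <- params$kappa / 2
  z <- pi * R * abs(k) / L
  out <- numeric(length(k))
  nz <- k != 0
  zz <- z[nz]
  out[nz] <- hk * 2 * R^3 / L *
    (-sin(zz) / zz^3 + (1 - a) * cos(zz) / zz^2 + a / zz^2)
  if (any(!nz)) {
    # (1/2L) * 2 * int_0^R [(r-ell)^2 - (R-ell)^2] dr, times kappa/2
    ell <- params$ell
    out[!nz] <- hk * (((R - ell)^3 + ell^3) / 3 - R * (R - ell)^2) / L
  }
  out
}

#' @rdname potential_mode_1d
#' @param k1,k2 Integer mode indices of the square-box expansion
#'   (vectorized in parallel).  The coefficient depends on `k1^2 + k2^2`
#'   only (the potential is radial):
#'   \deqn{\hat V_{k_1,k_2} = \frac{\pi}{L^2}\left(
#'     \frac{\pi R^3 \ell}{2 z^2}\left[J_1(z)H_0(z) - J_0(z)H_1(z)\right]
#'     - \frac{R^4}{z^2} J_2(z)\right),
#'     \qquad z = \frac{\pi R}{L}\sqrt{k_1^2+k_2^2},}
#'   with Bessel `J` and Struve `H` functions, scaled by `kappa/2`.
#' @export
potential_mode_2d <- function(k1, k2, params) {
  R <- params$R; L <- params$L; ell <- params$ell; hk <- params$kappa / 2
  n2 <- k1^2 + k2^2
  out <- numeric(length(n2))
  nz <- n2 != 0
  if (any(nz)) {
    z <- pi * R * sqrt(n2[nz]) / L
    out[nz] <- hk * pi / L^2 *
      (pi * R^3 * ell / (2 * z^2) *
         (besselJ(z, 1) * struve_h(0, z) - besselJ(z, 0) * struve_h(1, z)) -
         R^4 / z^2 * besselJ(z, 2))
  }
  if (any(!nz)) {
    # (1/4L^2) * 2*pi * int_0^R U(r) r dr with U = (r-ell)^2 - (R-ell)^2
    out[!nz] <- hk * 2 * pi / (4 * L^2) *
      (R^4 / 4 - 2 * ell * R^3 / 3 + ell^2 * R^2 / 2 - (R - ell)^2 * R^2 / 2)
  }
  out
}

#' Link density of the fast-relinking closure
#'
#' In the fast linking/unlinking regime the two-particle link density is
#' slaved to the particle density:
#' \deqn{g(x, y) = \frac{\nu_f}{2 \xi \nu_d} f(x) f(y) \chi_{|x-y| \le R}.}
#'
#' @param f_x,f_y Particle density values at the two endpoints (`>= 0`).
#' @param separation Distance between the endpoints.
#' @param params A [net_params()] object.
#' @param xi_ratio Limiting link-to-particle ratio `xi > 0`.
#' @return Link density value.
#' @export
link_density <- function(f_x, f_y, separation, params, xi_ratio) {
  if (any(xi_ratio <= 0)) stop("'xi_ratio' must be > 0")
  if (any(f_x < 0) || any(f_y < 0)) stop("densities must be >= 0")
  ifelse(separation <= params$R,
         params$nu_f / (2 * xi_ratio * params$nu_d) * f_x * f_y, 0)
}
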