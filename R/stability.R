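#' Linear growth rate of a Fourier perturbation of the uniform state
#'
#' Linearizing the aggregation-diffusion equation around the uniform density
#' and expanding in box modes \eqn{e_k = \exp(i\pi k\cdot x/L)} decouples the
#' modes, each evolving as \eqn{\partial_t \hat\rho_k = \lambda_k \hat\rho_k}
#' with
#' \deqn{\lambda_k = -\frac{\pi^2 |k|^2}{L^2}\,(D + \hat V_k),}
#' where `|k|^2 = k^2` in 1D and `k1^2 + k2^2` in 2D.  The uniform state is
#' unstable to mode `k` exactly when `D < -Vhat_k`.
#'
#' @param mode Integer mode index (1D), or a length-2 integer vector /
#'   two-column matrix of `(k1, k2)` pairs (2D).  The zero mode is rejected
#'   (it is the conserved mass).
#' @param D Noise intensity; defaults to `params$D`.
#' @param params A [net_params()] object.
#' @return A data frame (one row per mode) with columns `k1`, `k2` (`k2 = 0`
#'   and absent conceptually in 1D), `z` (reduced wavenumber), `vhat` and
#'   `growth_rate`.
#' @examples
#' p <- net_params(D = 0.0030, ell = 0.4725)
#' growth_rate(1, params = p)$growth_rate  # ~0.0010
#' @export
growth_rate <- function(mode, D = params$D, params) {
  km <- normalize_modes(mode, params$dim)
  if (any(rowSums(km^2) == 0))
    stop("the zero mode carries the conserved mass and has no growth rate")
  n2 <- km[, 1]^2 + km[, 2]^2
  vhat <- if (params$dim == 1L) potential_mode_1d(km[, 1], params)
          else potential_mode_2d(km[, 1], km[, 2], params)
  data.frame(k1 = km[, 1], k2 = km[, 2],
             z = pi * params$R * sqrt(n2) / params$L,
             vhat = vhat,
             growth_rate = -pi^2 * n2 / params$L^2 * (D + vhat))
}

normalize_modes <- function(mode, dim) {
  if (is.matrix(mode)) {
    if (ncol(mode) != 2L) stop("mode matrix must have two columns")
    return(mode)
  }
  if (dim == 1L) cbind(as.numeric(mode), 0)
  else if (length(mode) == 2L) rbind(as.numeric(mode))
  else stop("a 2D mode must be a (k1, k2) pair or a two-column matrix")
}

#' Critical noise intensity of the first Fourier mode
#'
#' The uniform state loses stability to the first box mode when the noise
#' drops below \eqn{D_c = -\hat V_1} (1D) or \eqn{-\hat V_{1,0}} (2D).  When
#' the first mode of the potential is nonnegative (`ell >= ell_c`) no positive
#' threshold exists and the uniform state is stable for every `D`; zero is
#' returned with attribute `always_stable = TRUE`.
#'
#' @param params A [net_params()] object.
#' @return `D_c >= 0`, with attribute `always_stable`.
#' @examples
#' critical_noise(net_params(ell = 0.4725))  # ~0.0040
#' critical_noise(net_params(ell = 0.3))     # ~0.0347
#' @export
critical_noise <- function(params) {
  v1 <- if (params$dim == 1L) potential_mode_1d(1, params)
        else potential_mode_2d(1, 0, params)
  dc <- -v1
  if (dc <= 0) structure(0, always_stable = TRUE)
  else structure(dc, always_stable = FALSE)
}

#' Critical spring-length ratio alpha_c
#'
#' Largest ratio `alpha = ell/R` at which the first Fourier mode of the
#' potential vanishes; for `alpha < alpha_c` the potential is destabilizing
#' (aggregating) and a positive critical noise exists.  In 1D the root is
#' available in closed form,
#' \deqn{\alpha_c = \frac{\sin z_1 / z_1 - \cos z_1}{1 - \cos z_1},
#'   \qquad z_1 = \pi R / L,}
#' which reduces to \eqn{(4-\pi)(\sqrt 2 + 1)/\pi} when `z_1 = pi/4`.  In 2D,
#' `alpha_c` solves
#' \deqn{\frac{\pi}{2}\,\alpha\,[J_1 H_0 - J_0 H_1](z_{1,0}) = J_2(z_{1,0})}
#' and is found by bisection (the left side is linear in `alpha`).
#'
#' @param params A [net_params()] object; only `R/L` and `dim` matter.
#' @return `alpha_c` in (0, 1).
#' @examples
#' critical_alpha(net_params())                    # 1D, R/L = 1/4: 0.6597
#' critical_alpha(net_params(R = 3, ell = 0.9, dim = 2))  # R/L = 1: 0.6621
#' @export
critical_alpha <- function(params) {
  z1 <- pi * params$R / params$L
  if (params$dim == 1L) {
    (sin(z1) / z1 - cos(z1)) / (1 - cos(z1))
  } else {
    jh <- besselJ(z1, 1) * struve_h(0, z1) - besselJ(z1, 0) * struve_h(1, z1)
    root <- besselJ(z1, 2) / (pi / 2 * jh)
    if (!is.finite(root) || root <= 0 || root >= 1)
      stop(sprintf("no admissible root: J2(z)/( (pi/2)[J1H0-J0H1](z) ) = %g", root))
    root
  }
}

#' 1D critical lengths and the bifurcation-type boundary
#'
#' Computes the three organizing constants of the 1D phase diagram:
#' `ell_c = R * alpha_c`, above which the uniform state is stable for every
#' noise level; `ell_star`, the root of the cubic-coefficient discriminant
#' \eqn{2\hat V_2 - \hat V_1 = 0} at which the bifurcation changes from
#' subcritical (`ell < ell_star`) to supercritical
#' (`ell_star < ell < ell_c`); and `D_star`, the critical noise at
#' `ell_star`.  For the reference geometry `R = 0.75`, `L = 3` these are
#' approximately 0.4947, 0.4530 and 0.0074.
#'
#' @param params A [net_params()] object (the `ell` slot is ignored).
#' @return A list with `ell_c`, `ell_star`, `D_star`.
#' @export
critical_lengths_1d <- function(params) {
  ell_c <- params$R * critical_alpha(modifyList2(params, dim = 1L))
  disc <- function(l) {
    p <- modifyList2(params, ell = l)
    2 * potential_mode_1d(2, p) - potential_mode_1d(1, p)
  }
  lo <- 1e-8; hi <- ell_c - 1e-8
  if (disc(lo) * disc(hi) > 0)
    stop(sprintf("discriminant does not change sign on (0, ell_c): [%g, %g]",
                 disc(lo), disc(hi)))
  ell_star <- stats::uniroot(disc, c(lo, hi), tol = 1e-12)$root
  D_star <- critical_noise(modifyList2(params, ell = ell_star))
  list(ell_c = ell_c, ell_star = ell_star, D_star = as.numeric(D_star))
}

# modifyList for net_params that revalidates
modifyList2 <- function(params, ...) {
  p <- unclass(params)
  new <- list(...)
  p[names(new)] <- new
  do.call(net_params, p[c("D", "ell", "R", "L", "kappa", "nu_f", "nu_d",
                          "mu", "dim")])
}

#' Noise intensity realizing a prescribed growth rate
#'
#' Inverts the dispersion relation for the first mode:
#' \deqn{D = -\hat V_1 - \lambda\,L^2/\pi^2,}
#' so that `growth_rate(mode, D) == lam`.  Used to build the tables of noise
#' values at fixed distance-to-threshold `lam` that parameterize the
#' bifurcation sweeps.
#'
#' @param lam Target growth rate(s) of the first mode.
#' @param mode First mode: `1` (1D) or `c(1, 0)` (2D).
#' @param params A [net_params()] object.
#' @return Noise value(s) `D`.  Values of `lam` beyond the attainable range
#'   yield negative `D`, returned with a warning.
#' @export
noise_for_growth <- function(lam, mode = if (params$dim == 1L) 1 else c(1, 0),
                             params) {
  km <- normalize_modes(mode, params$dim)
  n2 <- km[, 1]^2 + km[, 2]^2
  vhat <- if (params$dim == 1L) potential_mode_1d(km[, 1], params)
          else potential_mode_2d(km[, 1], km[, 2], params)
  D <- -vhat - lam * params$L^2 / (pi^2 * n2)
  if (any(D < 0))
    warning("requested growth rate exceeds the attainable range: negative D")
  D
}

#' 1D bifurcation-type classification
#'
#' The weakly nonlinear expansion of the first unstable mode has cubic
#' coefficient proportional to \eqn{\hat V_1 (2\hat V_2 - \hat V_1)}; with
#' \eqn{\hat V_1 < 0} at onset the bifurcation is supercritical (continuous)
#' when \eqn{2\hat V_2 - \hat V_1 > 0} and subcritical (discontinuous) when
#' \eqn{< 0}.  The criterion involves only the potential, not `D` (the
#' potential is even, so \eqn{\hat V_{-1} = \hat V_1}).
#'
#' @param params A [net_params()] object.
#' @param tol Discriminant values within `tol` of zero are reported as the
#'   boundary regime `"degenerate"`.
#' @return A list with `regime` (`"supercritical"`, `"subcritical"`,
#'   `"stable"` when `ell >= ell_c`, or `"degenerate"`), `discriminant`
#'   (`2*Vhat_2 - Vhat_1`) and `critical_noise`.
#' @examples
#' bifurcation_type_1d(net_params(ell = 0.3))$regime     # subcritical
#' bifurcation_type_1d(net_params(ell = 0.4725))$regime  # supercritical
#' @export
bifurcation_type_1d <- function(params, tol = 1e-10) {
  disc <- 2 * potential_mode_1d(2, params) - potential_mode_1d(1, params)
  dc <- critical_noise(params)
  regime <-
    if (attr(dc, "always_stable")) "stable"
    else if (abs(disc) <= tol) "degenerate"
    else if (disc > 0) "supercritical" else "subcritical"
  list(regime = regime, discriminant = disc, critical_noise = as.numeric(dc))
}

#' 2D bifurcation discriminant V* and the Proposition coefficients c, d
#'
#' On the square box the critical modes `(1,0)` and `(0,1)` interact through
#' the `(1,1)` and `(2,0)` harmonics, and the bifurcation type at the
#' threshold crossing depends on `D`.  With
#' \deqn{c = \frac{\hat V_{1,0}(2\hat V_{2,0}-\hat V_{-1,0})}{D+\hat V_{2,0}},
#'  \qquad d = -\left|\frac{4\hat V_{1,0}\hat V_{1,1}}{D+\hat V_{1,1}}\right|,}
#' the bifurcation is supercritical if `c < d` and subcritical if `c > d`;
#' equivalently, through the sign of
#' \deqn{V^* = \hat V_{1,0}(2\hat V_{2,0}-\hat V_{-1,0})\,|D+\hat V_{1,1}|
#'   + 4 (D+\hat V_{2,0})\,|\hat V_{1,0}\hat V_{1,1}|,}
#' subcritical when `V* > 0`.  By default `D` is evaluated at the crossing,
#' `D = -Vhat_{1,0}(alpha)`.
#'
#' @param alpha Spring-length ratio `ell/R` in `[0, alpha_c)`.
#' @param ratio_RL Geometry ratio `R/L` in `(0, 1]`.
#' @param D Noise at which the proposition is evaluated; `NULL` (default)
#'   means the threshold value `-Vhat_{1,0}`.
#' @param L Domain half-size (sets the absolute scale; the sign of `V*`
#'   depends only on `alpha` and `R/L`).
#' @return A list with `vstar`, `c`, `d`, `D` and `regime`.
#' @export
vstar_discriminant <- function(alpha, ratio_RL, D = NULL, L = 3) {
  R <- ratio_RL * L
  p <- net_params(D = 0, ell = alpha * R, R = R, L = L, dim = 2L)
  v10 <- potential_mode_2d(1, 0, p)
  v20 <- potential_mode_2d(2, 0, p)
  v11 <- potential_mode_2d(1, 1, p)
  if (is.null(D)) D <- -v10
  if (abs(D + v20) < 1e-12 || abs(D + v11) < 1e-12)
    stop("degenerate higher mode: D + Vhat within 1e-12 of zero")
  cc <- v10 * (2 * v20 - v10) / (D + v20)
  dd <- -abs(4 * v10 * v11 / (D + v11))
  vstar <- v10 * (2 * v20 - v10) * abs(D + v11) + 4 * (D + v20) * abs(v10 * v11)
  list(vstar = vstar, c = cc, d = dd, D = D,
       regime = if (vstar > 0) "subcritical" else if (vstar < 0)
         "supercritical" else "degenerate")
}

#' Supercritical window of the 2D phase diagram
#'
#' Scans `alpha` over `(0, alpha_c)` for sign changes of `V*` evaluated at
#' the threshold noise, refines each crossing by bisection, and returns the
#' interval(s) on which the bifurcation is supercritical (`V* < 0`).
#'
#' As `alpha` approaches `alpha_c` both factors of each `V*` term vanish and
#' `V*` itself decays to zero; sign excursions whose depth is below
#' `rel_depth` times the scan's maximum `|V*|` are classified as numerically
#' degenerate and dropped: at that depth the quartic terms neglected by the
#' weakly nonlinear expansion dominate, so the expansion cannot resolve the
#' bifurcation type there.  (For `R/L = 1/2` and `1/4` this removes
#' excursions 6-12 orders of magnitude shallower than the genuine
#' `R/L = 1` window.)
#'
#' @param ratio_RL Geometry ratio `R/L` in `(0, 1]`.
#' @param L Domain half-size.
#' @param n_scan Number of scan points (uniform in `alpha`).
#' @param rel_depth Relative depth below which a `V* < 0` excursion is
#'   considered degenerate.
#' @param tol Bisection tolerance in `alpha`.
#' @return A list with `window` (length-2 numeric, or `NULL` when no
#'   non-degenerate supercritical interval exists), `intervals` (matrix of
#'   all sign-negative intervals with their depths) and `alpha_c`.
#' @examples
#' \donttest{supercritical_window_2d(1)$window  # ~(0.1016, 0.5818)}
#' @export
supercritical_window_2d <- function(ratio_RL, L = 3, n_scan = 2000,
                                    rel_depth = 1e-4, tol = 1e-8) {
  ac <- critical_alpha(net_params(D = 0, ell = 0, R = ratio_RL * L, L = L,
                                  dim = 2L))
  vs <- function(a) vstar_discriminant(a, ratio_RL, L = L)$vstar
  grid <- seq(ac * 1e-4, ac * (1 - 1e-6), length.out = n_scan)
  vals <- vapply(grid, vs, 0)
  sgn <- sign(vals)
  cross <- which(sgn[-1] * sgn[-n_scan] < 0)
  roots <- vapply(cross, function(i)
    stats::uniroot(vs, c(grid[i], grid[i + 1]), tol = tol)$root, 0)
  edges <- c(grid[1], roots, grid[n_scan])
  intervals <- NULL
  for (j in seq_len(length(edges) - 1L)) {
    inside <- grid >= edges[j] & grid <= edges[j + 1L]
    if (!any(inside)) next
    if (stats::median(vals[inside]) < 0) {
      depth <- min(vals[inside])
      intervals <- rbind(intervals,
                         c(lo = edges[j], hi = edges[j + 1L], depth = depth))
    }
  }
  max_abs <- max(abs(vals))
  window <- NULL
  if (!is.null(intervals)) {
    keep <- intervals[, "depth"] < -rel_depth * max_abs
    kept <- intervals[keep, , drop = FALSE]
    if (nrow(kept) > 0) {
      w <- kept[which.min(kept[, "depth"]), ]
      window <- unname(c(w["lo"], w["hi"]))
      # snap window edges interior to the scan range onto exact roots only
      if (window[1] <= grid[1] + 1e-12) window[1] <- 0
    }
  }
  list(window = window, intervals = intervals, alpha_c = ac)
}

#' Weakly nonlinear amplitude prediction near a supercritical onset
#'
#' For a supercritical 1D bifurcation at distance `lam` above threshold, the
#' amplitude equation for the critical mode saturates at
#' \deqn{|A| = \frac{\sqrt\lambda\,L}{2\sqrt2\,\pi^2}
#'   \sqrt{\frac{S}{-\hat V_1 (2\hat V_2-\hat V_1)}},}
#' and the resulting steady perturbation amplitude is estimated by
#' \deqn{|\rho|_{th} = 2|A| + \frac{\lambda L}{\pi^2 (2\hat V_2-\hat V_1)}.}
#' `S` is the saturation factor coupling the critical mode to its second
#' harmonic.  The literal expansion gives `S = 2*lam - lambda_2` with
#' `lambda_2` the (negative) relaxation rate of mode 2 at
#' `D = noise_for_growth(lam)`; since `|lambda_2| >> lam` near onset, the
#' leading-order form `S = -lambda_2` is the one the reference threshold
#' tables follow, and is the default here (`saturation = "leading"`;
#' `"full"` keeps the `2*lam` shift).  Second-harmonic coefficients
#' \eqn{h_{\pm 2} = -4\pi^2 \hat V_{\pm 1} / (L (2\lambda - \lambda_2))} are
#' returned alongside.
#'
#' @param lam Distance to threshold (growth rate of mode 1), `>= 0`.
#' @param params A [net_params()] object in the supercritical regime.
#' @param saturation `"leading"` or `"full"` (see Details).
#' @return A list with `lam`, `A_sat`, `rho_th`, `h2`, `h_minus2`,
#'   `lambda_2` and `D`.
#' @examples
#' p <- net_params(ell = 0.4725)
#' amplitude_prediction(0.0010, p)$A_sat  # ~0.1094
#' @export
amplitude_prediction <- function(lam, params,
                                 saturation = c("leading", "full")) {
  saturation <- match.arg(saturation)
  if (any(lam < 0)) stop("'lam' must be >= 0")
  v1 <- potential_mode_1d(1, params)
  v2 <- potential_mode_1d(2, params)
  disc <- 2 * v2 - v1
  if (disc <= 0)
    stop("amplitude prediction requires the supercritical regime (2*Vhat_2 > Vhat_1)")
  L <- params$L
  D <- noise_for_growth(lam, 1, params)
  lam2 <- -(4 * pi^2 / L^2) * (D + v2)
  S <- if (saturation == "leading") -lam2 else 2 * lam - lam2
  if (any(abs(S) < 1e-14)) stop("vanishing saturation factor 2*lam - lambda_2")
  A <- sqrt(lam) * L / (2 * sqrt(2) * pi^2) * sqrt(S / (-v1 * disc))
  rho_th <- 2 * A + lam * L / (pi^2 * disc)
  h_den <- 2 * lam - lam2
  list(lam = lam, A_sat = A, rho_th = rho_th,
       h2 = -4 * pi^2 / L * v1 / h_den,
       h_minus2 = -4 * pi^2 / L * v1 / h_den,
       lambda_2 = lam2, D = D)
}

#' Write a spectral report as CSV
#'
#' Convenience emitter for mode tables: augments [growth_rate()] output with
#' the threshold and classification columns and writes a delimited file.
#'
#' @param modes Modes as in [growth_rate()].
#' @param params A [net_params()] object.
#' @param path Output CSV path.
#' @return The table, invisibly.
#' @export
write_spectral_report <- function(modes, params, path) {
  tab <- growth_rate(modes, params = params)
  dc <- critical_noise(params)
  cls <- if (params$dim == 1L) bifurcation_type_1d(params)
         else vstar_discriminant(params$alpha, params$R / params$L,
                                 L = params$L)
  tab$D_c <- as.numeric(dc)
  tab$regime <- cls$regime
  tab$discriminant <- if (params$dim == 1L) cls$discriminant else cls$vstar
  utils::write.csv(tab, path, row.names = FALSE)
  invisible(tab)
}
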