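#' Cell-averaged density field on the periodic interval
#'
#' Light container for the finite-volume solvers: `n_cells` uniform cells on
#' `[-L, L]` with strictly positive cell averages summing (times `dx`) to the
#' total mass.
#'
#' @param values Positive cell averages.
#' @param L Domain half-size.
#' @return An object of class `"density_field_1d"` with fields `values`, `x`
#'   (cell centers), `dx`, `n_cells`, `L`.
#' @export
density_field_1d <- function(values, L) {
  n <- length(values)
  if (any(!is.finite(values)) || any(values <= 0))
    stop("cell averages must be finite and > 0")
  dx <- 2 * L / n
  structure(list(values = as.numeric(values),
                 x = -L + (seq_len(n) - 0.5) * dx,
                 dx = dx, n_cells = n, L = L),
            class = "density_field_1d")
}

#' @export
print.density_field_1d <- function(x, ...) {
  cat(sprintf("<density_field_1d> %d cells on [-%g, %g], mass %.12f\n",
              x$n_cells, x$L, x$L, total_mass(x)))
  invisible(x)
}

#' Total mass of a density field
#' @param field A `density_field_1d` or `density_field_2d`.
#' @return Midpoint-rule integral of the density.
#' @export
total_mass <- function(field) {
  if (inherits(field, "density_field_2d")) sum(field$values) * field$dx^2
  else sum(field$values) * field$dx
}

#' Cosine-perturbed initial density
#'
#' Cell averages of \eqn{f_0(x) = 1/(2L) + \delta \cos(\pi x / L)}, computed
#' from the exact antiderivative so the discrete mass is exactly 1 (the
#' cosine integrates to zero over the period).
#'
#' @param delta Perturbation amplitude, `< 1/(2L)` to keep positivity.
#' @param n_cells Number of cells.
#' @param params A [net_params()] object (only `L` is used).
#' @return A [density_field_1d()].
#' @export
initial_density_1d <- function(delta, n_cells, params) {
  L <- params$L
  if (delta < 0 || delta >= 1 / (2 * L))
    stop("'delta' must lie in [0, 1/(2L)) to keep the density positive")
  dx <- 2 * L / n_cells
  edges <- -L + (0:n_cells) * dx
  anti <- function(x) x / (2 * L) + delta * L / pi * sin(pi * x / L)
  vals <- diff(anti(edges)) / dx
  density_field_1d(vals, L)
}

#' Sampled interaction kernel for the periodic grid
#'
#' Samples the spring potential at the minimum-image distances of all
#' cell-center offsets; the discrete periodic convolution with this kernel is
#' the finite-volume surrogate of `V*f`.
#'
#' @param params A [net_params()] object.
#' @param n_cells Grid size.
#' @return Numeric vector of length `n_cells` (`kern[m]` is the offset of
#'   `m - 1` cells).
#' @export
macro_kernel_1d <- function(params, n_cells) {
  L <- params$L
  dx <- 2 * L / n_cells
  off <- (seq_len(n_cells) - 1) * dx
  d <- abs(off - 2 * L * round(off / (2 * L)))
  spring_potential(d, params)
}

#' Discrete periodic convolution V*f
#'
#' @param field A [density_field_1d()].
#' @param params A [net_params()] object.
#' @param kernel Optional kernel override (e.g. for diagnostics); defaults to
#'   [macro_kernel_1d()].
#' @return Numeric vector of `(V*f)` at cell centers.
#' @export
periodic_convolution_1d <- function(field, params, kernel = NULL) {
  if (is.null(kernel)) kernel <- macro_kernel_1d(params, field$n_cells)
  conv1d_cpp(field$values, kernel, field$dx)
}

#' One finite-volume step of the aggregation-diffusion equation
#'
#' Advances \eqn{\partial_t f = \partial_x (f\, \partial_x \xi)},
#' \eqn{\xi = D \log f + V*f}, by `dt` using the gradient-flow upwind scheme:
#' edge velocities \eqn{u_{i+1/2} = -(\xi_{i+1}-\xi_i)/dx}, upwind edge flux
#' \eqn{F_{i+1/2} = u^+ f_i + u^- f_{i+1}}, forward Euler in time.  The
#' requested `dt` is split internally whenever it exceeds the stability bound
#' `min(cfl*dx/max|u|, diff_factor*dx^2/D)`, under which the update is
#' positivity preserving, mass conservative (telescoping fluxes) and
#' well-balanced (constant `xi` gives zero flux exactly).
#'
#' @param field A [density_field_1d()].
#' @param dt Time increment.
#' @param params A [net_params()] object.
#' @param kernel Optional kernel override.
#' @param cfl Advective CFL factor.
#' @param diff_factor Diffusive stability factor.
#' @return Updated [density_field_1d()].
#' @export
fv_step_1d <- function(field, dt, params, kernel = NULL,
                       cfl = 0.4, diff_factor = 0.2) {
  if (is.null(kernel)) kernel <- macro_kernel_1d(params, field$n_cells)
  density_field_1d(macro1d_step_cpp(field$values, kernel, params$D, field$dx,
                                    dt, cfl, diff_factor), field$L)
}

#' Steady-state residual xi*
#'
#' Maximum deviation of \eqn{\xi = D \log f + V*f} from its spatial mean;
#' zero exactly at steady states of the gradient flow.
#'
#' @inheritParams fv_step_1d
#' @return Scalar residual.
#' @export
steady_state_residual_1d <- function(field, params, kernel = NULL) {
  if (any(field$values <= 0)) stop("density must be positive (log)")
  if (is.null(kernel)) kernel <- macro_kernel_1d(params, field$n_cells)
  macro1d_xi_cpp(field$values, kernel, params$D, field$dx)$xi_star
}

#' First-mode order parameter Q
#'
#' \eqn{Q = \sqrt{c_1^2 + s_1^2}} with
#' \eqn{c_1 = L^{-1}\int f \cos(\pi x/L)},
#' \eqn{s_1 = L^{-1}\int f \sin(\pi x/L)} (midpoint rule on the periodic
#' grid, which coincides with the trapezoidal rule there).  Zero for the
#' uniform state; equal to the cosine amplitude for a pure first-mode
#' profile.
#'
#' @param field A [density_field_1d()].
#' @return `Q >= 0`.
#' @export
order_parameter_1d <- function(field) {
  w <- pi * field$x / field$L
  c1 <- sum(field$values * cos(w)) * field$dx / field$L
  s1 <- sum(field$values * sin(w)) * field$dx / field$L
  sqrt(c1^2 + s1^2)
}

#' Discrete free energy of the aggregation-diffusion flow
#'
#' \eqn{E[f] = \int \left( D f \log f + \tfrac12 f (V*f) \right) dx}
#' by the midpoint rule; the scheme is designed so this decays along
#' trajectories.
#'
#' @inheritParams fv_step_1d
#' @return Scalar energy.
#' @export
free_energy_1d <- function(field, params, kernel = NULL) {
  if (is.null(kernel)) kernel <- macro_kernel_1d(params, field$n_cells)
  macro1d_xi_cpp(field$values, kernel, params$D, field$dx)$energy
}

#' Evolve to the steady state
#'
#' Runs the finite-volume scheme until the residual [steady_state_residual_1d()]
#' drops below `tol` (the steady-state stopping rule), recording the residual
#' and free energy on a geometric time grid.
#'
#' @param field Initial [density_field_1d()]; defaults to
#'   [initial_density_1d()] with amplitude `delta`.
#' @param params A [net_params()] object.
#' @param delta Initial perturbation amplitude used when `field` is `NULL`.
#' @param n_cells Grid size used when `field` is `NULL`.
#' @param tol Residual tolerance defining `T_max`.
#' @param t_max,max_steps Safety caps; exceeding them returns the best state
#'   with `converged = FALSE`.
#' @param kernel Optional kernel override.
#' @param cfl,diff_factor Stability factors, as in [fv_step_1d()].
#' @param dt_ceiling Upper bound on the adaptive step.
#' @return An object of class `"steady_state_result"`: list with `density`,
#'   `t_max`, `residual_trace` (data frame `t`, `xi_star`, `energy`), `Q`,
#'   `rho_num` (max-norm distance from the uniform value), `converged`,
#'   `steps`.
#' @examples
#' \donttest{
#' p <- net_params(D = 0.0030, ell = 0.4725)
#' res <- run_to_steady_1d(params = p, n_cells = 128)
#' res$Q; res$rho_num
#' }
#' @export
run_to_steady_1d <- function(field = NULL, params, delta = 0.01,
                             n_cells = 256, tol = 1e-7,
                             t_max = 1e7, max_steps = 5e6, kernel = NULL,
                             cfl = 0.4, diff_factor = 0.2, dt_ceiling = 1) {
  if (is.null(field)) field <- initial_density_1d(delta, n_cells, params)
  if (is.null(kernel)) kernel <- macro_kernel_1d(params, field$n_cells)
  out <- macro1d_run_cpp(field$values, kernel, params$D, field$dx, tol,
                         t_max, max_steps, cfl, diff_factor, dt_ceiling)
  dens <- density_field_1d(out$f, field$L)
  structure(list(
    density = dens,
    t_max = out$t_max,
    residual_trace = data.frame(t = out$trace_t, xi_star = out$trace_xi,
                                energy = out$trace_energy),
    Q = order_parameter_1d(dens),
    rho_num = max(abs(dens$values - 1 / (2 * field$L))),
    converged = out$converged,
    steps = out$steps,
    params = params), class = "steady_state_result")
}

#' @export
print.steady_state_result <- function(x, ...) {
  cat(sprintf("<steady_state_result> T_max = %.4g (%s), Q = %.4g, |rho|_num = %.4g\n",
              x$t_max, if (x$converged) "converged" else "NOT converged",
              x$Q, x$rho_num))
  invisible(x)
}
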