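#' Cell-averaged density field on the periodic square
#'
#' @param values Positive matrix of cell averages (`n_cells` x `n_cells`);
#'   rows index `x`, columns index `y`.
#' @param L Domain half-size (the domain is `[-L, L]^2`).
#' @return An object of class `"density_field_2d"`.
#' @export
density_field_2d <- function(values, L) {
  if (!is.matrix(values) || nrow(values) != ncol(values))
    stop("'values' must be a square matrix")
  if (any(!is.finite(values)) || any(values <= 0))
    stop("cell averages must be finite and > 0")
  n <- nrow(values)
  dx <- 2 * L / n
  structure(list(values = values,
                 x = -L + (seq_len(n) - 0.5) * dx,
                 dx = dx, n_cells = n, L = L),
            class = "density_field_2d")
}

#' @export
print.density_field_2d <- function(x, ...) {
  cat(sprintf("<density_field_2d> %d^2 cells on [-%g, %g]^2, mass %.12f\n",
              x$n_cells, x$L, x$L, total_mass(x)))
  invisible(x)
}

#' Cosine-perturbed initial density on the square
#'
#' Cell averages of
#' \eqn{f_0(x,y) = 1/(4L^2) + \delta \cos(\pi x/L) + \delta_y \cos(\pi y/L)}.
#' The reference perturbation is `x`-only (`delta_y = 0`), as in the 1D case.
#' A deterministic solver keeps an `x`-only datum exactly `y`-invariant
#' (stripes); a small `delta_y > 0` seeds the symmetry breaking through which
#' the square-lattice mode coupling - and hence the 2D bifurcation type -
#' expresses itself.  See the methods vignette.
#'
#' @param delta Amplitude of the `x` cosine; `delta + delta_y < 1/(4L^2)`.
#' @param n_cells Cells per dimension.
#' @param params A [net_params()] object.
#' @param delta_y Amplitude of the `y` cosine.
#' @return A [density_field_2d()].
#' @export
initial_density_2d <- function(delta, n_cells, params, delta_y = 0) {
  L <- params$L
  if (delta < 0 || delta_y < 0 || delta + delta_y >= 1 / (4 * L^2))
    stop("'delta' + 'delta_y' must lie in [0, 1/(4L^2)) for positivity")
  dx <- 2 * L / n_cells
  edges <- -L + (0:n_cells) * dx
  avg_cos <- function(a) diff(a * L / pi * sin(pi * edges / L)) / dx
  cx <- avg_cos(delta); cy <- avg_cos(delta_y)
  vals <- matrix(1 / (4 * L^2), n_cells, n_cells) +
    outer(cx, rep(1, n_cells)) + outer(rep(1, n_cells), cy)
  density_field_2d(vals, L)
}

#' Sampled 2D interaction kernel
#'
#' Radial spring potential at the minimum-image distance of every cell-offset
#' pair; circular FFT convolution with this matrix realizes `V*f` on the
#' periodic square.
#'
#' @param params A [net_params()] object.
#' @param n_cells Cells per dimension.
#' @return `n_cells` x `n_cells` numeric matrix.
#' @export
macro_kernel_2d <- function(params, n_cells) {
  L <- params$L
  dx <- 2 * L / n_cells
  off <- (seq_len(n_cells) - 1) * dx
  o <- off - 2 * L * round(off / (2 * L))
  d <- sqrt(outer(o^2, o^2, "+"))
  matrix(spring_potential(as.vector(d), params), n_cells, n_cells)
}

#' @rdname periodic_convolution_1d
#' @export
periodic_convolution_2d <- function(field, params, kernel = NULL) {
  if (is.null(kernel)) kernel <- macro_kernel_2d(params, field$n_cells)
  macro2d_xi_cpp(field$values, kernel, params$D, field$dx)$conv
}

#' @rdname fv_step_1d
#' @export
fv_step_2d <- function(field, dt, params, kernel = NULL,
                       cfl = 0.4, diff_factor = 0.2) {
  if (is.null(kernel)) kernel <- macro_kernel_2d(params, field$n_cells)
  density_field_2d(macro2d_step_cpp(field$values, kernel, params$D, field$dx,
                                    dt, cfl, diff_factor), field$L)
}

#' @rdname steady_state_residual_1d
#' @export
steady_state_residual_2d <- function(field, params, kernel = NULL) {
  if (any(field$values <= 0)) stop("density must be positive (log)")
  if (is.null(kernel)) kernel <- macro_kernel_2d(params, field$n_cells)
  macro2d_xi_cpp(field$values, kernel, params$D, field$dx)$xi_star
}

#' @rdname free_energy_1d
#' @export
free_energy_2d <- function(field, params, kernel = NULL) {
  if (is.null(kernel)) kernel <- macro_kernel_2d(params, field$n_cells)
  macro2d_xi_cpp(field$values, kernel, params$D, field$dx)$energy
}

#' 2D order parameter
#'
#' Cosine projection of the steady density on the first `x` mode,
#' \deqn{Q = \frac{1}{2L^2} \int\!\!\int f(x,y) \cos(\pi x/L)\, dx\, dy,}
#' evaluated by the midpoint rule.  Signed: a profile shifted by half a
#' period in `x` flips the sign.
#'
#' @param field A [density_field_2d()].
#' @return Scalar `Q`.
#' @export
order_parameter_2d <- function(field) {
  cx <- cos(pi * field$x / field$L)
  sum(field$values * outer(cx, rep(1, field$n_cells))) * field$dx^2 /
    (2 * field$L^2)
}

#' Evolve the 2D density to the steady state
#'
#' Same scheme, stopping rule and outputs as [run_to_steady_1d()], extended
#' dimension by dimension (upwind fluxes per axis, shared CFL).  Near
#' threshold these runs are the slowest objects in the package: the
#' `max_steps` cap acts as the runtime guard, and a non-converged result can
#' be resumed by passing its `density` back in as `field`.
#'
#' @inheritParams run_to_steady_1d
#' @param delta_y `y`-perturbation amplitude used when `field` is `NULL`
#'   (see [initial_density_2d()]).
#' @return A `"steady_state_result"`; `Q` is the signed 2D projection and
#'   `rho_num` the max-norm distance from `1/(4L^2)`.
#' @export
run_to_steady_2d <- function(field = NULL, params, delta = 0.01,
                             n_cells = 128, delta_y = 0, tol = 1e-7,
                             t_max = 1e7, max_steps = 5e6, kernel = NULL,
                             cfl = 0.4, diff_factor = 0.2, dt_ceiling = 1) {
  if (is.null(field))
    field <- initial_density_2d(delta, n_cells, params, delta_y = delta_y)
  if (is.null(kernel)) kernel <- macro_kernel_2d(params, field$n_cells)
  out <- macro2d_run_cpp(field$values, kernel, params$D, field$dx, tol,
                         t_max, max_steps, cfl, diff_factor, dt_ceiling)
  dens <- density_field_2d(out$f, field$L)
  structure(list(
    density = dens,
    t_max = out$t_max,
    residual_trace = data.frame(t = out$trace_t, xi_star = out$trace_xi,
                                energy = out$trace_energy),
    Q = order_parameter_2d(dens),
    rho_num = max(abs(dens$values - 1 / (2 * field$L)^2)),
    converged = out$converged,
    steps = out$steps,
    params = params), class = "steady_state_result")
}
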