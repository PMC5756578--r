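#' Configuration of the particle simulator
#'
#' Settings of the agent-based model: `N` overdamped Brownian particles on
#' the periodic interval, linked in pairs by springs that appear (between
#' unlinked pairs closer than `R`) and disappear as Poisson processes whose
#' frequencies scale like `1/epsilon^2`.  `epsilon = 0` selects the limiting
#' model in which the link network is instantaneously equilibrated and every
#' pair within `R` interacts with the mean-field weight
#' `nu_f / (nu_d (N-1))`.
#'
#' @param N Number of particles (`>= 2`).
#' @param epsilon Scale-separation parameter, `>= 0`; `0` means the limiting
#'   model.
#' @param dt_max Hard ceiling on the adaptive time step.
#' @param delta_step Maximal deterministic displacement per step: the step is
#'   reduced so `max |drift| * dt <= delta_step`.
#' @param t_final Final simulation time.
#' @param n_bins Histogram bins for the density estimator over `[-L, L]`.
#' @param n_replicates Ensemble size for [run_micro()].
#' @param xi_init Initial link-to-particle ratio `K/N` (`epsilon > 0` only).
#' @param c_eps Link time-step safety factor: with `epsilon > 0`,
#'   `dt <= c_eps * epsilon^2 / max(nu_f, nu_d)`, keeping per-event
#'   probabilities below `1 - exp(-c_eps)` per step.
#' @param seed RNG seed consumed by [run_micro()].
#' @param mean_field_norm Apply the `nu_f/(nu_d (N-1))` normalization to the
#'   `epsilon = 0` drift (the choice consistent with the macroscopic
#'   equation; see the methods vignette).
#' @return An object of class `"micro_config"`.
#' @export
micro_config <- function(N = 1000, epsilon = 0, dt_max = 0.1,
                         delta_step = 0.1, t_final = 20, n_bins = 60,
                         n_replicates = 6, xi_init = 0.1, c_eps = 0.1,
                         seed = 1L, mean_field_norm = TRUE) {
  stopifnot(N >= 2, epsilon >= 0, t_final > 0, dt_max > 0, delta_step > 0,
            n_bins >= 2, n_replicates >= 1, xi_init >= 0, c_eps > 0)
  structure(list(N = as.integer(N), epsilon = epsilon, dt_max = dt_max,
                 delta_step = delta_step, t_final = t_final,
                 n_bins = as.integer(n_bins),
                 n_replicates = as.integer(n_replicates), xi_init = xi_init,
                 c_eps = c_eps, seed = as.integer(seed),
                 mean_field_norm = isTRUE(mean_field_norm)),
            class = "micro_config")
}

#' Periodic wrap and minimum-image displacement
#'
#' `wrap_periodic()` maps coordinates into `[-L, L)`; `min_image()` reduces a
#' displacement to its shortest periodic image in `[-L, L]`.
#'
#' @param x Coordinates.
#' @param d Displacements.
#' @param L Domain half-size.
#' @return Numeric vector of the same length.
#' @export
wrap_periodic <- function(x, L) {
  y <- (x + L) %% (2 * L)
  y - L
}

#' @rdname wrap_periodic
#' @export
min_image <- function(d, L) d - 2 * L * round(d / (2 * L))

#' Sample particle positions from the perturbed initial density
#'
#' Draws `N` i.i.d. positions from
#' \eqn{f_0(x) = 1/(2L) + \delta \cos(\pi x/L)} by numerical inversion of the
#' CDF on a fine grid.
#'
#' @param delta Perturbation amplitude, `< 1/(2L)`.
#' @param config A [micro_config()].
#' @param params A [net_params()] object.
#' @param n_grid Inversion grid resolution.
#' @return Numeric vector of `N` positions in `[-L, L)`.
#' @export
sample_initial_positions <- function(delta, config, params, n_grid = 8192) {
  L <- params$L
  if (delta < 0 || delta >= 1 / (2 * L)) stop("'delta' out of range")
  u <- stats::runif(config$N)
  if (delta == 0) return(-L + 2 * L * u)
  xg <- seq(-L, L, length.out = n_grid)
  cdf <- (xg + L) / (2 * L) + delta * L / pi * sin(pi * xg / L)
  wrap_periodic(stats::approx(cdf, xg, xout = u, rule = 2)$y, L)
}

#' Initial link set
#'
#' Draws `round(xi_init * N)` links uniformly without replacement from the
#' pairs at minimum-image distance `<= R`.  If fewer eligible pairs exist,
#' all are used (with a warning).
#'
#' @param positions Particle positions.
#' @param config A [micro_config()].
#' @param params A [net_params()] object.
#' @return Two-column integer matrix of linked index pairs (`i < j`).
#' @export
initialize_links <- function(positions, config, params) {
  if (config$epsilon <= 0)
    stop("the limiting model (epsilon = 0) carries no explicit link set")
  pairs <- close_pairs(positions, params)
  K <- round(config$xi_init * config$N)
  if (nrow(pairs) < K) {
    warning(sprintf("only %d eligible pairs for %d requested links",
                    nrow(pairs), K))
    return(pairs)
  }
  pairs[sample.int(nrow(pairs), K), , drop = FALSE]
}

# all unordered pairs with min-image distance <= R (small-N reference)
close_pairs <- function(positions, params) {
  N <- length(positions)
  ij <- which(upper.tri(matrix(0, N, N)), arr.ind = TRUE)
  d <- abs(min_image(positions[ij[, 1]] - positions[ij[, 2]], params$L))
  m <- ij[d <= params$R, , drop = FALSE]
  colnames(m) <- c("i", "j")
  m
}

#' Stochastic link turnover over one time step
#'
#' Every unlinked pair within the detection radius gains a link with
#' probability \eqn{P_f = 1 - e^{-\nu_f \Delta t / ((N-1)\varepsilon^2)}}
#' (per-pair creation rate `nu_f / (N-1)`, matching the mean-field scaling of
#' the linking frequency), and every existing link is destroyed with
#' probability \eqn{P_d = 1 - e^{-\nu_d \Delta t / \varepsilon^2}} (per-link
#' rate `nu_d`).  Creation and destruction are evaluated independently
#' within the step.  The stationary per-pair linkage probability of this
#' two-state chain is `nu_f / (nu_f + nu_d (N-1))`.
#'
#' @param links Two-column integer matrix of current links.
#' @param positions Particle positions.
#' @param dt Time step.
#' @param config A [micro_config()].
#' @param params A [net_params()] object.
#' @return Updated link matrix.
#' @export
update_links <- function(links, positions, dt, config, params) {
  N <- config$N; eps <- config$epsilon
  if (eps <= 0) stop("link turnover requires epsilon > 0")
  pd <- 1 - exp(-params$nu_d * dt / eps^2)
  pf <- 1 - exp(-params$nu_f * dt / ((N - 1) * eps^2))
  keep <- stats::runif(nrow(links)) >= pd
  links <- links[keep, , drop = FALSE]
  cand <- close_pairs(positions, params)
  if (nrow(cand) > 0) {
    key <- function(m) m[, 1] * (N + 1) + m[, 2]
    cand <- cand[!(key(cand) %in% key(links)), , drop = FALSE]
    add <- stats::runif(nrow(cand)) < pf
    links <- rbind(links, cand[add, , drop = FALSE])
  }
  links
}

#' Per-particle drift
#'
#' With an explicit link set (`epsilon > 0`) each link contributes the
#' spring force \eqn{-\kappa(r-\ell)} along the minimum-image direction.  In
#' the limiting model (`epsilon = 0`, `links = NULL`) every pair within `R`
#' contributes, weighted by `nu_f / (nu_d (N-1))` when
#' `config$mean_field_norm` is set.
#'
#' @param positions Particle positions.
#' @param links Link matrix, or `NULL` for the limiting model.
#' @param config A [micro_config()].
#' @param params A [net_params()] object.
#' @return Numeric drift vector (one entry per particle).
#' @export
particle_forces <- function(positions, links = NULL, config, params) {
  N <- length(positions)
  drift <- numeric(N)
  if (is.null(links)) {
    pr <- close_pairs(positions, params)
    norm <- if (config$mean_field_norm)
      params$nu_f / (params$nu_d * (N - 1)) else 1
  } else {
    pr <- links
    norm <- 1
  }
  if (nrow(pr) > 0) {
    d <- min_image(positions[pr[, 1]] - positions[pr[, 2]], params$L)
    r <- abs(d)
    g <- ifelse(r > 0, norm * params$kappa * (r - params$ell) * sign(d), 0)
    # gradient descent of the link energy: particle i feels -grad_i
    for (k in seq_len(nrow(pr))) {
      drift[pr[k, 1]] <- drift[pr[k, 1]] - g[k]
      drift[pr[k, 2]] <- drift[pr[k, 2]] + g[k]
    }
  }
  drift
}

#' Adaptive time step
#'
#' `dt = min(dt_max, delta_step / max|drift|, c_eps * epsilon^2 / max(nu_f,
#' nu_d))`, the last term only for `epsilon > 0`.  Deterministic given the
#' state.
#'
#' @param drift Current drift vector.
#' @param config A [micro_config()].
#' @param params A [net_params()] object.
#' @return Scalar `dt`.
#' @export
adaptive_dt <- function(drift, config, params) {
  dt <- config$dt_max
  dmax <- max(abs(drift))
  if (dmax > 0) dt <- min(dt, config$delta_step / dmax)
  if (config$epsilon > 0)
    dt <- min(dt, config$c_eps * config$epsilon^2 / max(params$nu_f, params$nu_d))
  dt
}

#' One Euler-Maruyama step (reference implementation)
#'
#' \eqn{X^{n+1} = X^n + b\,\Delta t + \sqrt{2D\Delta t}\,\mathcal N(0,1)}
#' with periodic wrap, followed by link turnover when `epsilon > 0`.
#' [run_micro()] drives the equivalent compiled loop; this version backs the
#' unit tests of the individual operations.
#'
#' @inheritParams particle_forces
#' @param dt Time step (typically from [adaptive_dt()]).
#' @return List with `positions` and `links`.
#' @export
micro_step <- function(positions, links = NULL, dt, config, params) {
  drift <- particle_forces(positions, links, config, params)
  positions <- wrap_periodic(
    positions + drift * dt +
      sqrt(2 * params$D * dt) * stats::rnorm(length(positions)), params$L)
  if (config$epsilon > 0)
    links <- update_links(links, positions, dt, config, params)
  list(positions = positions, links = links)
}

#' Histogram density estimator
#'
#' Bins positions into `n_bins` equal boxes over `[-L, L]` and normalizes so
#' the midpoint-rule integral of the returned density is exactly 1.
#'
#' @param positions Particle positions in `[-L, L)`.
#' @param n_bins Number of bins.
#' @param L Domain half-size.
#' @return List with `density`, `centers`, `dx`.
#' @export
estimate_density <- function(positions, n_bins, L) {
  dx <- 2 * L / n_bins
  b <- pmin(pmax(floor((positions + L) / dx), 0), n_bins - 1)
  cnt <- tabulate(b + 1L, nbins = n_bins)
  list(density = cnt / (sum(cnt) * dx),
       centers = -L + (seq_len(n_bins) - 0.5) * dx, dx = dx)
}

#' Recenter positions at their circular mean
#'
#' Computes the periodic center of mass
#' \eqn{X_m = (L/\pi)\,\mathrm{arg}\left(\tfrac12\sum_j e^{i\pi X_j/L}\right)}
#' and shifts all particles by `-X_m` with periodic wrap, so the circular
#' mean of the output is zero.  Idempotent.  When the phase resultant
#' vanishes (perfectly uniform configuration) the input is returned
#' unchanged with a warning.
#'
#' @param positions Particle positions.
#' @param L Domain half-size.
#' @return Recentered positions in `[-L, L)`.
#' @export
recenter_positions <- function(positions, L) {
  ph <- pi * positions / L
  cc <- sum(cos(ph)); ss <- sum(sin(ph))
  if (sqrt(cc^2 + ss^2) <= 1e-12 * length(positions)) {
    warning("vanishing phase resultant: recentering skipped")
    return(positions)
  }
  xm <- L / pi * atan2(ss, cc)
  wrap_periodic(positions - xm, L)
}

#' Order parameter of a binned density
#'
#' @param density,centers As returned by [estimate_density()].
#' @param L Domain half-size.
#' @return `Q = sqrt(c1^2 + s1^2)` by the midpoint/trapezoidal rule.
#' @export
order_parameter_micro <- function(density, centers, L) {
  dx <- centers[2] - centers[1]
  c1 <- sum(density * cos(pi * centers / L)) * dx / L
  s1 <- sum(density * sin(pi * centers / L)) * dx / L
  sqrt(c1^2 + s1^2)
}

#' Run a replicate ensemble of the particle simulator
#'
#' For each replicate: sample initial positions from the perturbed density,
#' initialize links (`epsilon > 0`), evolve to `t_final` with the compiled
#' Euler-Maruyama loop, and accumulate the recentered binned density over
#' the sampling window `[avg_start, t_final]`.  Reported per replicate are
#' the time-averaged recentered density and the order parameter `Q`
#' (time-average of the instantaneous binned-density `Q` over the window);
#' the ensemble density is the replicate mean.
#'
#' @param config A [micro_config()]; `config$seed` seeds the whole ensemble,
#'   so identical configurations reproduce identical trajectories.
#' @param params A [net_params()] object.
#' @param delta Initial perturbation amplitude.
#' @param avg_start Start of the sampling window (default `0.8 * t_final`).
#' @param sample_dt Time between samples (default: window/25).
#' @return List with `density` (ensemble mean), `centers`, `Q` (per
#'   replicate, time-averaged), `q_mean`, `replicates` (raw per-replicate
#'   outputs of the compiled loop) and the echoed `config`/`params`.
#' @export
run_micro <- function(config, params, delta = 0.01, avg_start = NULL,
                      sample_dt = NULL) {
  if (is.null(avg_start)) avg_start <- 0.8 * config$t_final
  if (is.null(sample_dt)) sample_dt <- max((config$t_final - avg_start) / 25,
                                           1e-8)
  set.seed(config$seed)
  drift_norm <- if (config$mean_field_norm)
    params$nu_f / (params$nu_d * (config$N - 1)) else 1
  reps <- vector("list", config$n_replicates)
  for (r in seq_len(config$n_replicates)) {
    x0 <- sample_initial_positions(delta, config, params)
    links0 <- if (config$epsilon > 0) initialize_links(x0, config, params)
              else matrix(0L, 0, 2)
    reps[[r]] <- micro_run_cpp(
      x0, links0, params$L, params$R, params$ell, params$kappa, params$D,
      params$nu_f, params$nu_d, config$epsilon, drift_norm,
      config$t_final, config$dt_max, config$delta_step, config$c_eps,
      config$n_bins, avg_start, sample_dt)
  }
  dens <- rowMeans(vapply(reps, function(z) as.numeric(z$density),
                          numeric(config$n_bins)))
  Q <- vapply(reps, function(z) mean(z$trace[, "Q"]), 0)
  dx <- 2 * params$L / config$n_bins
  list(density = dens,
       centers = -params$L + (seq_len(config$n_bins) - 0.5) * dx,
       Q = Q, q_mean = mean(Q), replicates = reps,
       config = config, params = params)
}
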