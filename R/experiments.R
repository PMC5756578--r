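#' Threshold table of the 1D bifurcation sweeps
#'
#' For each spring length, inverts the first-mode dispersion relation to the
#' noise values realizing a grid of distances-to-threshold `lambda`:
#' `D = -Vhat_1(ell) - lambda L^2 / pi^2`.  The default grid and lengths
#' reproduce the reference table of supercritical (`ell = 0.4725`) and
#' subcritical (`ell = 0.3`) sweep parameters.
#'
#' @param lambdas Growth-rate grid.
#' @param ells Spring lengths (one output column per length).
#' @param params Base [net_params()] (geometry `R`, `L`).
#' @param digits Rounding applied to the `D` columns (`NULL` for none).
#' @return Data frame: `lambda`, then one `D` column per spring length.
#' @export
threshold_table_1d <- function(lambdas = seq(1e-3, -3e-4, by = -1e-4),
                               ells = c(0.4725, 0.3),
                               params = net_params(), digits = 4) {
  out <- data.frame(lambda = lambdas)
  for (ell in ells) {
    p <- modifyList2(params, ell = ell, dim = 1L)
    D <- noise_for_growth(lambdas, 1, p)
    out[[sprintf("D_ell_%g", ell)]] <- if (is.null(digits)) D
                                       else round(D, digits)
  }
  out
}

#' Amplitude table of the supercritical branch
#'
#' Analytic saturated amplitude `|A|` and perturbation estimate `|rho|_th`
#' from [amplitude_prediction()] over a `lambda` grid; optionally the
#' numerical amplitude `|rho|_num` from the finite-volume steady state at
#' `D = noise_for_growth(lambda)`.
#'
#' @param lambdas Growth-rate grid (`>= 0`).
#' @param ell Spring length (supercritical regime).
#' @param params Base [net_params()].
#' @param numeric Also run the 1D solver for `|rho|_num` (slow).
#' @param n_cells,tol,delta Solver settings for the numeric column.
#' @param digits Rounding of the analytic columns (`NULL` for none).
#' @return Data frame: `lambda`, `A`, `rho_th` (+ `rho_num`, `converged`).
#' @export
amplitude_table_1d <- function(lambdas = seq(1e-3, 0, by = -1e-4),
                               ell = 0.4725, params = net_params(),
                               numeric = FALSE, n_cells = 256, tol = 1e-7,
                               delta = 0.01, digits = 4) {
  p0 <- modifyList2(params, ell = ell, dim = 1L)
  A <- rho_th <- numeric(length(lambdas))
  for (i in seq_along(lambdas)) {
    if (lambdas[i] == 0) { A[i] <- 0; rho_th[i] <- 0; next }
    ap <- amplitude_prediction(lambdas[i], p0)
    A[i] <- ap$A_sat; rho_th[i] <- ap$rho_th
  }
  out <- data.frame(lambda = lambdas,
                    A = if (is.null(digits)) A else round(A, digits),
                    rho_th = if (is.null(digits)) rho_th
                             else round(rho_th, digits))
  if (numeric) {
    out$rho_num <- NA_real_; out$converged <- NA
    for (i in seq_along(lambdas)) {
      D <- noise_for_growth(lambdas[i], 1, p0)
      res <- run_to_steady_1d(params = modifyList2(p0, D = D),
                              delta = delta, n_cells = n_cells, tol = tol)
      out$rho_num[i] <- res$rho_num
      out$converged[i] <- res$converged
    }
  }
  out
}

#' Threshold table of the 2D case study
#'
#' Noise values `D = -Vhat_{1,0} - lambda L^2/pi^2` for the square-box cases
#' sharing `alpha = ell/R` but differing in `R/L`.  The default five ratios
#' span the window in which the 2D bifurcation changes type.
#'
#' @param lambdas Growth-rate grid.
#' @param ratios `R/L` values (one column per case).
#' @param alpha Spring-length ratio.
#' @param L Domain half-size.
#' @param digits Rounding (`NULL` for none).
#' @return Data frame: `lambda`, then one `D` column per ratio.
#' @export
threshold_table_2d <- function(lambdas = seq(5e-3, 1e-3, by = -1e-3),
                               ratios = c(1, 0.975, 0.95, 0.925, 0.9),
                               alpha = 0.3, L = 3, digits = 4) {
  out <- data.frame(lambda = lambdas)
  for (i in seq_along(ratios)) {
    R <- ratios[i] * L
    p <- net_params(D = 0, ell = alpha * R, R = R, L = L, dim = 2L)
    D <- noise_for_growth(lambdas, c(1, 0), p)
    out[[sprintf("D_case_%d", i)]] <- if (is.null(digits)) D
                                      else round(D, digits)
  }
  out
}

#' Bifurcation sweep Q(D)
#'
#' Computes the steady-state order parameter over a noise grid, either with
#' the 1D macroscopic solver or with the particle ensemble, producing the
#' data behind a bifurcation diagram.
#'
#' @param tier `"macro1d"` or `"micro"`.
#' @param ell Spring length.
#' @param D_values Noise grid (defaults to the matching column of
#'   [threshold_table_1d()]).
#' @param params Base [net_params()].
#' @param n_cells,tol,delta,max_steps Macro solver settings.
#' @param config [micro_config()] for the micro tier.
#' @param avg_start,sample_dt Micro sampling window controls.
#' @return Data frame with columns `D`, `Q`, `converged` (macro) or `Q_sd`
#'   (micro ensemble spread).  Failures at individual grid points are
#'   recorded as `NA` rows and the sweep continues.
#' @export
sweep_bifurcation <- function(tier = c("macro1d", "micro"), ell,
                              D_values = NULL, params = net_params(),
                              n_cells = 256, tol = 1e-7, delta = 0.01,
                              max_steps = 5e6, config = NULL,
                              avg_start = NULL, sample_dt = NULL) {
  tier <- match.arg(tier)
  if (is.null(D_values)) {
    tt <- threshold_table_1d(ells = ell, params = params, digits = NULL)
    D_values <- tt[[2]]
  }
  out <- data.frame(D = D_values, Q = NA_real_)
  if (tier == "macro1d") {
    out$converged <- NA
    for (i in seq_along(D_values)) {
      res <- try(run_to_steady_1d(params = modifyList2(params, ell = ell,
                                                       D = D_values[i]),
                                  delta = delta, n_cells = n_cells,
                                  tol = tol, max_steps = max_steps),
                 silent = TRUE)
      if (inherits(res, "try-error")) next
      out$Q[i] <- res$Q; out$converged[i] <- res$converged
    }
  } else {
    if (is.null(config)) config <- micro_config()
    out$Q_sd <- NA_real_
    for (i in seq_along(D_values)) {
      cfg <- config
      cfg$seed <- config$seed + i - 1L   # fresh stream per sweep point
      res <- try(run_micro(cfg, modifyList2(params, ell = ell,
                                            D = D_values[i]),
                           delta = delta, avg_start = avg_start,
                           sample_dt = sample_dt), silent = TRUE)
      if (inherits(res, "try-error")) next
      out$Q[i] <- res$q_mean; out$Q_sd[i] <- stats::sd(res$Q)
    }
  }
  out
}

#' Locate the transitional noise from a Q(D) sweep
#'
#' Classifies each sweep point as aggregated (`Q > q_threshold`) or uniform
#' and returns the midpoint between the last aggregated and the first
#' subsequent uniform noise value; the half-gap is the grid uncertainty.
#'
#' @param sweep Data frame from [sweep_bifurcation()] (columns `D`, `Q`),
#'   any order.
#' @param q_threshold Aggregation threshold on `Q`.
#' @return List with `D_transition`, `half_width`, or `NULL` if the sweep
#'   does not bracket a transition.
#' @export
transition_from_sweep <- function(sweep, q_threshold) {
  s <- sweep[order(sweep$D), ]
  s <- s[!is.na(s$Q), ]
  agg <- s$Q > q_threshold
  if (all(agg) || !any(agg)) return(NULL)
  last_agg <- max(which(agg))
  if (last_agg == nrow(s)) return(NULL)
  list(D_transition = (s$D[last_agg] + s$D[last_agg + 1]) / 2,
       half_width = (s$D[last_agg + 1] - s$D[last_agg]) / 2)
}

#' Micro-macro density overlay
#'
#' Runs the limiting particle model (ensemble, recentered, time-averaged
#' density) and the macroscopic solver at the same `(ell, D)` from the same
#' perturbed initial density, and reports both profiles with their
#' discrepancy.
#'
#' @param ell Spring length.
#' @param D Noise intensity.
#' @param params Base [net_params()].
#' @param config [micro_config()] (epsilon is forced to 0).
#' @param delta Shared initial perturbation amplitude.
#' @param n_cells Macro grid size.
#' @param t_final Micro horizon; the macro solver is run to its steady state.
#' @param times Optional vector of intermediate comparison times; when given,
#'   both tiers are compared at each time (macro advanced to `t`, micro
#'   density time-averaged over the trailing tenth of `[0, t]`) instead of
#'   at the macro steady state.
#' @param avg_start,sample_dt Micro sampling window controls.
#' @param tol Macro stopping tolerance.
#' @return List with `overlay` (data frame `x`, `f_macro`, `f_micro`, plus a
#'   `t` column when `times` is given), `l_inf`, `l2` (per time), and the
#'   run objects.
#' @export
overlay_micro_macro <- function(ell, D, params = net_params(),
                                config = micro_config(), delta = 0.01,
                                n_cells = 256, t_final = NULL, times = NULL,
                                avg_start = NULL, sample_dt = NULL,
                                tol = 1e-7) {
  p <- modifyList2(params, ell = ell, D = D)
  config$epsilon <- 0
  if (!is.null(t_final)) config$t_final <- t_final
  dx_fun <- function(centers) centers[2] - centers[1]
  if (is.null(times)) {
    mac <- run_to_steady_1d(params = p, delta = delta, n_cells = n_cells,
                            tol = tol)
    mic <- run_micro(config, p, delta = delta, avg_start = avg_start,
                     sample_dt = sample_dt)
    f_mac <- stats::approx(mac$density$x, mac$density$values,
                           xout = mic$centers, rule = 2)$y
    overlay <- data.frame(x = mic$centers, f_macro = f_mac,
                          f_micro = mic$density)
    dev <- overlay$f_micro - overlay$f_macro
    return(list(overlay = overlay, l_inf = max(abs(dev)),
                l2 = sqrt(sum(dev^2) * dx_fun(mic$centers)),
                macro = mac, micro = mic))
  }
  times <- sort(times)
  field <- initial_density_1d(delta, n_cells, p)
  kernel <- macro_kernel_1d(p, n_cells)
  rows <- list(); l_inf <- l2 <- numeric(length(times))
  t_prev <- 0
  for (i in seq_along(times)) {
    field <- fv_step_1d(field, times[i] - t_prev, p, kernel = kernel)
    t_prev <- times[i]
    cfg <- config
    cfg$t_final <- times[i]
    mic <- run_micro(cfg, p, delta = delta, avg_start = 0.9 * times[i])
    f_mac <- stats::approx(field$x, field$values, xout = mic$centers,
                           rule = 2)$y
    dev <- mic$density - f_mac
    l_inf[i] <- max(abs(dev))
    l2[i] <- sqrt(sum(dev^2) * dx_fun(mic$centers))
    rows[[i]] <- data.frame(t = times[i], x = mic$centers, f_macro = f_mac,
                            f_micro = mic$density)
  }
  list(overlay = do.call(rbind, rows), l_inf = l_inf, l2 = l2,
       macro = field, micro = NULL)
}

#' Write a run summary as JSON
#'
#' Records parameters, settings and headline scalars of a run in a flat
#' JSON object (via jsonlite when installed, else a minimal writer).
#'
#' @param x Named list of scalars / short vectors.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_run_summary <- function(x, path) {
  if (requireNamespace("jsonlite", quietly = TRUE)) {
    jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA)
  } else {
    enc <- function(v) {
      if (is.character(v)) sprintf("\"%s\"", v)
      else paste0("[", paste(format(v, digits = 17), collapse = ", "), "]")
    }
    writeLines(paste0("{", paste(sprintf("\"%s\": %s", names(x),
                                         vapply(x, enc, "")),
                                 collapse = ", "), "}"), path)
  }
  invisible(path)
}
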