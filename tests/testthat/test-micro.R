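test_that("initial sampling follows the perturbed density and the seed", {
  p <- params_super()
  cfg <- micro_config(N = 10000, seed = 1)
  set.seed(2)
  x <- sample_initial_positions(0, cfg, p)
  expect_true(all(x >= -p$L & x < p$L))
  ks <- suppressWarnings(stats::ks.test(x, stats::punif, -p$L, p$L))
  expect_gt(ks$p.value, 0.001)
  # histogram of a large perturbed sample within 3-sigma multinomial bands
  cfg2 <- micro_config(N = 100000)
  set.seed(3)
  y <- sample_initial_positions(0.01, cfg2, p)
  br <- seq(-p$L, p$L, length.out = 31)
  cnt <- graphics::hist(y, breaks = br, plot = FALSE)$counts
  pr <- diff((br + p$L) / (2 * p$L) + 0.01 * p$L / pi * sin(pi * br / p$L))
  expect_true(all(abs(cnt - cfg2$N * pr) <=
                    3 * sqrt(cfg2$N * pr * (1 - pr)) + 1))
  set.seed(9); a <- sample_initial_positions(0.01, cfg, p)
  set.seed(9); b <- sample_initial_positions(0.01, cfg, p)
  expect_identical(a, b)
})

test_that("initial links are the requested fraction of close pairs", {
  p <- params_super()
  cfg <- micro_config(N = 200, epsilon = 1 / 6, xi_init = 0.1)
  set.seed(4)
  x <- sample_initial_positions(0, cfg, p)
  lk <- initialize_links(x, cfg, p)
  expect_equal(nrow(lk), 20)
  d <- abs(min_image(x[lk[, 1]] - x[lk[, 2]], p$L))
  expect_true(all(d <= p$R))
  expect_true(all(lk[, 1] < lk[, 2]))
  cfg0 <- micro_config(N = 50, epsilon = 1 / 6, xi_init = 0)
  expect_equal(nrow(initialize_links(x[1:50], cfg0, p)), 0)
})

test_that("link turnover matches the two-state Markov chain stationary law", {
  p <- net_params(D = 0, ell = 0.1, R = 0.75, L = 3, nu_f = 1, nu_d = 1)
  N <- 5
  cfg <- micro_config(N = N, epsilon = 0.5, xi_init = 0)
  x <- seq(0, 0.2, length.out = N)      # mutually within R forever
  dt <- 0.01
  pf0 <- 1 - exp(-p$nu_f * dt / ((N - 1) * cfg$epsilon^2))
  pd0 <- 1 - exp(-p$nu_d * dt / cfg$epsilon^2)
  stat_discrete <- pf0 / (pf0 + pd0)
  stat_rate <- p$nu_f / (p$nu_f + p$nu_d * (N - 1))
  expect_equal(stat_discrete, stat_rate, tolerance = 0.02)
  set.seed(6)
  links <- matrix(0L, 0, 2)
  n_steps <- 30000L; burn <- 2000L
  occ <- 0
  for (s in seq_len(n_steps)) {
    links <- update_links(links, x, dt, cfg, p)
    if (s > burn) occ <- occ + nrow(links)
  }
  frac <- occ / ((n_steps - burn) * choose(N, 2))
  expect_close(frac, stat_discrete, 0.012)   # ~3.5 sigma Monte-Carlo band
  # creation probability expands to the rate for small dt
  expect_equal(pf0, p$nu_f * dt / ((N - 1) * cfg$epsilon^2), tolerance = 1e-2)
  # a huge destruction exponent clears the links in one step (particles
  # placed beyond R so nothing can re-form)
  set.seed(7)
  far <- c(-2.4, -1.2, 0, 1.2, 2.4)   # mutual (min-image) gaps 1.2 > R
  cfg5 <- micro_config(N = 5, epsilon = 0.5, xi_init = 0)
  lk <- update_links(cbind(1:2, 3:4), far, 1e3, cfg5, p)
  expect_equal(nrow(lk), 0)
})

test_that("forces follow the spring law in both model variants", {
  p <- net_params(D = 0, ell = 0.3, R = 0.75)
  cfg <- micro_config(N = 2, epsilon = 1 / 6)
  # linked pair at rest length: no drift
  f <- particle_forces(c(0, 0.3), links = cbind(1L, 2L), cfg, p)
  expect_equal(f, c(0, 0))
  # compressed below rest length: drift pushes apart
  f2 <- particle_forces(c(0, 0.15), links = cbind(1L, 2L), cfg, p)
  expect_lt(f2[1], 0); expect_gt(f2[2], 0)
  expect_equal(f2, c(-0.3, 0.3))      # kappa (r - ell) = 2 * (-0.15)
  # limiting model, three particles on a line: hand-computed pair sum
  cfg3 <- micro_config(N = 3, epsilon = 0)
  x <- c(-0.4, 0, 0.5)
  f3 <- particle_forces(x, NULL, cfg3, p)
  norm <- 1 / 2                        # nu_f / (nu_d (N-1))
  d12 <- 0.4; d23 <- 0.5; d13 <- 0.9   # d13 > R: excluded
  expect_equal(f3[1], norm * 2 * (d12 - 0.3))
  expect_equal(f3[2], norm * (-2 * (d12 - 0.3) + 2 * (d23 - 0.3)))
  expect_equal(f3[3], norm * (-2 * (d23 - 0.3)))
  expect_equal(sum(f3), 0, tolerance = 1e-14)   # action = reaction
})

test_that("Euler-Maruyama step statistics and deterministic limits", {
  p <- net_params(D = 0, ell = 0.3)
  x <- seq(-2.8, 2.0, length.out = 6)   # spaced beyond R: no interactions
  cfg <- micro_config(N = 6, epsilon = 0)
  set.seed(1)
  st <- micro_step(x, NULL, dt = 0.05, cfg, p)
  expect_equal(st$positions, x)         # D = 0, no forces: frozen
  pD <- net_params(D = 0.004, ell = 0.3)
  cfgD <- micro_config(N = 10000, epsilon = 0)
  set.seed(2)
  x0 <- rep(0, 10000)
  stD <- micro_step(x0, NULL, dt = 0.05, cfgD, pD)
  expect_equal(stats::var(stD$positions), 2 * pD$D * 0.05, tolerance = 0.05)
  # single linked pair relaxes to the rest length
  cfg2 <- micro_config(N = 2, epsilon = 1 / 6, dt_max = 0.01)
  y <- c(0, 0.7); links <- cbind(1L, 2L)
  pl <- net_params(D = 0, ell = 0.3, nu_d = 1e-9)  # links effectively frozen
  set.seed(3)
  for (i in 1:2000) {
    dt <- adaptive_dt(particle_forces(y, links, cfg2, pl), cfg2, pl)
    y <- micro_step(y, links, dt, cfg2, pl)$positions
    links <- cbind(1L, 2L)
  }
  expect_equal(abs(min_image(y[1] - y[2], pl$L)), 0.3, tolerance = 1e-6)
})

test_that("adaptive step obeys its three caps", {
  p <- params_super()
  cfg <- micro_config(epsilon = 0, dt_max = 0.1, delta_step = 0.1)
  expect_equal(adaptive_dt(rep(0, 5), cfg, p), 0.1)
  expect_equal(adaptive_dt(c(0, 10), cfg, p), 0.01)
  cfg_e <- micro_config(epsilon = 1 / 6, dt_max = 0.1, c_eps = 0.1)
  expect_equal(adaptive_dt(rep(0, 5), cfg_e, p), 0.1 * (1 / 36))
  cfg_e2 <- micro_config(epsilon = 1 / 12, dt_max = 0.1, c_eps = 0.1)
  expect_equal(adaptive_dt(rep(0, 5), cfg_e2, p) /
                 adaptive_dt(rep(0, 5), cfg_e, p), 1 / 4)
})

test_that("density estimator is normalized with the stated bin geometry", {
  L <- 3
  d <- estimate_density(rep(0.1, 500), n_bins = 20, L = L)
  expect_equal(sum(d$density) * d$dx, 1, tolerance = 1e-12)
  expect_equal(max(d$density), 1 / d$dx)      # all mass in one bin
  expect_equal(sum(d$density > 0), 1)
  set.seed(11)
  u <- stats::runif(200000, -L, L)
  du <- estimate_density(u, n_bins = 30, L = L)
  pr <- 1 / 30
  expect_true(all(abs(du$density - 1 / (2 * L)) <=
                    3 * sqrt(pr * (1 - pr) * 2e5) / (2e5 * du$dx)))
})

test_that("recentering is exact, idempotent and unwraps boundary clusters", {
  L <- 3
  set.seed(12)
  x <- 1 + stats::rnorm(400, sd = 0.2)
  y <- recenter_positions(x, L)
  expect_equal(mean(y), 0, tolerance = 0.05)
  ph <- sum(exp(1i * pi * y / L))
  expect_lt(abs(Arg(ph)), 1e-10)               # circular mean at 0
  expect_equal(recenter_positions(y, L), y, tolerance = 1e-10)
  # cluster straddling +/- L
  xw <- wrap_periodic(L + stats::rnorm(400, sd = 0.15), L)
  yw <- recenter_positions(xw, L)
  expect_lt(max(abs(yw)), 1)                   # unwrapped around 0
  expect_warning(recenter_positions(c(-1.5, 1.5), L), "resultant")
})

test_that("ensemble runs are reproducible and compiled/interpreted paths agree", {
  p <- net_params(D = 0.002, ell = 0.3)
  cfg <- micro_config(N = 60, epsilon = 0, t_final = 2, n_replicates = 2,
                      seed = 42)
  r1 <- run_micro(cfg, p)
  r2 <- run_micro(cfg, p)
  expect_identical(r1$density, r2$density)
  expect_identical(r1$Q, r2$Q)
  expect_identical(r1$replicates[[1]]$positions, r2$replicates[[1]]$positions)
  # deterministic (D = 0) trajectory: compiled loop vs reference R loop
  p0 <- net_params(D = 0, ell = 0.3)
  cfg0 <- micro_config(N = 40, epsilon = 0, t_final = 1, seed = 1)
  set.seed(8)
  x0 <- sample_initial_positions(0.01, cfg0, p0)
  out <- netphase:::micro_run_cpp(x0, matrix(0L, 0, 2), p0$L, p0$R, p0$ell, p0$kappa,
                       p0$D, p0$nu_f, p0$nu_d, 0, 1 / 39, 1, cfg0$dt_max,
                       cfg0$delta_step, cfg0$c_eps, 20, 1, 10)
  xr <- x0; t <- 0
  while (t < 1) {
    dr <- particle_forces(xr, NULL, cfg0, p0)
    dt <- min(adaptive_dt(dr, cfg0, p0), 1 - t)
    xr <- wrap_periodic(xr + dr * dt, p0$L)
    t <- t + dt
  }
  expect_equal(out$positions, xr, tolerance = 1e-12)
})

test_that("pure-diffusion ensembles sit at the finite-N noise floor", {
  # negligible interaction radius: force-free Brownian particles
  p <- net_params(D = 0.004, ell = 0, R = 1e-3)
  cfg <- micro_config(N = 2000, epsilon = 0, t_final = 40, n_replicates = 3,
                      seed = 21, dt_max = 0.25)
  r <- run_micro(cfg, p, delta = 0)
  floor_rms <- sqrt(1 / (cfg$N * p$L^2))       # E[Q^2] of N uniform points
  expect_lt(r$q_mean, 3 * floor_rms)
  expect_gt(r$q_mean, floor_rms / 10)
  expect_lt(max(abs(r$density - 1 / 6)), 5 * sqrt(1 / 6 / (cfg$N * 3 * 0.1)))
})

test_that("finite-eps dynamics tracks the limiting model away from threshold", {
  # strongly unstable regime so that a short horizon suffices; the link
  # process then only has to keep the effective pair weight near its
  # stationary value for the two tiers to agree
  # (not too far below threshold: deep in the unstable regime the density
  # splits into several bumps and the first-mode Q no longer measures
  # aggregation)
  p <- net_params(D = 0.025, ell = 0.3)
  cfg0 <- micro_config(N = 150, epsilon = 0, t_final = 300, n_replicates = 2,
                       seed = 13, dt_max = 0.25)
  q0 <- run_micro(cfg0, p, delta = 0.01)$q_mean
  cfg_e <- micro_config(N = 150, epsilon = 1 / 6, t_final = 300,
                        n_replicates = 2, seed = 13)
  qe <- run_micro(cfg_e, p, delta = 0.01)$q_mean
  expect_gt(q0, 0.15)          # aggregated
  expect_gt(qe, 0.15)          # finite-eps aggregates too
  expect_lt(abs(qe - q0), 0.2)
})
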