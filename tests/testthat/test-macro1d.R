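test_that("initial density has exact mass and the stated extrema", {
  p <- params_super()
  f <- initial_density_1d(0.01, 256, p)
  expect_equal(total_mass(f), 1, tolerance = 1e-12)
  expect_equal(max(f$values), 1 / 6 + 0.01, tolerance = 1e-4)
  expect_equal(which.max(f$values), 128, tolerance = 1)  # peak at x = 0
  f0 <- initial_density_1d(0, 64, p)
  expect_true(all(abs(f0$values - 1 / 6) < 1e-15))
  expect_error(initial_density_1d(1 / 6, 64, p), "delta")
})

test_that("periodic convolution is linear, exact on simple inputs, and matches the oracle", {
  p <- params_super()
  n <- 64
  f <- initial_density_1d(0, n, p)
  kern <- macro_kernel_1d(p, n)
  # uniform density: convolution is the constant (1/2L) * int V
  cu <- periodic_convolution_1d(f, p)
  expect_equal(cu, rep(sum(kern) * f$dx / 6, n), tolerance = 1e-14)
  # single-cell mass reproduces the sampled kernel
  v <- rep(1e-9, n); v[1] <- 1
  fd <- density_field_1d(v, p$L)
  cd <- periodic_convolution_1d(fd, p)
  expect_close(cd, ((1 - 1e-9) * kern + 1e-9 * sum(kern)) * fd$dx, 1e-12)
  # random field vs brute-force O(n^2) sum
  set.seed(5)
  fr <- density_field_1d(runif(n, 0.05, 0.3), p$L)
  expect_equal(periodic_convolution_1d(fr, p),
               conv_oracle_1d(fr$values, kern, fr$dx), tolerance = 1e-12)
})

test_that("the scheme is well balanced, conservative and positive", {
  p <- params_super()
  f <- initial_density_1d(0, 128, p)
  f1 <- fv_step_1d(f, 0.5, p)
  expect_equal(f1$values, f$values, tolerance = 1e-15)  # uniform fixed point
  fp <- initial_density_1d(0.01, 128, p)
  f2 <- fv_step_1d(fp, 0.5, p)
  expect_equal(total_mass(f2), 1, tolerance = 1e-13)
  expect_true(all(f2$values > 0))
  # a strongly peaked state stays positive and conservative too
  set.seed(8)
  v <- exp(3 * cos(pi * (1:128) / 64)); v <- v / (sum(v) * fp$dx)
  f3 <- fv_step_1d(density_field_1d(v, p$L), 0.2, p)
  expect_equal(total_mass(f3), 1, tolerance = 1e-12)
  expect_true(all(f3$values > 0))
})

test_that("with a zero kernel the scheme converges to the torus heat solution", {
  p <- net_params(D = 0.05, ell = 0.3)
  t_end <- 2
  err <- vapply(c(64, 128), function(n) {
    f <- initial_density_1d(0.02, n, p)
    kern0 <- rep(0, n)
    res <- run_to_steady_1d(field = f, params = p, kernel = kern0,
                            tol = 0, t_max = t_end, max_steps = 1e6)
    exact <- 1 / 6 + 0.02 * exp(-p$D * (pi / p$L)^2 * t_end) *
      cos(pi * res$density$x / p$L)
    max(abs(res$density$values - exact))
  }, 0)
  expect_lt(err[2], err[1])          # refines with the grid
  expect_lt(err[2], 1e-4)
})

test_that("steady-state residual matches its definition and vanishes when uniform", {
  p <- params_super()
  f <- initial_density_1d(0, 64, p)
  expect_equal(steady_state_residual_1d(f, p), 0, tolerance = 1e-14)
  fp <- initial_density_1d(0.01, 64, p)
  xi <- p$D * log(fp$values) + periodic_convolution_1d(fp, p)
  expect_equal(steady_state_residual_1d(fp, p),
               max(abs(xi - mean(xi))), tolerance = 1e-12)
})

test_that("order parameter recovers pure-mode amplitudes and is rotation invariant", {
  p <- params_super()
  n <- 128
  x <- -p$L + (seq_len(n) - 0.5) * (2 * p$L / n)
  fu <- density_field_1d(rep(1 / 6, n), p$L)
  expect_equal(order_parameter_1d(fu), 0, tolerance = 1e-15)
  a <- 0.05
  fc <- density_field_1d(1 / 6 + a * cos(pi * x / p$L), p$L)
  fs <- density_field_1d(1 / 6 + a * sin(pi * x / p$L), p$L)
  expect_equal(order_parameter_1d(fc), a, tolerance = 1e-10)
  expect_equal(order_parameter_1d(fs), a, tolerance = 1e-10)
})

test_that("free energy is translation invariant and decays along trajectories", {
  p <- params_super()
  n <- 128
  x <- -p$L + (seq_len(n) - 0.5) * (2 * p$L / n)
  v <- 1 / 6 + 0.05 * cos(pi * x / p$L)
  e1 <- free_energy_1d(density_field_1d(v, p$L), p)
  e2 <- free_energy_1d(density_field_1d(v[c(33:n, 1:32)], p$L), p)
  expect_equal(e1, e2, tolerance = 1e-13)
  # V = 0, uniform: E = D log(1/2L)
  expect_equal(free_energy_1d(density_field_1d(rep(1 / 6, n), p$L), p,
                              kernel = rep(0, n)),
               p$D * log(1 / 6), tolerance = 1e-12)
  res <- run_to_steady_1d(params = p, n_cells = 128, max_steps = 4e4, tol = 1e-7)
  de <- diff(res$residual_trace$energy)
  expect_true(all(de <= 1e-11))
})

test_that("a linearly stable run relaxes to the uniform state", {
  p <- net_params(D = 0.0043, ell = 0.4725)
  res <- run_to_steady_1d(params = p, n_cells = 128)
  expect_true(res$converged)
  expect_lt(res$Q, 1e-3)
  expect_lt(max(abs(res$density$values - 1 / 6)), 1e-3)
  expect_lt(utils::tail(res$residual_trace$xi_star, 1), 1e-7)
})

test_that("mass and positivity hold across a full aggregating run", {
  p <- params_super(D = 0.0030)
  res <- run_to_steady_1d(params = p, n_cells = 128)
  expect_true(res$converged)
  expect_equal(total_mass(res$density), 1, tolerance = 1e-12)
  expect_true(all(res$density$values > 0))
  expect_gt(res$Q, 0.1)   # aggregated branch
})
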