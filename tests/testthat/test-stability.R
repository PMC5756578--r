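test_that("growth rate follows the dispersion relation and its threshold", {
  p <- params_super(D = 0.0030)
  expect_close(growth_rate(1, params = p)$growth_rate, 0.0010, 1e-4)
  # vanishes exactly at D = -Vhat_1
  d0 <- -potential_mode_1d(1, p)
  expect_equal(growth_rate(1, D = d0, params = p)$growth_rate, 0)
  # all higher modes decay at the sweep parameters (first-mode dominance)
  gr <- growth_rate(2:50, D = 0.0030, params = p)
  expect_true(all(gr$growth_rate < 0))
  expect_error(growth_rate(0, params = p), "zero mode")
})

test_that("noise_for_growth inverts growth_rate to machine precision", {
  p <- params_super()
  set.seed(1)
  for (lam in runif(8, -5e-4, 2e-3)) {
    D <- noise_for_growth(lam, 1, p)
    expect_close(growth_rate(1, D = D, params = p)$growth_rate, lam, 1e-12)
  }
  p2 <- params_case_2d(1)
  D <- noise_for_growth(5e-3, c(1, 0), p2)
  expect_close(growth_rate(c(1, 0), D = D, params = p2)$growth_rate, 5e-3,
               1e-12)
  expect_warning(noise_for_growth(10, 1, p), "attainable")
})

test_that("critical noise reproduces the two reference thresholds", {
  expect_close(as.numeric(critical_noise(params_super())), 0.0040, 5e-5)
  expect_close(as.numeric(critical_noise(params_sub())), 0.0347, 5e-5)
  # at ell_c the threshold vanishes and the flag flips
  lc <- critical_lengths_1d(net_params())$ell_c
  dc <- critical_noise(net_params(ell = lc + 1e-6))
  expect_equal(as.numeric(dc), 0)
  expect_true(attr(dc, "always_stable"))
})

test_that("1D critical lengths match their closed forms", {
  cl <- critical_lengths_1d(net_params())
  expect_close(cl$ell_c, 0.75 * (4 - pi) * (sqrt(2) + 1) / pi, 1e-12)
  expect_close(cl$ell_star,
               0.75 * ((pi - 4) * sqrt(2) + 2) / (pi * (sqrt(2) - 1)), 1e-9)
  expect_equal(round(cl$ell_star, 4), 0.4530)
  expect_equal(round(cl$D_star, 4), 0.0074)
})

test_that("critical noise is affine in ell with the reference slope and root", {
  ells <- seq(0, 0.49, length.out = 12)
  dc <- vapply(ells, function(l)
    as.numeric(critical_noise(net_params(ell = l))), 0)
  fit <- stats::lm(dc ~ ells)
  expect_close(unname(fit$coefficients[2]), -0.1781, 1e-4)
  expect_close(unname(-fit$coefficients[1] / fit$coefficients[2]), 0.4947,
               1e-4)
  expect_lt(max(abs(stats::residuals(fit))), 1e-12)   # exactly affine
})

test_that("1D bifurcation classification flips at ell_star", {
  expect_identical(bifurcation_type_1d(params_sub())$regime, "subcritical")
  expect_identical(bifurcation_type_1d(params_super())$regime, "supercritical")
  ls <- critical_lengths_1d(net_params())$ell_star
  expect_close(bifurcation_type_1d(net_params(ell = ls))$discriminant, 0,
               1e-10)
  lc <- critical_lengths_1d(net_params())$ell_c
  expect_identical(bifurcation_type_1d(net_params(ell = lc + 1e-4))$regime,
                   "stable")
})

test_that("2D critical alpha matches the Bessel-Struve roots", {
  # frozen roots, cross-checked against scipy.special struve/jv
  expect_close(critical_alpha(params_case_2d(1)), 0.66210001, 5e-5)
  expect_close(critical_alpha(net_params(R = 1.5, L = 3, ell = 0, dim = 2L)),
               0.73333121, 5e-5)
  expect_close(critical_alpha(net_params(R = 0.75, L = 3, ell = 0, dim = 2L)),
               0.74607113, 5e-5)
})

test_that("V* and (c, d) forms of the 2D criterion agree in sign", {
  set.seed(3)
  n_ok <- 0
  while (n_ok < 20) {
    r <- runif(1, 0.3, 1)
    ac <- critical_alpha(net_params(R = 3 * r, L = 3, ell = 0, dim = 2L))
    a <- runif(1, 0.02, 0.95 * ac)
    v <- vstar_discriminant(a, r)
    expect_equal(sign(v$vstar), sign(v$c - v$d))
    n_ok <- n_ok + 1
  }
  # the printed regimes of the five-case study
  expect_identical(vstar_discriminant(0.3, 1)$regime, "supercritical")
  expect_identical(vstar_discriminant(0.3, 0.975)$regime, "supercritical")
  expect_identical(vstar_discriminant(0.3, 0.95)$regime, "subcritical")
  expect_identical(vstar_discriminant(0.3, 0.9)$regime, "subcritical")
})

test_that("supercritical window matches the reference and V* flips at its edges", {
  w <- supercritical_window_2d(1)
  expect_equal(round(w$window, 4), c(0.1016, 0.5818))
  eps <- 1e-5
  expect_gt(vstar_discriminant(w$window[1] - eps, 1)$vstar, 0)
  expect_lt(vstar_discriminant(w$window[1] + eps, 1)$vstar, 0)
  expect_lt(vstar_discriminant(w$window[2] - eps, 1)$vstar, 0)
  expect_gt(vstar_discriminant(w$window[2] + eps, 1)$vstar, 0)
})

test_that("no resolvable supercritical window for smaller R/L", {
  for (r in c(0.5, 0.25)) {
    w <- supercritical_window_2d(r)
    expect_null(w$window)
    # any raw sign excursion is confined to the degenerate collar below
    # alpha_c and is orders of magnitude shallower than the R/L = 1 window
    if (!is.null(w$intervals)) {
      expect_true(all(w$intervals[, "lo"] > 0.9 * w$alpha_c))
      expect_true(all(w$intervals[, "depth"] > -1e-6))
    }
  }
})

test_that("amplitude prediction reproduces the printed columns and bounds", {
  p <- params_super()
  a10 <- amplitude_prediction(0.0010, p)
  expect_equal(round(a10$A_sat, 4), 0.1094)
  expect_equal(round(a10$rho_th, 4), 0.3428)
  a5 <- amplitude_prediction(0.0005, p)
  expect_equal(round(a5$A_sat, 4), 0.0847)
  expect_equal(round(a5$rho_th, 4), 0.2314)
  expect_equal(amplitude_prediction(0, p)$A_sat, 0)
  expect_equal(amplitude_prediction(0, p)$rho_th, 0)
  # the saturated amplitude scales as sqrt(lam) with a near-constant
  # prefactor, and the initial perturbation delta = 0.01 respects the
  # smallness condition delta <= sqrt(lam) over the tabulated sweep range
  lams <- seq(1e-4, 1e-3, length.out = 10)
  pref <- vapply(lams, function(l) amplitude_prediction(l, p)$A_sat / sqrt(l), 0)
  expect_lt(diff(range(pref)) / mean(pref), 0.25)
  expect_true(all(0.01 <= sqrt(lams)))
  expect_error(amplitude_prediction(-1e-4, p), "lam")
  expect_error(amplitude_prediction(1e-4, params_sub()), "supercritical")
})

test_that("first-mode dominance holds at every tabulated sweep point", {
  tt <- threshold_table_1d(digits = NULL)
  for (col in c(2, 3)) {
    ell <- c(0.4725, 0.3)[col - 1]
    for (i in seq_len(nrow(tt))) {
      gr <- growth_rate(2:100, D = tt[i, col],
                        params = net_params(ell = ell))
      expect_true(all(gr$growth_rate < 0))
    }
  }
})

test_that("spectral report CSV has the documented layout", {
  path <- withr::local_tempfile(fileext = ".csv")
  tab <- write_spectral_report(1:4, params_super(), path)
  back <- read.csv(path)
  expect_named(back, c("k1", "k2", "z", "vhat", "growth_rate", "D_c",
                       "regime", "discriminant"))
  expect_equal(back$vhat, tab$vhat, tolerance = 1e-12)
})
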