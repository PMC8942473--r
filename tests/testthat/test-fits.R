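test_that("noiseless Boltzmann data are recovered to machine-level accuracy", {
  dat <- gen_curve_data("boltzmann1", list(x_half = 0.42, slope = 8))
  fit <- fit_boltzmann(dat)
  expect_lt(abs(fit$x_half - 0.42) / 0.42, 1e-6)
  expect_lt(abs(fit$slope_s - 8) / 8, 1e-6)
  # fitted curve passes through 0.5 at its midpoint
  expect_equal(predict(fit, fit$x_half), 0.5)
  # gating force is slope * kT (per um)
  expect_equal(fit$z, fit$slope_s * 1.380649e-23 * 295 * 1e6,
               tolerance = 1e-12)
})

test_that("Boltzmann fitting recovers midpoints from noisy activation curves", {
  errs <- vapply(1:30, function(s) {
    dat <- gen_curve_data("boltzmann1", list(x_half = 0.42, slope = 8),
                          noise_sd = 0.02, seed = s)
    dat$y <- pmin(pmax(dat$y, 0), 1.05)
    fit <- fit_boltzmann(dat, seed = s)
    abs(fit$x_half - 0.42) / 0.42
  }, numeric(1))
  expect_lt(median(errs), 0.02)
})

test_that("Boltzmann fit is equivariant under a change of length units", {
  dat <- gen_curve_data("boltzmann1", list(x_half = 0.42, slope = 8),
                        noise_sd = 0.02, seed = 2)
  dat$y <- pmin(pmax(dat$y, 0), 1.05)
  fit_um <- fit_boltzmann(dat, seed = 1)
  dat_nm <- data.frame(x = dat$x * 1000, y = dat$y)
  fit_nm <- fit_boltzmann(dat_nm, seed = 1)
  expect_equal(fit_nm$x_half, fit_um$x_half * 1000, tolerance = 1e-4)
  expect_equal(fit_nm$slope_s, fit_um$slope_s / 1000, tolerance = 1e-4)
})

test_that("two-component Boltzmann nests the single-component model", {
  dat <- gen_curve_data("boltzmann1", list(x_half = 0.42, slope = 8),
                        x = seq(0, 1.2, by = 0.1))
  fit2 <- fit_boltzmann(dat, n_components = 2, seed = 3)
  # weighted-sum model must fit one-component data essentially perfectly
  expect_lt(fit2$rss, 1e-8)
  pred <- predict(fit2, dat$x)
  expect_lt(max(abs(pred - dat$y)), 1e-4)

  bi <- gen_curve_data("boltzmann2",
                       list(x_half1 = 0.25, slope1 = 20, x_half2 = 0.8,
                            slope2 = 15, w1 = 0.6))
  fitb <- fit_boltzmann(bi, n_components = 2, seed = 3)
  expect_lt(fitb$rss, 1e-8)
  expect_error(fit_boltzmann(bi[1:5, ], n_components = 2), "at least 7")
})

test_that("dose-response fits recover the Hill parameters", {
  dat <- gen_curve_data("dose", list(i_initial = 426, i_final = 0,
                                     c_half = 0.9, hill_p = 1))
  fit <- fit_dose_response(dat)
  expect_lt(abs(fit$c_half - 0.9) / 0.9, 1e-6)
  expect_lt(abs(fit$hill_p - 1), 1e-6)
  # half-block identity at the fitted IC50
  expect_equal(predict(fit, fit$c_half), fit$i_initial / 2,
               tolerance = 1e-6)
  expect_error(fit_dose_response(data.frame(x = c(1, 2, 3, 4),
                                            y = rep(5, 4))),
               "nothing to fit")
})

test_that("noisy dose-response recovery stays within a few percent", {
  conc_grid <- rep(c(0.05, 0.1, 0.2, 0.45, 0.9, 1.8, 3.6, 10, 30),
                   each = 4)  # four cells per concentration
  errs <- t(vapply(1:30, function(s) {
    dat <- gen_curve_data("dose", list(i_initial = 426, i_final = 0,
                                       c_half = 0.9, hill_p = 1),
                          x = conc_grid, noise_sd = 8, seed = s)
    fit <- fit_dose_response(dat, seed = s)
    c(abs(fit$c_half - 0.9) / 0.9, abs(fit$hill_p - 1))
  }, numeric(2)))
  expect_lt(median(errs[, 1]), 0.05)
  expect_lt(median(errs[, 2]), 0.05)
})

test_that("bi-exponential fits recover decay components", {
  true <- list(a1 = 250, tau1 = 3.6, a2 = 120, tau2 = 24, a_ss = 56)
  dat <- gen_curve_data("biexp", true)
  fit <- fit_biexp(dat, seed = 1)
  expect_lt(abs(fit$tau1 - 3.6) / 3.6, 1e-3)
  expect_lt(abs(fit$tau2 - 24) / 24, 1e-3)
  expect_false(fit$single_exponential)
  expect_lt(fit$tau1, fit$tau2)
})

test_that("bi-exponential fit accepts current traces with a window", {
  true <- list(a1 = 250, tau1 = 3.6, a2 = 120, tau2 = 24, a_ss = 56)
  y <- biexp_current(seq(0, 150, by = 0.05), true$a1, true$tau1, true$a2,
                     true$tau2, true$a_ss)
  tr <- trace(c(rep(56, 200), y), dt = 0.05, kind = "current")
  fit <- fit_biexp(tr, fit_window = c(10, 160), seed = 1)
  expect_lt(abs(fit$tau2 - 24) / 24, 1e-3)
  expect_error(fit_biexp(trace(y, dt = 0.05, kind = "voltage")), "current")
})

test_that("degenerate decays are handled: constant input and tau collapse", {
  flat <- trace(rep(42, 100), dt = 1, kind = "current")
  fit <- fit_biexp(flat)
  expect_equal(fit$a1, 0)
  expect_equal(fit$a2, 0)
  expect_equal(fit$a_ss, 42)

  # nearly equal time constants collapse and the fit is re-run and flagged
  tg <- seq(0, 60, by = 0.5)
  y <- 150 * exp(-tg / 6) + 100 * exp(-tg / 7.2) + 20
  expect_warning(fit1 <- fit_biexp(data.frame(t = tg, i = y), seed = 1),
                 "collapsed")
  expect_true(fit1$single_exponential)
  # the effective single time constant lies between the two true ones
  expect_gt(fit1$tau1, 6)
  expect_lt(fit1$tau1, 7.2)
})

test_that("I-V regression matches the closed-form OLS oracle", {
  v <- seq(-90, 90, by = 30)
  dat <- data.frame(v = v, i = iv_current(v, 3.2, -1.4))
  fit <- fit_iv(dat)
  expect_equal(fit$conductance, 3.2, tolerance = 1e-10)
  expect_equal(fit$e_rev, -1.4, tolerance = 1e-8)
  expect_equal(fit$r_squared, 1)

  fit2 <- fit_iv(data.frame(v = c(-10, 0, 10), i = c(-10, 0, 10)))
  expect_equal(fit2$conductance, 1)
  expect_equal(fit2$e_rev, 0, tolerance = 1e-12)

  set.seed(8)
  for (rep in 1:20) {
    dat <- gen_curve_data("iv", list(conductance = 3.2, e_rev = -1.4),
                          noise_sd = 25, seed = rep)
    fit <- fit_iv(dat)
    ols <- oracle_ols(dat$x, dat$y)
    expect_equal(fit$conductance, unname(ols["slope"]), tolerance = 1e-12)
    expect_equal(fit$e_rev, unname(-ols["intercept"] / ols["slope"]),
                 tolerance = 1e-10)
  }
  expect_error(fit_iv(data.frame(v = c(0, 0, 1), i = c(1, 2, 3))),
               "distinct")
})

test_that("fitted curves never lose to the generating parameters", {
  # optimizer sanity: RSS(fit) <= RSS(truth) on noisy draws
  wins <- 0L
  for (s in 1:25) {
    dat <- gen_curve_data("boltzmann1", list(x_half = 0.42, slope = 8),
                          noise_sd = 0.02, seed = 100 + s)
    dat$y <- pmin(pmax(dat$y, 0), 1.05)
    fit <- fit_boltzmann(dat, seed = s)
    rss_true <- sum((dat$y - boltzmann_po(dat$x, 0.42, 8))^2)
    if (fit$rss <= rss_true + 1e-12) wins <- wins + 1L
  }
  expect_gte(wins, 24L)
})
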