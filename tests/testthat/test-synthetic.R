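test_that("degenerate concentrations give perfect and absent locking", {
  delta <- gen_phase_locked_train(rate = 50, frequency = 50, duration = 2e4,
                                  mean_phase = 1, kappa = Inf, seed = 1)
  ph <- spike_phases(delta)
  expect_true(all(abs(ph - 1) < 1e-9))
  expect_equal(vector_strength(ph)$vs, 1)

  unif <- gen_phase_locked_train(rate = 50, frequency = 50, duration = 4e5,
                                 kappa = 0, seed = 2)
  expect_lt(vector_strength(spike_phases(unif))$vs, 0.02)
})

test_that("generated phase concentration matches the Bessel-ratio oracle", {
  # I1(2)/I0(2) computed independently in the helper
  tr <- gen_phase_locked_train(rate = 50, frequency = 50, duration = 2e5,
                               kappa = 2, seed = 31)
  vs <- vector_strength(spike_phases(tr))$vs
  target <- oracle_vm_resultant(2)
  n <- length(tr$times)
  se <- sqrt((1 - target^2) / (2 * n))
  expect_lt(abs(vs - target), 3 * se)
})

test_that("spike counts track rate * duration and trains are reproducible", {
  tr <- gen_phase_locked_train(rate = 25, frequency = 100, duration = 1e5,
                               kappa = 2, seed = 5)
  n <- length(tr$times)
  # binomial(10^4 cycles, 1/4): 3 sigma around 2500
  expect_lt(abs(n - 2500), 3 * sqrt(1e4 * 0.25 * 0.75))
  tr2 <- gen_phase_locked_train(rate = 25, frequency = 100, duration = 1e5,
                                kappa = 2, seed = 5)
  expect_identical(tr$times, tr2$times)
  expect_error(gen_phase_locked_train(rate = 10, frequency = 50,
                                      duration = 100, weights = c(2, 1),
                                      mean_phase = c(0, 1),
                                      kappa = c(1, 1)),
               "sum to 1")
})

test_that("curve generator satisfies the family identities", {
  b <- gen_curve_data("boltzmann1", list(x_half = 0.42, slope = 8),
                      x = 0.42)
  expect_equal(b$y, 0.5)
  iv <- gen_curve_data("iv", list(conductance = 1, e_rev = 0), x = 10)
  expect_equal(iv$y, 10)
  d <- gen_curve_data("dose",
                      list(i_initial = 400, i_final = 0, c_half = 0.9,
                           hill_p = 1), x = 0.9)
  expect_equal(d$y, 200)
  expect_error(gen_curve_data("weibull", list()), "arg")
  # seeded noise is reproducible
  g1 <- gen_curve_data("iv", list(conductance = 3.2, e_rev = -1.4),
                       noise_sd = 10, seed = 3)
  g2 <- gen_curve_data("iv", list(conductance = 3.2, e_rev = -1.4),
                       noise_sd = 10, seed = 3)
  expect_identical(g1$y, g2$y)
})

test_that("unstimulated membrane stays exactly at rest", {
  p <- neuron_params()
  sim <- simulate_neuron(p, duration = 200, dt = 0.05)
  expect_length(sim$spikes$times, 0L)
  expect_true(all(sim$voltage$samples == p$e_l))
})

test_that("with g_MA = 0 the model is a plain leaky integrate-and-fire", {
  # subthreshold current step: analytic exponential charging
  p <- neuron_params(g_ma = 0)
  stim <- step_ramp_stimulus("current", amplitude = 0.015, onset = 0,
                             duration = 200)
  sim <- simulate_neuron(p, current_stim = stim, duration = 200, dt = 0.005)
  tt <- trace_times(sim$voltage)
  tau <- p$c_m / p$g_l
  analytic <- p$e_l + (15 / p$g_l) * (1 - exp(-tt / tau))
  expect_length(sim$spikes$times, 0L)
  expect_lt(max(abs(sim$voltage$samples - analytic)), 0.05)

  # suprathreshold step: first crossing at the analytic threshold time
  stim2 <- step_ramp_stimulus("current", amplitude = 0.03, onset = 0,
                              duration = 200)
  sim2 <- simulate_neuron(p, current_stim = stim2, duration = 200,
                          dt = 0.005)
  t_th <- -tau * log(1 - (p$v_th - p$e_l) / (30 / p$g_l))
  expect_gt(length(sim2$spikes$times), 0L)
  expect_lt(abs(sim2$spikes$times[1L] - t_th), 0.1)
})

test_that("Hill-model block reduces the MA response monotonically", {
  mech <- step_ramp_stimulus("displacement", amplitude = 0.6, onset = 10,
                             duration = 80)
  conc <- c(0, 0.3, 0.9, 3, 10)
  depol <- vapply(conc, function(cc) {
    p <- neuron_params(v_th = 100,  # disable spiking to read raw depolarization
                       block_fraction = hill_block_fraction(cc, 0.9, 1))
    sim <- simulate_neuron(p, mech_stim = mech, duration = 100, dt = 0.02)
    max(sim$voltage$samples)
  }, numeric(1))
  expect_true(all(diff(depol) < 0))
})

test_that("displacement steps evoke a bi-exponential MA current decay", {
  # voltage-clamp analog: a huge capacitance pins V at rest, so the
  # reconstructed MA current is the adaptation kernel times a constant
  # driving force
  p <- neuron_params(c_m = 1e7, v_th = 100)
  mech <- step_ramp_stimulus("displacement", amplitude = 1.12, onset = 0,
                             duration = 300)
  sim <- simulate_neuron(p, mech_stim = mech, duration = 300, dt = 0.01)
  v <- sim$voltage$samples
  i_ma <- p$c_m * diff(v) / 0.01 + p$g_l * (v[-length(v)] - p$e_l)
  tt <- trace_times(sim$voltage)[-length(v)]
  keep <- tt <= 200
  fit <- fit_biexp(data.frame(t = tt[keep], i = i_ma[keep]), seed = 1)
  expect_false(fit$single_exponential)
  expect_lt(abs(fit$tau1 - 3.6) / 3.6, 0.05)
  expect_lt(abs(fit$tau2 - 24) / 24, 0.05)
  # amplitude fractions follow the configured a1/a2/a_ss split
  tot <- fit$a1 + fit$a2 + fit$a_ss
  expect_equal(fit$a1 / tot, 0.5, tolerance = 0.05)
})

test_that("simulation is bit-for-bit reproducible under a fixed seed", {
  stim <- sinusoid_stimulus("current", 50, 0.05, duration = 300)
  mech <- sinusoid_stimulus("displacement", 50, 0.4, duration = 300)
  s1 <- simulate_neuron(neuron_params(noise_sd = 50, seed = 9), stim, mech,
                        duration = 300, dt = 0.05)
  s2 <- simulate_neuron(neuron_params(noise_sd = 50, seed = 9), stim, mech,
                        duration = 300, dt = 0.05)
  expect_identical(s1$voltage$samples, s2$voltage$samples)
  expect_identical(s1$spikes$times, s2$spikes$times)
})

test_that("integration preconditions are enforced", {
  p <- neuron_params()
  expect_error(simulate_neuron(p, duration = 10, dt = 1),
               "0.1 \\* tau1")
  cur <- sinusoid_stimulus("current", 50, 0.05, duration = 10)
  expect_error(simulate_neuron(p, mech_stim = cur, duration = 10),
               "displacement")
})

test_that("simulator voltage excursions are detectable end-to-end", {
  mech <- step_ramp_stimulus("displacement", amplitude = 0.8, onset = 5,
                             duration = 80)
  sim <- simulate_neuron(neuron_params(), mech_stim = mech, duration = 100,
                         dt = 0.02)
  expect_gt(length(sim$spikes$times), 0L)
  detected <- detect_spikes(sim$voltage, criterion = 0, dead_time = 1)
  expect_equal(length(detected$times), length(sim$spikes$times))
  expect_true(all(abs(detected$times - (sim$spikes$times + 0.5)) < 0.1))
})
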