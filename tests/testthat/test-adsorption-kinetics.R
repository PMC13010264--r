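test_that("steady-state release ratio follows (1+E_i)/(1-E_i)", {
  expect_equal(steady_state_ratio(adsorption_params(0.02, 0)), 1.0)
  expect_equal(steady_state_ratio(adsorption_params(0.02, 0.5)), 3.0)
  # long-time ODE oracle at E_i = 0.19
  p <- adsorption_params(k_off = 0.01, E_i = 0.19)
  d <- competition_design(sample_times = c(4000, 5000))
  s <- simulate_competition(p, d)
  ratio_ode <- s$f12[2] / s$f13[2]
  expect_equal(ratio_ode, 1.19 / 0.81, tolerance = 1e-6)
  expect_equal(steady_state_ratio(p), ratio_ode, tolerance = 1e-6)
  expect_error(steady_state_ratio(adsorption_params(0.02, 1)), "diverges")
  # strictly increasing in E_i
  r <- vapply(seq(0, 0.95, by = 0.05), steady_state_ratio, numeric(1))
  expect_true(all(diff(r) > 0))
})

test_that("forward simulation matches the closed-form exchange oracle", {
  for (cse in list(c(0.01, 0.19), c(0.005, 0.54), c(0.05, 0))) {
    p <- adsorption_params(k_off = cse[1], E_i = cse[2])
    d <- competition_design()
    sim <- simulate_competition(p, d)
    f12_oracle <- oracle_competition_f12(cse[1], cse[2], d$sample_times)
    expect_equal(sim$f12, f12_oracle, tolerance = 1e-4)
    expect_equal(sim$f12 + sim$f13, rep(1, nrow(sim)), tolerance = 1e-9)
  }
})

test_that("simulation limits behave as the model demands", {
  # fully reversible: late release approaches 50/50
  p0 <- adsorption_params(k_off = 0.02, E_i = 0)
  d_long <- competition_design(sample_times = seq(500, 3000, 500))
  s0 <- simulate_competition(p0, d_long)
  expect_lt(abs(s0$f12[6] / s0$f13[6] - 1), 1e-4)
  # fully irreversible: labeled substrate never sees enzyme
  p1 <- adsorption_params(k_off = 0.02, E_i = 1)
  s1 <- simulate_competition(p1, competition_design())
  expect_true(all(s1$f13 == 0))
  # E_i = 0.54: limiting ratio 1.54/0.46
  p54 <- adsorption_params(k_off = 0.01, E_i = 0.54)
  s54 <- simulate_competition(p54, competition_design(sample_times = c(4500, 5000)))
  expect_equal(s54$f12[2] / s54$f13[2], 1.54 / 0.46, tolerance = 1e-4)
  # f12 non-increasing toward steady state
  s <- simulate_competition(adsorption_params(0.01, 0.19), competition_design())
  expect_true(all(diff(s$f12) <= 0))
  # simulate at t = 50/k_off reproduces the analytic limit
  k <- 0.01
  sl <- simulate_competition(adsorption_params(k, 0.3),
                             competition_design(sample_times = c(0.9, 1) * 50 / k))
  expect_equal(sl$f12[2] / sl$f13[2], steady_state_ratio(0.3), tolerance = 1e-4)
})

test_that("enzyme is conserved along the ODE solution", {
  p <- adsorption_params(k_off = 0.01, E_i = 0.3)
  d <- competition_design()
  sol <- fibrildyn:::competition_solve(p, d, d$sample_times)
  total <- sol$R12 + sol$R13 + p$E_i * d$E_total
  free <- d$E_total - total
  expect_true(all(abs(total + free - d$E_total) < 1e-9 * d$E_total))
  expect_true(all(free > -1e-12))
})

test_that("constructor invariants are enforced", {
  expect_error(adsorption_params(-0.1, 0.5), "non-negative")
  expect_error(adsorption_params(0.1, 1.2), "E_i")
  expect_error(competition_design(S12_0 = 0), "substrate")
  expect_error(competition_design(sample_times = c(10, 10, 20)), "increasing")
  expect_error(competition_design(fit_window = c(800, 900)), "overlap")
})

test_that("noise-free fits recover the generating parameters", {
  d <- competition_design()
  for (truth in list(c(0.01, 0.19), c(0.005, 0.54))) {
    s <- simulate_competition(adsorption_params(truth[1], truth[2]), d)
    fit <- fit_competition(s, d)
    expect_true(fit$converged)
    expect_equal(unname(fit$estimates["k_off"]), truth[1], tolerance = 1e-3)
    expect_lt(abs(fit$estimates["E_i"] - truth[2]), 1e-3)
    expect_true(fit$k_off_identifiable)
    # CIs contain the point estimates
    expect_true(all(fit$conf_int[, 1] <= fit$estimates + 1e-12))
    expect_true(all(fit$conf_int[, 2] >= fit$estimates - 1e-12))
  }
})

test_that("an already-equilibrated series flags k_off as unidentifiable", {
  d <- competition_design()
  flat <- data.frame(time = d$sample_times, f12 = 0.5, f13 = 0.5)
  fit <- fit_competition(flat, d)
  expect_lt(fit$estimates["E_i"], 0.02)
  expect_false(fit$k_off_identifiable)
})

test_that("fitting demands enough usable samples", {
  d <- competition_design(sample_times = c(30, 60, 90))
  s <- data.frame(time = c(30, 60, 90), f12 = c(0.9, 0.8, 0.7))
  expect_error(fit_competition(s, d), "at least 4")
})

test_that("noisy replicates recover E_i without gross bias", {
  d <- competition_design(noise_sd = 0.03)
  est <- vapply(1:6, function(i) {
    g <- gen_competition_data(adsorption_params(0.01, 0.19), d, seed = i)
    unname(fit_competition(g$series, d)$estimates["E_i"])
  }, numeric(1))
  expect_lt(abs(mean(est) - 0.19), 0.05)
})

test_that("synthetic competition data are reproducible and validated", {
  d <- competition_design(noise_sd = 0.03)
  p <- adsorption_params(0.01, 0.19)
  a <- gen_competition_data(p, d, seed = 42)
  b <- gen_competition_data(p, d, seed = 42)
  expect_identical(a$series, b$series)
  expect_identical(a$truth, p)
  expect_equal(a$series$f12 + a$series$f13, rep(1, nrow(a$series)))
  d$noise_sd <- 0
  expect_identical(gen_competition_data(p, d, seed = 1)$series,
                   simulate_competition(p, d))
  d$noise_sd <- 0.6
  expect_error(gen_competition_data(p, d, seed = 1), "noise_sd")
})
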