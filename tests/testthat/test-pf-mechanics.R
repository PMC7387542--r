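test_that("zero-temperature equilibrium chain is stationary and at zero strain", {
  ch <- pf_chain(16)
  cfg <- sim_config(duration = 2e-9, temperature = 0, record_stride = 200,
                    seed = 1)
  run <- simulate_single_pf(ch, cfg = cfg)
  expect_lt(max(abs(run$state$pf[[1]] - ch$pf[[1]])), 1e-12)
  # mobile part carries no strain: bonds at well depth, hinges at theta0
  e <- total_energy(ch)
  expect_equal(e$spring, 0, tolerance = 1e-20)
  expect_equal(e$longitudinal, 7 * -interaction_params()$b_long)
  # only the restrained bottom intra-dimer hinge is strained
  expect_equal(e$bend, bending_energy(0), tolerance = 1e-10)
})

test_that("zero-temperature relaxation descends to the analytic equilibrium", {
  ch <- pf_chain(12)
  pert <- ch
  pert$pf[[1]][5:12, 1] <- pert$pf[[1]][5:12, 1] + 0.4
  pert$pf[[1]][5:12, 3] <- pert$pf[[1]][5:12, 3] - 0.1
  e0 <- total_energy(pert)$total
  run <- relax_state(pert, max_steps = 6e6)
  e1 <- total_energy(run$state)$total
  expect_true(run$converged)
  expect_lt(e1, e0)
  expect_equal(e1, total_energy(ch)$total, tolerance = 1e-6)
  th <- diff(run$state$pf[[1]][3:12, 3])
  expect_equal(unname(th), rep(0.2, 9), tolerance = 1e-3)
})

test_that("hysteresis passage counting matches constructed signals", {
  crit <- straightening_criteria()
  # constant at the equilibrium angle: no events
  expect_equal(straightening_frequency(rep(0.2, 100), crit, duration = 1), 0)
  # 10 Hz square wave between 0.2 and 0.0 over 1 s: 10 complete passages
  sq <- rep(c(0.2, 0), 10)
  expect_equal(straightening_frequency(sq, crit, duration = 1), 10)
  # dither around one threshold must not count
  dith <- 0.05 + 0.02 * rep(c(-1, 1), 50)
  expect_equal(straightening_frequency(dith, crit, duration = 1), 0)
  expect_error(straightening_frequency(numeric(0), crit, duration = 1),
               "empty")
})

test_that("single free hinge satisfies equipartition: Var(theta) = kBT/B", {
  ch <- pf_chain(4)  # bottom dimer fixed, one free dimer
  cfg <- sim_config(duration = 4e-7, record_stride = 20, seed = 31)
  run <- simulate_single_pf(ch, cfg = cfg,
                            criteria = straightening_criteria(monitored_index = 3))
  th <- run$trace$theta_mon
  th <- th[-seq_len(1000)]  # burn-in
  expect_equal(sd(th), sqrt(kBT(310) / 174), tolerance = 0.05)
  expect_equal(mean(th), 0.2, tolerance = 0.1)
})

test_that("trajectories are bit-identical under the same seed and differ otherwise", {
  ch <- pf_chain(8)
  cfg <- sim_config(duration = 2e-8, record_stride = 100, seed = 77)
  r1 <- simulate_single_pf(ch, cfg = cfg)
  r2 <- simulate_single_pf(ch, cfg = cfg)
  expect_identical(r1$state$pf[[1]], r2$state$pf[[1]])
  cfg$seed <- 78
  r3 <- simulate_single_pf(ch, cfg = cfg)
  expect_false(identical(r1$state$pf[[1]], r3$state$pf[[1]]))
})

test_that("persistence-length estimator matches the independent hinge-chain oracle", {
  # chain of hinges with iid normal deflections, variance s2, spacing l:
  # <cos(delta(s) - delta(0))> = exp(-m s2 / 2) => xi_d = 2 l / s2
  set.seed(5)
  s2 <- 0.01; l <- 4
  dev <- matrix(rnorm(800 * 12, sd = sqrt(s2)), 800, 12)
  tau <- t(apply(dev, 1, cumsum))
  xi <- dynamic_persistence_length(tau, spacing = l)
  expect_equal(xi, 2 * l / s2, tolerance = 0.1)
  # noise-free trajectory: infinite persistence length
  expect_identical(dynamic_persistence_length(matrix(0.2, 200, 8),
                                              spacing = 4), Inf)
  expect_error(dynamic_persistence_length(matrix(0, 50, 8)), ">= 100")
})

test_that("a floppy chain sustains essentially no force", {
  f <- max_sustainable_force(mechanical_params(B = 0.01), f_max = 10)
  expect_lt(f, 0.5)
})
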