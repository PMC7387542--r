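test_that("total lattice energy matches an independent closed-form sum", {
  nd <- 5
  st <- mt_state(nd, "GTP", window_dimers = 3)
  mech <- mechanical_params()
  inter <- interaction_params(b_lat = 8, b_long = 7)
  e <- total_energy(st, mech, inter)
  ref <- straight_lattice_energy(nd, b_lat = 8, b_long = 7)
  expect_equal(e$lateral, ref$lateral, tolerance = 1e-10)
  expect_equal(e$longitudinal, ref$longitudinal, tolerance = 1e-10)
  expect_equal(e$bend, ref$bend, tolerance = 1e-10)
  expect_equal(e$spring, 0, tolerance = 1e-20)
  expect_equal(e$total, ref$total, tolerance = 1e-10)

  # empty state
  empty <- mtdyn:::.new_mt_state(list(), list(), integer(), n_pf = 0L)
  expect_equal(total_energy(empty)$total, 0)

  # invariance under rigid axial translation
  st2 <- st
  st2$pf <- lapply(st2$pf, function(m) { m[, 2] <- m[, 2] + 37.5; m })
  expect_equal(total_energy(st2, mech, inter)$total, e$total,
               tolerance = 1e-10)
})

test_that("nucleotide effect selects per-dimer lateral depth and stiffness", {
  nd <- 4
  ne <- nucleotide_effect("lateral-bond")  # b_lat 8 / 4.7
  gtp <- mt_state(nd, "GTP", window_dimers = 2)
  gdp <- mt_state(nd, "GDP", window_dimers = 2)
  inter <- interaction_params()
  e_gtp <- total_energy(gtp, inter = inter, nuc_effect = ne)
  e_gdp <- total_energy(gdp, inter = inter, nuc_effect = ne)
  expect_equal(e_gtp$lateral, 13 * 2 * nd * -8, tolerance = 1e-10)
  expect_equal(e_gdp$lateral, 13 * 2 * nd * -4.7, tolerance = 1e-10)
})

test_that("a free monomer diffuses with variance 2 kBT dt / gamma per coordinate", {
  st <- mtdyn:::.new_mt_state(list(cbind(x = 0, z = 0, tau = 0)),
                              list(1L), 0L, 1L, lateral = FALSE)
  cfg <- sim_config(duration = 3e-8, record_stride = 1, seed = 42)
  run <- mtdyn:::.run(st, mechanical_params(), interaction_params(),
                      cfg = cfg)
  dz <- diff(run$trace$tip_z)
  v_exp <- 2 * kBT(310) * cfg$dt / mtdyn:::.gamma_q(1e-3, 2)
  expect_equal(var(dz), v_exp, tolerance = 0.03)
})

test_that("kinetic step: addition probability arithmetic and placement geometry", {
  kin <- kinetic_params(k_on = 0.26, c_tub = 10, t_kin = 0.013)
  expect_equal(kin$k_on * kin$c_tub * kin$t_kin, 0.0338)
  # no additions at zero concentration
  set.seed(1)
  st <- mt_state(3, "GTP", n_pf = 13)
  ks <- kinetic_step(st, kinetic_params(c_tub = 0, k_hydr = 0))
  expect_equal(nrow(ks$events), 0)
  expect_equal(nrow(ks$state$pf[[1]]), 6)
  # nucleotide composition conserved without hydrolysis
  st2 <- init_capped_mt(10, cap_dimers = 40, seed = 2)
  n0 <- sum(vapply(st2$nuc, sum, 1L))
  set.seed(2)
  ks2 <- kinetic_step(st2, kinetic_params(c_tub = 0, k_hydr = 0))
  expect_equal(sum(vapply(ks2$state$nuc, sum, 1L)), n0)
  # forced addition continues the tip tangent with unstretched bonds
  set.seed(3)
  one <- pf_chain(6)
  ks3 <- kinetic_step(one, kinetic_params(k_on = 76.9, c_tub = 1, k_hydr = 0))
  m <- ks3$state$pf[[1]]
  expect_equal(nrow(m), 8)
  expect_equal(diff(m[6:8, "tau"]), c(0.2, 0.2), tolerance = 1e-12)
  e <- total_energy(ks3$state)
  expect_equal(e$spring, 0, tolerance = 1e-18)
  # event counts follow the binomial expectation
  set.seed(4)
  kin5 <- kinetic_params(k_on = 0.26, c_tub = 40, k_hydr = 0)  # P = 0.1352
  n_add <- sum(replicate(300, nrow(kinetic_step(st, kin5)$events)))
  expect_equal(n_add / (300 * 13), 0.1352, tolerance = 0.15)
})

test_that("detachment removes terminal oligomers past the threshold", {
  inter <- interaction_params(b_long = 7, r_long = 0.5)
  st <- mt_state(6, "GDP", window_dimers = 4, n_pf = 13)
  # intact lattice: nothing to remove
  d0 <- detach_oligomers(st, inter)
  expect_equal(nrow(d0$events), 0)
  # displace the terminal dimer of PF 4 far beyond the barrier
  st1 <- st
  st1$pf[[4]][11:12, 1] <- st1$pf[[4]][11:12, 1] + 30
  d1 <- detach_oligomers(st1, inter)
  expect_equal(d1$events$pf, 4)
  expect_equal(d1$events$size, 1)
  expect_equal(nrow(d1$state$pf[[4]]), 10)
  # a 3-dimer curl whose basal bond is broken goes as one oligomer
  st2 <- st
  st2$pf[[7]][7:12, 1] <- st2$pf[[7]][7:12, 1] + 30
  d2 <- detach_oligomers(st2, inter)
  expect_equal(d2$events$size, 3)
  expect_equal(nrow(d2$state$pf[[7]]), 6)
  # a stretched-but-bound bond (inside the barrier) is not detached
  st3 <- st
  st3$pf[[2]][11:12, 1] <- st3$pf[[2]][11:12, 1] + 0.6  # r < 2 r_long
  expect_equal(nrow(detach_oligomers(st3, inter)$events), 0)
})

test_that("capped initialisation: count, profile and pure-GDP limit", {
  expect_equal(sum(vapply(init_capped_mt(20, cap_dimers = 0)$nuc, sum, 1L)),
               0)
  counts <- vapply(1:60, function(s) {
    sum(vapply(init_capped_mt(30, cap_dimers = 120, cap_length = 110,
                              seed = s)$nuc, sum, 1L))
  }, 1L)
  expect_lt(abs(mean(counts) - 120), 3 * sqrt(120))
  # GTP fraction non-increasing with distance from the plus end
  prof <- Reduce(`+`, lapply(1:40, function(s) {
    Reduce(`+`, init_capped_mt(30, cap_dimers = 120, seed = s)$nuc)
  }))
  frac <- rev(prof)  # index 1 = plus end
  half <- length(frac) / 2
  expect_gt(mean(frac[1:half]), mean(frac[(half + 1):length(frac)]))
  expect_error(init_capped_mt(4, cap_dimers = 1000), "cap larger")
})

test_that("one-PF lattice stepping reproduces the single-PF path exactly", {
  ch <- pf_chain(10)
  cfg <- sim_config(duration = 4e-9, record_stride = 2000, seed = 9)
  a <- simulate_single_pf(ch, cfg = cfg)
  b <- mtdyn:::.run(ch, mechanical_params(), interaction_params(),
                    cfg = cfg)
  expect_identical(a$state$pf[[1]], b$state$pf[[1]])
})

test_that("T = 0 lattice relaxation is monotone non-increasing in energy", {
  st <- mt_state(4, "GTP", window_dimers = 2)
  st$pf[[3]][7:8, 1] <- st$pf[[3]][7:8, 1] + 0.8
  mech <- mechanical_params()
  inter <- interaction_params()
  cfg <- sim_config(temperature = 0, record_stride = 0, snap_stride = 0)
  e <- total_energy(st, mech, inter)$total
  cur <- st
  for (i in 1:5) {
    cur <- brownian_substep(cur, mech, inter, cfg, n_steps = 400)
    e2 <- total_energy(cur, mech, inter)$total
    expect_lte(e2, e + 1e-9)
    e <- e2
  }
})

test_that("subunit bookkeeping: event log replays to the final counts", {
  dp <- desk_params("shortening")
  st <- mt_state(14, "GDP", window_dimers = dp$kin$window_dimers)
  cfg <- sim_config(dt = dp$dt, duration = 4e-6, record_stride = 1e5,
                    seed = 21)
  run <- run_mt(st, dp$mech, dp$inter, NULL, dp$kin, "constant", cfg = cfg)
  lost <- sum(run$events$value[run$events$type == "detachment"])
  added <- sum(run$events$type == "addition")
  k0 <- sum(vapply(st$pf, nrow, 1L))
  k1 <- sum(vapply(run$state$pf, nrow, 1L))
  expect_equal(k1, k0 + 2 * added - 2 * lost)
})

test_that("rate measurement: slope recovery and degenerate inputs", {
  tr <- data.frame(t = seq(0, 1, by = 0.01), length = 20 * seq(0, 1, by = 0.01))
  expect_equal(measure_rate(tr), 20)
  expect_equal(measure_rate(data.frame(t = 0:10, length = rep(5, 11))), 0)
  # noisy shortening trace: unbiased slope across draws
  set.seed(8)
  sl <- replicate(60, {
    t <- seq(0, 0.5, by = 0.01)
    measure_rate(data.frame(t = t, length = -400 * t + rnorm(length(t), 0, 5)),
                 burn_in = 0.05)
  })
  expect_equal(mean(sl), -400, tolerance = 0.01)
  expect_error(measure_rate(tr, burn_in = 2), "exceed")
})
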