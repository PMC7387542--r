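test_that("stall interpolation finds the zero crossing or reports unbracketed", {
  fv <- data.frame(force = c(0, 2, 4), velocity = c(-300, -80, 120))
  st <- stall_from_table(fv)
  expect_true(st$bracketed)
  expect_equal(st$stall, 2 + 80 / 200 * 2)
  un <- stall_from_table(data.frame(force = c(0, 2), velocity = c(-5, -1)))
  expect_false(un$bracketed)
  expect_true(is.na(un$stall))
  ex <- stall_from_table(data.frame(force = c(1, 3), velocity = c(-2, 0)))
  expect_equal(ex$stall, 3)
})

test_that("ring placement sits below the lowest curl origin at wall contact", {
  st <- mt_state(10, "GDP", window_dimers = 6)
  coup <- dam1_ring_coupler(st, ring_params(), force = 1.5, offset = 16)
  expect_equal(length(coup$z), 13)
  tipz <- max(st$pf[[1]][, 2])
  expect_equal(coup$z[1], tipz - 16)   # blunt state: origin = tip
  expect_equal(coup$x[1], 5)           # R_dam1 + r_tub contact
  expect_equal(mtdyn:::.to_pN(coup$F), 1.5)
})

test_that("symmetric ring under zero noise stays symmetric", {
  dp <- desk_params("shortening")
  st <- mt_state(10, "GDP", window_dimers = 6)
  coup <- dam1_ring_coupler(st, ring_params(), force = 2)
  cfg <- sim_config(dt = dp$dt, temperature = 0, duration = 4e-9,
                    record_stride = 500, seed = 3)
  run <- mtdyn:::.run(st, dp$mech, dp$inter, kin = NULL, coupler = coup,
                      cfg = cfg)
  expect_lt(diff(range(run$ring_z)), 1e-9)
  expect_lt(diff(range(run$ring_x)), 1e-9)
})

test_that("a huge load pulls the ring off a blunt tip (ring lost event)", {
  dp <- desk_params("shortening")
  st <- mt_state(8, "GDP", window_dimers = 4)
  coup <- dam1_ring_coupler(st, ring_params(), force = 300, offset = 5)
  cfg <- sim_config(dt = dp$dt, duration = 3e-6, record_stride = 1e5,
                    seed = 13)
  kin <- kinetic_params(c_tub = 0, k_hydr = 0, window_dimers = 4)
  run <- run_mt(st, dp$mech,
                interaction_params(a_lat = 6.3, b_lat = 8, r_lat = 1,
                                   b_long = 7, r_long = 0.5),
                NULL, kin, "constant", coupler = coup, cfg = cfg)
  expect_true(run$ring_lost)
  expect_true("ring_lost" %in% run$events$type)
})

test_that("obstacle blocks additions that would overlap it", {
  dp <- desk_params("growth", c_tub = 40, compression = 2e4)
  st <- mt_state(8, "GTP", window_dimers = 4)
  coup <- obstacle_coupler(st, force = 2, gap = 0.2)
  # pin the obstacle by zeroing temperature: blunt tip right under the
  # sphere; every insertion site overlaps it
  cfg <- sim_config(dt = dp$dt, temperature = 0, duration = 0.12,
                    record_stride = 1e5, seed = 5)
  run <- run_mt(st, dp$mech, dp$inter, NULL, dp$kin, "constant",
                coupler = coup, cfg = cfg)
  expect_equal(sum(run$events$type == "addition"), 0)
  # without the obstacle, the same protocol adds dimers
  run2 <- run_mt(st, dp$mech, dp$inter, NULL, dp$kin, "constant",
                 cfg = cfg)
  expect_gt(sum(run2$events$type == "addition"), 5)
})
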