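test_that("spring, bending and repulsion energies match closed forms", {
  mech <- mechanical_params()  # k = 310, B = 174, theta0 = 0.2
  expect_identical(spring_energy(0, mech), 0)
  expect_equal(spring_energy(0.1, mech), 1.55)
  expect_error(spring_energy(-0.1, mech), "must be >= 0")

  expect_identical(bending_energy(0.2, mech), 0)
  expect_equal(bending_energy(0.3, mech), 0.87)
  # symmetry about theta0
  x <- seq(0.01, 0.5, by = 0.07)
  expect_equal(bending_energy(0.2 + x, mech), bending_energy(0.2 - x, mech))

  # repulsion: no 1/2 prefactor, continuous at contact, zero far away
  expect_identical(repulsion_energy(5, R = 3, r = 2), 0)
  expect_equal(repulsion_energy(4.9, R = 3, r = 2, k_rep = 100), 1.0)
  expect_identical(repulsion_energy(50, R = 3, r = 2), 0)
  eps <- 1e-9
  expect_lt(repulsion_energy(5 - eps, R = 3, r = 2), 1e-12)
})

test_that("breakable bond has depth -b at contact and an a-scaled barrier", {
  expect_equal(bond_energy(0, a = 6.3, b = 8), -8)
  expect_equal(bond_energy(0, a = 0, b = 3.3), -3.3)
  # decays to zero
  expect_lt(abs(bond_energy(30, a = 6.3, b = 8, w = 1)), 1e-8)
  # with b = 0 the maximum is 8 exp(-2) a at r = 2w (analytic)
  for (w in c(0.3, 0.8, 1.2)) {
    bar <- bond_barrier(a = 5, b = 0, w = w)
    expect_equal(bar$height, 8 * exp(-2) * 5, tolerance = 1e-6)
    expect_equal(bar$at, 2 * w, tolerance = 1e-3)
  }
  # full-expression barrier from the dense-grid oracle
  grid <- seq(1e-4, 5, length.out = 40001)
  oracle <- max(bond_energy(grid, a = 6.3, b = 8, w = 0.5))
  expect_equal(bond_barrier(6.3, 8, 0.5)$height, oracle, tolerance = 1e-6)
  # barrier height is monotone increasing in a at fixed b, w
  h <- vapply(c(1, 2, 4, 6.3, 9), function(a) bond_barrier(a, 4, 0.8)$height, 1)
  expect_true(all(diff(h) > 0))
  expect_error(bond_energy(1, 1, 1, w = 0), "w must be > 0")
})

test_that("linker potential is a flat well with harmonic rise, continuous at l_max", {
  rp <- ring_params()  # l0 = 5, l_max = 6, k = 0.01
  expect_equal(rp$E_depth, 0.5 * 0.01 * 1^2)
  expect_equal(linker_energy(rp$l_max, rp), 0)           # continuity by E_depth
  expect_equal(linker_energy(rp$l0, rp), -rp$E_depth)    # harmonic term vanishes
  expect_equal(linker_energy(4.9, rp), -rp$E_depth)      # flat well
  expect_identical(linker_energy(6.5, rp), 0)
  # continuity at l_max for arbitrary valid parameters
  for (kl in c(0.01, 0.5, 2)) {
    rpx <- ring_params(l0 = 4.2, l_max = 7.1, k_linker = kl)
    eps <- 1e-8
    expect_lt(abs(linker_energy(7.1 - eps, rpx) - linker_energy(7.1 + eps, rpx)),
              1e-6)
  }
  expect_error(ring_params(l0 = 6, l_max = 5), "l0 must be < l_max")
})

test_that("analytic gradients match centered finite differences on a grid", {
  mech <- mechanical_params()
  for (d in c(0.05, 0.3, 1.2)) {
    expect_equal(spring_energy_grad(d, mech),
                 fd_grad(function(x) spring_energy(x, mech), d),
                 tolerance = 1e-6)
  }
  for (th in c(-0.1, 0.18, 0.4)) {
    expect_equal(bending_energy_grad(th, mech),
                 fd_grad(function(x) bending_energy(x, mech), th),
                 tolerance = 1e-6)
  }
  for (d in c(3.2, 4.4, 4.9)) {  # inside contact of R+r = 5
    expect_equal(repulsion_energy_grad(d),
                 fd_grad(function(x) repulsion_energy(x), d),
                 tolerance = 1e-6)
  }
  for (a in c(0, 2.1, 6.3)) for (b in c(0, 4.7, 8)) for (w in c(0.3, 1)) {
    for (d in c(0.1, 0.5 * w, 2 * w, 4 * w)) {
      g <- bond_energy_grad(d, a, b, w)
      expect_equal(g, fd_grad(function(x) bond_energy(x, a, b, w), d),
                   tolerance = 1e-6 * max(1, abs(g)))
    }
  }
  rp <- ring_params(k_linker = 0.8)
  for (d in c(5.3, 5.8)) {  # inside the harmonic rise
    expect_equal(linker_energy_grad(d, rp),
                 fd_grad(function(x) linker_energy(x, rp), d),
                 tolerance = 1e-6)
  }
})

test_that("parameter invariants are enforced", {
  expect_error(mechanical_params(theta0 = 2), "theta0")
  expect_error(mechanical_params(r_tub = 0), "r_tub")
  expect_error(interaction_params(b_lat = -1), "depths")
  expect_error(kinetic_params(k_on = 10, c_tub = 100, t_kin = 0.013),
               "exceeds 1")
  expect_error(nucleotide_effect("lateral-bond", B_gtp = 78, B_gdp = 174),
               "B_gtp must equal")
  expect_error(nucleotide_effect("bending-stiffness", b_lat_gtp = 1,
                                 b_lat_gdp = 2), "b_lat_gtp must equal")
})
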