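test_that("pair potential is truncated-and-shifted 12-6 LJ", {
  ff <- lj_force_field(cutoff = 2.5)
  # shift makes the potential vanish at the cutoff exactly
  expect_identical(pair_energy(2.5, ff), 0)
  expect_identical(pair_energy(3.7, ff), 0)
  # value at the minimum: -1 - U_LJ(2.5), with U_LJ(2.5) = 4*(2.5^-12 - 2.5^-6)
  u_rc <- 4 * (2.5^-12 - 2.5^-6)
  expect_equal(pair_energy(2^(1 / 6), ff), -1 - u_rc, tolerance = 1e-12)
  expect_equal(pair_energy(2^(1 / 6), ff), -0.9836831088, tolerance = 1e-9)
  # cutoff at the minimum: purely repulsive fluid, shift cancels the well
  ffw <- wca_ff()
  expect_equal(pair_energy(2^(1 / 6), ffw), 0, tolerance = 1e-15)
  expect_gt(pair_energy(1.0, ffw), 0)
  # approach to the cutoff from below is continuous
  expect_lt(abs(pair_energy(2^(1 / 6) - 1e-8, ffw)), 1e-6)
  expect_error(pair_energy(0, ffw), "overlap")
})

test_that("mixture force field applies per-pair epsilon", {
  ff <- binary_mixture_force_field()
  expect_equal(ff$epsilon["A", "B"], 1.1)
  r <- 1.05
  uAA <- pair_energy(r, ff, "A", "A")
  uBB <- pair_energy(r, ff, "B", "B")
  uAB <- pair_energy(r, ff, "A", "B")
  expect_equal(uAB, (uAA + uBB) / 2, tolerance = 1e-12)
})

test_that("cell-list forces equal brute-force minimum-image forces", {
  ff <- lj_force_field(cutoff = 2.5)
  cfg <- lattice_configuration(100, 0.6, seed = 31, jitter = 0.3)
  sidx <- match(cfg$species, ff$species) - 1L
  fb <- blockfluct:::cpp_forces(cfg$positions, sidx, cfg$box_edge,
                                ff$epsilon, ff$sigma, ff$cutoff, "brute")
  fc <- blockfluct:::cpp_forces(cfg$positions, sidx, cfg$box_edge,
                                ff$epsilon, ff$sigma, ff$cutoff, "cell")
  expect_lt(max(abs(fb$forces - fc$forces)), 1e-10)
  expect_equal(fb$potential_energy, fc$potential_energy, tolerance = 1e-12)
  expect_equal(fb$virial, fc$virial, tolerance = 1e-12)
})

test_that("velocity Verlet conserves energy with the thermostat off", {
  cfg <- lattice_configuration(125, 0.7, seed = 32)
  prot <- simulation_protocol(
    temperature = 1.0, friction = 0,
    n_equilibration_steps = 0L, n_production_steps = 1000L,
    frame_stride = 20L, seed = 33
  )
  tr <- run_nvt(cfg, wca_ff(), prot)
  e <- tr$energies$potential + tr$energies$kinetic
  expect_lt((max(e) - min(e)) / tr$n_particles, 1e-4)
})

test_that("Langevin thermostat holds the kinetic temperature", {
  tr <- small_wca_trajectory()
  expect_equal(kinetic_temperature(tr), 1.2, tolerance = 0.02)
})

test_that("trajectories are bit-identical for identical seeds", {
  cfg <- lattice_configuration(64, 0.5, seed = 34)
  prot <- simulation_protocol(temperature = 1.0, friction = 1,
                              n_equilibration_steps = 100L,
                              n_production_steps = 500L,
                              frame_stride = 100L, seed = 35)
  t1 <- run_nvt(cfg, wca_ff(), prot)
  t2 <- run_nvt(cfg, wca_ff(), prot)
  expect_identical(t1$frames[[5]]$positions, t2$frames[[5]]$positions)
  prot2 <- simulation_protocol(temperature = 1.0, friction = 1,
                               n_equilibration_steps = 100L,
                               n_production_steps = 500L,
                               frame_stride = 100L, seed = 36)
  t3 <- run_nvt(cfg, wca_ff(), prot2)
  expect_false(identical(t1$frames[[5]]$positions, t3$frames[[5]]$positions))
})

test_that("virial pressure matches a hand-summed pair virial", {
  # ideal gas: no pair interactions, P = rho kT exactly
  ff0 <- lj_force_field(epsilon = 0, sigma = 1, cutoff = 2^(1 / 6))
  cfg <- generate_ideal_gas(500, box_edge = 10, seed = 41)
  expect_equal(virial_pressure(cfg, ff0, temperature = 1.2),
               0.5 * 1.2, tolerance = 1e-12)

  # three particles with printed coordinates: brute-force pair virial
  pos <- rbind(c(1.0, 1.0, 1.0), c(2.0, 1.0, 1.0), c(1.0, 1.9, 1.0))
  cfg3 <- configuration(pos, box_edge = 8, frame_index = 0)
  ff <- lj_force_field(cutoff = 2.5)
  w <- 0
  for (p in list(c(1, 2), c(1, 3), c(2, 3))) {
    d <- pos[p[1], ] - pos[p[2], ]
    r <- sqrt(sum(d^2))
    if (r < 2.5) {
      sr6 <- r^-6
      w <- w + 24 * (2 * sr6^2 - sr6)   # r * |F(r)|, sign per 12-6 form
    }
  }
  p_hand <- 3 / 8^3 * 1.2 + w / (3 * 8^3)
  expect_equal(virial_pressure(cfg3, ff, temperature = 1.2), p_hand,
               tolerance = 1e-12)

  # dense purely repulsive fluid: positive virial, P > rho kT
  tr <- small_wca_trajectory()
  p <- virial_pressure(tr$frames[[50]], wca_ff(), 1.2)
  expect_gt(p, 0.864 * 1.2)
})

test_that("density tuning inverts the ideal-gas equation of state", {
  ff0 <- lj_force_field(epsilon = 0, sigma = 1, cutoff = 2^(1 / 6))
  rho <- tune_density_to_pressure(ff0, temperature = 1.2,
                                  target_pressure = 0.6,
                                  tolerance = 0.01,
                                  bracket = c(0.1, 1.0),
                                  n_particles = 200L, n_steps = 500L,
                                  seed = 51)
  expect_equal(as.numeric(rho), 0.5, tolerance = 0.02)
  expect_error(
    tune_density_to_pressure(ff0, 1.2, 0.6, tolerance = 0, seed = 51),
    "tolerance"
  )
  expect_error(
    tune_density_to_pressure(ff0, 1.2, 50, tolerance = 0.01,
                             bracket = c(0.1, 0.2), n_particles = 100L,
                             n_steps = 200L, seed = 52),
    "not bracketed"
  )
})

test_that("pair correlations of the dense repulsive fluid decay within a few sigma", {
  tr <- small_wca_trajectory()
  g <- radial_distribution(tr, r_max = 3.5, dr = 0.1)
  tail_region <- g$g[g$r > 2.5]
  expect_lt(max(abs(tail_region - 1)), 0.15)
  # strong structure at contact, unlike the far field
  expect_gt(max(g$g), 1.5)
})
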