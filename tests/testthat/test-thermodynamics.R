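test_that("compressibility conversions evaluate the stated relations", {
  # ideal gas: chi_inf = 1 recovers kappa_IG = 1/(rho kT)
  expect_equal(kappa_from_chi(1, rho = 0.5, kT = 1.2), 1 / 0.6,
               tolerance = 1e-12)
  # the reference fluid: chi_inf = 0.0295 at rho = 0.864, kBT = 1.2
  expect_equal(kappa_from_chi(0.0295, 0.864, 1.2), 0.0295 / (0.864 * 1.2),
               tolerance = 1e-12)
  expect_identical(kappa_from_chi(0, 1, 1), 0)
  expect_error(kappa_from_chi(1, -1, 1), "rho")

  # mixture with vanishing KBIs: ideal gas at total density
  expect_equal(kappa_from_kbi(0, 0, 0, 0.3, 0.2, 1.2),
               1 / (1.2 * 0.5), tolerance = 1e-12)
  # pure-A limit equals the single-component relation via
  # chi_inf = 1 + rho_A G_AA
  G <- -0.9; rhoA <- 0.8; kT <- 1.2
  expect_equal(kappa_from_kbi(G, 0.1, 0.05, rhoA, 0, kT),
               (1 + rhoA * G) / (kT * rhoA), tolerance = 1e-12)
  expect_equal(kappa_from_kbi(G, 0.1, 0.05, rhoA, 0, kT),
               kappa_from_chi(1 + rhoA * G, rhoA, kT), tolerance = 1e-12)
})

test_that("chemical-potential derivative follows the KBI expression", {
  # ideal: kT/rhoA
  expect_equal(dmuA_drhoA(0, 0, 0.4, 1.2), 3, tolerance = 1e-12)
  # only the difference G_AB - G_AA matters
  expect_equal(dmuA_drhoA(0.7, 0.7, 0.4, 1.2), 3, tolerance = 1e-12)
  # direct arithmetic: kT*(1/rhoA + 0.5/(1 - 0.2))
  expect_equal(dmuA_drhoA(G_AA = -0.25, G_AB = 0.25, rho_A = 0.4, kT = 1.2),
               1.2 * (2.5 + 0.5 / 0.8), tolerance = 1e-12)
  expect_equal(dmuA_drhoA(-0.25, 0.25, 0.4, 1.2), 3.75, tolerance = 1e-12)
  # 1 + rhoA*(G_AA - G_AB) = 0 marks a demixing instability
  expect_error(dmuA_drhoA(G_AA = -2.5, G_AB = 0, rho_A = 0.4, kT = 1),
               "pole|instab")
})

test_that("ideal-gas quadrature reproduces kT log(rho/rho0) to 1e-6", {
  kT <- 1.2
  tab <- ideal_kappa_table(kT = kT, n = 100L)
  mu <- integrate_mu(tab, reference_density = 0.6)
  expect_lt(max(abs(mu$delta_mu - kT * log(tab$rho / 0.6))), 1e-6)
  # exact zero at a tabulated reference point
  mu0 <- integrate_mu(tab, reference_density = tab$rho[50])
  expect_identical(mu0$delta_mu[50], 0)
  # excess curve is flat for the ideal gas
  ex <- excess_mu(mu)
  expect_lt(diff(range(ex$delta_mu_ex)), 1e-5)
})

test_that("mixture route with vanishing KBIs gives a flat excess curve", {
  kT <- 1.2
  rhoA <- seq(0.2, 0.8, length.out = 60)
  tab <- thermo_table(data.frame(xA = rep(0.5, 60), rho_A = rhoA,
                                 G_AA = 0, G_AB = 0), kT = kT)
  mu <- integrate_mu(tab, reference_density = rhoA[30])
  # with vanishing KBIs the derivative is the ideal kT/rhoA, so delta_mu
  # is kT*log(rhoA/rhoA0) and removing the ideal density/concentration
  # terms leaves a constant
  expect_lt(max(abs(mu$delta_mu - kT * log(rhoA / rhoA[30]))), 1e-6)
  ex <- excess_mu(mu)
  expect_lt(diff(range(ex$delta_mu_ex)), 1e-5)
})

test_that("quadrature converges under grid refinement", {
  kT <- 1.0
  rho <- seq(0.3, 0.9, length.out = 25)
  kap <- 1 / (rho * kT) * (1 + 0.3 * rho)   # smooth non-ideal table
  tab <- thermo_table(data.frame(rho = rho, kappa = kap), kT = kT)
  mu1 <- integrate_mu(tab, 0.6, refine = 32L)
  mu2 <- integrate_mu(tab, 0.6, refine = 64L)
  expect_lt(max(abs(mu1$delta_mu - mu2$delta_mu)), 1e-4)
})

test_that("excess curves anchor exactly through an external reference", {
  kT <- 1.2
  tab <- ideal_kappa_table(kT = kT, n = 50L)
  mu <- integrate_mu(tab, reference_density = 0.6)
  anchor_rho <- tab$rho[20]
  ex <- excess_mu(mu, reference_axis = anchor_rho, reference_mu = -2.75)
  expect_equal(ex$delta_mu_ex[20], -2.75, tolerance = 1e-12)
  expect_error(excess_mu(mu, reference_axis = anchor_rho),
               "reference_mu")
})

test_that("integration preconditions are enforced", {
  tab <- ideal_kappa_table(n = 20L)
  expect_error(integrate_mu(tab, reference_density = 5), "inside")
  bad <- data.frame(rho = c(0.2, 0.4, 0.6), kappa = c(1, -1, 1))
  tb <- thermo_table(bad, kT = 1)
  expect_error(integrate_mu(tb, 0.4), "positive")
  expect_error(thermo_table(data.frame(rho = c(0.4, 0.2), kappa = 1:2), 1),
               "increasing")
})

test_that("non-monotone compressibility scans raise a data-quality warning", {
  rho <- seq(0.2, 0.5, length.out = 10)
  kap <- 1 / rho
  tab_ok <- thermo_table(data.frame(rho = rho, kappa = kap), kT = 1.15)
  expect_silent(check_kappa_monotone(tab_ok))
  kap_cusp <- kap + 2 * exp(-((rho - 0.32) / 0.03)^2)   # near-critical bump
  tab_cusp <- thermo_table(data.frame(rho = rho, kappa = kap_cusp), kT = 1.15)
  expect_warning(check_kappa_monotone(tab_cusp), "monoton")
})
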