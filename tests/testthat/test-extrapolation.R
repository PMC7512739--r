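test_that("noiseless model curves are recovered exactly", {
  grid <- seq(0.04, 0.98, by = 0.02)
  # linear model (no 1/lambda term)
  sp1 <- synthetic_curve_spec(chi_inf = 0.0295, c1 = 0.415, c2 = 0,
                              L0 = 48.83, lambda_grid = grid)
  f1 <- fit_chi_linear(generate_synthetic_curve(sp1), window = c(0.04, 0.3))
  expect_equal(f1$parameters[["chi_inf"]], 0.0295, tolerance = 1e-7)
  expect_equal(f1$parameters[["c"]], 0.415, tolerance = 1e-7)

  # model with the 1/lambda boundary term
  sp2 <- synthetic_curve_spec(chi_inf = 0.8, c1 = 0.3, c2 = 5, L0 = 20,
                              lambda_grid = grid)
  f2 <- fit_chi_inverse(generate_synthetic_curve(sp2), window = c(0.04, 0.3))
  expect_equal(f2$parameters[["chi_inf"]], 0.8, tolerance = 1e-7)
  expect_equal(f2$parameters[["c1"]], 0.3, tolerance = 1e-7)
  expect_equal(f2$parameters[["b2"]], 5 / 20^2, tolerance = 1e-9)

  # ideal-gas curve: chi_inf = 1, no boundary constant
  spi <- synthetic_curve_spec(chi_inf = 1, c1 = 0, c2 = 0, L0 = 30,
                              lambda_grid = grid)
  fi <- fit_chi_linear(generate_synthetic_curve(spi), window = c(0.04, 0.3))
  expect_equal(fi$parameters[["chi_inf"]], 1, tolerance = 1e-9)
  expect_equal(fi$parameters[["c"]], 0, tolerance = 1e-9)
})

test_that("the linear fit is the b2 = 0 restriction of the inverse-term fit", {
  grid <- seq(0.05, 0.95, by = 0.03)
  sp <- synthetic_curve_spec(chi_inf = 0.2, c1 = 0.5, c2 = 0, L0 = 25,
                             noise_sd = 0.002, seed = 91,
                             lambda_grid = grid)
  cv <- generate_synthetic_curve(sp)
  fl <- fit_chi_linear(cv, window = c(0.05, 0.3))
  fb <- fit_chi_inverse(cv, window = c(0.05, 0.3))
  # same data, nested models: b2 compatible with zero and chi_inf agrees
  # within the enlarged uncertainty of the richer model
  expect_lt(abs(fb$parameters[["b2"]]), 3 * fb$stderr[["b2"]])
  expect_lt(abs(fb$parameters[["chi_inf"]] - fl$parameters[["chi_inf"]]),
            3 * fb$stderr[["chi_inf"]])

  # exact algebraic nesting on noiseless data
  sp0 <- synthetic_curve_spec(chi_inf = 0.2, c1 = 0.5, c2 = 0, L0 = 25,
                              lambda_grid = grid)
  cv0 <- generate_synthetic_curve(sp0)
  fl0 <- fit_chi_linear(cv0, window = c(0.05, 0.3))
  fb0 <- fit_chi_inverse(cv0, window = c(0.05, 0.3))
  expect_equal(fb0$parameters[["chi_inf"]], fl0$parameters[["chi_inf"]],
               tolerance = 1e-6)
  expect_equal(fb0$parameters[["b2"]], 0, tolerance = 1e-9)
})

test_that("synthetic near-critical curves need the 1/lambda term", {
  grid <- seq(0.05, 0.5, by = 0.015)
  # a curve with a material 1/lambda contribution (long correlation length)
  sp_crit <- synthetic_curve_spec(chi_inf = 2.5, c1 = -1.2, c2 = 30,
                                  L0 = 43, noise_sd = 1e-3, seed = 92,
                                  lambda_grid = grid)
  cv <- generate_synthetic_curve(sp_crit)
  fb <- fit_chi_inverse(cv, window = c(0.05, 0.3))
  expect_gt(fb$parameters[["b2"]], 5 * fb$stderr[["b2"]])
  # ignoring the term biases the extrapolated value
  fl <- fit_chi_linear(cv, window = c(0.05, 0.3))
  expect_gt(abs(fl$parameters[["chi_inf"]] - 2.5), 0.5)
  expect_lt(abs(fb$parameters[["chi_inf"]] - 2.5), 0.1)
})

test_that("KBI fits recover synthetic thermodynamic-limit values exactly", {
  L0 <- 30; rhoA <- 0.432
  lam <- seq(0.07, 0.9, by = 0.02)
  gaa <- (lam * (-0.5) * (1 - lam^3) - lam^4 / rhoA + 0.3 / L0) / lam
  gab <- (lam * 0.25 * (1 - lam^3) - 0.1 / L0) / lam
  kc <- structure(
    rbind(
      data.frame(lambda = lam, i = "A", j = "A", G = gaa, stderr = 0,
                 n_blocks = NA),
      data.frame(lambda = lam, i = "A", j = "B", G = gab, stderr = 0,
                 n_blocks = NA)
    ),
    class = c("sba_kbi_curves", "data.frame"),
    rho = c(A = rhoA, B = 0.4),
    system = list(N0 = NA, L0 = L0, rho = 0.832, kT = 1.2)
  )
  fits <- fit_kbi(kc, window = c(0.07, 0.3))
  expect_equal(fits$AA$parameters[["G_inf"]], -0.5, tolerance = 1e-7)
  expect_equal(fits$AA$parameters[["alpha"]], 0.3, tolerance = 1e-7)
  expect_equal(fits$AB$parameters[["G_inf"]], 0.25, tolerance = 1e-7)
  expect_equal(fits$AB$parameters[["alpha"]], -0.1, tolerance = 1e-7)
})

test_that("model prediction evaluates the stated closed forms", {
  grid <- seq(0.05, 0.95, by = 0.05)
  sp <- synthetic_curve_spec(chi_inf = 0.3, c1 = 0, c2 = 0, L0 = 20,
                             lambda_grid = grid)
  fit <- fit_chi_linear(generate_synthetic_curve(sp), window = c(0.05, 0.3))
  # at lambda = 1 with c = 0 the ensemble factor gives exactly zero signal
  expect_equal(predict_model(fit, 1), 0, tolerance = 1e-9)

  # self-pair KBI model with G_inf = 0, alpha = 0 keeps only the known
  # -lambda^4/rho_i term: at lambda = 0.5, rho_i = 0.432
  kfit <- structure(
    list(model_id = "kbi", parameters = c(G_inf = 0, alpha = 0),
         stderr = c(G_inf = 0, alpha = 0), window = c(0.05, 0.3),
         n_points = 10L, L0 = 30, rho_i = 0.432, self = TRUE),
    class = "sba_fit"
  )
  expect_equal(predict_model(kfit, 0.5), -0.5^4 / 0.432, tolerance = 1e-12)

  # refitting the model to its own prediction is idempotent
  lam_fit <- grid[grid <= 0.3]
  pred <- predict_model(fit, grid)
  cv2 <- blockfluct:::new_fluct_curve(
    lambda = grid, chi = pred / grid, stderr = rep(0, length(grid)),
    n_blocks = NA, system = list(N0 = NA, L0 = 20, rho = NA, kT = NA),
    seed = NA
  )
  fit2 <- fit_chi_linear(cv2, window = c(0.05, 0.3))
  expect_equal(fit2$parameters, fit$parameters, tolerance = 1e-9)

  expect_error(predict_model(fit, c(-0.1, 0.5)), "lambda")
})

test_that("fitted model superimposes on well-sampled data over the full range", {
  # on the ideal gas the finite-size model is exact, so the small-window
  # fit must predict the entire 0 < lambda < 1 curve within sampling error
  tr <- ideal_gas_trajectory(120, nA = 1200, box_edge = 10, seed = 111)
  grid <- seq(0.06, 0.98, by = 0.04)
  cv <- fluctuation_curve(tr, lambda_grid = grid,
                          n_blocks_per_frame = 100, seed = 112)
  fit <- fit_chi_linear(cv, window = c(0.06, 0.3))
  pred <- predict_model(fit, grid)
  dev <- abs(grid * cv$chi - pred)
  within <- dev <= 3 * grid * cv$stderr + 1e-12
  expect_gte(mean(within), 0.9)
})

test_that("parameter recovery is accurate and confidence intervals honest", {
  # 200 noisy synthetic curves at up to 5% relative noise
  n_rep <- 200
  grid <- seq(0.05, 0.4, by = 0.01)
  chi_true <- 0.5; c_true <- 0.35; L0 <- 30
  signal <- mean(abs(chi_true * grid * (1 - grid^3) + c_true / L0))
  errs <- numeric(n_rep)
  covered <- logical(n_rep)
  for (k in seq_len(n_rep)) {
    frac <- 0.01 + 0.04 * (k - 1) / (n_rep - 1)
    sp <- synthetic_curve_spec(chi_inf = chi_true, c1 = c_true, c2 = 0,
                               L0 = L0, noise_sd = frac * signal,
                               seed = 9000 + k, lambda_grid = grid)
    f <- fit_chi_linear(generate_synthetic_curve(sp), window = c(0.05, 0.3))
    est <- f$parameters[["chi_inf"]]
    se <- f$stderr[["chi_inf"]]
    errs[k] <- abs(est - chi_true) / chi_true
    ci_half <- qt(0.975, df = f$df) * se
    covered[k] <- abs(est - chi_true) <= ci_half
  }
  expect_lt(median(errs), 0.02)
  expect_gte(mean(covered), 0.90)
  expect_lte(mean(covered), 0.99)
})

test_that("fit window validation is enforced", {
  sp <- synthetic_curve_spec(chi_inf = 0.3, c1 = 0.1, L0 = 20,
                             lambda_grid = seq(0.05, 0.95, by = 0.05))
  cv <- generate_synthetic_curve(sp)
  expect_error(fit_chi_linear(cv, window = c(0.2, 0.21)), "fewer than 5")
  expect_error(fit_chi_linear(cv, window = c(0.3, 0.2)), "window")
  expect_error(fit_chi_linear(cv, window = c(0, 0.3)), "window")
})
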