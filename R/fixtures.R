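# Synthetic inputs with known ground truth.  The ideal gas is the exact
# oracle of the whole method: placing N0 particles uniformly in the box
# makes the count in a block of relative volume lambda^3 exactly
# binomial(N0, lambda^3), hence Var/mean = 1 - lambda^3 -- the pure
# canonical-ensemble finite-size law with chi_inf = 1 and no boundary term.

#' Generate an ideal-gas configuration
#'
#' Places `n_particles` independently and uniformly in a cubic box, the
#' exact closed-form reference for the block-fluctuation estimators: block
#' counts at block-to-box ratio `lambda` are binomial(N0, lambda^3), so the
#' fluctuation ratio is exactly `1 - lambda^3`.
#'
#' @param n_particles number of particles (>= 1).
#' @param box_edge box edge L0 in sigma.
#' @param seed integer seed (mandatory; recorded in the output).
#' @param frame_index frame label for the configuration.
#' @return An [configuration()] object with all species `"A"`.
#' @export
generate_ideal_gas <- function(n_particles, box_edge, seed, frame_index = 0L) {
  check_scalar(n_particles, "n_particles", positive = TRUE, integer = TRUE)
  check_scalar(box_edge, "box_edge", positive = TRUE)
  pos <- with_seed(seed, matrix(runif(3L * n_particles, 0, box_edge),
                                ncol = 3L))
  cfg <- configuration(pos, species = "A", box_edge = box_edge,
                       frame_index = frame_index)
  attr(cfg, "seed") <- seed
  cfg
}

#' Generate an ideal binary-mixture configuration
#'
#' Both species are placed independently and uniformly, so cross-species
#' block counts are independent: the finite-size Kirkwood-Buff estimator
#' must give G_AB(lambda) = 0 and G_AA(lambda) = -lambda^3 / rho_A in
#' expectation.
#'
#' @param nA,nB particle counts of species A and B (>= 1 each).
#' @inheritParams generate_ideal_gas
#' @return An [configuration()] object with species `"A"` and `"B"`.
#' @export
generate_ideal_binary <- function(nA, nB, box_edge, seed, frame_index = 0L) {
  check_scalar(nA, "nA", positive = TRUE, integer = TRUE)
  check_scalar(nB, "nB", positive = TRUE, integer = TRUE)
  check_scalar(box_edge, "box_edge", positive = TRUE)
  n <- nA + nB
  pos <- with_seed(seed, matrix(runif(3L * n, 0, box_edge), ncol = 3L))
  cfg <- configuration(pos, species = rep(c("A", "B"), c(nA, nB)),
                       box_edge = box_edge, frame_index = frame_index)
  attr(cfg, "seed") <- seed
  cfg
}

#' Generate a trajectory of independent ideal-gas frames
#'
#' An ideal gas has no dynamics worth simulating: a "trajectory" of
#' independent uniform frames is statistically equivalent to sampling a
#' non-interacting fluid and far cheaper.  One RNG stream seeded once
#' produces all frames.
#'
#' @param n_frames number of independent frames.
#' @param nA,nB species counts; `nB = 0` gives a single-component gas.
#' @inheritParams generate_ideal_gas
#' @return An [trajectory()] object.
#' @export
ideal_gas_trajectory <- function(n_frames, nA, nB = 0L, box_edge, seed) {
  check_scalar(n_frames, "n_frames", positive = TRUE, integer = TRUE)
  check_scalar(nA, "nA", positive = TRUE, integer = TRUE)
  check_scalar(nB, "nB", nonneg = TRUE, integer = TRUE)
  check_scalar(box_edge, "box_edge", positive = TRUE)
  n <- nA + nB
  sp <- rep(c("A", "B"), c(nA, nB))
  frames <- with_seed(seed, lapply(seq_len(n_frames), function(k) {
    configuration(matrix(runif(3L * n, 0, box_edge), ncol = 3L),
                  species = sp, box_edge = box_edge, frame_index = k - 1L)
  }))
  trajectory(frames,
             source = sprintf("ideal gas (%d A, %d B), i.i.d. frames", nA, nB),
             seed = seed)
}

#' Specification of a synthetic finite-size fluctuation curve
#'
#' Parameters of the scaled-fluctuation model with both boundary terms,
#' `lambda*chi(lambda) = lambda*chi_inf*(1 - lambda^3) + c1/L0 + b2/lambda`,
#' where `b2 = c2/L0^2` is the dimensionless coefficient of the `1/lambda`
#' term (kept as a single fitted constant).
#'
#' @param chi_inf thermodynamic-limit reduced compressibility (ground truth).
#' @param c1 linear boundary constant in sigma.
#' @param c2 second boundary constant in sigma (0 disables the `1/lambda`
#'   term); stored internally as `b2 = c2 / L0^2`.
#' @param L0 box edge in sigma.
#' @param noise_sd standard deviation of additive zero-mean Gaussian noise
#'   applied to `lambda*chi(lambda)`; `0` gives an exact model curve.
#' @param lambda_grid strictly increasing block-size ratios in (0, 1].
#' @param seed integer seed for the noise stream.
#' @return A list of class `sba_curve_spec`.
#' @export
synthetic_curve_spec <- function(chi_inf, c1 = 0, c2 = 0, L0,
                                 noise_sd = 0,
                                 lambda_grid = seq(0.05, 1, by = 0.025),
                                 seed = 1L) {
  check_scalar(chi_inf, "chi_inf", nonneg = TRUE)
  check_scalar(c1, "c1")
  check_scalar(c2, "c2")
  check_scalar(L0, "L0", positive = TRUE)
  check_scalar(noise_sd, "noise_sd", nonneg = TRUE)
  if (length(lambda_grid) < 1L || any(!is.finite(lambda_grid)) ||
      any(lambda_grid <= 0) || any(lambda_grid > 1) ||
      is.unsorted(lambda_grid, strictly = TRUE)) {
    stop("`lambda_grid` must be strictly increasing values in (0, 1]",
         call. = FALSE)
  }
  structure(
    list(chi_inf = chi_inf, c1 = c1, c2 = c2, b2 = c2 / L0^2, L0 = L0,
         noise_sd = noise_sd, lambda_grid = lambda_grid, seed = seed),
    class = "sba_curve_spec"
  )
}

# Scaled-fluctuation model lambda*chi(lambda); shared by the generator and
# by predict() on fit results so noiseless synthetic curves are reproduced
# exactly by the fitting module.
lambda_chi_model <- function(lambda, chi_inf, c1, b2, L0) {
  if (b2 != 0 && any(lambda <= 0)) {
    stop("lambda must be > 0 when the 1/lambda term is present",
         call. = FALSE)
  }
  lambda * chi_inf * (1 - lambda^3) + c1 / L0 + b2 / lambda
}

# Scaled Kirkwood-Buff model lambda*G_ij(lambda).
lambda_kbi_model <- function(lambda, G_inf, alpha, L0, rho_i, self) {
  lambda * G_inf * (1 - lambda^3) -
    (if (self) lambda^4 / rho_i else 0) + alpha / L0
}

#' Generate a synthetic fluctuation curve
#'
#' Draws `lambda*chi(lambda)` from the finite-size model of
#' [synthetic_curve_spec()] plus zero-mean Gaussian noise, and returns it
#' as a fluctuation curve carrying the ground truth in its metadata so
#' fitting can be validated by parameter recovery.
#'
#' @param spec an [synthetic_curve_spec()] object.
#' @return An `sba_fluct_curve` (see [fluctuation_curve()]); the `chi`
#'   column holds `lambda*chi(lambda) / lambda`, i.e. values on the chi
#'   scale, with `stderr = noise_sd / lambda`.
#' @export
generate_synthetic_curve <- function(spec) {
  if (!inherits(spec, "sba_curve_spec")) {
    stop("`spec` must be created by synthetic_curve_spec()", call. = FALSE)
  }
  lam <- spec$lambda_grid
  y <- lambda_chi_model(lam, spec$chi_inf, spec$c1, spec$b2, spec$L0)
  if (spec$noise_sd > 0) {
    y <- y + with_seed(spec$seed, rnorm(length(lam), 0, spec$noise_sd))
  }
  new_fluct_curve(
    lambda = lam,
    chi = y / lam,
    stderr = spec$noise_sd / lam,
    n_blocks = rep(NA_integer_, length(lam)),
    system = list(N0 = NA_integer_, L0 = spec$L0, rho = NA_real_,
                  kT = NA_real_),
    seed = spec$seed,
    truth = spec
  )
}
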