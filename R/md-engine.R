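# Minimal NVT molecular dynamics for truncated-and-shifted Lennard-Jones
# (TSLJ) fluids: velocity Verlet with a BAOAB-split Langevin thermostat,
# linked-cell force evaluation, reduced LJ units throughout (m = 1).

#' Define a truncated-and-shifted Lennard-Jones force field
#'
#' The 12-6 pair potential is truncated at `cutoff` and shifted so that
#' U(cutoff) = 0 exactly; the force keeps the truncation discontinuity at
#' the cutoff.  `cutoff = 2^(1/6)` sigma places the truncation at the
#' potential minimum and yields a purely repulsive (WCA-like) fluid.
#'
#' @param epsilon pair interaction strengths in epsilon: a scalar (single
#'   component) or a symmetric matrix over species.  Zero is allowed and
#'   gives a non-interacting (ideal-gas) system.
#' @param sigma pair diameters in sigma: scalar or symmetric matrix.
#' @param cutoff cutoff radius rc in sigma.
#' @param species character labels, one per species (row/column order of
#'   the matrices).
#' @return An object of class `sba_forcefield`.
#' @export
lj_force_field <- function(epsilon = 1, sigma = 1, cutoff = 2^(1 / 6),
                           species = NULL) {
  epsilon <- as.matrix(epsilon)
  sigma <- as.matrix(sigma)
  s <- nrow(epsilon)
  if (is.null(species)) species <- LETTERS[seq_len(s)]
  if (ncol(epsilon) != s || any(dim(sigma) != s) || length(species) != s) {
    stop("`epsilon`, `sigma` and `species` must agree in dimension",
         call. = FALSE)
  }
  if (!isSymmetric(unname(epsilon)) || !isSymmetric(unname(sigma))) {
    stop("`epsilon` and `sigma` must be symmetric", call. = FALSE)
  }
  if (any(epsilon < 0) || any(sigma <= 0)) {
    stop("`epsilon` must be >= 0 and `sigma` > 0", call. = FALSE)
  }
  check_scalar(cutoff, "cutoff", positive = TRUE)
  dimnames(epsilon) <- dimnames(sigma) <- list(species, species)
  structure(
    list(species = species, epsilon = epsilon, sigma = sigma,
         cutoff = cutoff, shifted = TRUE),
    class = "sba_forcefield"
  )
}

#' @export
print.sba_forcefield <- function(x, ...) {
  cat(sprintf("<sba_forcefield> TSLJ, %d species (%s), rc = %g sigma\n",
              length(x$species), paste(x$species, collapse = ", "),
              x$cutoff))
  invisible(x)
}

#' Force field of the repulsive binary Lennard-Jones mixture
#'
#' Equal diameters, `eps_AA = 1.2`, `eps_BB = 1.0`,
#' `eps_AB = (eps_AA + eps_BB)/2 = 1.1`, cutoff `2^(1/6)` sigma.
#'
#' @return An [lj_force_field()] over species A and B.
#' @export
binary_mixture_force_field <- function() {
  lj_force_field(
    epsilon = matrix(c(1.2, 1.1, 1.1, 1.0), 2, 2),
    sigma = matrix(1, 2, 2),
    cutoff = 2^(1 / 6),
    species = c("A", "B")
  )
}

#' Truncated-and-shifted pair potential energy
#'
#' @param r separation(s) in sigma; all > 0 (exact zero separation is an
#'   overlap error).
#' @param ff an [lj_force_field()].
#' @param species_i,species_j species labels of the pair.
#' @return Energy in epsilon: `4*eps*((sig/r)^12 - (sig/r)^6) - U_LJ(rc)`
#'   for `r < rc`, exactly 0 for `r >= rc`.
#' @export
pair_energy <- function(r, ff, species_i = NULL, species_j = NULL) {
  stopifnot(inherits(ff, "sba_forcefield"))
  if (is.null(species_i)) species_i <- ff$species[1L]
  if (is.null(species_j)) species_j <- ff$species[1L]
  if (any(!is.finite(r)) || any(r < 0)) {
    stop("`r` must be finite and >= 0", call. = FALSE)
  }
  if (any(r == 0)) stop("particle overlap: r = 0", call. = FALSE)
  e <- ff$epsilon[species_i, species_j]
  s <- ff$sigma[species_i, species_j]
  rc <- ff$cutoff
  ulj <- function(rr) 4 * e * ((s / rr)^12 - (s / rr)^6)
  u <- ifelse(r < rc, ulj(r) - ulj(rc), 0)
  as.numeric(u)
}

#' Define an NVT simulation protocol
#'
#' @param temperature target kBT in epsilon.
#' @param timestep integration timestep in `sigma*sqrt(m/epsilon)`
#'   (default 1e-3).
#' @param friction Langevin damping coefficient gamma in inverse time units
#'   (default 1); `0` disables the thermostat (NVE velocity Verlet).
#' @param n_equilibration_steps,n_production_steps step counts.
#' @param frame_stride production steps between stored frames.
#' @param seed integer seed for velocity initialisation and thermostat
#'   noise (mandatory).
#' @return A list of class `sba_protocol`.
#' @export
simulation_protocol <- function(temperature, timestep = 1e-3, friction = 1,
                                n_equilibration_steps = 10000L,
                                n_production_steps = 50000L,
                                frame_stride = 100L, seed) {
  check_scalar(temperature, "temperature", positive = TRUE)
  check_scalar(timestep, "timestep", positive = TRUE)
  check_scalar(friction, "friction", nonneg = TRUE)
  check_scalar(n_equilibration_steps, "n_equilibration_steps", nonneg = TRUE,
               integer = TRUE)
  check_scalar(n_production_steps, "n_production_steps", positive = TRUE,
               integer = TRUE)
  check_scalar(frame_stride, "frame_stride", positive = TRUE, integer = TRUE)
  check_scalar(seed, "seed", integer = TRUE)
  structure(
    list(temperature = temperature, timestep = timestep, friction = friction,
         n_equilibration_steps = as.integer(n_equilibration_steps),
         n_production_steps = as.integer(n_production_steps),
         frame_stride = as.integer(frame_stride), seed = seed),
    class = "sba_protocol"
  )
}

#' Initial configuration on a perturbed cubic lattice
#'
#' Places particles on a simple cubic lattice at the target density with a
#' small random jitter, avoiding overlaps; species labels are assigned to
#' lattice sites in random order so mixtures start well mixed.
#'
#' @param n_particles particle count.
#' @param density number density rho in sigma^-3 (fixes the box edge).
#' @param species per-particle labels, or a single label.
#' @param seed integer seed.
#' @param jitter uniform displacement half-width in units of the lattice
#'   spacing.
#' @return An [configuration()].
#' @export
lattice_configuration <- function(n_particles, density, species = "A", seed,
                                  jitter = 0.1) {
  check_scalar(n_particles, "n_particles", positive = TRUE, integer = TRUE)
  check_scalar(density, "density", positive = TRUE)
  L0 <- (n_particles / density)^(1 / 3)
  ncell <- ceiling(n_particles^(1 / 3))
  a <- L0 / ncell
  sites <- as.matrix(expand.grid(x = seq_len(ncell) - 1,
                                 y = seq_len(ncell) - 1,
                                 z = seq_len(ncell) - 1)) * a + a / 2
  if (length(species) == 1L) species <- rep(species, n_particles)
  with_seed(seed, {
    keep <- sample.int(nrow(sites), n_particles)
    pos <- sites[keep, , drop = FALSE] +
      matrix(runif(3L * n_particles, -jitter * a, jitter * a), ncol = 3L)
    configuration(pos, species = sample(species), box_edge = L0)
  })
}

#' Run Langevin NVT molecular dynamics
#'
#' BAOAB-split velocity Verlet with Langevin thermostat; with
#' `friction = 0` the scheme is plain velocity Verlet (NVE).  Trajectories
#' are bit-identical for identical inputs and seed.
#'
#' @param initial an [configuration()]; every species label must appear in
#'   the force field.
#' @param ff an [lj_force_field()]; requires `cutoff < box_edge / 2`.
#' @param protocol an [simulation_protocol()].
#' @return An [trajectory()] whose metadata carries per-frame potential,
#'   kinetic energy and pair virial (`energies` element).
#' @export
run_nvt <- function(initial, ff, protocol) {
  stopifnot(inherits(initial, "sba_config"),
            inherits(ff, "sba_forcefield"),
            inherits(protocol, "sba_protocol"))
  L0 <- initial$box_edge
  if (ff$cutoff >= L0 / 2) {
    stop("cutoff must be smaller than half the box edge", call. = FALSE)
  }
  sidx <- match(initial$species, ff$species)
  if (anyNA(sidx)) {
    stop("configuration contains species missing from the force field",
         call. = FALSE)
  }
  res <- cpp_run_nvt(
    initial$positions, sidx - 1L, L0,
    ff$epsilon, ff$sigma, ff$cutoff,
    protocol$timestep, protocol$friction, protocol$temperature,
    protocol$n_equilibration_steps, protocol$n_production_steps,
    protocol$frame_stride, protocol$seed
  )
  frames <- lapply(seq_along(res$frames), function(k) {
    configuration(res$frames[[k]], species = initial$species,
                  box_edge = L0, frame_index = k - 1L)
  })
  traj <- trajectory(frames, temperature = protocol$temperature,
                     source = "run_nvt (TSLJ, Langevin BAOAB)",
                     seed = protocol$seed)
  traj$energies <- data.frame(
    step = res$step,
    potential = res$potential_energy,
    kinetic = res$kinetic_energy,
    virial = res$virial
  )
  traj$forcefield <- ff
  traj$protocol <- protocol
  traj
}

#' Mean kinetic temperature of a trajectory
#'
#' `kBT_kin = 2 <KE> / (3 N)` averaged over stored frames.
#'
#' @param traj a trajectory produced by [run_nvt()].
#' @return Temperature in epsilon.
#' @export
kinetic_temperature <- function(traj) {
  stopifnot(inherits(traj, "sba_trajectory"))
  if (is.null(traj$energies)) {
    stop("trajectory carries no kinetic-energy record", call. = FALSE)
  }
  mean(2 * traj$energies$kinetic / (3 * traj$n_particles))
}

#' Virial pressure of a configuration
#'
#' `P = rho * kBT + W / (3 V0)` with the pair virial
#' `W = sum_pairs r . F(r)` evaluated with minimum-image distances.
#'
#' @param config an [configuration()].
#' @param ff an [lj_force_field()].
#' @param temperature kBT in epsilon for the kinetic (ideal) part.
#' @return Pressure in epsilon/sigma^3.
#' @export
virial_pressure <- function(config, ff, temperature) {
  stopifnot(inherits(config, "sba_config"), inherits(ff, "sba_forcefield"))
  check_scalar(temperature, "temperature", positive = TRUE)
  sidx <- match(config$species, ff$species)
  if (anyNA(sidx)) {
    stop("configuration contains species missing from the force field",
         call. = FALSE)
  }
  L0 <- config$box_edge
  f <- cpp_forces(config$positions, sidx - 1L, L0, ff$epsilon, ff$sigma,
                  ff$cutoff, "cell")
  n <- nrow(config$positions)
  n / L0^3 * temperature + f$virial / (3 * L0^3)
}

# Time-averaged virial pressure over the frames of an NVT run, using the
# per-frame virial recorded by the integrator.
mean_virial_pressure <- function(traj) {
  if (is.null(traj$energies)) {
    stop("trajectory carries no virial record", call. = FALSE)
  }
  V0 <- traj$box_edge^3
  mean(traj$density * traj$temperature + traj$energies$virial / (3 * V0))
}

#' Find the density that realises a target pressure
#'
#' Bracketing plus bisection on the time-averaged virial pressure of short
#' NVT runs, the NVT replacement for a barostat.  Pressure is monotone in
#' density for these purely repulsive fluids.
#'
#' @param ff an [lj_force_field()].
#' @param temperature kBT in epsilon.
#' @param target_pressure target P in epsilon/sigma^3.
#' @param mole_fractions named species fractions (default: pure first
#'   species).
#' @param tolerance pressure tolerance in epsilon/sigma^3 (> 0; stochastic
#'   pressure estimates make an exact match unattainable).
#' @param bracket density search interval in sigma^-3.
#' @param n_particles particles per probe run.
#' @param n_steps production steps per probe run.
#' @param seed integer seed.
#' @return The tuned density (numeric), with the scanned `(rho, P)` table
#'   as attribute `scan`.
#' @export
tune_density_to_pressure <- function(ff, temperature, target_pressure,
                                     mole_fractions = NULL, tolerance = 0.05,
                                     bracket = c(0.1, 1.2),
                                     n_particles = 500L, n_steps = 4000L,
                                     seed) {
  stopifnot(inherits(ff, "sba_forcefield"))
  check_scalar(temperature, "temperature", positive = TRUE)
  check_scalar(target_pressure, "target_pressure", positive = TRUE)
  check_scalar(tolerance, "tolerance", positive = TRUE)
  check_scalar(seed, "seed", integer = TRUE)
  if (is.null(mole_fractions)) {
    mole_fractions <- setNames(c(1, rep(0, length(ff$species) - 1L)),
                               ff$species)
  }
  mole_fractions <- mole_fractions / sum(mole_fractions)
  counts <- round(mole_fractions * n_particles)
  counts[1L] <- n_particles - sum(counts[-1L])
  sp <- rep(names(counts), counts)

  pressure_at <- function(rho, probe_seed) {
    cfg <- lattice_configuration(n_particles, rho, species = sp,
                                 seed = probe_seed)
    prot <- simulation_protocol(
      temperature = temperature, friction = 1,
      n_equilibration_steps = max(1000L, n_steps %/% 4L),
      n_production_steps = n_steps, frame_stride = max(1L, n_steps %/% 50L),
      seed = probe_seed
    )
    mean_virial_pressure(run_nvt(cfg, ff, prot))
  }

  scan <- data.frame(rho = numeric(0), pressure = numeric(0))
  probe <- function(rho, k) {
    p <- pressure_at(rho, seed + k)
    scan[nrow(scan) + 1L, ] <<- c(rho, p)
    p
  }
  lo <- bracket[1L]; hi <- bracket[2L]
  p_lo <- probe(lo, 1L); p_hi <- probe(hi, 2L)
  if ((p_lo - target_pressure) * (p_hi - target_pressure) > 0) {
    msg <- paste(sprintf("  rho = %.4f  P = %.4f", scan$rho, scan$pressure),
                 collapse = "\n")
    stop(sprintf(
      "target pressure %g not bracketed in [%g, %g]; scanned:\n%s",
      target_pressure, lo, hi, msg
    ), call. = FALSE)
  }
  k <- 2L
  mid <- (lo + hi) / 2; p_mid <- NA_real_
  for (it in seq_len(30L)) {
    mid <- (lo + hi) / 2
    k <- k + 1L
    p_mid <- probe(mid, k)
    if (abs(p_mid - target_pressure) < tolerance) break
    if ((p_lo - target_pressure) * (p_mid - target_pressure) <= 0) {
      hi <- mid; p_hi <- p_mid
    } else {
      lo <- mid; p_lo <- p_mid
    }
    if (hi - lo < 1e-4) break
  }
  structure(mid, scan = scan, pressure = p_mid)
}
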