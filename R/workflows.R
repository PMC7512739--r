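# End-to-end workflows wiring simulation, block analysis, extrapolation
# and thermodynamics together, with presets for the three canonical
# experiments.  Each workflow is deterministic given its config (explicit
# seeds everywhere) and writes every intermediate to disk.

#' Workflow presets
#'
#' Named state points with scaled-down run lengths suitable for a desk
#' machine:
#' * `single_component_wca`: purely repulsive TSLJ fluid
#'   (rc = 2^(1/6) sigma) at `rho sigma^3 = 0.864`, `kBT = 1.2 eps`.
#' * `near_critical_lj25`: TSLJ with rc = 2.5 sigma at `rho sigma^3 = 0.3`,
#'   `kBT = 1.15 eps` (close to the critical point, where the 1/lambda
#'   boundary term matters).
#' * `binary_mixture`: repulsive binary mixture (eps_AA = 1.2,
#'   eps_BB = 1.0, eps_AB = 1.1) at `kBT = 1.2 eps`, `rho sigma^3 = 0.86`,
#'   equimolar by default.
#'
#' `production_scale = TRUE` restores the full production-scale particle
#' numbers and step counts (cluster-sized runs).
#'
#' @param name preset name.
#' @param production_scale use full production-scale sizes.
#' @return A config list for [sba_simulate()].
#' @export
sba_preset <- function(name = c("single_component_wca", "near_critical_lj25",
                                "binary_mixture"),
                       production_scale = FALSE) {
  name <- match.arg(name)
  base <- switch(name,
    single_component_wca = list(
      workflow = name,
      forcefield = list(epsilon = 1, sigma = 1, cutoff = 2^(1 / 6),
                        species = "A"),
      density = 0.864, temperature = 1.2, mole_fractions = c(A = 1),
      n_particles = if (production_scale) 1e5 else 2000,
      n_equilibration_steps = if (production_scale) 2e6 else 2e4,
      n_production_steps = if (production_scale) 1e6 else 2e5,
      frame_stride = if (production_scale) 1000 else 800,
      n_blocks_per_frame = 100
    ),
    near_critical_lj25 = list(
      workflow = name,
      forcefield = list(epsilon = 1, sigma = 1, cutoff = 2.5, species = "A"),
      density = 0.3, temperature = 1.15, mole_fractions = c(A = 1),
      n_particles = if (production_scale) 24000 else 2000,
      n_equilibration_steps = if (production_scale) 2e6 else 2e4,
      n_production_steps = if (production_scale) 1e6 else 1e5,
      frame_stride = if (production_scale) 1000 else 500,
      n_blocks_per_frame = 100
    ),
    binary_mixture = list(
      workflow = name,
      forcefield = list(
        epsilon = matrix(c(1.2, 1.1, 1.1, 1.0), 2, 2),
        sigma = matrix(1, 2, 2), cutoff = 2^(1 / 6), species = c("A", "B")
      ),
      density = 0.86, temperature = 1.2, mole_fractions = c(A = 0.5, B = 0.5),
      n_particles = if (production_scale) 23328 else 1000,
      n_equilibration_steps = if (production_scale) 64e6 else 2e4,
      n_production_steps = if (production_scale) 2e6 else 1e5,
      frame_stride = if (production_scale) 2500 else 500,
      n_blocks_per_frame = if (production_scale) 1000 else 400
    )
  )
  c(base, list(timestep = 1e-3, friction = 1))
}

config_forcefield <- function(config) {
  ffc <- config$forcefield
  lj_force_field(epsilon = ffc$epsilon, sigma = ffc$sigma,
                 cutoff = ffc$cutoff, species = ffc$species)
}

require_seed <- function(config) {
  if (is.null(config$seed)) {
    stop("config must carry an explicit `seed` (stochastic stages are never implicitly seeded)",
         call. = FALSE)
  }
  check_scalar(config$seed, "seed", integer = TRUE)
}

validate_sim_config <- function(config) {
  problems <- character(0)
  need <- c("forcefield", "density", "temperature", "n_particles",
            "n_equilibration_steps", "n_production_steps", "frame_stride")
  for (k in need) {
    if (is.null(config[[k]])) problems <- c(problems, sprintf("missing `%s`", k))
  }
  if (is.null(config$seed)) problems <- c(problems, "missing `seed`")
  if (length(problems)) {
    stop(paste(c("invalid config:", paste(" -", problems)), collapse = "\n"),
         call. = FALSE)
  }
}

#' Simulate a trajectory from a workflow config
#'
#' Runs the MD engine per config and writes an extended-XYZ trajectory plus
#' a provenance sidecar (JSON when the jsonlite package is available,
#' key-value text otherwise) to `output_dir`.
#'
#' @param config a config list (see [sba_preset()]) with a mandatory
#'   `seed`; `output_dir = NULL` skips writing.
#' @return The [trajectory()], invisibly when written.
#' @export
sba_simulate <- function(config) {
  validate_sim_config(config)
  require_seed(config)
  ff <- config_forcefield(config)
  mf <- config$mole_fractions
  if (is.null(mf)) mf <- setNames(1, ff$species[1L])
  counts <- round(mf / sum(mf) * config$n_particles)
  counts[1L] <- config$n_particles - sum(counts[-1L])
  sp <- rep(names(counts), counts)
  init <- lattice_configuration(config$n_particles, config$density,
                                species = sp, seed = config$seed)
  prot <- simulation_protocol(
    temperature = config$temperature,
    timestep = config$timestep %||% 1e-3,
    friction = config$friction %||% 1,
    n_equilibration_steps = config$n_equilibration_steps,
    n_production_steps = config$n_production_steps,
    frame_stride = config$frame_stride,
    seed = config$seed
  )
  traj <- run_nvt(init, ff, prot)
  if (!is.null(config$output_dir)) {
    dir.create(config$output_dir, showWarnings = FALSE, recursive = TRUE)
    xyz <- file.path(config$output_dir, "trajectory.xyz")
    write_trajectory(traj, xyz)
    prov <- list(workflow = config$workflow %||% "custom",
                 n_particles = config$n_particles,
                 density = config$density,
                 temperature = config$temperature,
                 cutoff = ff$cutoff,
                 n_equilibration_steps = config$n_equilibration_steps,
                 n_production_steps = config$n_production_steps,
                 frame_stride = config$frame_stride,
                 seed = config$seed)
    if (requireNamespace("jsonlite", quietly = TRUE)) {
      jsonlite::write_json(prov, file.path(config$output_dir,
                                           "provenance.json"),
                           auto_unbox = TRUE, digits = NA)
    } else {
      writeLines(sprintf("%s: %s", names(prov), unlist(prov)),
                 file.path(config$output_dir, "provenance.txt"))
    }
    return(invisible(traj))
  }
  traj
}

#' Analyze a trajectory: curves, fits and compressibility
#'
#' Runs the full pipeline: fluctuation curve (all systems) and KBI curves
#' (multi-species systems), small-window fits, and compressibility from
#' both routes where applicable.  Every intermediate is written to
#' `output_dir` when given.
#'
#' @param traj an [trajectory()] or path to an extended-XYZ file.
#' @param config list with optional `lambda_grid`, `window`,
#'   `n_blocks_per_frame`, `output_dir`, and mandatory `seed`.
#' @return List with elements `curve`, `fit`, `kappa`, and for mixtures
#'   `kbi`, `kbi_fits`, `kappa_kbi`.
#' @export
sba_analyze <- function(traj, config = list()) {
  if (is.character(traj)) traj <- read_trajectory(traj)
  stopifnot(inherits(traj, "sba_trajectory"))
  require_seed(config)
  kT <- config$temperature %||% traj$temperature
  out <- list()
  curve <- fluctuation_curve(
    traj, lambda_grid = config$lambda_grid,
    n_blocks_per_frame = config$n_blocks_per_frame %||% 100L,
    seed = config$seed
  )
  fit <- fit_chi_linear(curve, window = config$window,
                        zeta_guard = config$zeta_guard %||% 0)
  out$curve <- curve
  out$fit <- fit
  if (is.finite(kT)) {
    out$kappa <- kappa_from_chi(max(fit$parameters[["chi_inf"]], 0),
                                traj$density, kT)
  }
  n_species <- length(species_names(traj))
  if (n_species >= 2L) {
    kbi <- kbi_curve(traj, lambda_grid = config$lambda_grid,
                     n_blocks_per_frame = config$n_blocks_per_frame %||% 1000L,
                     seed = config$seed + 1L)
    kfits <- fit_kbi(kbi, window = config$window,
                     zeta_guard = config$zeta_guard %||% 0)
    out$kbi <- kbi
    out$kbi_fits <- kfits
    rho <- attr(kbi, "rho")
    if (is.finite(kT) && all(c("AA", "BB", "AB") %in% names(kfits))) {
      out$kappa_kbi <- kappa_from_kbi(
        kfits$AA$parameters[["G_inf"]], kfits$BB$parameters[["G_inf"]],
        kfits$AB$parameters[["G_inf"]], rho[["A"]], rho[["B"]], kT
      )
    }
  }
  if (!is.null(config$output_dir)) {
    dir.create(config$output_dir, showWarnings = FALSE, recursive = TRUE)
    write_table(curve, file.path(config$output_dir, "fluctuation_curve.dat"))
    write_fit(fit, file.path(config$output_dir, "chi_fit.dat"))
    if (!is.null(out$kbi)) {
      write_table(out$kbi, file.path(config$output_dir, "kbi_curves.dat"))
      write_fit(out$kbi_fits, file.path(config$output_dir, "kbi_fits.dat"))
    }
  }
  out
}

#' Chemical-potential workflow over a state-point scan
#'
#' Integrates the chemical-potential differences over a thermodynamic
#' table, forms the excess curve and optionally anchors it to an external
#' reference value.
#'
#' @param table an [thermo_table()].
#' @param reference_density reference density for [integrate_mu()].
#' @param reference_axis,reference_mu optional anchoring of the excess
#'   curve (see [excess_mu()]).
#' @param output_dir optional output directory.
#' @return An `sba_chempot` curve with `delta_mu` and `delta_mu_ex`.
#' @export
sba_chempot <- function(table, reference_density, reference_axis = NULL,
                        reference_mu = NULL, output_dir = NULL) {
  stopifnot(inherits(table, "sba_thermo"))
  if (identical(attr(table, "mode"), "single")) check_kappa_monotone(table)
  curve <- integrate_mu(table, reference_density)
  curve <- excess_mu(curve, reference_axis = reference_axis,
                     reference_mu = reference_mu)
  if (!is.null(output_dir)) {
    dir.create(output_dir, showWarnings = FALSE, recursive = TRUE)
    write_table(curve, file.path(output_dir, "chempot_curve.dat"))
  }
  curve
}
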