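# Shared fixtures, built in code and memoised so expensive MD runs are
# computed once per test session.

.fixture_cache <- new.env(parent = emptyenv())

memo_fixture <- function(key, expr) {
  if (!exists(key, envir = .fixture_cache)) {
    assign(key, force(expr), envir = .fixture_cache)
  }
  get(key, envir = .fixture_cache)
}

wca_ff <- function() lj_force_field(epsilon = 1, sigma = 1,
                                    cutoff = 2^(1 / 6))

# Small purely repulsive fluid at the reference state point
# (rho sigma^3 = 0.864, kBT = 1.2 eps); enough frames for estimator and
# consistency checks, cheap enough for routine test runs.
small_wca_trajectory <- function() {
  memo_fixture("small_wca", {
    cfg <- lattice_configuration(512, 0.864, seed = 101)
    prot <- simulation_protocol(
      temperature = 1.2, friction = 1,
      n_equilibration_steps = 5000L, n_production_steps = 40000L,
      frame_stride = 400L, seed = 101
    )
    run_nvt(cfg, wca_ff(), prot)
  })
}

# Scaled-down reproduction run for the headline compressibility numbers:
# N0 = 2000 at rho sigma^3 = 0.864, kBT = 1.2 eps, 2.5e5 production steps.
reference_wca_trajectory <- function() {
  memo_fixture("reference_wca", {
    cfg <- lattice_configuration(2000, 0.864, seed = 401)
    prot <- simulation_protocol(
      temperature = 1.2, friction = 1,
      n_equilibration_steps = 2.5e4L, n_production_steps = 2.5e5L,
      frame_stride = 250L, seed = 401
    )
    run_nvt(cfg, wca_ff(), prot)
  })
}

ideal_kappa_table <- function(kT = 1.2, n = 100L) {
  rho <- seq(0.2, 1.0, length.out = n)
  thermo_table(data.frame(rho = rho, kappa = 1 / (rho * kT)), kT = kT)
}
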