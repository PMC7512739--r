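# Conversion of extrapolated fluctuation quantities into bulk observables:
# isothermal compressibility, chemical-potential derivatives, and
# integrated chemical-potential curves relative to a reference state.
# Everything in reduced LJ units.

#' Isothermal compressibility from the reduced compressibility
#'
#' `kappa_T = chi_inf / (rho * kBT)`; `chi_inf = 1` recovers the ideal-gas
#' compressibility `1 / (rho * kBT)`.
#'
#' @param chi_inf thermodynamic-limit reduced compressibility
#'   (dimensionless, >= 0).
#' @param rho number density in sigma^-3.
#' @param kT temperature kBT in epsilon.
#' @return kappa_T in sigma^3/epsilon.
#' @export
kappa_from_chi <- function(chi_inf, rho, kT) {
  if (any(!is.finite(chi_inf)) || any(chi_inf < 0)) {
    stop("`chi_inf` must be finite and >= 0", call. = FALSE)
  }
  if (any(rho <= 0) || any(kT <= 0)) {
    stop("`rho` and `kT` must be > 0", call. = FALSE)
  }
  chi_inf / (rho * kT)
}

#' Isothermal compressibility of a binary mixture from Kirkwood-Buff
#' integrals
#'
#' `kappa_T = (1 + rhoA*GAA + rhoB*GBB + rhoA*rhoB*(GAA*GBB - GAB^2)) /
#'            (kBT * (rhoA + rhoB + rhoA*rhoB*(GAA + GBB - 2*GAB)))`.
#' With `rhoB = 0` this reduces to the single-component relation
#' `kappa_T = (1 + rhoA*GAA) / (kBT * rhoA)`.
#'
#' @param G_AA,G_BB,G_AB thermodynamic-limit KBIs in sigma^3.
#' @param rho_A,rho_B species number densities in sigma^-3 (`rho_B = 0`
#'   gives the pure-A limit).
#' @param kT temperature kBT in epsilon.
#' @return kappa_T in sigma^3/epsilon.
#' @export
kappa_from_kbi <- function(G_AA, G_BB, G_AB, rho_A, rho_B, kT) {
  if (any(rho_A <= 0) || any(rho_B < 0) || any(kT <= 0)) {
    stop("`rho_A` must be > 0, `rho_B` >= 0 and `kT` > 0", call. = FALSE)
  }
  num <- 1 + rho_A * G_AA + rho_B * G_BB +
    rho_A * rho_B * (G_AA * G_BB - G_AB^2)
  den <- kT * (rho_A + rho_B + rho_A * rho_B * (G_AA + G_BB - 2 * G_AB))
  if (any(abs(den) < .Machine$double.eps * 100)) {
    stop("vanishing denominator: thermodynamically unstable input",
         call. = FALSE)
  }
  num / den
}

#' Chemical-potential derivative of species A from KBIs
#'
#' `d muA / d rhoA = kBT * (1/rhoA + (GAB - GAA) / (1 + rhoA*(GAA - GAB)))`
#' at fixed pressure and temperature.  A vanishing denominator marks a
#' demixing instability and is reported as an error.
#'
#' @param G_AA,G_AB thermodynamic-limit KBIs in sigma^3.
#' @param rho_A number density of species A in sigma^-3.
#' @param kT temperature kBT in epsilon.
#' @return Derivative in epsilon*sigma^3.
#' @export
dmuA_drhoA <- function(G_AA, G_AB, rho_A, kT) {
  if (any(rho_A <= 0) || any(kT <= 0)) {
    stop("`rho_A` and `kT` must be > 0", call. = FALSE)
  }
  den <- 1 + rho_A * (G_AA - G_AB)
  if (any(abs(den) < 1e-12)) {
    stop("pole in the chemical-potential derivative (demixing instability)",
         call. = FALSE)
  }
  kT * (1 / rho_A + (G_AB - G_AA) / den)
}

#' Build a thermodynamic state-point table
#'
#' Single-component: columns `rho` and `kappa` (optionally `kappa_se`).
#' Mixture: columns `xA`, `rho_A`, `G_AA`, `G_AB` (per-point extrapolated
#' KBIs).  The axis must be strictly increasing.
#'
#' @param df data frame with the columns above.
#' @param kT temperature kBT in epsilon.
#' @return An `sba_thermo` table.
#' @export
thermo_table <- function(df, kT) {
  check_scalar(kT, "kT", positive = TRUE)
  df <- as.data.frame(df)
  single <- all(c("rho", "kappa") %in% names(df))
  mixture <- all(c("rho_A", "G_AA", "G_AB") %in% names(df))
  if (!single && !mixture) {
    stop("need columns (rho, kappa) or (rho_A, G_AA, G_AB)", call. = FALSE)
  }
  axis <- if (single) df$rho else df$rho_A
  if (any(axis <= 0) || is.unsorted(axis, strictly = TRUE)) {
    stop("density axis must be strictly increasing and positive",
         call. = FALSE)
  }
  if (nrow(df) < 2L) stop("need at least 2 state points", call. = FALSE)
  structure(df, class = c("sba_thermo", "data.frame"),
            kT = kT, mode = if (single) "single" else "mixture",
            system = list(kT = kT))
}

# Monotone piecewise-cubic interpolant of tabulated state-point data;
# avoids the spurious oscillation ordinary splines would feed into the
# 1/(rho^2 kappa) integrand.  Monotone tables get the Hyman-filtered
# spline (4th-order accurate on smooth data); non-monotone tables (e.g. a
# near-critical compressibility cusp) fall back to Fritsch-Carlson
# monotone Hermite, which is shape-preserving for arbitrary data.
interp_fun <- function(x, y) {
  dy <- diff(y)
  if (all(dy >= 0) || all(dy <= 0)) {
    splinefun(x, y, method = "hyman")
  } else {
    splinefun(x, y, method = "monoH.FC")
  }
}

#' Integrate chemical-potential differences over a state-point scan
#'
#' Single-component tables integrate `d mu = d rho / (rho^2 kappa_T)`;
#' mixture tables integrate the KBI-based derivative of [dmuA_drhoA()].
#' Tabulated quantities are interpolated with a monotone piecewise cubic
#' and integrated by composite trapezoid on a refined grid;
#' `delta_mu(reference) = 0` exactly.
#'
#' @param table an [thermo_table()].
#' @param reference_density reference density (same axis as the table;
#'   must lie inside the tabulated range).
#' @param refine subintervals per tabulated interval for the quadrature
#'   (halving the effective spacing changes delta_mu by well under 1e-4
#'   epsilon on smooth tables).
#' @return An `sba_chempot` data frame with the table axis, `delta_mu`
#'   (epsilon) and, when per-point uncertainties are available, a
#'   first-order propagated `delta_mu_se`.
#' @export
integrate_mu <- function(table, reference_density, refine = 64L) {
  stopifnot(inherits(table, "sba_thermo"))
  kT <- attr(table, "kT")
  mode <- attr(table, "mode")
  single <- identical(mode, "single")
  axis <- if (single) table$rho else table$rho_A
  check_scalar(reference_density, "reference_density", positive = TRUE)
  if (reference_density < min(axis) || reference_density > max(axis)) {
    stop("`reference_density` must lie inside the tabulated axis range",
         call. = FALSE)
  }
  if (single) {
    if (any(table$kappa <= 0)) {
      stop("kappa_T must be positive throughout the integration domain",
           call. = FALSE)
    }
    kap <- interp_fun(axis, table$kappa)
    integrand <- function(r) 1 / (r^2 * kap(r))
  } else {
    gaa <- interp_fun(axis, table$G_AA)
    gab <- interp_fun(axis, table$G_AB)
    integrand <- function(r) {
      den <- 1 + r * (gaa(r) - gab(r))
      if (any(abs(den) < 1e-12)) {
        stop("pole in the chemical-potential derivative inside the scan",
             call. = FALSE)
      }
      kT * (1 / r + (gab(r) - gaa(r)) / den)
    }
  }
  # refined grid containing every table node and the reference exactly
  grid <- sort(unique(c(
    unlist(lapply(seq_len(length(axis) - 1L), function(k) {
      seq(axis[k], axis[k + 1L], length.out = refine + 1L)
    })),
    reference_density
  )))
  f <- integrand(grid)
  h <- diff(grid)
  cum <- c(0, cumsum(h * (f[-1L] + f[-length(f)]) / 2))
  at <- function(r) cum[match(r, grid)]
  ref0 <- at(reference_density)
  delta_mu <- vapply(axis, at, 0) - ref0

  out <- data.frame(axis = axis, delta_mu = delta_mu)
  names(out)[1L] <- if (single) "rho" else "rho_A"
  if (!single && "xA" %in% names(table)) out$xA <- table$xA
  if (single && "kappa_se" %in% names(table)) {
    # first-order propagation: each node's kappa enters delta_mu through
    # roughly its half-neighbourhood of the integrand
    w <- numeric(length(axis))
    lo <- min(reference_density, axis)
    for (k in seq_along(axis)) {
      span_lo <- if (k == 1L) axis[1L] else (axis[k - 1L] + axis[k]) / 2
      span_hi <- if (k == length(axis)) axis[k] else (axis[k] + axis[k + 1L]) / 2
      w[k] <- span_hi - span_lo
    }
    dmu_dkap <- -1 / (axis^2 * table$kappa^2)
    node_var <- (w * dmu_dkap * table$kappa_se)^2
    out$delta_mu_se <- sqrt(vapply(seq_along(axis), function(k) {
      between <- axis > min(reference_density, axis[k]) - 1e-12 &
        axis < max(reference_density, axis[k]) + 1e-12
      sum(node_var[between])
    }, 0))
  }
  structure(out, class = c("sba_chempot", "data.frame"),
            kT = kT, mode = mode,
            reference = list(density = reference_density, mu0 = NA_real_),
            system = list(kT = kT))
}

#' Excess (residual) chemical potential of a curve
#'
#' Subtracts the density-dependent ideal-gas part, `kBT * ln(rho)` (and
#' `kBT * ln(xA)` for mixtures): the result is the chemical potential in
#' excess of an ideal gas at the same density, temperature and
#' composition, up to an additive constant fixed by the reference state.
#' Anchoring to an absolute value requires an externally computed
#' `reference_mu` (e.g. from a thermodynamic-integration method); it is
#' never invented here.
#'
#' @param curve an `sba_chempot` from [integrate_mu()].
#' @param reference_axis axis value (density or `rho_A`) at which the
#'   output must pass through `reference_mu`; `NULL` leaves the curve
#'   unanchored (additive constant carried as is).
#' @param reference_mu externally supplied excess chemical potential in
#'   epsilon at `reference_axis`.
#' @return The curve with a `delta_mu_ex` column (epsilon).
#' @export
excess_mu <- function(curve, reference_axis = NULL, reference_mu = NULL) {
  stopifnot(inherits(curve, "sba_chempot"))
  kT <- attr(curve, "kT")
  single <- identical(attr(curve, "mode"), "single")
  axis <- if (single) curve$rho else curve$rho_A
  if (any(axis <= 0)) stop("densities must be > 0", call. = FALSE)
  ex <- curve$delta_mu - kT * log(axis)
  if (!single) {
    if (!("xA" %in% names(curve))) {
      stop("mixture curve needs an `xA` column for the concentration term",
           call. = FALSE)
    }
    if (any(curve$xA <= 0)) stop("mole fractions must be > 0", call. = FALSE)
    ex <- ex - kT * log(curve$xA)
  }
  if (!is.null(reference_axis)) {
    if (is.null(reference_mu)) {
      stop("anchoring requires `reference_mu` (externally computed)",
           call. = FALSE)
    }
    k <- which.min(abs(axis - reference_axis))
    if (abs(axis[k] - reference_axis) > 1e-8 * max(1, abs(reference_axis))) {
      stop("`reference_axis` must coincide with a tabulated axis point",
           call. = FALSE)
    }
    ex <- ex + (reference_mu - ex[k])
    attr(curve, "reference") <- list(axis = reference_axis,
                                     mu0 = reference_mu,
                                     provenance = "user-supplied")
  }
  curve$delta_mu_ex <- ex
  curve
}

#' Warn if a compressibility scan is not monotonically decreasing
#'
#' Dense simple liquids away from criticality become less compressible as
#' density grows; a non-monotone scan is flagged as a data-quality warning
#' (it is expected behaviour near a critical point, where kappa_T has a
#' cusp).
#'
#' @param table an [thermo_table()] in single-component mode.
#' @return `TRUE` (monotone) or `FALSE` (warning issued), invisibly.
#' @export
check_kappa_monotone <- function(table) {
  stopifnot(inherits(table, "sba_thermo"))
  if (!identical(attr(table, "mode"), "single")) {
    stop("monotonicity check applies to single-component tables",
         call. = FALSE)
  }
  ok <- !is.unsorted(rev(table$kappa))
  if (!ok) {
    warning("kappa_T(rho) is not monotonically decreasing; expected away from criticality",
            call. = FALSE)
  }
  invisible(ok)
}
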