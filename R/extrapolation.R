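# Fits of the finite-size scaling models in a small-lambda window.  All
# three models are linear in their parameters once the known pieces are
# arranged, so weighted least squares (weights 1/stderr^2 when sampling
# uncertainties are available) does the whole job:
#
#   chi_linear  : lambda*chi = chi_inf * lambda*(1-lambda^3) + c/L0
#   chi_inverse : lambda*chi = chi_inf * lambda*(1-lambda^3) + c1/L0 + b2/lambda
#   kbi         : lambda*G + lambda^4*delta_ij/rho_i
#                           = G_inf * lambda*(1-lambda^3) + alpha_ij/L0
#
# The regressor lambda*(1-lambda^3) keeps the known lambda^4 piece of the
# ensemble factor, so noiseless model curves are recovered exactly and the
# chi_linear fit is the exact b2 = 0 restriction of chi_inverse.  Within
# the customary lambda < 0.3 window the lambda^4 term is numerically
# negligible anyway, and the slope/intercept reading (slope = chi_inf,
# intercept = c/L0) is unchanged.

default_fit_window <- function(curve, zeta_guard = 0) {
  L0 <- attr(curve, "system")$L0
  lo <- if (is.finite(L0)) max(2 / L0, zeta_guard / L0, 1e-6) else 1e-6
  c(lo, 0.3)
}

fit_points <- function(curve, window) {
  if (length(window) != 2L || any(!is.finite(window)) ||
      window[1L] <= 0 || window[2L] >= 1 || window[1L] >= window[2L]) {
    stop("`window` must be an increasing pair inside (0, 1)", call. = FALSE)
  }
  lam <- curve$lambda
  keep <- lam >= window[1L] & lam <= window[2L] & is.finite(curve[[2L]])
  if (sum(keep) < 5L) {
    stop(sprintf("fewer than 5 finite points in the fit window [%g, %g]",
                 window[1L], window[2L]), call. = FALSE)
  }
  keep
}

# Weighted linear fit of y on design X (no implicit intercept).  Uses lm()
# so parameter covariance comes from the standard regression machinery.
wls <- function(X, y, se) {
  dat <- as.data.frame(X)
  dat$y <- y
  use_w <- !is.null(se) && all(is.finite(se)) && all(se > 0)
  fml <- stats::as.formula(paste("y ~ 0 +", paste(colnames(X), collapse = " + ")))
  if (use_w) {
    dat$.w <- 1 / se^2
    fit <- lm(fml, data = dat, weights = .w)
  } else {
    fit <- lm(fml, data = dat)
  }
  # near-collinearity diagnostic on the scaled design
  Xs <- scale(X, center = FALSE)
  sv <- svd(Xs, nu = 0, nv = 0)$d
  cond <- if (min(sv) <= 0) Inf else max(sv) / min(sv)
  if (!is.finite(cond) || cond > 1e10) {
    stop("singular or near-singular design matrix in the fit window",
         call. = FALSE)
  }
  if (cond > 1e6) {
    warning(sprintf("ill-conditioned design (condition number %.3g)", cond))
  }
  # summary.lm warns on numerically exact fits (noiseless model curves);
  # that case is legitimate here
  s <- suppressWarnings(summary(fit))
  list(coef = coef(fit), se = s$coefficients[, "Std. Error"],
       cov = s$sigma^2 * s$cov.unscaled, sigma = s$sigma,
       df = fit$df.residual,
       residuals = stats::residuals(fit), cond = cond)
}

new_fit_result <- function(model_id, pars, par_se, cov, window, n_points,
                           sigma, df, L0, extra = list()) {
  structure(
    c(list(model_id = model_id, parameters = pars, stderr = par_se,
           cov = cov, window = window, n_points = n_points,
           residual_sd = sigma, df = df, L0 = L0), extra),
    class = "sba_fit"
  )
}

#' @export
print.sba_fit <- function(x, ...) {
  cat(sprintf("<sba_fit> model %s, window [%g, %g], %d points\n",
              x$model_id, x$window[1L], x$window[2L], x$n_points))
  out <- data.frame(estimate = x$parameters, stderr = x$stderr)
  print(out, ...)
  invisible(x)
}

#' Linear finite-size fit of a fluctuation curve
#'
#' Weighted least squares of `lambda*chi(lambda)` against
#' `lambda*(1 - lambda^3)` plus an intercept inside a small-lambda window:
#' the slope is the thermodynamic-limit reduced compressibility `chi_inf`,
#' the intercept times `L0` the intensive boundary constant `c`.  Weights
#' are `1/stderr^2` when the curve carries finite positive uncertainties,
#' ordinary least squares otherwise.
#'
#' @param curve an `sba_fluct_curve`.
#' @param window fit window `c(lambda_min, lambda_max)` inside (0, 1);
#'   default `[max(2/L0, zeta_guard/L0), 0.3]`.  The window must sit at
#'   block sizes above the correlation length; the guard is the caller's
#'   assertion, never estimated automatically.
#' @param zeta_guard correlation-length guard in sigma used by the default
#'   window.
#' @return An `sba_fit` with parameters `chi_inf` and `c` (sigma).
#' @export
fit_chi_linear <- function(curve, window = NULL, zeta_guard = 0) {
  stopifnot(inherits(curve, "sba_fluct_curve"))
  if (is.null(window)) window <- default_fit_window(curve, zeta_guard)
  keep <- fit_points(curve, window)
  lam <- curve$lambda[keep]
  y <- lam * curve$chi[keep]
  se <- lam * curve$stderr[keep]
  L0 <- attr(curve, "system")$L0
  if (!is.finite(L0)) stop("curve metadata lacks L0", call. = FALSE)
  X <- cbind(slope = lam * (1 - lam^3), intercept = 1)
  f <- wls(X, y, se)
  pars <- c(chi_inf = unname(f$coef["slope"]),
            c = unname(f$coef["intercept"]) * L0)
  par_se <- c(chi_inf = unname(f$se["slope"]),
              c = unname(f$se["intercept"]) * L0)
  new_fit_result("chi_linear", pars, par_se, f$cov, window, sum(keep),
                 f$sigma, f$df, L0)
}

#' Finite-size fit with the near-critical 1/lambda boundary term
#'
#' Adds a `b2 / lambda` basis function (with `b2 = c2 / L0^2` kept as one
#' dimensionless fitted constant) to the linear model.  This term becomes
#' material when the correlation length approaches the block size, e.g.
#' near a critical point; far from criticality its fitted value is
#' statistically indistinguishable from zero.
#'
#' @inheritParams fit_chi_linear
#' @return An `sba_fit` with parameters `chi_inf`, `c1` (sigma) and `b2`.
#' @export
fit_chi_inverse <- function(curve, window = NULL, zeta_guard = 0) {
  stopifnot(inherits(curve, "sba_fluct_curve"))
  if (is.null(window)) window <- default_fit_window(curve, zeta_guard)
  if (window[1L] <= 0) stop("window must exclude lambda = 0", call. = FALSE)
  keep <- fit_points(curve, window)
  lam <- curve$lambda[keep]
  y <- lam * curve$chi[keep]
  se <- lam * curve$stderr[keep]
  L0 <- attr(curve, "system")$L0
  if (!is.finite(L0)) stop("curve metadata lacks L0", call. = FALSE)
  X <- cbind(slope = lam * (1 - lam^3), intercept = 1, inv = 1 / lam)
  f <- wls(X, y, se)
  pars <- c(chi_inf = unname(f$coef["slope"]),
            c1 = unname(f$coef["intercept"]) * L0,
            b2 = unname(f$coef["inv"]))
  par_se <- c(chi_inf = unname(f$se["slope"]),
              c1 = unname(f$se["intercept"]) * L0,
              b2 = unname(f$se["inv"]))
  new_fit_result("chi_inverse", pars, par_se, f$cov, window, sum(keep),
                 f$sigma, f$df, L0)
}

#' Finite-size fits of Kirkwood-Buff integral curves
#'
#' For each species pair, least squares of
#' `lambda*G_ij(lambda) + lambda^4 * delta_ij / rho_i` (the known
#' self-count term subtracted using the trajectory densities) against
#' `lambda*(1 - lambda^3)` plus an intercept: slope `G_ij_inf` (sigma^3),
#' intercept `alpha_ij / L0`.
#'
#' @param curves an `sba_kbi_curves` from [kbi_curve()].
#' @inheritParams fit_chi_linear
#' @return A named list of `sba_fit` objects, one per pair (names like
#'   `"AA"`), each with parameters `G_inf` and `alpha` (sigma).
#' @export
fit_kbi <- function(curves, window = NULL, zeta_guard = 0) {
  stopifnot(inherits(curves, "sba_kbi_curves"))
  rho <- attr(curves, "rho")
  L0 <- attr(curves, "system")$L0
  if (!is.finite(L0)) stop("curve metadata lacks L0", call. = FALSE)
  pairs <- unique(curves[, c("i", "j")])
  out <- list()
  for (r in seq_len(nrow(pairs))) {
    i <- pairs$i[r]; j <- pairs$j[r]
    sub <- curves[curves$i == i & curves$j == j, ]
    sub_curve <- structure(
      data.frame(lambda = sub$lambda, G = sub$G, stderr = sub$stderr),
      system = list(L0 = L0)
    )
    win <- if (is.null(window)) {
      lo <- max(2 / L0, zeta_guard / L0, 1e-6)
      c(lo, 0.3)
    } else window
    keep <- fit_points(sub_curve, win)
    lam <- sub$lambda[keep]
    self <- i == j
    y <- lam * sub$G[keep] + (if (self) lam^4 / rho[[i]] else 0)
    se <- lam * sub$stderr[keep]
    X <- cbind(slope = lam * (1 - lam^3), intercept = 1)
    f <- wls(X, y, se)
    pars <- c(G_inf = unname(f$coef["slope"]),
              alpha = unname(f$coef["intercept"]) * L0)
    par_se <- c(G_inf = unname(f$se["slope"]),
                alpha = unname(f$se["intercept"]) * L0)
    out[[paste0(i, j)]] <- new_fit_result(
      "kbi", pars, par_se, f$cov, win, sum(keep), f$sigma, f$df, L0,
      extra = list(pair = c(i, j), rho_i = unname(rho[[i]]), self = self)
    )
  }
  out
}

#' Evaluate a fitted finite-size model on a lambda grid
#'
#' Returns the scaled model values (`lambda*chi` or `lambda*G`), including
#' the full `(1 - lambda^3)` ensemble factor and, for self-pair KBIs, the
#' known `-lambda^4 / rho_i` term, so the fitted small-window model can be
#' overlaid on data across the whole range `0 < lambda <= 1`.
#'
#' @param fit an `sba_fit`.
#' @param lambda_grid evaluation points in (0, 1].
#' @return Numeric vector of `lambda`-scaled model values.
#' @export
predict_model <- function(fit, lambda_grid) {
  stopifnot(inherits(fit, "sba_fit"))
  check_lambda(lambda_grid)
  p <- fit$parameters
  switch(fit$model_id,
    chi_linear = lambda_chi_model(lambda_grid, p[["chi_inf"]], p[["c"]],
                                  0, fit$L0),
    chi_inverse = lambda_chi_model(lambda_grid, p[["chi_inf"]], p[["c1"]],
                                   p[["b2"]], fit$L0),
    kbi = lambda_kbi_model(lambda_grid, p[["G_inf"]], p[["alpha"]], fit$L0,
                           fit$rho_i, fit$self),
    stop("unknown model id", call. = FALSE)
  )
}

#' Serialise a fit result to a '#'-headered table
#'
#' @param fit an `sba_fit` (or a list of them, e.g. from [fit_kbi()]).
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_fit <- function(fit, path) {
  fits <- if (inherits(fit, "sba_fit")) list(fit = fit) else fit
  rows <- do.call(rbind, lapply(names(fits), function(nm) {
    f <- fits[[nm]]
    data.frame(fit = nm, model = f$model_id,
               parameter = names(f$parameters),
               estimate = unname(f$parameters),
               stderr = unname(f$stderr),
               window_lo = f$window[1L], window_hi = f$window[2L],
               n_points = f$n_points)
  }))
  write_table(structure(rows, window = fits[[1L]]$window), path,
              extra = list(model = paste(
                unique(vapply(fits, `[[`, "", "model_id")), collapse = " ")))
}
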