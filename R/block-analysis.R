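# Block-counting estimators.  Cubic subdomains of edge L = lambda*L0 are
# placed at uniform random origins (blocks may wrap across the periodic
# boundary); membership is half-open per axis so tiling blocks never
# double-count.  Moments of the block counts are pooled over all (frame,
# block) samples per lambda; standard errors come from a frame-level
# delete-one jackknife, which respects temporal correlation within a frame
# while treating frames as approximately independent.

new_fluct_curve <- function(lambda, chi, stderr, n_blocks, system, seed,
                            truth = NULL) {
  df <- data.frame(lambda = lambda, chi = chi, stderr = stderr,
                   n_blocks = n_blocks)
  structure(df, class = c("sba_fluct_curve", "data.frame"),
            system = system, seed = seed, truth = truth)
}

#' @export
print.sba_fluct_curve <- function(x, ...) {
  sys <- attr(x, "system")
  cat(sprintf(
    "<sba_fluct_curve> %d lambda points%s\n", nrow(x),
    if (!is.null(sys) && is.finite(sys$L0)) sprintf(", L0 = %g sigma", sys$L0) else ""
  ))
  print.data.frame(x, ...)
  invisible(x)
}

default_lambda_grid <- function(L0, floor_sigma = 1, n = 60L) {
  lo <- max(floor_sigma / L0, 0.02)
  if (lo >= 1) stop("box too small for the requested block-size floor",
                    call. = FALSE)
  g <- exp(seq(log(lo), 0, length.out = n))
  g[length(g)] <- 1
  g
}

check_lambda <- function(lambda) {
  if (any(!is.finite(lambda)) || any(lambda <= 0) || any(lambda > 1)) {
    stop("lambda values must lie in (0, 1]", call. = FALSE)
  }
  lambda
}

# Count particles per species for a set of origins; shared kernel of the
# random-origin and exhaustive-grid estimators.
block_counts_at <- function(config, origins, edges) {
  sp <- sort(unique(config$species))
  idx <- match(config$species, sp) - 1L
  counts <- cpp_block_counts(config$positions, idx, length(sp),
                             config$box_edge, origins, edges)
  colnames(counts) <- sp
  counts
}

#' Sample particle counts in randomly placed blocks
#'
#' Draws `n_blocks` block origins uniformly over the box and counts the
#' particles of each species inside the cubic block of edge
#' `lambda * box_edge` anchored at each origin (with periodic wrapping).
#'
#' @param config an [configuration()].
#' @param lambda block-to-box edge ratio in (0, 1].
#' @param n_blocks number of random blocks.
#' @param seed integer seed for the origin placement.
#' @return A data frame with the origin coordinates and one count column
#'   per species, ordered as the sorted species labels.
#' @export
sample_block_counts <- function(config, lambda, n_blocks = 100L, seed) {
  stopifnot(inherits(config, "sba_config"))
  check_lambda(lambda)
  check_scalar(lambda, "lambda")
  check_scalar(n_blocks, "n_blocks", positive = TRUE, integer = TRUE)
  L0 <- config$box_edge
  origins <- with_seed(seed, matrix(runif(3L * n_blocks, 0, L0), ncol = 3L))
  counts <- block_counts_at(config, origins, rep(lambda * L0, n_blocks))
  out <- data.frame(lambda = lambda, frame_index = config$frame_index,
                    origin_x = origins[, 1L], origin_y = origins[, 2L],
                    origin_z = origins[, 3L])
  cbind(out, as.data.frame(counts))
}

#' Count particles over an exhaustive grid of block origins
#'
#' Deterministic counterpart of [sample_block_counts()] used to validate
#' the random-origin estimator: origins form a regular grid with the given
#' spacing along each axis.
#'
#' @inheritParams sample_block_counts
#' @param grid_spacing origin spacing in sigma; must not exceed
#'   `lambda * box_edge / 2` so the grid resolves the block size.
#' @return As [sample_block_counts()], without origin randomness.
#' @export
exhaustive_block_counts <- function(config, lambda, grid_spacing) {
  stopifnot(inherits(config, "sba_config"))
  check_lambda(lambda)
  check_scalar(lambda, "lambda")
  check_scalar(grid_spacing, "grid_spacing", positive = TRUE)
  L0 <- config$box_edge
  if (grid_spacing > lambda * L0 / 2) {
    stop("`grid_spacing` must be <= lambda * box_edge / 2", call. = FALSE)
  }
  ax <- seq(0, L0 - grid_spacing / 2, by = grid_spacing)
  if (length(ax)^3 > 2e6) {
    stop("origin grid too fine: more than 2e6 origins", call. = FALSE)
  }
  origins <- as.matrix(expand.grid(x = ax, y = ax, z = ax))
  counts <- block_counts_at(config, origins, rep(lambda * L0, nrow(origins)))
  out <- data.frame(lambda = lambda, frame_index = config$frame_index,
                    origin_x = origins[, 1L], origin_y = origins[, 2L],
                    origin_z = origins[, 3L])
  cbind(out, as.data.frame(counts))
}

# Per-frame block-count moment accumulation over a lambda grid.  Returns,
# for each frame, block-averaged first moments per species and second
# moments per (unordered) species pair, for every lambda.
accumulate_moments <- function(traj, lambda_grid, n_blocks, seed) {
  L0 <- traj$box_edge
  sp <- species_names(traj)
  s <- length(sp)
  nl <- length(lambda_grid)
  nf <- length(traj$frames)
  pair_i <- rep(seq_len(s), times = s)[rep(seq_len(s), times = s) <=
                                         rep(seq_len(s), each = s)]
  pair_j <- rep(seq_len(s), each = s)[rep(seq_len(s), times = s) <=
                                        rep(seq_len(s), each = s)]
  np <- length(pair_i)
  m1 <- array(0, dim = c(nf, nl, s))
  m2 <- array(0, dim = c(nf, nl, np))
  edges <- rep(lambda_grid * L0, each = n_blocks)
  lam_group <- rep(seq_len(nl), each = n_blocks)
  with_seed(seed, {
    for (f in seq_len(nf)) {
      origins <- matrix(runif(3L * n_blocks * nl, 0, L0), ncol = 3L)
      counts <- block_counts_at(traj$frames[[f]], origins, edges)
      for (l in seq_len(nl)) {
        cc <- counts[lam_group == l, , drop = FALSE]
        m1[f, l, ] <- colMeans(cc)
        for (p in seq_len(np)) {
          m2[f, l, p] <- mean(cc[, pair_i[p]] * cc[, pair_j[p]])
        }
      }
    }
  })
  list(m1 = m1, m2 = m2, species = sp, pair_i = pair_i, pair_j = pair_j,
       n_blocks = n_blocks)
}

# Delete-one-frame jackknife of a statistic computed from pooled frame
# means.  `fun(m1, m2)` maps pooled first/second moments to the statistic.
jackknife_ratio <- function(m1f, m2f, fun) {
  nf <- length(m1f[[1L]])
  est <- fun(vapply(m1f, mean, 0), vapply(m2f, mean, 0))
  if (nf < 2L) return(c(est, NA_real_))
  loo <- vapply(seq_len(nf), function(f) {
    fun(vapply(m1f, function(v) mean(v[-f]), 0),
        vapply(m2f, function(v) mean(v[-f]), 0))
  }, 0)
  se <- sqrt((nf - 1) / nf * sum((loo - mean(loo))^2))
  c(est, se)
}

#' Finite-size fluctuation curve of a trajectory
#'
#' Estimates the reduced finite-size compressibility
#' `chi_T(lambda) = (<N^2> - <N>^2) / <N>` of the total particle count in
#' cubic blocks of edge `lambda * L0`, over a grid of block sizes.  Moments
#' are pooled over all (frame, block) samples; standard errors come from a
#' frame-level jackknife.  For any closed (fixed-N) trajectory the value at
#' `lambda = 1` is exactly zero.
#'
#' @param traj an [trajectory()].
#' @param lambda_grid block-size ratios in (0, 1]; default 60
#'   logarithmically spaced values from `max(1/L0, 0.02)` (blocks no
#'   smaller than 1 sigma) to 1.
#' @param n_blocks_per_frame random blocks per frame (default 100).
#' @param seed integer seed for block placement.
#' @return An `sba_fluct_curve` data frame with columns `lambda`, `chi`,
#'   `stderr`, `n_blocks`, and metadata attributes `system` (N0, L0, rho,
#'   kT) and `seed`.
#' @export
fluctuation_curve <- function(traj, lambda_grid = NULL,
                              n_blocks_per_frame = 100L, seed) {
  stopifnot(inherits(traj, "sba_trajectory"))
  if (length(traj$frames) == 0L) stop("empty trajectory", call. = FALSE)
  if (is.null(lambda_grid)) lambda_grid <- default_lambda_grid(traj$box_edge)
  if (length(lambda_grid) == 0L) stop("empty lambda grid", call. = FALSE)
  check_lambda(lambda_grid)
  check_scalar(n_blocks_per_frame, "n_blocks_per_frame", positive = TRUE,
               integer = TRUE)
  acc <- accumulate_moments(traj, lambda_grid, n_blocks_per_frame, seed)
  s <- length(acc$species)
  np <- length(acc$pair_i)
  nf <- length(traj$frames)
  # total-count moments: sum species first moments; second moment of the
  # total is the sum over all ordered pairs
  nl <- length(lambda_grid)
  ord_mult <- ifelse(acc$pair_i == acc$pair_j, 1, 2)
  res <- vapply(seq_len(nl), function(l) {
    m1mat <- matrix(acc$m1[, l, ], nrow = nf, ncol = s)
    m2mat <- matrix(acc$m2[, l, ], nrow = nf, ncol = np)
    m1f <- list(tot = rowSums(m1mat))
    m2f <- list(tot2 = as.vector(m2mat %*% ord_mult))
    jackknife_ratio(m1f, m2f, function(m1, m2) {
      v <- m2[["tot2"]] - m1[["tot"]]^2
      if (m1[["tot"]] <= 0) return(NA_real_)
      v / m1[["tot"]]
    })
  }, c(0, 0))
  new_fluct_curve(
    lambda = lambda_grid, chi = res[1L, ], stderr = res[2L, ],
    n_blocks = rep(n_blocks_per_frame * length(traj$frames), nl),
    system = list(N0 = traj$n_particles, L0 = traj$box_edge,
                  rho = traj$density, kT = traj$temperature),
    seed = seed
  )
}

#' Finite-size Kirkwood-Buff integral curves of a trajectory
#'
#' For every unordered species pair (i, j) estimates the finite-size KBI
#' `G_ij(lambda) = V (<Ni Nj> - <Ni><Nj>) / (<Ni><Nj>) - delta_ij V / <Ni>`
#' with `V = (lambda * L0)^3`, from block counts in randomly placed cubic
#' subdomains.  The estimator is symmetric in (i, j) by construction, so
#' `G_AB = G_BA` exactly.  At `lambda = 1` the count fluctuations of a
#' closed system vanish, giving `G_ii = -1/rho_i` exactly (the
#' equation-derived closed-box limit; plotting conventions that show
#' `+1/rho_i` differ only by sign).
#'
#' @inheritParams fluctuation_curve
#' @param n_blocks_per_frame random blocks per frame (default 1000, the
#'   customary choice for mixtures).
#' @param lambda_grid default as in [fluctuation_curve()] but with blocks
#'   no smaller than 2 sigma.
#' @return An `sba_kbi_curves` data frame with columns `lambda`, `i`, `j`,
#'   `G`, `stderr`, `n_blocks`; attribute `rho` holds per-species number
#'   densities.
#' @export
kbi_curve <- function(traj, lambda_grid = NULL, n_blocks_per_frame = 1000L,
                      seed) {
  stopifnot(inherits(traj, "sba_trajectory"))
  if (length(traj$frames) == 0L) stop("empty trajectory", call. = FALSE)
  if (is.null(lambda_grid)) {
    lambda_grid <- default_lambda_grid(traj$box_edge, floor_sigma = 2)
  }
  if (length(lambda_grid) == 0L) stop("empty lambda grid", call. = FALSE)
  check_lambda(lambda_grid)
  check_scalar(n_blocks_per_frame, "n_blocks_per_frame", positive = TRUE,
               integer = TRUE)
  L0 <- traj$box_edge
  acc <- accumulate_moments(traj, lambda_grid, n_blocks_per_frame, seed)
  sp <- acc$species
  rho <- species_counts(traj) / L0^3
  nl <- length(lambda_grid)
  np <- length(acc$pair_i)
  rows <- vector("list", nl * np)
  k <- 0L
  for (l in seq_len(nl)) {
    V <- (lambda_grid[l] * L0)^3
    for (p in seq_len(np)) {
      i <- acc$pair_i[p]; j <- acc$pair_j[p]
      m1f <- list(ni = acc$m1[, l, i], nj = acc$m1[, l, j])
      m2f <- list(nij = acc$m2[, l, p])
      est <- jackknife_ratio(m1f, m2f, function(m1, m2) {
        cov <- m2[["nij"]] - m1[["ni"]] * m1[["nj"]]
        V * cov / (m1[["ni"]] * m1[["nj"]]) -
          (if (i == j) V / m1[["ni"]] else 0)
      })
      k <- k + 1L
      rows[[k]] <- data.frame(lambda = lambda_grid[l], i = sp[i], j = sp[j],
                              G = est[1L], stderr = est[2L],
                              n_blocks = n_blocks_per_frame *
                                length(traj$frames))
    }
  }
  out <- do.call(rbind, rows)
  structure(out, class = c("sba_kbi_curves", "data.frame"),
            rho = rho,
            system = list(N0 = traj$n_particles, L0 = L0, rho = traj$density,
                          kT = traj$temperature),
            seed = seed)
}

#' @export
print.sba_kbi_curves <- function(x, ...) {
  rho <- attr(x, "rho")
  cat(sprintf("<sba_kbi_curves> pairs: %s; rho = %s sigma^-3\n",
              paste(unique(paste0(x$i, x$j)), collapse = ", "),
              paste(sprintf("%s: %.4g", names(rho), rho), collapse = ", ")))
  print.data.frame(x, ...)
  invisible(x)
}

#' Radial distribution function of a trajectory
#'
#' Minimum-image pair histogram g(r), averaged over frames.  Used as a
#' diagnostic that pair correlations decay within a few sigma, which the
#' small-lambda fit window of the extrapolation step assumes.
#'
#' @param traj an [trajectory()].
#' @param r_max histogram range in sigma (must be < L0/2).
#' @param dr bin width in sigma.
#' @param frames indices of frames to use (default: up to 20 spread evenly).
#' @return Data frame with bin centres `r` and `g`.
#' @export
radial_distribution <- function(traj, r_max = NULL, dr = 0.05,
                                frames = NULL) {
  stopifnot(inherits(traj, "sba_trajectory"))
  L0 <- traj$box_edge
  if (is.null(r_max)) r_max <- 0.45 * L0
  if (r_max >= L0 / 2) stop("`r_max` must be < L0/2", call. = FALSE)
  if (is.null(frames)) {
    nf <- length(traj$frames)
    frames <- unique(round(seq(1, nf, length.out = min(20L, nf))))
  }
  breaks <- seq(0, r_max, by = dr)
  hist_tot <- numeric(length(breaks) - 1L)
  n <- traj$n_particles
  for (f in frames) {
    p <- traj$frames[[f]]$positions
    d <- numeric(0)
    for (ax in 1:3) {
      dd <- outer(p[, ax], p[, ax], "-")
      dd <- dd - L0 * round(dd / L0)
      d <- if (ax == 1) dd^2 else d + dd^2
    }
    r <- sqrt(d[upper.tri(d)])
    hist_tot <- hist_tot + tabulate(findInterval(r[r < r_max], breaks),
                                    nbins = length(breaks) - 1L)
  }
  rho <- traj$density
  centre <- breaks[-1L] - dr / 2
  shell <- 4 / 3 * pi * (breaks[-1L]^3 - breaks[-length(breaks)]^3)
  norm <- length(frames) * n / 2 * shell * rho
  data.frame(r = centre, g = hist_tot / norm)
}
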