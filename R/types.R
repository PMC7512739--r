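#' Construct a single-frame configuration
#'
#' A configuration is one snapshot of a periodic cubic box: wrapped particle
#' positions, per-particle species labels and the box edge, all in reduced
#' Lennard-Jones units (lengths in sigma).
#'
#' @param positions numeric matrix with one row per particle and columns
#'   x, y, z.  Coordinates are wrapped into `[0, box_edge)`.
#' @param species character vector of per-particle species labels (recycled
#'   if length 1).
#' @param box_edge cubic box edge `L0 > 0` in sigma.
#' @param frame_index non-negative integer frame label.
#' @return An object of class `sba_config`.
#' @export
configuration <- function(positions, species = "A", box_edge,
                          frame_index = 0L) {
  positions <- as.matrix(positions)
  if (ncol(positions) != 3L || !is.numeric(positions)) {
    stop("`positions` must be a numeric matrix with 3 columns", call. = FALSE)
  }
  check_scalar(box_edge, "box_edge", positive = TRUE)
  check_scalar(frame_index, "frame_index", nonneg = TRUE, integer = TRUE)
  n <- nrow(positions)
  if (n < 1L) stop("a configuration needs at least one particle", call. = FALSE)
  if (length(species) == 1L) species <- rep(species, n)
  if (length(species) != n) {
    stop("`species` must have one label per particle", call. = FALSE)
  }
  structure(
    list(
      positions = wrap_coords(unname(positions), box_edge),
      species = as.character(species),
      box_edge = box_edge,
      frame_index = as.integer(frame_index)
    ),
    class = "sba_config"
  )
}

#' @export
print.sba_config <- function(x, ...) {
  tab <- table(x$species)
  cat(sprintf(
    "<sba_config> %d particles (%s), box edge L0 = %g sigma, frame %d\n",
    nrow(x$positions),
    paste(sprintf("%s: %d", names(tab), tab), collapse = ", "),
    x$box_edge, x$frame_index
  ))
  invisible(x)
}

#' Assemble configurations into a trajectory
#'
#' All frames of a trajectory must share particle count, species multiset
#' and box edge (closed NVT system); violations are hard errors naming the
#' offending frame.
#'
#' @param frames list of [configuration()] objects.
#' @param temperature target temperature kBT in epsilon, or `NA`.
#' @param source free-text description of where the frames came from.
#' @param seed the seed used to generate the frames, or `NA`.
#' @return An object of class `sba_trajectory`.
#' @export
trajectory <- function(frames, temperature = NA_real_, source = "",
                       seed = NA_real_) {
  if (!is.list(frames) || length(frames) == 0L) {
    stop("`frames` must be a non-empty list of configurations", call. = FALSE)
  }
  ref <- frames[[1L]]
  if (!inherits(ref, "sba_config")) {
    stop("frames must be `sba_config` objects", call. = FALSE)
  }
  n0 <- nrow(ref$positions)
  sp0 <- sort(ref$species)
  for (k in seq_along(frames)) {
    fr <- frames[[k]]
    if (!inherits(fr, "sba_config")) {
      stop(sprintf("frame %d is not an `sba_config`", k), call. = FALSE)
    }
    if (nrow(fr$positions) != n0) {
      stop(sprintf(
        "frame %d has %d particles but frame 1 has %d (closed system)",
        k, nrow(fr$positions), n0
      ), call. = FALSE)
    }
    if (!identical(sort(fr$species), sp0)) {
      stop(sprintf("frame %d has a different species composition", k),
           call. = FALSE)
    }
    if (!isTRUE(all.equal(fr$box_edge, ref$box_edge))) {
      stop(sprintf("frame %d has a different box edge", k), call. = FALSE)
    }
  }
  structure(
    list(
      frames = frames,
      n_particles = n0,
      box_edge = ref$box_edge,
      density = n0 / ref$box_edge^3,
      temperature = temperature,
      source = source,
      seed = seed
    ),
    class = "sba_trajectory"
  )
}

#' @export
print.sba_trajectory <- function(x, ...) {
  cat(sprintf(
    "<sba_trajectory> %d frames, N0 = %d, L0 = %g sigma, rho = %.4g sigma^-3%s\n",
    length(x$frames), x$n_particles, x$box_edge, x$density,
    if (is.finite(x$temperature)) sprintf(", kBT = %g eps", x$temperature) else ""
  ))
  if (nzchar(x$source)) cat(" source:", x$source, "\n")
  invisible(x)
}

species_names <- function(traj) sort(unique(traj$frames[[1L]]$species))

species_counts <- function(traj) {
  tab <- table(traj$frames[[1L]]$species)
  setNames(as.integer(tab), names(tab))[species_names(traj)]
}
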