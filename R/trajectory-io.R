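# Extended-XYZ trajectory I/O and '#'-headered tabular formats.  Extended
# XYZ is the single canonical trajectory dialect here: human readable and
# box-aware.  Coordinates are stored wrapped into [0, L0) at full double
# precision ("%.17g", which round-trips doubles exactly).

#' Write a trajectory (or single configuration) to extended-XYZ
#'
#' One frame per block: particle count line, a comment line with
#' `Lattice="..." Properties=species:S:1:pos:R:3 box_edge=<L0>
#' frame_index=<k> wrapped=T` key-value pairs, then one `label x y z` row
#' per particle.
#'
#' @param x an [trajectory()] or [configuration()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_trajectory <- function(x, path) {
  if (inherits(x, "sba_config")) {
    x <- trajectory(list(x))
  }
  stopifnot(inherits(x, "sba_trajectory"))
  con <- file(path, open = "wt")
  on.exit(close(con))
  for (fr in x$frames) {
    L0 <- fmt_num(fr$box_edge)
    comment <- sprintf(
      'Lattice="%s 0 0 0 %s 0 0 0 %s" Properties=species:S:1:pos:R:3 box_edge=%s frame_index=%d wrapped=T%s',
      L0, L0, L0, L0, fr$frame_index,
      if (is.finite(x$temperature)) sprintf(" temperature=%s",
                                            fmt_num(x$temperature)) else ""
    )
    writeLines(c(as.character(nrow(fr$positions)), comment), con)
    writeLines(sprintf("%s %s %s %s", fr$species,
                       fmt_num(fr$positions[, 1L]),
                       fmt_num(fr$positions[, 2L]),
                       fmt_num(fr$positions[, 3L])), con)
  }
  invisible(path)
}

parse_xyz_comment <- function(line) {
  out <- list()
  # quoted values first (Lattice="...")
  m <- gregexpr('([A-Za-z_][A-Za-z0-9_]*)="([^"]*)"', line)
  for (tok in regmatches(line, m)[[1L]]) {
    key <- sub('=.*', '', tok)
    val <- sub('^[^"]*"', '', sub('"$', '', tok))
    out[[key]] <- val
  }
  rest <- gsub('([A-Za-z_][A-Za-z0-9_]*)="[^"]*"', '', line)
  m2 <- gregexpr('([A-Za-z_][A-Za-z0-9_]*)=([^\\s"]+)', rest, perl = TRUE)
  for (tok in regmatches(rest, m2)[[1L]]) {
    key <- sub('=.*', '', tok)
    out[[key]] <- sub('^[^=]*=', '', tok)
  }
  out
}

#' Read an extended-XYZ trajectory
#'
#' The box edge is taken from a `box_edge` key or from a cubic diagonal
#' `Lattice`; a frame without box metadata is a hard error because block
#' analysis is meaningless without `L0`.  Frames with inconsistent particle
#' counts are rejected, naming the frame.
#'
#' @param path file path.
#' @return An [trajectory()].
#' @export
read_trajectory <- function(path) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path),
                               call. = FALSE)
  lines <- readLines(path)
  lines <- lines[!(seq_along(lines) > suppressWarnings(
    max(which(nzchar(trimws(lines))), 0)))]
  frames <- list()
  i <- 1L
  k <- 0L
  temperature <- NA_real_
  while (i <= length(lines)) {
    n <- suppressWarnings(as.integer(trimws(lines[i])))
    if (is.na(n) || n < 1L) {
      stop(sprintf("line %d: expected a particle count, got '%s'",
                   i, lines[i]), call. = FALSE)
    }
    k <- k + 1L
    if (i + 1L + n > length(lines)) {
      stop(sprintf("frame %d: truncated file", k), call. = FALSE)
    }
    meta <- parse_xyz_comment(lines[i + 1L])
    L0 <- NA_real_
    if (!is.null(meta$box_edge)) {
      L0 <- as.numeric(meta$box_edge)
    } else if (!is.null(meta$Lattice)) {
      lat <- as.numeric(strsplit(trimws(meta$Lattice), "\\s+")[[1L]])
      if (length(lat) == 9L && lat[1L] == lat[5L] && lat[5L] == lat[9L] &&
          all(lat[-c(1L, 5L, 9L)] == 0)) {
        L0 <- lat[1L]
      } else {
        stop(sprintf("frame %d: only cubic (diagonal) lattices are supported",
                     k), call. = FALSE)
      }
    }
    if (!is.finite(L0)) {
      stop(sprintf(
        "frame %d: missing box metadata (box_edge or cubic Lattice)", k
      ), call. = FALSE)
    }
    if (!is.null(meta$temperature)) temperature <- as.numeric(meta$temperature)
    rows <- strsplit(trimws(lines[(i + 2L):(i + 1L + n)]), "\\s+")
    bad <- which(lengths(rows) < 4L)
    if (length(bad)) {
      stop(sprintf("frame %d: malformed particle row %d", k, bad[1L]),
           call. = FALSE)
    }
    tab <- matrix(unlist(lapply(rows, `[`, 1:4)), ncol = 4L, byrow = TRUE)
    pos <- matrix(as.numeric(tab[, 2:4]), ncol = 3L)
    if (anyNA(pos)) {
      stop(sprintf("frame %d: non-numeric coordinates", k), call. = FALSE)
    }
    fi <- if (!is.null(meta$frame_index)) as.integer(meta$frame_index) else
      k - 1L
    frames[[k]] <- configuration(pos, species = tab[, 1L], box_edge = L0,
                                 frame_index = fi)
    i <- i + 2L + n
  }
  if (length(frames) == 0L) stop("no frames found", call. = FALSE)
  trajectory(frames, temperature = temperature,
             source = sprintf("read from %s", path))
}

# ---- '#'-headered tables ---------------------------------------------------

table_type <- function(x) {
  if (inherits(x, "sba_fluct_curve")) "fluctuation_curve"
  else if (inherits(x, "sba_kbi_curves")) "kbi_curves"
  else if (inherits(x, "sba_thermo")) "thermo_table"
  else if (inherits(x, "sba_chempot")) "chempot_curve"
  else "table"
}

#' Write an analysis table with a commented metadata header
#'
#' Serialises fluctuation curves, KBI curve sets, thermodynamic scans and
#' chemical-potential curves as whitespace-separated text with `#`-prefixed
#' `key: value` header lines (units, system metadata, seeds, fit windows)
#' at full double precision.
#'
#' @param x a data-frame-based package object (e.g. from
#'   [fluctuation_curve()]).
#' @param path output file path.
#' @param extra named list of additional header fields.
#' @return `path`, invisibly.
#' @export
write_table <- function(x, path, extra = list()) {
  if (!is.data.frame(x) || nrow(x) == 0L) {
    stop("refusing to write an empty table", call. = FALSE)
  }
  hdr <- c(type = table_type(x))
  sys <- attr(x, "system")
  if (!is.null(sys)) {
    for (k in names(sys)) {
      if (length(sys[[k]]) == 1L && is.finite(sys[[k]])) {
        hdr[k] <- fmt_num(as.numeric(sys[[k]]))
      }
    }
  }
  rho <- attr(x, "rho")
  if (!is.null(rho)) {
    hdr["rho_species"] <- paste(sprintf("%s=%s", names(rho), fmt_num(rho)),
                                collapse = " ")
  }
  if (!is.null(attr(x, "seed")) && is.finite(attr(x, "seed"))) {
    hdr["seed"] <- fmt_num(attr(x, "seed"))
  }
  if (!is.null(attr(x, "window"))) {
    hdr["fit_window"] <- paste(fmt_num(attr(x, "window")), collapse = " ")
  }
  hdr["units"] <- "reduced LJ (length sigma, energy eps); coordinates wrapped to [0, L0)"
  for (k in names(extra)) hdr[k] <- as.character(extra[[k]])
  con <- file(path, open = "wt")
  on.exit(close(con))
  writeLines(sprintf("# %s: %s", names(hdr), hdr), con)
  writeLines(paste("#", paste(names(x), collapse = " ")), con)
  cols <- lapply(x, function(col) {
    if (is.numeric(col)) fmt_num(col) else as.character(col)
  })
  writeLines(do.call(paste, cols), con)
  invisible(path)
}

#' Read a table written by [write_table()]
#'
#' @param path file path.
#' @return A data frame with the header fields in attribute `header`; the
#'   package class implied by the `type` field is restored.
#' @export
read_sba_table <- function(path) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path),
                               call. = FALSE)
  lines <- readLines(path)
  hdr_lines <- grep("^#", lines, value = TRUE)
  data_lines <- grep("^#", lines, invert = TRUE, value = TRUE)
  data_lines <- data_lines[nzchar(trimws(data_lines))]
  kv <- hdr_lines[grepl("^# [A-Za-z_][A-Za-z0-9_]*:", hdr_lines)]
  header <- list()
  for (ln in kv) {
    key <- sub("^# ([A-Za-z_][A-Za-z0-9_]*):.*$", "\\1", ln)
    header[[key]] <- sub("^# [A-Za-z_][A-Za-z0-9_]*: ?", "", ln)
  }
  col_line <- hdr_lines[length(hdr_lines)]
  cols <- strsplit(trimws(sub("^#", "", col_line)), "\\s+")[[1L]]
  if (length(data_lines) == 0L) stop("table has no data rows", call. = FALSE)
  parts <- strsplit(trimws(data_lines), "\\s+")
  if (any(lengths(parts) != length(cols))) {
    stop("malformed table: row/column mismatch", call. = FALSE)
  }
  mat <- matrix(unlist(parts), ncol = length(cols), byrow = TRUE)
  df <- as.data.frame(mat, stringsAsFactors = FALSE)
  names(df) <- cols
  for (j in seq_along(df)) {
    num <- suppressWarnings(as.numeric(df[[j]]))
    if (!anyNA(num[!(df[[j]] %in% c("NA", "NaN"))])) df[[j]] <- num
  }
  cls <- switch(header$type %||% "table",
                fluctuation_curve = c("sba_fluct_curve", "data.frame"),
                kbi_curves = c("sba_kbi_curves", "data.frame"),
                thermo_table = c("sba_thermo", "data.frame"),
                chempot_curve = c("sba_chempot", "data.frame"),
                "data.frame")
  class(df) <- cls
  attr(df, "header") <- header
  sysk <- intersect(c("N0", "L0", "rho", "kT"), names(header))
  if (length(sysk)) {
    attr(df, "system") <- lapply(setNames(header[sysk], sysk), as.numeric)
  }
  df
}

`%||%` <- function(a, b) if (is.null(a)) b else a
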