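#' Molecular configuration of a nanotube wall
#'
#' A `molecule_frame` holds one configuration of dye molecules: Cartesian
#' positions (in Angstrom), unit transition-dipole vectors, the tube (long)
#' axis, the largest box dimension used for feature regularization, and a
#' wall tag (`"IW"` inner wall / `"OW"` outer wall) per molecule.
#'
#' The aggregate is invariant under inversion of the chromophore core, so the
#' sign of each transition dipole is a convention: dipoles are flipped at
#' construction so that their component along the tube axis is non-negative.
#' Dipoles supplied with non-unit length are renormalized; zero-length
#' dipoles are an error.
#'
#' @param positions numeric N x 3 matrix, Angstrom.
#' @param dipoles numeric N x 3 matrix of transition-dipole directions.
#' @param axis tube axis, length-3 numeric; normalized internally.
#' @param box_max_dim largest box dimension in Angstrom; defaults to the
#'   largest coordinate extent of `positions` (and is never allowed below it).
#' @param wall character vector of `"IW"`/`"OW"` tags, recycled if length 1.
#' @param patch optional integer patch labels (e.g. ground truth from a
#'   generator); `NA` for unassigned molecules.
#' @return An object of class `molecule_frame`.
#' @export
molecule_frame <- function(positions, dipoles, axis = c(0, 0, 1),
                           box_max_dim = NULL, wall = "IW", patch = NULL) {
  positions <- as.matrix(positions)
  dipoles <- as.matrix(dipoles)
  storage.mode(positions) <- "double"
  storage.mode(dipoles) <- "double"
  n <- nrow(positions)
  if (ncol(positions) != 3L || ncol(dipoles) != 3L)
    stop("positions and dipoles must have 3 columns")
  if (nrow(dipoles) != n)
    stop("positions and dipoles must have the same number of rows")
  if (!all(is.finite(positions)) || !all(is.finite(dipoles)))
    stop("positions and dipoles must be finite")
  axis <- unit(as.numeric(axis))

  nrm <- row_norms(dipoles)
  if (any(nrm < 1e-12))
    stop("zero-length transition dipole(s) at row(s): ",
         paste(which(nrm < 1e-12), collapse = ", "))
  dipoles <- dipoles / nrm
  # sign convention: positive direction with respect to the tubular axis
  ax <- drop(dipoles %*% axis)
  flip <- ax < 0
  if (any(flip)) dipoles[flip, ] <- -dipoles[flip, , drop = FALSE]

  extent <- if (n > 0) max(apply(positions, 2, function(x) diff(range(x))), 0) else 0
  box_max_dim <- max(box_max_dim %||% extent, extent)

  wall <- rep_len(as.character(wall), n)
  if (!all(wall %in% c("IW", "OW")))
    stop("wall tags must be 'IW' or 'OW'")
  if (!is.null(patch)) patch <- rep_len(as.integer(patch), n)

  structure(
    list(positions = positions, dipoles = dipoles, axis = axis,
         box_max_dim = box_max_dim, wall = wall, patch = patch),
    class = "molecule_frame")
}

#' @export
print.molecule_frame <- function(x, ...) {
  cat(sprintf("molecule_frame: %d molecules (%d IW, %d OW)\n",
              n_molecules(x), sum(x$wall == "IW"), sum(x$wall == "OW")))
  cat(sprintf("  axis: [%.3f, %.3f, %.3f], box_max_dim: %.1f A\n",
              x$axis[1], x$axis[2], x$axis[3], x$box_max_dim))
  cat(sprintf("  axial order parameter f = %.3f\n", axial_order(x)))
  invisible(x)
}

#' Number of molecules in a frame
#' @param frame a `molecule_frame`.
#' @return integer count.
#' @export
n_molecules <- function(frame) nrow(frame$positions)

#' Global axial orientational order parameter
#'
#' The mean squared projection of the unit transition dipoles on the tube
#' axis, f = mean((d . axis)^2): 1 for perfectly axial dipoles, 1/3 for an
#' isotropic orientation distribution.
#'
#' @param frame a `molecule_frame`.
#' @return numeric scalar in \[0, 1\] (`NaN` for an empty frame).
#' @export
axial_order <- function(frame) {
  if (n_molecules(frame) == 0L) return(NaN)
  mean(drop(frame$dipoles %*% frame$axis)^2)
}

#' Subset a frame by wall or index
#'
#' @param frame a `molecule_frame`.
#' @param wall keep only molecules with this wall tag (`"IW"` or `"OW"`).
#' @param idx integer or logical index of molecules to keep.
#' @return A `molecule_frame` with the selected molecules; `box_max_dim` and
#'   `axis` are inherited from the input.
#' @export
subset_frame <- function(frame, wall = NULL, idx = NULL) {
  keep <- rep(TRUE, n_molecules(frame))
  if (!is.null(wall)) keep <- keep & frame$wall %in% wall
  if (!is.null(idx)) {
    sel <- rep(FALSE, n_molecules(frame))
    sel[idx] <- TRUE
    keep <- keep & sel
  }
  molecule_frame(frame$positions[keep, , drop = FALSE],
                 frame$dipoles[keep, , drop = FALSE],
                 axis = frame$axis, box_max_dim = frame$box_max_dim,
                 wall = frame$wall[keep],
                 patch = if (is.null(frame$patch)) NULL else frame$patch[keep])
}

#' Concatenate two frames
#'
#' @param a,b `molecule_frame` objects sharing the same axis (checked to
#'   1e-9).
#' @return Combined `molecule_frame`; `box_max_dim` is recomputed as the
#'   maximum of the inputs and the combined extent.
#' @export
merge_frames <- function(a, b) {
  if (max(abs(a$axis - b$axis)) > 1e-9) stop("frames have different axes")
  pa <- if (is.null(a$patch)) rep(NA_integer_, n_molecules(a)) else a$patch
  pb <- if (is.null(b$patch)) rep(NA_integer_, n_molecules(b)) else b$patch
  patch <- c(pa, pb)
  if (all(is.na(patch))) patch <- NULL
  molecule_frame(rbind(a$positions, b$positions),
                 rbind(a$dipoles, b$dipoles),
                 axis = a$axis,
                 box_max_dim = max(a$box_max_dim, b$box_max_dim),
                 wall = c(a$wall, b$wall), patch = patch)
}

#' Frame with random positions and isotropic dipole orientations
#'
#' Generates `n` molecules with positions uniform in a cubic box and dipole
#' directions drawn independently and uniformly on the sphere (then mapped to
#' the axial hemisphere by the frame sign convention, which leaves all
#' quadratic observables such as LD unchanged).
#'
#' @param n number of molecules.
#' @param box box edge length in Angstrom.
#' @param axis tube axis.
#' @param seed integer seed; `NULL` uses the current RNG stream.
#' @return A `molecule_frame`.
#' @export
random_frame <- function(n, box = 1000, axis = c(0, 0, 1), seed = NULL) {
  with_seed(seed, {
    pos <- matrix(stats::runif(3 * n, 0, box), ncol = 3)
    d <- matrix(stats::rnorm(3 * n), ncol = 3)
    molecule_frame(pos, d, axis = axis)
  })
}

#' Read a molecule frame from a 7-column text table
#'
#' The format is one molecule per row: `id x y z dx dy dz`, whitespace or
#' tab separated, with `#` comment lines. Positions are in Angstrom; dipole
#' vectors are renormalized to unit length on input.
#'
#' @param path file path.
#' @param axis tube axis to attach to the frame.
#' @param wall wall tag(s) for the molecules.
#' @return A `molecule_frame`.
#' @export
read_frame <- function(path, axis = c(0, 0, 1), wall = "IW") {
  lines <- readLines(path)
  keep <- !grepl("^\\s*(#|$)", lines)
  rows <- which(keep)
  if (length(rows) == 0L) stop("no data rows in ", path)
  parsed <- lapply(rows, function(i) {
    toks <- strsplit(trimws(lines[i]), "\\s+")[[1]]
    if (length(toks) != 7L)
      stop(sprintf("parse error at line %d of %s: expected 7 columns, got %d",
                   i, path, length(toks)))
    vals <- suppressWarnings(as.numeric(toks))
    if (anyNA(vals))
      stop(sprintf("parse error at line %d of %s: non-numeric field", i, path))
    vals
  })
  m <- do.call(rbind, parsed)
  d <- m[, 5:7, drop = FALSE]
  if (any(row_norms(d) < 1e-12)) {
    bad <- rows[row_norms(d) < 1e-12][1]
    stop(sprintf("zero-length dipole at line %d of %s", bad, path))
  }
  molecule_frame(m[, 2:4, drop = FALSE], d, axis = axis, wall = wall)
}

#' Write a molecule frame to the 7-column text format
#'
#' @param frame a `molecule_frame`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_frame <- function(frame, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("# id x y z dx dy dz  (positions in Angstrom, unit dipoles)", con)
  n <- n_molecules(frame)
  for (i in seq_len(n)) {
    writeLines(sprintf("%d %.6f %.6f %.6f %.8f %.8f %.8f", i,
                       frame$positions[i, 1], frame$positions[i, 2],
                       frame$positions[i, 3], frame$dipoles[i, 1],
                       frame$dipoles[i, 2], frame$dipoles[i, 3]), con)
  }
  invisible(path)
}
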