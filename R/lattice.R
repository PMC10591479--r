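#' Planar wall lattice specification
#'
#' Describes the two-dimensional packing motif of the dye molecules in a
#' wall: a planar unit cell (`basis_a`, `basis_b`, in nm), a motif of
#' fractional offsets within the cell, and the in-plane angle of the
#' transition dipole relative to `basis_a`. The default is a staggered
#' "brickwork" motif with two molecules per cell. The numeric lattice
#' constants are configurable placeholders chosen to give a realistic
#' molecular areal density; the dipole angle default makes dipoles mostly
#' axial once the sheet is rolled with `basis_a` as the wrapping direction.
#'
#' @param basis_a,basis_b length-2 numeric lattice vectors in nm; must be
#'   linearly independent. `basis_a` is the direction wrapped around the
#'   cylinder circumference by [roll_to_cylinder()].
#' @param dipole_angle in-plane dipole angle in radians, measured from
#'   `basis_a` towards `basis_b`.
#' @param motif_offsets list of length-2 fractional offsets within the cell.
#' @return An object of class `lattice_spec`.
#' @export
lattice_spec <- function(basis_a = c(0.7, 0), basis_b = c(0, 2.1),
                         dipole_angle = 1.45,
                         motif_offsets = list(c(0, 0), c(0.5, 0.5))) {
  basis_a <- as.numeric(basis_a); basis_b <- as.numeric(basis_b)
  if (length(basis_a) != 2L || length(basis_b) != 2L)
    stop("basis vectors must be 2D")
  det <- basis_a[1] * basis_b[2] - basis_a[2] * basis_b[1]
  if (abs(det) < 1e-12) stop("invalid lattice spec: degenerate basis vectors")
  if (length(motif_offsets) < 1L) stop("motif_offsets must have length >= 1")
  motif_offsets <- lapply(motif_offsets, as.numeric)
  if (any(vapply(motif_offsets, length, 1L) != 2L))
    stop("motif offsets must be 2D fractional coordinates")
  structure(list(basis_a = basis_a, basis_b = basis_b,
                 dipole_angle = wrap_angle(dipole_angle),
                 molecules_per_cell = length(motif_offsets),
                 motif_offsets = motif_offsets),
            class = "lattice_spec")
}

#' Tube geometry specification
#'
#' Inner- and outer-wall radii default to the cryo-TEM values for
#' double-walled C8S3 nanotubes (inner diameter 6.9 nm, outer 13.5 nm).
#'
#' @param radius_iw,radius_ow wall radii in nm, `0 < radius_iw < radius_ow`.
#' @param length tube segment length in nm.
#' @param axis tube axis direction (normalized internally).
#' @return An object of class `tube_spec`.
#' @export
tube_spec <- function(radius_iw = 3.45, radius_ow = 6.75, length = 20,
                      axis = c(0, 0, 1)) {
  if (!(radius_iw > 0 && radius_ow > radius_iw))
    stop("require 0 < radius_iw < radius_ow")
  if (length <= 0) stop("tube length must be positive")
  structure(list(radius_iw = radius_iw, radius_ow = radius_ow,
                 length = length, axis = unit(as.numeric(axis))),
            class = "tube_spec")
}

#' Build a planar lattice sheet
#'
#' Tiles `n_a` x `n_b` unit cells of a [lattice_spec()] into a planar sheet.
#' Positions are in nm in the lattice plane; every molecule carries the
#' spec's in-plane dipole angle.
#'
#' @param spec a `lattice_spec`.
#' @param n_a,n_b number of cells along `basis_a` / `basis_b` (>= 1).
#' @return An object of class `lattice_sheet`: 2D positions (nm), in-plane
#'   dipole angles, and the generating spec and cell counts.
#' @export
build_lattice <- function(spec, n_a, n_b) {
  stopifnot(inherits(spec, "lattice_spec"))
  n_a <- as.integer(n_a); n_b <- as.integer(n_b)
  if (n_a < 1L || n_b < 1L) stop("n_a and n_b must be >= 1")
  B <- rbind(spec$basis_a, spec$basis_b)  # rows: lattice vectors
  cells <- as.matrix(expand.grid(ia = seq_len(n_a) - 1L, ib = seq_len(n_b) - 1L))
  pos <- do.call(rbind, lapply(spec$motif_offsets, function(off) {
    (cells[, "ia"] + off[1]) %o% spec$basis_a +
      (cells[, "ib"] + off[2]) %o% spec$basis_b
  }))
  # order molecules cell-by-cell for reproducible indexing
  ord <- order(rep(seq_len(nrow(cells)), times = spec$molecules_per_cell),
               rep(seq_along(spec$motif_offsets), each = nrow(cells)))
  pos <- pos[ord, , drop = FALSE]
  structure(list(positions = pos,
                 angles = rep(spec$dipole_angle, nrow(pos)),
                 spec = spec, n_a = n_a, n_b = n_b),
            class = "lattice_sheet")
}

# Orthonormal basis (e1, e2) spanning the plane perpendicular to axis.
axis_basis <- function(axis) {
  e1 <- perp_vector(axis)
  e2 <- c(axis[2] * e1[3] - axis[3] * e1[2],
          axis[3] * e1[1] - axis[1] * e1[3],
          axis[1] * e1[2] - axis[2] * e1[1])
  list(e1 = e1, e2 = unit(e2))
}

# In-surface angle -> 3D tangent-plane dipole at azimuth phi.
# theta is measured from the circumferential tangent towards the tube axis,
# so theta = pi/2 is perfectly axial.
surface_dipole <- function(theta, phi, axis) {
  theta <- rep_len(theta, length(phi))
  ab <- axis_basis(axis)
  tangent <- -sin(phi) %o% ab$e1 + cos(phi) %o% ab$e2
  cos(theta) * tangent + sin(theta) %o% axis
}

#' Roll a planar sheet into a cylinder
#'
#' Wraps the sheet around a cylinder of the given radius: the direction of
#' `n_a * basis_a` becomes the circumference and the perpendicular in-plane
#' direction becomes the tube axis. The wrapped width is rescaled to exactly
#' `2*pi*radius`; if it differs from that circumference by more than one
#' lattice constant `|basis_a|` a warning is issued. In-plane dipole angles
#' are mapped to 3D tangent-plane vectors; the frame constructor then flips
#' each dipole, if needed, so its axial component is non-negative.
#'
#' @param sheet a `lattice_sheet` from [build_lattice()].
#' @param radius cylinder radius in nm (> 0).
#' @param axis tube axis direction.
#' @param wall wall tag for the resulting molecules (`"IW"` or `"OW"`).
#' @return A [molecule_frame()] with positions in Angstrom, all at distance
#'   `radius` from the axis.
#' @export
roll_to_cylinder <- function(sheet, radius, axis = c(0, 0, 1), wall = "IW") {
  stopifnot(inherits(sheet, "lattice_sheet"))
  if (radius <= 0) stop("radius must be positive")
  axis <- unit(as.numeric(axis))
  spec <- sheet$spec

  wrap <- sheet$n_a * spec$basis_a            # wrapping vector, nm
  width <- sqrt(sum(wrap^2))
  circumference <- 2 * pi * radius
  if (abs(width - circumference) > sqrt(sum(spec$basis_a^2)))
    warning(sprintf(
      "sheet width %.3f nm differs from circumference %.3f nm by more than one lattice constant; rescaling",
      width, circumference))
  u1 <- wrap / width                          # rolled (circumferential) dir
  u2 <- c(-u1[2], u1[1])                      # axial dir in the sheet plane

  s <- drop(sheet$positions %*% u1) * (circumference / width)
  h <- drop(sheet$positions %*% u2)
  phi <- 2 * pi * s / circumference

  ab <- axis_basis(axis)
  pos_nm <- radius * (cos(phi) %o% ab$e1 + sin(phi) %o% ab$e2) + h %o% axis

  # in-plane dipole (relative to basis_a) decomposed on (u1, u2); the u1
  # component rides the local circumferential tangent after rolling
  a_hat <- unit(spec$basis_a)
  d2 <- cbind(cos(sheet$angles), sin(sheet$angles))  # in basis (a_hat, a_hat^perp)
  R <- cbind(c(a_hat[1], a_hat[2]), c(-a_hat[2], a_hat[1]))
  d2 <- d2 %*% t(R)                            # sheet x-y components
  dR <- d2[, 1] * u1[1] + d2[, 2] * u1[2]
  dA <- d2[, 1] * u2[1] + d2[, 2] * u2[2]
  tangent <- -sin(phi) %o% ab$e1 + cos(phi) %o% ab$e2
  dip <- dR * tangent + dA %o% axis

  molecule_frame(10 * pos_nm, dip, axis = axis, wall = wall)
}
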