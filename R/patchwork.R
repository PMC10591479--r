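# Outer-wall site scaffold: lattice sites rolled onto the outer cylinder,
# with azimuths and a nearest-neighbour adjacency used by the patchwork and
# assembly generators.
ow_sites <- function(tube, lattice) {
  stopifnot(inherits(tube, "tube_spec"), inherits(lattice, "lattice_spec"))
  a_len <- sqrt(sum(lattice$basis_a^2))
  u2 <- c(-lattice$basis_a[2], lattice$basis_a[1]) / a_len
  b_axial <- abs(sum(lattice$basis_b * u2))
  n_a <- max(3L, round(2 * pi * tube$radius_ow / a_len))
  n_b <- max(1L, floor(tube$length / b_axial))
  sheet <- build_lattice(lattice, n_a, n_b)
  frame <- suppressWarnings(
    roll_to_cylinder(sheet, tube$radius_ow, axis = tube$axis, wall = "OW"))
  ab <- axis_basis(tube$axis)
  phi <- atan2(drop(frame$positions %*% ab$e2), drop(frame$positions %*% ab$e1))
  d <- as.matrix(stats::dist(frame$positions))
  diag(d) <- Inf
  # include the staggered (brick-diagonal) neighbours, not just the stacking
  # direction, so the adjacency graph of a full wall is connected
  cutoff <- 1.6 * min(d)
  nb <- lapply(seq_len(nrow(d)), function(i) which(d[i, ] <= cutoff))
  list(positions = frame$positions, phi = phi, neighbours = nb,
       n = nrow(frame$positions), axis = tube$axis)
}

# Resolve steric clashes at patch boundaries: where the extended-dipole
# charges (+- l/2 along the dipole) of two molecules come closer than
# `clearance` (Angstrom), the higher-index molecule is pushed radially
# outward in 0.7 A steps, emulating the off-lattice buckling of molecules
# at a domain wall. Deterministic; on-lattice ordered walls are untouched.
declash_positions <- function(pos, dip, axis, l = 7, clearance = 0.7,
                              max_iter = 8L) {
  n <- nrow(pos)
  if (n < 2L) return(pos)
  for (iter in seq_len(max_iter)) {
    plus <- pos + (l / 2) * dip
    minus <- pos - (l / 2) * dip
    gap <- pmin(cross_dist(plus, plus), cross_dist(plus, minus),
                cross_dist(minus, plus), cross_dist(minus, minus))
    gap[lower.tri(gap, diag = TRUE)] <- Inf
    bad <- which(gap < clearance, arr.ind = TRUE)
    if (nrow(bad) == 0L) break
    move <- unique(pmax(bad[, 1], bad[, 2]))
    radial <- pos[move, , drop = FALSE] -
      (pos[move, , drop = FALSE] %*% axis) %*% t(axis)
    radial <- radial / pmax(sqrt(rowSums(radial^2)), 1e-9)
    pos[move, ] <- pos[move, , drop = FALSE] + 0.7 * radial
  }
  pos
}

# Frame for the occupied outer-wall sites, dipoles set from the in-surface
# angle of each site's patch.
ow_frame <- function(sites, occ, lab, angles, axis) {
  idx <- which(occ)
  if (length(idx) == 0L)
    return(NULL)
  theta <- angles[lab[idx]]
  dip <- surface_dipole(theta, sites$phi[idx], axis)
  pos <- declash_positions(sites$positions[idx, , drop = FALSE], dip, axis)
  molecule_frame(pos, dip, axis = axis, wall = "OW", patch = lab[idx])
}

#' Generate a patchwork outer wall on top of an inner-wall template
#'
#' Places `n_ow` molecules on the outer cylinder in `n_patches` spatially
#' contiguous groups. All molecules of one patch share one random in-surface
#' dipole angle; angles are independent and uniform across patches. Sites
#' are lattice sites of the rolled outer wall, so no two outer-wall
#' molecules are closer than the lattice spacing.
#'
#' @param iw inner-wall `molecule_frame` (used as the template; returned
#'   unchanged when `n_ow = 0`).
#' @param tube a [tube_spec()].
#' @param lattice a [lattice_spec()] for the outer wall.
#' @param n_ow number of outer-wall molecules (>= 0).
#' @param n_patches number of patches (>= 1).
#' @param seed integer seed (`NULL` = current RNG stream).
#' @return A `molecule_frame` combining the inner wall and the patchwork
#'   outer wall; outer-wall molecules carry their generating patch label in
#'   `$patch`.
#' @export
generate_patchwork <- function(iw, tube, lattice, n_ow, n_patches = 1L,
                               seed = NULL) {
  if (n_ow < 0) stop("n_ow must be >= 0")
  if (n_patches < 1) stop("n_patches must be >= 1")
  if (n_ow == 0L) return(iw)
  sites <- ow_sites(tube, lattice)
  if (n_ow > sites$n)
    stop(sprintf("n_ow = %d exceeds outer-surface capacity (%d sites)",
                 n_ow, sites$n))
  n_patches <- min(as.integer(n_patches), n_ow)
  with_seed(seed, {
    seeds <- sample.int(sites$n, n_patches)
    angles <- stats::runif(n_patches, 0, 2 * pi)
    lab <- integer(sites$n)                     # 0 = unassigned
    lab[seeds] <- seq_len(n_patches)
    frontiers <- as.list(seeds)
    placed <- n_patches
    # balanced multi-source breadth-first growth
    while (placed < n_ow) {
      grew <- FALSE
      for (p in seq_len(n_patches)) {
        if (placed >= n_ow) break
        fr <- frontiers[[p]]
        while (length(fr) > 0L) {
          cand <- setdiff(sites$neighbours[[fr[1]]], which(lab > 0L))
          if (length(cand) > 0L) {
            s <- cand[1]
            lab[s] <- p
            frontiers[[p]] <- c(fr, s)
            placed <- placed + 1L
            grew <- TRUE
            break
          }
          fr <- fr[-1]
          frontiers[[p]] <- fr
        }
      }
      if (!grew) {
        # leftover sites disconnected from all frontiers: attach each to the
        # patch with the nearest seed (contiguity no longer guaranteed)
        free <- which(lab == 0L)
        need <- n_ow - placed
        d <- cross_dist(sites$positions[free, , drop = FALSE],
                        sites$positions[seeds, , drop = FALSE])
        pick <- order(apply(d, 1, min))[seq_len(need)]
        lab[free[pick]] <- apply(d[pick, , drop = FALSE], 1, which.min)
        placed <- n_ow
      }
    }
    ow <- ow_frame(sites, lab > 0L, lab, angles, tube$axis)
    merge_frames(iw, ow)
  })
}

#' Parameters of the stochastic outer-wall assembly model
#'
#' A deliberately simple lattice adsorption model that emulates the
#' statistical structure of outer-wall recovery: molecules adsorb on empty
#' outer-wall lattice sites at a constant per-site rate, join an adjacent
#' patch if one exists (adopting its orientation) or nucleate a new patch
#' with a random orientation, and whole patches reorient to the preferred
#' lattice orientation at a rate that scales inversely with patch size.
#' Adjacent patches with equal orientation merge. The rules are invented
#' stand-ins for the microscopic dynamics and are isolated in this module.
#'
#' @param adsorption_rate per-step occupation probability of an empty site.
#' @param nucleation_orientation_spread radians; new patch angles are drawn
#'   uniformly within this half-width around the preferred lattice angle
#'   (`pi` gives fully random orientations).
#' @param patch_reorientation_rate per-step reorientation probability of a
#'   patch of size 1; a patch of size s reorients with probability
#'   `min(1, rate / s)`.
#' @param n_steps number of time steps (>= 1).
#' @param n_sites optionally restrict the outer wall to the first `n_sites`
#'   lattice sites (default: full capacity).
#' @param seed integer seed.
#' @return An object of class `assembly_params`.
#' @export
assembly_params <- function(adsorption_rate = 0.08,
                            nucleation_orientation_spread = pi,
                            patch_reorientation_rate = 0.2,
                            n_steps = 30L, n_sites = NULL, seed = 1L) {
  if (adsorption_rate < 0 || patch_reorientation_rate < 0 ||
      nucleation_orientation_spread < 0)
    stop("rates and spreads must be >= 0")
  if (n_steps < 1) stop("n_steps must be >= 1")
  structure(list(adsorption_rate = adsorption_rate,
                 nucleation_orientation_spread = nucleation_orientation_spread,
                 patch_reorientation_rate = patch_reorientation_rate,
                 n_steps = as.integer(n_steps),
                 n_sites = if (is.null(n_sites)) NULL else as.integer(n_sites),
                 seed = seed),
            class = "assembly_params")
}

#' Simulate outer-wall recovery as a patchwork
#'
#' Runs the stochastic adsorption/nucleation/reorientation model of
#' [assembly_params()] on the outer-wall lattice of `tube` and returns the
#' time-ordered list of frames (inner wall plus occupied outer-wall sites),
#' starting from the bare inner wall at t = 0. Occupancy is non-decreasing
#' in time; runs are bit-reproducible from the seed.
#'
#' @param iw inner-wall `molecule_frame`.
#' @param tube a [tube_spec()].
#' @param lattice a [lattice_spec()] for the outer wall; its `dipole_angle`
#'   is the preferred orientation patches eventually adopt.
#' @param params an [assembly_params()].
#' @return List of `molecule_frame`s of length `n_steps + 1`, with an
#'   attribute `t = 0:n_steps`.
#' @export
simulate_assembly <- function(iw, tube, lattice, params) {
  stopifnot(inherits(params, "assembly_params"))
  sites <- ow_sites(tube, lattice)
  n <- if (is.null(params$n_sites)) sites$n else min(params$n_sites, sites$n)
  active <- seq_len(n)
  theta0 <- lattice$dipole_angle

  occ <- logical(sites$n)
  lab <- integer(sites$n)
  angles <- numeric(0)
  frames <- vector("list", params$n_steps + 1L)
  frames[[1]] <- iw

  with_seed(params$seed, {
    for (step in seq_len(params$n_steps)) {
      # adsorption (sequential in site order; occupancy updates as we go)
      empty <- active[!occ[active]]
      adsorb <- empty[stats::runif(length(empty)) < params$adsorption_rate]
      for (s in adsorb) {
        nb <- sites$neighbours[[s]]
        nb_lab <- lab[nb][occ[nb]]
        if (length(nb_lab) > 0L) {
          tab <- table(nb_lab)
          best <- as.integer(names(tab)[tab == max(tab)])
          lab[s] <- min(best)
        } else {
          angles <- c(angles, wrap_angle(
            theta0 + stats::runif(1, -1, 1) * params$nucleation_orientation_spread))
          lab[s] <- length(angles)
        }
        occ[s] <- TRUE
      }
      # whole-patch reorientation to the preferred lattice orientation
      present <- sort(unique(lab[occ]))
      sizes <- tabulate(lab[occ], nbins = length(angles))
      for (p in present) {
        if (stats::runif(1) < min(1, params$patch_reorientation_rate / sizes[p]))
          angles[p] <- theta0
      }
      # merge adjacent patches with identical orientation (lowest label wins)
      repeat {
        merged <- FALSE
        for (s in which(occ)) {
          for (t in sites$neighbours[[s]]) {
            if (occ[t] && lab[t] != lab[s] &&
                abs(angles[lab[t]] - angles[lab[s]]) < 1e-9) {
              keep <- min(lab[s], lab[t]); drop_ <- max(lab[s], lab[t])
              lab[lab == drop_] <- keep
              merged <- TRUE
            }
          }
        }
        if (!merged) break
      }
      ow <- ow_frame(sites, occ, lab, angles, tube$axis)
      frames[[step + 1L]] <- if (is.null(ow)) iw else merge_frames(iw, ow)
    }
  })
  attr(frames, "t") <- 0:params$n_steps
  frames
}
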