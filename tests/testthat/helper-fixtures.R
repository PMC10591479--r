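# Shared fixtures, all built in code.

# A rolled wall: n_a chosen to match the circumference of `radius`.
make_wall <- function(dipole_angle, radius, n_b = 2, wall = "IW",
                      axis = c(0, 0, 1)) {
  lat <- lattice_spec(dipole_angle = dipole_angle)
  n_a <- max(3L, round(2 * pi * radius / 0.7))
  suppressWarnings(
    roll_to_cylinder(build_lattice(lat, n_a, n_b), radius, axis = axis,
                     wall = wall))
}

# Fast exciton parameter sets.
ep_fast <- function(...) exciton_params(n_realizations = 8, seed = 99, ...)
ep_det <- function(...) exciton_params(sigma_site = 0, n_realizations = 1,
                                       seed = 1, ...)

# Frame of n uncoupled molecules (spaced far apart) with given unit dipoles.
sparse_frame <- function(dipoles, spacing = 1e5, axis = c(0, 0, 1)) {
  n <- nrow(dipoles)
  pos <- cbind(seq_len(n) * spacing, 0, 0)
  molecule_frame(pos, dipoles, axis = axis)
}

# Constructed multi-patch fixture: k spatially separated groups, each with
# a common, evenly spaced in-surface orientation. Group centres sit far
# apart along z so position and orientation are both well separated.
patch_fixture <- function(k, per_patch = 20, axis = c(0, 0, 1)) {
  thetas <- seq(0.2, pi - 0.2, length.out = k)
  pos <- NULL; dip <- NULL; lab <- NULL
  for (i in seq_len(k)) {
    gx <- rep(seq_len(per_patch), each = 1) * 8          # 8 A local spacing
    gp <- cbind(gx, 0, (i - 1) * 500)                    # groups 500 A apart
    d <- matrix(rep(c(cos(thetas[i]), 0, sin(thetas[i])), per_patch),
                ncol = 3, byrow = TRUE)
    pos <- rbind(pos, gp); dip <- rbind(dip, d)
    lab <- c(lab, rep(i, per_patch))
  }
  fr <- molecule_frame(pos, dip, axis = axis, patch = lab)
  fr
}

# Independent brute-force DBSCAN oracle: distance matrix, eps-graph over
# core points, connected components via igraph, border points attached to
# the lowest-indexed neighbouring cluster.
dbscan_oracle <- function(features, eps, min_pts) {
  n <- nrow(features)
  d <- as.matrix(dist(features))
  within <- d <= eps
  core <- rowSums(within) >= min_pts        # includes self (diag TRUE)
  labels <- rep(-1L, n)
  if (any(core)) {
    ci <- which(core)
    adj <- within[ci, ci, drop = FALSE]
    g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected",
                                             diag = FALSE)
    comp <- igraph::components(g)$membership
    # number clusters by smallest core index
    first <- tapply(ci, comp, min)
    ord <- rank(first)
    labels[ci] <- as.integer(ord[comp] - 1L)
    for (i in which(!core)) {
      nb <- ci[within[i, ci]]
      if (length(nb) > 0) labels[i] <- min(labels[nb])
    }
  }
  labels
}

# Partition of labels as a canonical set of sets (noise dropped), for
# permutation-invariance comparisons.
partition_sets <- function(labels, ids = seq_along(labels)) {
  keep <- labels >= 0
  sp <- split(ids[keep], labels[keep])
  unname(lapply(sp, function(s) sort(s)))
}

unitv <- function(v) v / sqrt(sum(v^2))
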