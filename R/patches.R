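#' Regularized position + orientation features for patch identification
#'
#' Builds the dimensionless 6-column feature matrix used for clustering:
#' positions divided by the largest box dimension, concatenated with the
#' unit transition-dipole components. Dipoles are mapped to the hemisphere with non-negative axial
#' component, honouring the inversion symmetry of the chromophore (without
#' this, antiparallel dipoles in one physical patch would split into two
#' clusters). All feature values lie in \[-1, 1\].
#'
#' @param frame a [molecule_frame()] with `box_max_dim > 0`.
#' @param orientation_weight multiplier applied to the dipole columns
#'   (default 1: positions and orientations weighted equally).
#' @return An object of class `patch_features`: list with the N x 6
#'   `features` matrix, the frame `axis`, and `dipoles` (the hemisphere-
#'   mapped unit dipoles).
#' @export
regularize <- function(frame, orientation_weight = 1) {
  if (frame$box_max_dim <= 0) stop("box_max_dim must be positive")
  pos <- frame$positions / frame$box_max_dim
  d <- frame$dipoles
  ax <- drop(d %*% frame$axis)
  flip <- ax < 0
  if (any(flip)) d[flip, ] <- -d[flip, , drop = FALSE]
  structure(list(features = cbind(pos, orientation_weight * d),
                 axis = frame$axis, dipoles = d),
            class = "patch_features")
}

# Deterministic DBSCAN in feature space. Core point: at least min_pts
# points (itself included) within eps. Clusters are grown breadth-first
# from core points in index order, so cluster ids follow the smallest core
# index and border points are claimed by the lowest-indexed cluster.
dbscan_labels <- function(features, eps, min_pts) {
  n <- nrow(features)
  d <- as.matrix(stats::dist(features))
  nb <- lapply(seq_len(n), function(i) which(d[i, ] <= eps))  # includes self
  core <- vapply(nb, length, 1L) >= min_pts
  labels <- rep(-1L, n)
  visited <- logical(n)
  cl <- 0L
  for (i in seq_len(n)) {
    if (visited[i] || !core[i]) next
    queue <- i
    visited[i] <- TRUE
    labels[i] <- cl
    while (length(queue) > 0L) {
      p <- queue[1]; queue <- queue[-1]
      for (q in nb[[p]]) {
        if (labels[q] == -1L) labels[q] <- cl       # border or new core
        if (core[q] && !visited[q]) {
          visited[q] <- TRUE
          labels[q] <- cl
          queue <- c(queue, q)
        }
      }
    }
    cl <- cl + 1L
  }
  labels
}

#' Identify orientational patches by density-based clustering
#'
#' Runs DBSCAN with the Euclidean metric in the 6-dimensional regularized
#' position + orientation space: points belong to the same patch when they
#' are density-connected through core points having at least `min_pts`
#' points (themselves included) within a hypersphere of radius `eps`.
#' Defaults `eps = 0.2` (dimensionless) and `min_pts = 2` follow the
#' published patch-identification settings. Points in no cluster are noise
#' (label -1). The result is deterministic for a fixed input order; border
#' points reachable from several clusters go to the lowest-indexed cluster.
#'
#' @param x a `patch_features` object or a [molecule_frame()] (regularized
#'   internally).
#' @param eps neighbourhood radius in feature space (> 0).
#' @param min_pts minimum number of points (self included) within `eps` for
#'   a core point.
#' @return An object of class `patch_assignment`: `labels` (N integers, -1
#'   = noise, clusters 0..n_patches-1), `n_patches`, `sizes`, `mean_dipole`
#'   (per-patch mean of hemisphere-mapped dipoles, rows), and the global
#'   axial order parameter `f`.
#' @export
identify_patches <- function(x, eps = 0.2, min_pts = 2L) {
  if (eps <= 0) stop("eps must be positive")
  feats <- if (inherits(x, "patch_features")) x else regularize(x)
  n <- nrow(feats$features)
  labels <- if (n == 0L) integer(0) else
    dbscan_labels(feats$features, eps, as.integer(min_pts))
  k <- if (n == 0L) 0L else max(labels) + 1L
  sizes <- if (k > 0L) tabulate(labels + 1L, nbins = k) else integer(0)
  mean_dipole <- if (k > 0L)
    t(vapply(seq_len(k) - 1L, function(cl)
      colMeans(feats$dipoles[labels == cl, , drop = FALSE]), numeric(3)))
  else matrix(numeric(0), 0, 3)
  f <- if (n > 0L) mean(drop(feats$dipoles %*% feats$axis)^2) else NaN
  structure(list(labels = labels, n_patches = k, sizes = sizes,
                 noise = sum(labels == -1L), mean_dipole = mean_dipole,
                 f = f, eps = eps, min_pts = as.integer(min_pts)),
            class = "patch_assignment")
}

#' @export
print.patch_assignment <- function(x, ...) {
  cat(sprintf("patch_assignment: %d patches, %d noise point(s), f = %.3f\n",
              x$n_patches, x$noise, x$f))
  if (x$n_patches > 0)
    cat("  sizes:", paste(x$sizes, collapse = ", "), "\n")
  invisible(x)
}

#' Per-frame patch statistics of a trajectory
#'
#' Identifies patches in every frame and summarizes the patch count, the
#' fraction of (non-noise) molecules in the largest patch, and the global
#' axial order parameter f. Optionally restricts the analysis to one wall
#' (e.g. the recovering outer wall).
#'
#' @param frames list of [molecule_frame()]s.
#' @param eps,min_pts DBSCAN settings, see [identify_patches()].
#' @param wall analyze only molecules with this wall tag (`NULL` = all).
#' @return data.frame with columns `t`, `n_molecules`, `n_patches`,
#'   `largest_fraction`, `f`.
#' @export
patch_timeseries <- function(frames, eps = 0.2, min_pts = 2L, wall = NULL) {
  if (length(frames) < 1L) stop("need at least one frame")
  t <- attr(frames, "t") %||% (seq_along(frames) - 1)
  rows <- lapply(seq_along(frames), function(i) {
    fr <- if (is.null(wall)) frames[[i]] else subset_frame(frames[[i]], wall)
    n <- n_molecules(fr)
    if (n == 0L)
      return(data.frame(t = t[i], n_molecules = 0L, n_patches = 0L,
                        largest_fraction = NA_real_, f = NA_real_))
    pa <- identify_patches(fr, eps = eps, min_pts = min_pts)
    lf <- if (pa$n_patches > 0L) max(pa$sizes) / sum(pa$sizes) else NA_real_
    data.frame(t = t[i], n_molecules = n, n_patches = pa$n_patches,
               largest_fraction = lf, f = pa$f)
  })
  do.call(rbind, rows)
}
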