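test_that("features are dimensionless, in range, on the axial hemisphere", {
  fr <- molecule_frame(rbind(c(0, 0, 0), c(100, 0, 0), c(50, 0, 0)),
                       rbind(c(0, 0, 1), c(0, 0, -1), c(0, 1, 0)))
  ft <- regularize(fr)
  expect_equal(ft$features[3, 1], 0.5)       # coordinate D/2 -> 0.5
  expect_equal(ft$features[2, 4:6], c(0, 0, 1), ignore_attr = TRUE)
  expect_true(all(ft$features >= -1 & ft$features <= 1))
  expect_true(all(abs(sqrt(rowSums(ft$features[, 4:6]^2)) - 1) < 1e-9))
  expect_true(all(ft$features[, 4:6] %*% fr$axis >= 0))
})

test_that("generated frames regularize into [-1, 1] features", {
  fr <- generate_patchwork(make_wall(1.17, 3.45, n_b = 2),
                           tube_spec(length = 4.2), lattice_spec(),
                           150, 4, seed = 3)
  ft <- regularize(fr)
  expect_true(all(ft$features >= -1 & ft$features <= 1))
})

test_that("orientation weighting scales only the dipole columns", {
  fr <- random_frame(20, seed = 1)
  f1 <- regularize(fr)$features
  f2 <- regularize(fr, orientation_weight = 0.5)$features
  expect_equal(f2[, 1:3], f1[, 1:3])
  expect_equal(f2[, 4:6], 0.5 * f1[, 4:6])
})

test_that("well-separated groups with distinct orientations form two patches", {
  fr <- patch_fixture(2, per_patch = 20)
  pa <- identify_patches(fr)
  expect_equal(pa$n_patches, 2L)
  expect_equal(sort(pa$sizes), c(20L, 20L))
  expect_equal(pa$noise, 0L)
  # recovered partition equals the generating labels
  expect_setequal(partition_sets(pa$labels),
                  partition_sets(fr$patch, seq_along(fr$patch)))
})

test_that("a five-patch constructed fixture is recovered exactly", {
  fr <- patch_fixture(5, per_patch = 20)
  pa <- identify_patches(fr, eps = 0.2, min_pts = 2)
  expect_equal(pa$n_patches, 5L)
  expect_equal(unname(pa$sizes), rep(20L, 5))
  expect_setequal(partition_sets(pa$labels),
                  partition_sets(fr$patch, seq_along(fr$patch)))
})

test_that("an isolated molecule is noise; co-located molecules one patch", {
  fr <- patch_fixture(1, per_patch = 10)
  lone <- molecule_frame(rbind(c(0, 0, 5000)), rbind(c(0, 0, 1)))
  both <- merge_frames(fr, lone)
  pa <- identify_patches(both)
  expect_equal(pa$labels[n_molecules(both)], -1L)
  expect_equal(pa$n_patches, 1L)

  same <- molecule_frame(matrix(0, 30, 3) + 1,
                         matrix(rep(c(0, 0, 1), 30), ncol = 3, byrow = TRUE),
                         box_max_dim = 10)
  pa2 <- identify_patches(same)
  expect_equal(pa2$n_patches, 1L)
  expect_equal(pa2$sizes, 30L)
})

test_that("every non-noise patch has at least two members", {
  for (seed in 1:3) {
    fr <- random_frame(60, box = 400, seed = seed)
    pa <- identify_patches(fr)
    if (pa$n_patches > 0) expect_true(all(pa$sizes >= 2))
    expect_equal(sum(pa$sizes) + pa$noise, 60L)
  }
})

test_that("DBSCAN matches the brute-force eps-graph oracle", {
  skip_if_not_installed("igraph")
  frames <- list(
    patch_fixture(3, per_patch = 15),
    random_frame(120, box = 300, seed = 11),
    random_frame(200, box = 150, seed = 12),
    generate_patchwork(make_wall(1.17, 3.45, n_b = 1),
                       tube_spec(length = 2.2), lattice_spec(), 90, 3,
                       seed = 13))
  for (fr in frames) {
    ft <- regularize(fr)
    for (eps in c(0.1, 0.2, 0.5)) {
      got <- identify_patches(ft, eps = eps)$labels
      want <- dbscan_oracle(ft$features, eps, 2L)
      expect_identical(got, want)
    }
  }
})

test_that("the cluster partition is invariant under input reordering", {
  fr <- generate_patchwork(make_wall(1.17, 3.45, n_b = 1),
                           tube_spec(length = 2.2), lattice_spec(), 80, 4,
                           seed = 5)
  ft <- regularize(fr)
  base <- identify_patches(ft)
  perm <- withr::with_seed(8, sample(nrow(ft$features)))
  ft_perm <- structure(list(features = ft$features[perm, ], axis = ft$axis,
                            dipoles = ft$dipoles[perm, ]),
                       class = "patch_features")
  shuf <- identify_patches(ft_perm)
  expect_equal(shuf$n_patches, base$n_patches)
  expect_setequal(partition_sets(shuf$labels, perm),
                  partition_sets(base$labels))
})

test_that("patch count is non-increasing in eps on noise-free frames", {
  fr <- generate_patchwork(make_wall(1.17, 3.45, n_b = 1),
                           tube_spec(length = 2.2), lattice_spec(), 100, 5,
                           seed = 2)
  ft <- regularize(fr)
  counts <- vapply(c(0.2, 0.3, 0.5, 0.8, 1.2, 2), function(e) {
    pa <- identify_patches(ft, eps = e)
    expect_equal(pa$noise, 0L)
    pa$n_patches
  }, 1L)
  expect_true(all(diff(counts) <= 0))
})

test_that("patch time series track merging and the empty outer wall", {
  tube <- tube_spec(length = 4.2)
  lat <- lattice_spec(dipole_angle = 1.45)
  iw <- make_wall(1.17, 3.45, n_b = 2)
  p <- assembly_params(adsorption_rate = 0.3, patch_reorientation_rate = 30,
                       n_steps = 16, seed = 14)
  frames <- simulate_assembly(iw, tube, lat, p)
  pt <- patch_timeseries(frames, wall = "OW")
  expect_equal(pt$n_patches[1], 0L)            # empty outer wall
  expect_true(is.na(pt$largest_fraction[1]))
  expect_equal(pt$n_patches[nrow(pt)], 1L)     # fast reorientation converges
  expect_equal(pt$largest_fraction[nrow(pt)], 1)
})

test_that("invalid clustering inputs are rejected", {
  fr <- random_frame(5, seed = 1)
  expect_error(identify_patches(fr, eps = 0), "eps")
  fr0 <- molecule_frame(rbind(c(0, 0, 0)), rbind(c(0, 0, 1)),
                        box_max_dim = 0)
  expect_error(regularize(fr0), "box_max_dim")
})
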