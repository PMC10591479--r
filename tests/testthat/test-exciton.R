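test_that("the transition dipole magnitude follows from q and l", {
  ep <- exciton_params()
  expect_equal(ep$mu, 0.34 * 7 * 4.80320, tolerance = 1e-12)
  expect_equal(ep$mu, 11.4, tolerance = 0.005)
  expect_error(exciton_params(mu = 12.5), "inconsistent")
})

test_that("extended-dipole coupling decays to zero at large separation", {
  ep <- ep_det()
  J <- extended_dipole_coupling(c(0, 0, 0), c(0, 0, 1),
                                c(1e6, 0, 0), c(0, 0, 1), ep)
  expect_lt(abs(J), 1e-6)
})

test_that("head-to-tail coupling matches the explicit four-charge sum", {
  ep <- ep_det()
  J <- extended_dipole_coupling(c(0, 0, 0), c(0, 0, 1),
                                c(0, 0, 10), c(0, 0, 1), ep)
  # independent arithmetic: charges at z = +-3.5 and 10 +- 3.5
  J_ref <- ep$alpha * (ep$mu / ep$l)^2 * (1 / 10 - 1 / 3 - 1 / 17 + 1 / 10)
  expect_equal(J, J_ref, tolerance = 1e-12)
  expect_lt(J, 0)
  # symmetric in the pair
  expect_equal(J, extended_dipole_coupling(c(0, 0, 10), c(0, 0, 1),
                                           c(0, 0, 0), c(0, 0, 1), ep))
})

test_that("coupling matches the point-dipole formula at r = 50 l", {
  ep <- ep_det()
  r <- 50 * ep$l
  cases <- list(
    list(dn = c(0, 0, 1), dm = c(0, 0, 1), sep = c(r, 0, 0), kappa = 1),
    list(dn = c(0, 0, 1), dm = c(0, 0, 1), sep = c(0, 0, r), kappa = -2),
    list(dn = c(1, 0, 0), dm = c(0, 1, 0), sep = c(0, 0, r), kappa = 0))
  for (cs in cases) {
    J <- extended_dipole_coupling(c(0, 0, 0), cs$dn, cs$sep, cs$dm, ep)
    J_pt <- ep$alpha * ep$mu^2 * cs$kappa / r^3
    if (cs$kappa == 0) expect_lt(abs(J), 1e-6)
    else expect_equal(J, J_pt, tolerance = 0.01)
  }
})

test_that("coincident charges raise a singular-geometry error", {
  ep <- ep_det()
  # centres 7 A apart along the shared dipole axis: charges coincide
  expect_error(extended_dipole_coupling(c(0, 0, 0), c(0, 0, 1),
                                        c(0, 0, 7), c(0, 0, 1), ep),
               "singular")
  fr <- molecule_frame(rbind(c(0, 0, 0), c(0, 0, 7)),
                       rbind(c(0, 0, 1), c(0, 0, 1)))
  expect_error(build_hamiltonian(fr, ep), "overlapping")
})

test_that("a single zero-disorder site sits at nu0 - delta", {
  fr <- sparse_frame(rbind(c(0, 0, 1)))
  H <- build_hamiltonian(fr, ep_det())
  expect_equal(dim(H$matrix), c(1L, 1L))
  expect_equal(H$matrix[1, 1], 19498 - 350)   # 19148
})

test_that("the Hamiltonian is symmetric with couplings off the diagonal", {
  fr <- make_wall(1.3, 3.45, n_b = 1)
  ep <- ep_fast()
  H <- withr::with_seed(1, build_hamiltonian(fr, ep))
  expect_lt(max(abs(H$matrix - t(H$matrix))), 1e-9)
  expect_equal(diag(H$matrix), H$site_frequencies - ep$delta)
})

test_that("sampled site energies have the configured disorder statistics", {
  fr <- sparse_frame(matrix(rep(c(0, 0, 1), 2000), ncol = 3, byrow = TRUE))
  ep <- exciton_params()
  d <- withr::with_seed(7, unlist(lapply(1:5, function(i)
    diag(build_hamiltonian(fr, ep, couplings = FALSE)$matrix))))
  expect_lt(abs(mean(d) - 19148), 3 * 231 / sqrt(10000))
  expect_equal(sd(d), 231, tolerance = 0.05)
})

test_that("strengths vanish for perpendicular polarization", {
  fr <- sparse_frame(rbind(c(0, 0, 1)))
  H <- build_hamiltonian(fr, ep_det())
  st <- stick_spectrum(H, fr, ep_det(), polarization = c(1, 0, 0))
  expect_equal(st$strength, 0)
})

test_that("the zero-disorder dimer matches the analytic 2x2 solution", {
  ep <- ep_det()
  d1 <- c(0, 0, 1)
  d2 <- unitv(c(0.3, 0, 1))   # non-parallel so both sticks are bright
  fr <- molecule_frame(rbind(c(0, 0, 0), c(12, 0, 0)), rbind(d1, d2))
  J <- extended_dipole_coupling(fr$positions[1, ], fr$dipoles[1, ],
                                fr$positions[2, ], fr$dipoles[2, ], ep)
  H <- build_hamiltonian(fr, ep)
  e <- c(0, 0, 1)
  st <- stick_spectrum(H, fr, ep, e)
  E0 <- ep$nu0 - ep$delta
  expect_equal(st$freq, sort(c(E0 - abs(J), E0 + abs(J))), tolerance = 1e-9)
  m <- ep$mu * drop(fr$dipoles %*% e)
  w_sym <- ((m[1] + m[2]) / sqrt(2))^2     # eigenvalue E0 + J
  w_asym <- ((m[1] - m[2]) / sqrt(2))^2    # eigenvalue E0 - J
  expected <- if (J > 0) c(w_asym, w_sym) else c(w_sym, w_asym)
  expect_equal(st$strength, expected, tolerance = 1e-9, ignore_attr = TRUE)
})

test_that("oscillator strengths obey the sum rule on every tested frame", {
  ep <- ep_fast()
  frames <- list(make_wall(1.3, 3.45, n_b = 2),
                 random_frame(150, seed = 17),
                 generate_patchwork(make_wall(1.17, 3.45, n_b = 1),
                                    tube_spec(length = 2.2), lattice_spec(),
                                    80, 3, seed = 6))
  for (fr in frames) {
    for (e in list(c(0, 0, 1), c(1, 0, 0), unitv(c(1, 1, 1)))) {
      H <- withr::with_seed(2, build_hamiltonian(fr, ep))
      st <- stick_spectrum(H, fr, ep, e)
      target <- sum((ep$mu * drop(fr$dipoles %*% e))^2)
      expect_equal(sum(st$strength), target, tolerance = 1e-8)
    }
  }
})

test_that("with no disorder one molecule gives a pure Gaussian line", {
  fr <- sparse_frame(rbind(c(0, 0, 1)))
  ep <- ep_det()
  sp <- absorption_spectrum(fr, ep, polarization = c(0, 0, 1))
  ref <- ep$mu^2 * dnorm(sp$wavenumber, 19148, ep$sigma_line)
  expect_equal(sp$A, ref, tolerance = 1e-12)
})

test_that("monomer ensemble peaks near nu0 - delta with quadrature width", {
  dip <- matrix(rep(c(0, 0, 1), 40), ncol = 3, byrow = TRUE)
  fr <- sparse_frame(dip)
  ep <- exciton_params(n_realizations = 400, seed = 12)
  sp <- full_spectrum(fr, ep, couplings = FALSE)
  pk <- find_peak(sp, "A_iso")
  expect_lt(abs(pk$wavenumber - 19148), 60)
  # spectral standard deviation matches the disorder/lineshape quadrature sum
  w <- sp$A_iso / sum(sp$A_iso)
  mu1 <- sum(w * sp$wavenumber)
  width <- sqrt(sum(w * (sp$wavenumber - mu1)^2))
  expect_equal(width, sqrt(231^2 + 75^2), tolerance = 0.05)
})

test_that("a coarse grid triggers an undersampling warning", {
  fr <- sparse_frame(rbind(c(0, 0, 1)))
  ep <- ep_det()
  expect_warning(
    absorption_spectrum(fr, ep, c(0, 0, 1), grid = seq(18000, 20000, 100)),
    "undersampled")
})

test_that("spectra are bit-identical under a fixed seed", {
  fr <- make_wall(1.3, 3.45, n_b = 1)
  ep <- ep_fast()
  expect_identical(full_spectrum(fr, ep), full_spectrum(fr, ep))
})

test_that("axial frames give LD_r = 3; 45-degree dipoles give LD = 0", {
  ax <- sparse_frame(matrix(rep(c(0, 0, 1), 30), ncol = 3, byrow = TRUE))
  ep <- ep_fast()
  sp <- full_spectrum(ax, ep, couplings = FALSE)
  expect_true(all(abs(sp$LD_r[!is.na(sp$LD_r)] - 3) < 1e-9))
  # dipoles bisecting the parallel and perpendicular directions: A_par = A_perp
  d45 <- unitv(c(1, 0, 1))   # e_perp for axis z is (1, 0, 0)
  fr <- sparse_frame(matrix(rep(d45, 30), ncol = 3, byrow = TRUE))
  sp <- full_spectrum(fr, ep, couplings = FALSE)
  expect_equal(sp$LD, rep(0, nrow(sp)), tolerance = 1e-12)
})

test_that("a defect-free rolled wall forms a red-shifted parallel J-band", {
  fr <- make_wall(1.45, 3.45, n_b = 2)
  sp <- full_spectrum(fr, ep_det())
  pk <- find_peak(sp, "A_par")
  expect_lt(pk$wavenumber, 19148)
  # dominant peak is parallel polarized
  expect_gt(sp$A_par[sp$wavenumber == pk$wavenumber],
            sp$A_perp[sp$wavenumber == pk$wavenumber])
})

test_that("interactions between separate patches barely affect the spectrum", {
  # two contiguous patches on the outer cylinder, separated in azimuth and
  # differing in orientation
  azimuth <- function(fr) atan2(fr$positions[, 2], fr$positions[, 1]) %% (2 * pi)
  w1 <- make_wall(1.45, 6.75, n_b = 2, wall = "OW")
  w2 <- make_wall(0.9, 6.75, n_b = 2, wall = "OW")
  p1 <- subset_frame(w1, idx = which(azimuth(w1) < 1.0))
  p2 <- subset_frame(w2, idx = which(azimuth(w2) > 2.5 & azimuth(w2) < 3.5))
  both <- merge_frames(p1, p2)
  ep <- ep_det()
  joint <- full_spectrum(both, ep)
  sep <- full_spectrum(p1, ep)$A_iso + full_spectrum(p2, ep)$A_iso
  l1 <- sum(abs(joint$A_iso - sep)) / sum(joint$A_iso)
  expect_lt(l1, 0.15)
})

test_that("removing the outer wall blue-shifts the inner-wall band", {
  iw <- make_wall(1.17, 3.45, n_b = 2)
  ow <- make_wall(1.45, 6.75, n_b = 2, wall = "OW")
  dw <- merge_frames(iw, ow)
  ep <- ep_det(sigma_line = 40)
  pk_iw <- find_peak(full_spectrum(iw, ep), "A_par")
  win <- band_window(pk_iw$wavenumber - 400, pk_iw$wavenumber + 150)
  pk_dw <- find_peak(full_spectrum(dw, ep), "A_par", win)
  expect_gt(pk_iw$wavenumber, pk_dw$wavenumber)
})
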