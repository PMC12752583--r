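# Forward solver, phantoms, noise models.

test_that("homogeneous uniaxial plate matches the closed form", {
  n <- 12
  g <- unit_grid(n)
  E0 <- 2.5
  ph <- make_phantom("homogeneous", g, E_bg = E0, nu_bg = 0)
  F <- 0.04
  u <- forward_solve(ph, boundary_load("uniform_load", F = F), g)
  nc <- node_coords(g)
  L <- 1  # right edge length
  # sigma_xx = F/L, ux = F x / (L E0), uy = 0 (nu = 0 decouples)
  expect_lt(max(abs(u$ux - F / (L * E0) * nc$x)) / (F / (L * E0)), 1e-6)
  expect_lt(max(abs(u$uy)), 1e-10)
  expect_lt(attr(u, "rel_residual"), 1e-8)
  s <- strain_from_displacement_fd(u)
  sig <- stress_from_strain(s, ph$elast)
  expect_equal(mean(sig$sxx), F / L, tolerance = 1e-6)
})

test_that("FEM passes the patch test (exact linear fields)", {
  g <- grid2d(9, 7, t = 0.9 / 8, h = 1.1 / 6)
  el <- homog_elast(g, E = 1.7, nu = 0.28)
  a <- c(0.3, -0.2, 0.15, 0.05)
  u <- fem_solve_dirichlet(el, g,
                           function(x, y) a[1] * x + a[2] * y,
                           function(x, y) a[3] * x + a[4] * y)
  s <- strain_from_displacement_fd(u)
  expect_lt(max(abs(s$exx - a[1])), 1e-10)
  expect_lt(max(abs(s$eyy - a[4])), 1e-10)
  expect_lt(max(abs(s$gxy - (a[2] + a[3]))), 1e-10)
})

test_that("scaling (E, F) together leaves displacements unchanged", {
  g <- unit_grid(10)
  for (profile in c("uniform_load", "normal_load", "central_uniform_load",
                    "uniform_strain")) {
    ph1 <- make_phantom("inclusion", g)
    u1 <- forward_solve(ph1, boundary_load(profile, F = 0.02), g)
    ph2 <- make_phantom("inclusion", g, E_bg = 7, E_inc = 21)  # 7 x E
    u2 <- forward_solve(ph2, boundary_load(profile, F = 0.14), g)
    expect_equal(u1$ux, u2$ux, tolerance = 1e-9, info = profile)
    expect_equal(u1$uy, u2$uy, tolerance = 1e-9, info = profile)
  }
})

test_that("forward solution satisfies the discrete equilibrium residual", {
  res_norm <- function(n) {
    g <- unit_grid(n)
    ph <- make_phantom("inclusion", g)
    u <- forward_solve(ph, boundary_load("uniform_load", F = 0.05), g)
    s <- strain_from_displacement_fd(u)
    sig <- stress_from_strain(s, ph$elast)
    r <- equilibrium_residual_fd(sig, ph$elast, g)
    # scale-free: normalize by the boundary stress scale / domain size
    mean(abs(r$rx) + abs(r$ry)) / (0.05 / 1)
  }
  r16 <- res_norm(16); r32 <- res_norm(32)
  expect_lt(r32, r16)  # decreases under refinement
})

test_that("load profiles integrate to F and have the right shape", {
  g <- unit_grid(16)
  ph <- make_phantom("homogeneous", g)
  for (profile in c("uniform_load", "normal_load", "central_uniform_load")) {
    u <- forward_solve(ph, boundary_load(profile, F = 0.05), g)
    s <- strain_from_displacement_fd(u)
    sig <- stress_from_strain(s, ph$elast)
    # x-equilibrium: integrated sigma_xx over any column ~ F
    colsum <- colSums(t(sig$sxx) * g$h)  # per column of cells
    expect_equal(mean(colsum), 0.05, tolerance = 0.02, info = profile)
  }
  # normal load concentrates stress near the middle of the loaded edge
  un <- forward_solve(ph, boundary_load("normal_load", F = 0.05), g)
  sn <- stress_from_strain(strain_from_displacement_fd(un), ph$elast)
  prof <- sn$sxx[nrow(sn$sxx), ]
  third <- length(prof) %/% 3
  expect_true(which.max(prof) > third && which.max(prof) <= 2 * third + 1)
  # uniform strain: right-edge ux is uniform
  us <- forward_solve(ph, boundary_load("uniform_strain", F = 0.05), g)
  expect_lt(diff(range(us$ux[g$nx, ])), 1e-10)
})

test_that("phantom descriptors produce the advertised structure", {
  g <- unit_grid(16)
  ph <- make_phantom("inclusion", g, E_bg = 1, E_inc = 5, radius = 0.2)
  expect_setequal(unique(as.vector(ph$elast$E)), c(1, 5))
  # determinism
  p1 <- make_phantom("multi_inclusion", g, seed = 42)
  p2 <- make_phantom("multi_inclusion", g, seed = 42)
  expect_identical(p1$elast$E, p2$elast$E)
  p3 <- make_phantom("multi_inclusion", g, seed = 43)
  expect_false(identical(p1$elast$E, p3$elast$E))
  # gradient monotone left -> right in E
  pg <- make_phantom("gradient", g, E_bg = 1, E_inc = 3)
  expect_true(all(diff(pg$elast$E[, 1]) >= 0))
  expect_equal(range(pg$elast$E), c(1 + (3 - 1) * 0.5 / 15, 1 + (3 - 1) * 14.5 / 15),
               tolerance = 1e-10)
  # bitmap mask
  msk <- matrix(FALSE, 15, 15); msk[3:5, 7:9] <- TRUE
  pb <- make_phantom("bitmap_mask", g, mask = msk, E_inc = 2)
  expect_equal(pb$elast$E[4, 8], 2)
  expect_equal(pb$elast$E[1, 1], 1)
  expect_error(make_phantom("bitmap_mask", g, mask = matrix(TRUE, 3, 3)), "mask")
})

test_that("gaussian noise follows sigma = u_bar / SNR per component", {
  g <- unit_grid(64)
  nc <- node_coords(g)
  # constant-mean fields with the worked-example magnitudes
  u <- displacement_field(matrix(1.27, 64, 64) + 0 * nc$x,
                          matrix(0.242, 64, 64), g)
  sp <- noise_spec("gaussian", snr = 100, seed = 9)
  un <- add_gaussian_noise(u, sp)
  sig <- attr(un, "sigma")
  expect_equal(sig[["ux"]], 0.0127)
  expect_equal(sig[["uy"]], 0.00242)
  # empirical std within 5% on a 64 x 64 grid
  expect_lt(abs(stats::sd(un$ux - u$ux) - 0.0127) / 0.0127, 0.05)
  expect_lt(abs(stats::sd(un$uy - u$uy) - 0.00242) / 0.00242, 0.05)
  # determinism and seed sensitivity
  un2 <- add_gaussian_noise(u, sp)
  expect_identical(un$ux, un2$ux)
  un3 <- add_gaussian_noise(u, noise_spec("gaussian", snr = 100, seed = 10))
  expect_false(identical(un$ux, un3$ux))
  # SNR -> Inf recovers the input
  uinf <- add_gaussian_noise(u, noise_spec("gaussian", snr = 1e12, seed = 1))
  expect_equal(uinf$ux, u$ux, tolerance = 1e-9)
  expect_error(noise_spec("gaussian", snr = -1), "snr")
})

test_that("structured noise: PSF normalization, delta limit, determinism", {
  k <- psf_kernel()
  expect_equal(sum(k), 1)
  g <- unit_grid(24)
  const <- displacement_field(matrix(0.5, 24, 24), matrix(0.2, 24, 24), g)
  # constant field with (effectively) zero additive noise passes through
  sp <- noise_spec("structured", snr = 1e12, seed = 4)
  out <- add_structured_noise(const, sp)
  expect_equal(out$ux, const$ux, tolerance = 1e-9)
  # huge spreads degenerate to a near-delta kernel
  kd <- psf_kernel(fc = 6, sx2 = 1e6, sy2 = 1e6)
  expect_equal(kd[(nrow(kd) + 1) / 2, (ncol(kd) + 1) / 2], 1, tolerance = 1e-8)
  # reproducibility
  nc <- node_coords(g)
  u <- displacement_field(0.1 * nc$x + 0.01 * nc$y, 0.05 * nc$y, g)
  spn <- noise_spec("structured", snr = 100, seed = 11)
  expect_identical(add_structured_noise(u, spn)$ux,
                   add_structured_noise(u, spn)$ux)
  # blur actually changes a non-constant field
  expect_gt(mae(add_structured_noise(u, noise_spec("structured", 1e12, 1))$ux, u$ux), 0)
})

test_that("mean_displacement modes", {
  g <- unit_grid(6)
  u <- displacement_field(matrix(c(1, 3), 6, 6), matrix(-2, 6, 6), g)
  expect_equal(mean_displacement(u)[["ux"]], 2)
  expect_equal(mean_displacement(u)[["uy"]], -2)
  expect_equal(mean_displacement(u, "absolute")[["uy"]], 2)
})

test_that("datasets from (cE, cF) are identical (identifiability gap)", {
  g <- unit_grid(12)
  nz <- noise_spec("gaussian", snr = 500, seed = 3)
  ds1 <- make_dataset(make_phantom("inclusion", g), g,
                      boundary_load("uniform_load", F = 0.03), nz)
  ds2 <- make_dataset(make_phantom("inclusion", g, E_bg = 10, E_inc = 30), g,
                      boundary_load("uniform_load", F = 0.3), nz)
  expect_equal(ds1$u_obs$ux, ds2$u_obs$ux, tolerance = 1e-9)
  expect_equal(ds1$u_obs$uy, ds2$u_obs$uy, tolerance = 1e-9)
})
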