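# Finite-difference kernels, valid convolution, strain and residual
# operators: exactness on affine fields, convergence, shape chain.

test_that("kernels have the documented entries and all sum to zero", {
  k <- fd_kernels()
  # wx differences along x (first index), wy along y
  expect_equal(k$wx, matrix(c(-0.5, -0.5, 0.5, 0.5), 2, 2, byrow = TRUE))
  expect_equal(k$wy, t(k$wx))
  expect_equal(k$wxx_x[1, ], rep(-1, 3))
  expect_equal(k$wxx_x[3, ], rep(1, 3))
  expect_equal(k$wyy_x, matrix(0, 3, 3))
  expect_equal(k$wxy_x, t(k$wxx_x))
  expect_equal(k$wxx_y, matrix(0, 3, 3))
  expect_equal(k$wyy_y, t(k$wxx_x))
  expect_equal(k$wxy_y, k$wxx_x)
  for (nm in names(k)) expect_equal(sum(k[[nm]]), 0, info = nm)
})

test_that("valid_convolve is the plain sliding sum of the kernel equation", {
  f <- matrix(c(1, 2, 3, 4), 2, 2, byrow = TRUE)
  expect_equal(valid_convolve(f, matrix(1)), f)
  # hand evaluation: wx differences along the first index
  k <- fd_kernels()
  expect_equal(valid_convolve(f, k$wx)[1, 1], 0.5 * (3 - 1) + 0.5 * (4 - 2))
  # constant field -> zero under every derivative kernel
  cf <- matrix(7, 6, 5)
  for (nm in names(k)) {
    expect_true(all(abs(valid_convolve(cf, k[[nm]])) < 1e-14), info = nm)
  }
  # shape contract and error
  expect_equal(dim(valid_convolve(matrix(0, 7, 5), matrix(0, 3, 3))), c(5L, 3L))
  expect_error(valid_convolve(matrix(0, 2, 2), matrix(0, 3, 3)), "smaller")
})

test_that("strain operator is exact on affine displacement fields", {
  g <- grid2d(9, 7, t = 0.13, h = 0.21)
  set.seed(7)
  for (rep in 1:5) {
    a <- rnorm(6)
    u <- make_u(g, function(x, y) a[1] + a[2] * x + a[3] * y,
                function(x, y) a[4] + a[5] * x + a[6] * y)
    s <- strain_from_displacement_fd(u)
    expect_equal(max(abs(s$exx - a[2])), 0, tolerance = 1e-12)
    expect_equal(max(abs(s$eyy - a[6])), 0, tolerance = 1e-12)
    expect_equal(max(abs(s$gxy - (a[3] + a[5]))), 0, tolerance = 1e-12)
  }
  # pure shear: ux = 0, uy = x
  u <- make_u(g, function(x, y) 0 * x, function(x, y) x)
  s <- strain_from_displacement_fd(u)
  expect_equal(max(abs(s$gxy - 1)), 0, tolerance = 1e-12)
})

test_that("strain operator gives the central difference of quadratics", {
  # ux = x^2 with t = 0.1: cell between x = 0.1, 0.2 sees (0.04-0.01)/0.1 = 0.3
  g <- grid2d(4, 4, t = 0.1, h = 0.1)
  u <- make_u(g, function(x, y) x^2, function(x, y) 0 * x)
  s <- strain_from_displacement_fd(u)
  expect_equal(s$exx[2, 1], 0.3)
})

test_that("paper-literal mode differs from physical by the per-axis spacing", {
  g <- grid2d(6, 6, t = 0.2, h = 0.5)
  u <- make_u(g, function(x, y) 0.3 * x + 0.1 * y, function(x, y) 0.2 * x - 0.4 * y)
  sp <- strain_from_displacement_fd(u, "physical")
  sl <- strain_from_displacement_fd(u, "paper_literal")
  expect_equal(sl$exx, sp$exx * g$t, tolerance = 1e-12)
  expect_equal(sl$eyy, sp$eyy * g$h, tolerance = 1e-12)
})

test_that("residual operator is exact on affine stress fields", {
  g <- grid2d(8, 9, t = 0.11, h = 0.07)
  cc <- cell_coords(g)
  set.seed(11)
  for (rep in 1:5) {
    a <- rnorm(9, 0, 1)
    sxx <- a[1] + a[2] * cc$x + a[3] * cc$y
    syy <- a[4] + a[5] * cc$x + a[6] * cc$y
    txy <- a[7] + a[8] * cc$x + a[9] * cc$y
    sig <- stress_field(sxx, syy, txy, g)
    r <- equilibrium_residual_fd(sig, grid = g)
    expect_equal(max(abs(r$rx - (a[2] + a[9]))), 0, tolerance = 1e-10)
    expect_equal(max(abs(r$ry - (a[8] + a[6]))), 0, tolerance = 1e-10)
  }
})

test_that("residual is linear in the stress field", {
  g <- grid2d(7, 7)
  d <- cell_dim(g)
  set.seed(3)
  sig <- stress_field(matrix(rnorm(prod(d)), d[1]), matrix(rnorm(prod(d)), d[1]),
                      matrix(rnorm(prod(d)), d[1]), g)
  sig3 <- stress_field(3 * sig$sxx, 3 * sig$syy, 3 * sig$txy, g)
  r1 <- equilibrium_residual_fd(sig, grid = g)
  r3 <- equilibrium_residual_fd(sig3, grid = g)
  expect_equal(r3$rx, 3 * r1$rx, tolerance = 1e-12)
  expect_equal(r3$ry, 3 * r1$ry, tolerance = 1e-12)
})

test_that("FD operators converge at first order or better on smooth fields", {
  err_at <- function(n) {
    g <- grid2d(n, n, t = 1 / (n - 1), h = 1 / (n - 1))
    u <- make_u(g, function(x, y) sin(2 * x) * cos(y), function(x, y) x^2 * y)
    s <- strain_from_displacement_fd(u)
    cc <- cell_coords(g)
    truth <- 2 * cos(2 * cc$x) * cos(cc$y)
    mean(abs(s$exx - truth))
  }
  e1 <- err_at(17); e2 <- err_at(33)
  ratio <- e1 / e2
  # halving the spacing should roughly halve the error (+/- generous band;
  # the symmetric cell-centered stencil is actually closer to 2nd order)
  expect_gt(ratio, 1.4)
})

test_that("shape chain runs Nx x Ny -> (Nx-1)(Ny-1) -> (Nx-3)(Ny-3)", {
  g <- grid2d(10, 8)
  u <- make_u(g, function(x, y) x * y, function(x, y) x + y)
  s <- strain_from_displacement_fd(u)
  expect_equal(dim(s$exx), c(9L, 7L))
  el <- homog_elast(g)
  sig <- stress_from_strain(s, el)
  r <- equilibrium_residual_fd(sig, el, g)
  expect_equal(dim(r$rx), c(7L, 5L))
  expect_equal(dim(attr(r, "normalized")), c(7L, 5L))
})

test_that("normalized residual uses the 3x3 modulus aggregation", {
  g <- grid2d(6, 6)
  d <- cell_dim(g)
  set.seed(5)
  sig <- stress_field(matrix(rnorm(prod(d)), d[1]), matrix(rnorm(prod(d)), d[1]),
                      matrix(rnorm(prod(d)), d[1]), g)
  E <- matrix(runif(prod(d), 1, 2), d[1], d[2])
  el <- elasticity_field(E, matrix(0.3, d[1], d[2]), g)
  r <- equilibrium_residual_fd(sig, el, g)
  Et <- valid_convolve(E, matrix(1, 3, 3))
  expect_equal(attr(r, "normalized"), (abs(r$rx) + abs(r$ry)) / Et, tolerance = 1e-12)
  # stress smaller than the 3x3 stencil is a structural error
  tiny <- list(sxx = matrix(0, 2, 2), syy = matrix(0, 2, 2),
               txy = matrix(0, 2, 2), grid = g)
  expect_error(equilibrium_residual_fd(tiny, grid = g), "3 x 3")
})
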