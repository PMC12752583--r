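# Shared fixtures. Everything is generated in code; no stored data.

# single-threaded BLAS before the first matrix product of the session
if (!nzchar(Sys.getenv("OPENBLAS_NUM_THREADS"))) {
  Sys.setenv(OPENBLAS_NUM_THREADS = "1", OMP_NUM_THREADS = "1")
}

# small unit square grid with n x n nodes
unit_grid <- function(n = 8, m = n) {
  grid2d(n, m, t = 1 / (n - 1), h = 1 / (m - 1))
}

# displacement field from analytic functions of (x, y)
make_u <- function(grid, fx, fy) {
  nc <- node_coords(grid)
  displacement_field(fx(nc$x, nc$y), fy(nc$x, nc$y), grid)
}

# homogeneous elasticity on the cell grid
homog_elast <- function(grid, E = 1, nu = 0.3) {
  d <- cell_dim(grid)
  elasticity_field(matrix(E, d[1], d[2]), matrix(nu, d[1], d[2]), grid)
}

# a small clean/noisy dataset for training tests
quick_dataset <- function(n = 16, snr = NULL, seed = 1L, descriptor = "inclusion",
                          F = 0.05, profile = "uniform_load") {
  g <- unit_grid(n)
  ph <- make_phantom(descriptor, g, seed = seed)
  nz <- if (is.null(snr)) NULL else noise_spec("gaussian", snr = snr, seed = seed)
  make_dataset(ph, g, boundary_load(profile, F = F), nz)
}

# micro training config: exercises all code paths in seconds
micro_config <- function(...) {
  do.call(preset_tiny,
          utils::modifyList(list(pretrain_u_iters = 60L,
                                 pretrain_eps_iters = 60L,
                                 full_iters = 120L), list(...)))
}
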