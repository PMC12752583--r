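#' Boundary load specification
#'
#' Describes the traction applied to the right edge of the plate. Four
#' profiles are supported: `uniform_strain` (a uniform prescribed x
#' displacement of the right edge, scaled so the total reaction force
#' equals `F`), `uniform_load` (constant traction), `normal_load`
#' (Gaussian-profile traction centered on the edge midpoint), and
#' `central_uniform_load` (uniform traction over the middle fraction of
#' the edge, 50 percent by default). All traction profiles integrate to
#' total force `F` per unit thickness; the left edge is always fully
#' clamped and the top/bottom edges are traction-free.
#'
#' @param profile one of `"uniform_strain"`, `"uniform_load"`,
#'   `"normal_load"`, `"central_uniform_load"`
#' @param F total applied force per unit thickness, > 0
#' @param side loaded side; only `"right"` is supported
#' @param std_frac for `normal_load`: Gaussian std as a fraction of the
#'   edge length (default 0.2)
#' @param covered_frac for `central_uniform_load`: covered fraction of the
#'   edge (default 0.5)
#' @return an object of class `boundary_load`
#' @export
boundary_load <- function(profile = c("uniform_load", "uniform_strain",
                                      "normal_load", "central_uniform_load"),
                          F = 1, side = "right",
                          std_frac = 0.2, covered_frac = 0.5) {
  profile <- match.arg(profile)
  if (!identical(side, "right")) stop("boundary_load: only side = 'right' is supported")
  if (!is.finite(F) || F <= 0) stop("boundary_load: F must be > 0")
  structure(list(side = side, profile = profile, F = as.numeric(F),
                 profile_params = list(std_frac = std_frac,
                                       covered_frac = covered_frac)),
            class = "boundary_load")
}

# Element stiffness building blocks for a t x h bilinear quadrilateral,
# plane stress, unit thickness. The constitutive matrix splits as
#   D = E/(1-nu^2) (D1 + nu D2) + E/(2(1+nu)) D3
# so Ke = cA (K1 + nu K2) + cS K3 with element-constant coefficients;
# K1..K3 depend only on (t, h) and are shared by all elements.
q4_component_stiffness <- function(t, h) {
  gp <- 1 / sqrt(3)
  pts <- rbind(c(-gp, -gp), c(gp, -gp), c(gp, gp), c(-gp, gp))
  D1 <- diag(c(1, 1, 0))
  D2 <- matrix(c(0, 1, 0, 1, 0, 0, 0, 0, 0), 3, 3)
  D3 <- diag(c(0, 0, 1))
  K1 <- K2 <- K3 <- matrix(0, 8, 8)
  detJ <- t * h / 4
  for (p in seq_len(4)) {
    xi <- pts[p, 1]; eta <- pts[p, 2]
    dNdxi  <- c(-(1 - eta), (1 - eta), (1 + eta), -(1 + eta)) / 4
    dNdeta <- c(-(1 - xi), -(1 + xi), (1 + xi), (1 - xi)) / 4
    dNdx <- dNdxi * 2 / t
    dNdy <- dNdeta * 2 / h
    B <- matrix(0, 3, 8)
    B[1, seq(1, 8, 2)] <- dNdx
    B[2, seq(2, 8, 2)] <- dNdy
    B[3, seq(1, 8, 2)] <- dNdy
    B[3, seq(2, 8, 2)] <- dNdx
    K1 <- K1 + t(B) %*% D1 %*% B * detJ
    K2 <- K2 + t(B) %*% D2 %*% B * detJ
    K3 <- K3 + t(B) %*% D3 %*% B * detJ
  }
  list(K1 = K1, K2 = K2, K3 = K3)
}

node_index <- function(i, j, nx) (j - 1L) * nx + i

# Assemble the global plane-stress stiffness for per-cell (E, nu).
assemble_stiffness <- function(elast, grid) {
  nx <- grid$nx; ny <- grid$ny
  ks <- q4_component_stiffness(grid$t, grid$h)
  ci <- rep(seq_len(nx - 1L), ny - 1L)
  cj <- rep(seq_len(ny - 1L), each = nx - 1L)
  n1 <- node_index(ci, cj, nx); n2 <- node_index(ci + 1L, cj, nx)
  n3 <- node_index(ci + 1L, cj + 1L, nx); n4 <- node_index(ci, cj + 1L, nx)
  # dof order per element: (ux, uy) for local nodes 1..4 at
  # (0,0), (t,0), (t,h), (0,h)
  edof <- cbind(2L * n1 - 1L, 2L * n1, 2L * n2 - 1L, 2L * n2,
                2L * n3 - 1L, 2L * n3, 2L * n4 - 1L, 2L * n4)
  E <- as.vector(elast$E); nu <- as.vector(elast$nu)
  cA <- E / (1 - nu^2)
  cS <- E / (2 * (1 + nu))
  k1 <- as.vector(ks$K1); k2 <- as.vector(ks$K2); k3 <- as.vector(ks$K3)
  vals <- outer(cA, k1) + outer(cA * nu, k2) + outer(cS, k3)  # nelem x 64
  rows <- edof[, rep(seq_len(8), times = 8)]
  cols <- edof[, rep(seq_len(8), each = 8)]
  Matrix::sparseMatrix(i = as.vector(rows), j = as.vector(cols),
                       x = as.vector(vals), dims = c(2L * nx * ny, 2L * nx * ny))
}

# Solve K u = f with Dirichlet values u[fixed_dofs] = fixed_vals.
solve_constrained <- function(K, f, fixed_dofs, fixed_vals) {
  n <- length(f)
  free <- setdiff(seq_len(n), fixed_dofs)
  if (length(free) == 0L) stop("fem: no free degrees of freedom")
  u <- numeric(n)
  u[fixed_dofs] <- fixed_vals
  rhs <- f[free] - as.vector(K[free, fixed_dofs, drop = FALSE] %*% fixed_vals)
  Kff <- Matrix::forceSymmetric(K[free, free, drop = FALSE])
  uf <- tryCatch(
    as.vector(Matrix::solve(Kff, rhs)),
    error = function(e) stop("fem: singular or ill-conditioned system (",
                             conditionMessage(e),
                             "); check boundary constraints")
  )
  u[free] <- uf
  resid <- as.vector(K %*% u) - f
  resid[fixed_dofs] <- 0  # reaction forces, not an error
  attr(u, "rel_residual") <- sqrt(sum(resid^2)) / max(sqrt(sum(f^2)), 1e-300)
  u
}

# Consistent nodal loads for a traction profile q(y) on the right edge,
# per-segment 2-point Gauss, then rescaled so the total is exactly F.
right_edge_loads <- function(grid, qfun, F) {
  ny <- grid$ny; h <- grid$h
  ys <- grid$origin[2] + (seq_len(ny) - 1) * h
  fn <- numeric(ny)
  gp <- 1 / sqrt(3)
  for (j in seq_len(ny - 1L)) {
    y0 <- ys[j]
    for (s in c(-gp, gp)) {
      yg <- y0 + (s + 1) / 2 * h
      q <- qfun(yg)
      N1 <- (1 - s) / 2; N2 <- (1 + s) / 2
      fn[j] <- fn[j] + q * N1 * h / 2
      fn[j + 1L] <- fn[j + 1L] + q * N2 * h / 2
    }
  }
  tot <- sum(fn)
  if (abs(tot) < 1e-300) stop("fem: traction profile integrates to zero")
  fn * (F / tot)
}

traction_profile <- function(load, grid) {
  L <- (grid$ny - 1) * grid$h
  y0 <- grid$origin[2]
  yc <- y0 + L / 2
  Fm <- load$F
  switch(load$profile,
    uniform_load = function(y) Fm / L,
    normal_load = {
      s <- load$profile_params$std_frac * L
      function(y) exp(-(y - yc)^2 / (2 * s^2))
    },
    central_uniform_load = {
      half <- load$profile_params$covered_frac * L / 2
      function(y) as.numeric(abs(y - yc) <= half + 1e-12)
    },
    stop("traction_profile: profile has no traction form: ", load$profile)
  )
}

#' Forward plane-stress solve on a structured grid
#'
#' Static linear elasticity with bilinear quadrilateral elements whose
#' material properties (E, nu) are constant per cell (the phantom's cell
#' grid). The left edge is fully clamped, the top and bottom edges are
#' traction-free, and the right edge carries the load described by a
#' [boundary_load()]. Displacements are returned on the Nx x Ny node grid.
#'
#' The returned field carries attributes: `"F"` (total applied force, for
#' `uniform_strain` the computed reaction), `"rel_residual"` (relative
#' algebraic residual of the solve), and `"load"`.
#'
#' @param phantom an [elasticity_field()] (or a phantom from
#'   [make_phantom()]) on the cell grid of `grid`
#' @param load a [boundary_load()]
#' @param grid the node [grid2d()]
#' @return a [displacement_field()]
#' @examples
#' g <- grid2d(8, 8, t = 1/7, h = 1/7)
#' ph <- make_phantom("homogeneous", g)
#' u <- forward_solve(ph, boundary_load("uniform_load", F = 0.01), g)
#' attr(u, "rel_residual") < 1e-8
#' @export
forward_solve <- function(phantom, load, grid) {
  elast <- if (inherits(phantom, "phantom")) phantom$elast else phantom
  if (!identical(dim(elast$E), as.integer(cell_dim(grid)))) {
    stop("forward_solve: phantom not defined on the cell grid of 'grid'")
  }
  nx <- grid$nx; ny <- grid$ny
  K <- assemble_stiffness(elast, grid)
  ndof <- 2L * nx * ny
  f <- numeric(ndof)
  left_nodes <- node_index(1L, seq_len(ny), nx)
  fixed <- c(2L * left_nodes - 1L, 2L * left_nodes)
  fixed_vals <- numeric(length(fixed))
  right_nodes <- node_index(nx, seq_len(ny), nx)

  if (identical(load$profile, "uniform_strain")) {
    # unit uniform x-displacement of the right edge, then scale by
    # linearity so the total reaction equals F
    fixed2 <- c(fixed, 2L * right_nodes - 1L)
    vals2 <- c(fixed_vals, rep(1, ny))
    u1 <- solve_constrained(K, f, fixed2, vals2)
    reaction <- sum((as.vector(K %*% u1))[2L * right_nodes - 1L])
    if (reaction <= 0) stop("fem: non-positive reaction under uniform strain")
    scale <- load$F / reaction
    u <- u1 * scale
    attr(u, "rel_residual") <- attr(u1, "rel_residual")
    Ftot <- load$F
  } else {
    qfun <- traction_profile(load, grid)
    f[2L * right_nodes - 1L] <- right_edge_loads(grid, qfun, load$F)
    u <- solve_constrained(K, f, fixed, fixed_vals)
    Ftot <- load$F
  }
  ux <- matrix(u[seq(1, ndof, 2)], nx, ny)
  uy <- matrix(u[seq(2, ndof, 2)], nx, ny)
  out <- displacement_field(ux, uy, grid)
  attr(out, "F") <- Ftot
  attr(out, "rel_residual") <- attr(u, "rel_residual")
  attr(out, "load") <- load
  out
}

#' Dirichlet-only solve (used by the patch test)
#'
#' Prescribes displacements on every boundary node from the supplied
#' functions and solves for the interior; no applied loads.
#'
#' @param elast an [elasticity_field()]
#' @param grid a [grid2d()]
#' @param ux_fun,uy_fun functions of (x, y) giving boundary displacements
#' @return a [displacement_field()]
#' @export
fem_solve_dirichlet <- function(elast, grid, ux_fun, uy_fun) {
  nx <- grid$nx; ny <- grid$ny
  K <- assemble_stiffness(elast, grid)
  nc <- node_coords(grid)
  on_bnd <- matrix(FALSE, nx, ny)
  on_bnd[1, ] <- TRUE; on_bnd[nx, ] <- TRUE
  on_bnd[, 1] <- TRUE; on_bnd[, ny] <- TRUE
  bidx <- which(on_bnd)
  fixed <- c(2L * bidx - 1L, 2L * bidx)
  vals <- c(ux_fun(nc$x[bidx], nc$y[bidx]), uy_fun(nc$x[bidx], nc$y[bidx]))
  u <- solve_constrained(K, numeric(2L * nx * ny), fixed, vals)
  ux <- matrix(u[seq(1, length(u), 2)], nx, ny)
  uy <- matrix(u[seq(2, length(u), 2)], nx, ny)
  displacement_field(ux, uy, grid)
}
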