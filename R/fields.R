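#' Field containers
#'
#' Light S3 wrappers pairing scalar-field matrices with their grid.
#' Displacements live on the Nx x Ny node grid; strain, stress and
#' elasticity on the (Nx-1) x (Ny-1) cell grid; equilibrium residuals on
#' (Nx-3) x (Ny-3). All constructors validate shapes and finiteness.
#'
#' @param ux,uy displacement components (length units), Nx x Ny matrices
#' @param grid a [grid2d()]
#' @return an object of the corresponding class
#' @name fields
NULL

#' @rdname fields
#' @export
displacement_field <- function(ux, uy, grid) {
  d <- c(grid$nx, grid$ny)
  check_mat(ux, d, "ux"); check_mat(uy, d, "uy")
  structure(list(ux = ux, uy = uy, grid = grid), class = "displacement_field")
}

#' @rdname fields
#' @param exx,eyy,gxy strain components (dimensionless) on the cell grid
#' @export
strain_field <- function(exx, eyy, gxy, grid) {
  d <- cell_dim(grid)
  check_mat(exx, d, "exx"); check_mat(eyy, d, "eyy"); check_mat(gxy, d, "gxy")
  structure(list(exx = exx, eyy = eyy, gxy = gxy, grid = grid),
            class = "strain_field")
}

#' @rdname fields
#' @param sxx,syy,txy stress components (stress units) on the cell grid
#' @export
stress_field <- function(sxx, syy, txy, grid) {
  d <- cell_dim(grid)
  check_mat(sxx, d, "sxx"); check_mat(syy, d, "syy"); check_mat(txy, d, "txy")
  structure(list(sxx = sxx, syy = syy, txy = txy, grid = grid),
            class = "stress_field")
}

#' @rdname fields
#' @param E Young's modulus (stress units), cell grid, strictly positive
#' @param nu Poisson's ratio (dimensionless), cell grid, in (-1, 0.5)
#' @export
elasticity_field <- function(E, nu, grid) {
  d <- cell_dim(grid)
  check_mat(E, d, "E"); check_mat(nu, d, "nu")
  if (any(E <= 0)) stop("elasticity_field: E must be > 0 everywhere")
  check_poisson(nu)
  structure(list(E = E, nu = nu, grid = grid), class = "elasticity_field")
}

# strict bound with a small guard so 1 - nu^2 stays well-conditioned
check_poisson <- function(nu, tol = 1e-6) {
  if (any(nu <= -1 + tol) || any(nu >= 0.5 - tol)) {
    stop("Poisson's ratio must lie strictly inside (-1, 0.5)")
  }
  invisible(nu)
}

#' @rdname fields
#' @param rx,ry equilibrium residual components on the (Nx-3) x (Ny-3) grid
#' @export
residual_field <- function(rx, ry, grid) {
  d <- residual_dim(grid)
  check_mat(rx, d, "rx"); check_mat(ry, d, "ry")
  structure(list(rx = rx, ry = ry, grid = grid), class = "residual_field")
}

#' @export
print.displacement_field <- function(x, ...) {
  cat(sprintf("<displacement_field> %d x %d nodes, mean |ux|=%.4g |uy|=%.4g\n",
              x$grid$nx, x$grid$ny, mean(abs(x$ux)), mean(abs(x$uy))))
  invisible(x)
}

#' @export
print.elasticity_field <- function(x, ...) {
  cat(sprintf("<elasticity_field> %d x %d cells, E in [%.4g, %.4g], nu in [%.3g, %.3g]\n",
              nrow(x$E), ncol(x$E), min(x$E), max(x$E), min(x$nu), max(x$nu)))
  invisible(x)
}
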