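#' Finite-difference convolution kernels
#'
#' The strain and equilibrium operators are sliding correlation sums
#' \deqn{(f * w)(i,j) = \sum_{a=1}^{A}\sum_{b=1}^{B} w(a,b)\, f(i+a-1,\, j+b-1)}
#' with no kernel flip and no padding. Kernels are stored in the package's
#' array convention: first index a = increasing x, second index b =
#' increasing y. In the common figure/image rendering (x along columns,
#' y upward along rows) each kernel appears as the transpose of the matrix
#' below.
#'
#' Strain kernels (2 x 2), differencing a node quantity to a cell center:
#' `wx` averages two forward x-differences, `wy` two forward y-differences.
#' Residual kernels (3 x 3) difference cell-centered stresses to the
#' interior residual grid: `rx` uses `wxx_x` (x-derivative of sxx) and
#' `wxy_x` (y-derivative of txy); `ry` uses `wyy_y` and `wxy_y`.
#' Every kernel sums to zero, so constants are annihilated.
#'
#' @return `fd_kernels()` returns a named list of kernel matrices.
#' @examples
#' k <- fd_kernels()
#' sum(k$wx)  # 0
#' @export
fd_kernels <- function() {
  # a (row) = x index, b (col) = y index
  wx <- matrix(c(-0.5, -0.5,
                  0.5,  0.5), 2, 2, byrow = TRUE)  # +/- along a (x)
  wy <- t(wx)                                      # +/- along b (y)
  ddx3 <- matrix(0, 3, 3); ddx3[1, ] <- -1; ddx3[3, ] <- 1  # x-difference
  ddy3 <- t(ddx3)                                           # y-difference
  list(
    wx = wx, wy = wy,
    wxx_x = ddx3, wyy_x = matrix(0, 3, 3), wxy_x = ddy3,
    wxx_y = matrix(0, 3, 3), wyy_y = ddy3, wxy_y = ddx3
  )
}

#' Valid (unpadded) correlation of a field with a kernel
#'
#' Plain sliding sum, correlation-style (no kernel flip): output entry
#' (i, j) is `sum_{a,b} kernel[a, b] * field[i + a - 1, j + b - 1]`.
#' Output shape is (M - A + 1) x (N - B + 1).
#'
#' @param field M x N numeric matrix
#' @param kernel A x B numeric matrix, A <= M and B <= N
#' @return the correlated matrix
#' @export
valid_convolve <- function(field, kernel) {
  M <- nrow(field); N <- ncol(field)
  A <- nrow(kernel); B <- ncol(kernel)
  if (M < A || N < B) stop("valid_convolve: field smaller than kernel")
  om <- M - A + 1L; on <- N - B + 1L
  out <- matrix(0, om, on)
  for (a in seq_len(A)) {
    for (b in seq_len(B)) {
      w <- kernel[a, b]
      if (w != 0) out <- out + w * field[a:(a + om - 1L), b:(b + on - 1L)]
    }
  }
  out
}

# Adjoint of valid_convolve w.r.t. the field: scatters an output-shaped
# gradient back to input shape. Needed by the training backward pass.
convolve_adjoint <- function(grad_out, kernel, dim_in) {
  A <- nrow(kernel); B <- ncol(kernel)
  om <- nrow(grad_out); on <- ncol(grad_out)
  gf <- matrix(0, dim_in[1], dim_in[2])
  for (a in seq_len(A)) {
    for (b in seq_len(B)) {
      w <- kernel[a, b]
      if (w != 0) {
        gf[a:(a + om - 1L), b:(b + on - 1L)] <-
          gf[a:(a + om - 1L), b:(b + on - 1L)] + w * grad_out
      }
    }
  }
  gf
}

#' Strain from displacement by finite differences
#'
#' Applies the 2 x 2 kernels of [fd_kernels()] to the displacement
#' components, mapping the Nx x Ny node grid to the (Nx-1) x (Ny-1) cell
#' grid:
#' eps_xx = (ux * wx)/sx, eps_yy = (uy * wy)/sy,
#' gamma_xy = (ux * wy)/sy + (uy * wx)/sx.
#'
#' In `"physical"` mode (sx, sy) = (t, h) so the result is a consistent
#' first-order derivative approximation, exact for affine displacement
#' fields. `"paper_literal"` mode uses (1, 1): the raw kernel sums, which
#' differ from physical mode by a fixed per-axis factor on a uniform grid.
#'
#' @param u a [displacement_field()]
#' @param spacing_mode `"physical"` (default) or `"paper_literal"`
#' @return a [strain_field()]
#' @export
strain_from_displacement_fd <- function(u, spacing_mode = c("physical", "paper_literal")) {
  spacing_mode <- match.arg(spacing_mode)
  k <- fd_kernels()
  g <- u$grid
  if (identical(spacing_mode, "physical")) {
    sx <- g$t; sy <- g$h
  } else {
    sx <- 1; sy <- 1
  }
  strain_field(
    exx = valid_convolve(u$ux, k$wx) / sx,
    eyy = valid_convolve(u$uy, k$wy) / sy,
    gxy = valid_convolve(u$ux, k$wy) / sy + valid_convolve(u$uy, k$wx) / sx,
    grid = g
  )
}

# 3x3 box sum (local aggregation used to normalize the PDE residual)
box3_sum <- function(m) valid_convolve(m, matrix(1, 3, 3))

#' Equilibrium residual of a stress field by finite differences
#'
#' Computes the discrete divergence of the stress field with the 3 x 3
#' kernels of [fd_kernels()], reducing the (Nx-1) x (Ny-1) cell grid to the
#' (Nx-3) x (Ny-3) residual grid:
#' rx = d(sxx)/dx + d(txy)/dy, ry = d(txy)/dx + d(syy)/dy.
#'
#' Each 3 x 3 kernel sums three central differences spanning 2 cells, so in
#' `"physical"` mode x-derivative sums are divided by 6 t and y-derivative
#' sums by 6 h, making the operator exact (zero residual) for stress fields
#' affine in (x, y). `"paper_literal"` divides the whole sum by h * t.
#'
#' When `elast` is supplied the normalized residual magnitude
#' `(|rx| + |ry|) / E_tilde` is attached as attribute `"normalized"`, where
#' `E_tilde` is the 3 x 3 box sum of the modulus over the same window.
#'
#' @param sigma a [stress_field()]
#' @param elast optional [elasticity_field()] for the normalization
#' @param grid grid (defaults to `sigma$grid`)
#' @param spacing_mode `"physical"` or `"paper_literal"`
#' @return a [residual_field()], optionally with attribute `"normalized"`
#' @export
equilibrium_residual_fd <- function(sigma, elast = NULL, grid = sigma$grid,
                                    spacing_mode = c("physical", "paper_literal")) {
  spacing_mode <- match.arg(spacing_mode)
  if (nrow(sigma$sxx) < 3L || ncol(sigma$sxx) < 3L) {
    stop("equilibrium_residual_fd: stress field must be at least 3 x 3")
  }
  k <- fd_kernels()
  if (identical(spacing_mode, "physical")) {
    dx <- 6 * grid$t; dy <- 6 * grid$h
    rx <- valid_convolve(sigma$sxx, k$wxx_x) / dx +
      valid_convolve(sigma$txy, k$wxy_x) / dy
    ry <- valid_convolve(sigma$txy, k$wxy_y) / dx +
      valid_convolve(sigma$syy, k$wyy_y) / dy
  } else {
    ht <- grid$h * grid$t
    rx <- (valid_convolve(sigma$sxx, k$wxx_x) +
             valid_convolve(sigma$txy, k$wxy_x)) / ht
    ry <- (valid_convolve(sigma$txy, k$wxy_y) +
             valid_convolve(sigma$syy, k$wyy_y)) / ht
  }
  res <- residual_field(rx, ry, grid)
  if (!is.null(elast)) {
    Et <- box3_sum(elast$E)
    if (any(Et <= 0)) stop("equilibrium_residual_fd: E_tilde <= 0 somewhere")
    attr(res, "normalized") <- (abs(rx) + abs(ry)) / Et
  }
  res
}
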