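#' Equispaced rectangular measurement grid
#'
#' Defines the node grid on which displacements are measured. Nodes are
#' indexed (i, j) with i = 1..Nx along x and j = 1..Ny along y; node (i, j)
#' sits at (x0 + (i-1) t, y0 + (j-1) h). Matrices attached to the grid use
#' the same convention: first (row) index = x, second (column) index = y.
#'
#' Derived grids: strain/stress/elasticity fields live on the
#' (Nx-1) x (Ny-1) cell centers, equilibrium residuals on (Nx-3) x (Ny-3).
#'
#' @param nx,ny number of grid lines along x and y (both >= 4 so the
#'   residual grid is non-empty)
#' @param t,h horizontal and vertical node spacing (length units, > 0)
#' @param origin physical coordinates (x0, y0) of node (1, 1)
#' @return an object of class `grid2d`
#' @examples
#' g <- grid2d(8, 6, t = 0.1, h = 0.2)
#' dim(node_coords(g)$x)
#' @export
grid2d <- function(nx, ny, t = 1, h = 1, origin = c(0, 0)) {
  nx <- as.integer(nx); ny <- as.integer(ny)
  if (nx < 4L || ny < 4L) {
    stop("grid2d: need nx >= 4 and ny >= 4 (residual grid must be non-empty)")
  }
  if (!is.finite(t) || !is.finite(h) || t <= 0 || h <= 0) {
    stop("grid2d: spacings t and h must be positive and finite")
  }
  structure(
    list(nx = nx, ny = ny, t = as.numeric(t), h = as.numeric(h),
         origin = as.numeric(origin[1:2])),
    class = "grid2d"
  )
}

#' @export
print.grid2d <- function(x, ...) {
  cat(sprintf("<grid2d> %d x %d nodes, spacing t=%g h=%g, origin (%g, %g)\n",
              x$nx, x$ny, x$t, x$h, x$origin[1], x$origin[2]))
  invisible(x)
}

#' Physical coordinates of grid nodes or cell centers
#'
#' @param grid a [grid2d()]
#' @return list with matrices `x`, `y` of the requested shape
#' @rdname node_coords
#' @export
node_coords <- function(grid) {
  xs <- grid$origin[1] + (seq_len(grid$nx) - 1) * grid$t
  ys <- grid$origin[2] + (seq_len(grid$ny) - 1) * grid$h
  list(x = matrix(xs, grid$nx, grid$ny),
       y = matrix(ys, grid$nx, grid$ny, byrow = TRUE))
}

#' @rdname node_coords
#' @export
cell_coords <- function(grid) {
  xs <- grid$origin[1] + (seq_len(grid$nx - 1) - 0.5) * grid$t
  ys <- grid$origin[2] + (seq_len(grid$ny - 1) - 0.5) * grid$h
  list(x = matrix(xs, grid$nx - 1, grid$ny - 1),
       y = matrix(ys, grid$nx - 1, grid$ny - 1, byrow = TRUE))
}

cell_dim <- function(grid) c(grid$nx - 1L, grid$ny - 1L)
residual_dim <- function(grid) c(grid$nx - 3L, grid$ny - 3L)

check_mat <- function(m, dims, what) {
  if (!is.matrix(m) || !identical(dim(m), as.integer(dims))) {
    stop(sprintf("%s: expected a %d x %d matrix", what, dims[1], dims[2]))
  }
  if (!all(is.finite(m))) stop(sprintf("%s: non-finite values", what))
  invisible(m)
}
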