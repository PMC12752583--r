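#' Generate a complete synthetic dataset
#'
#' Phantom -> forward FEM solve -> measurement noise. Returns everything a
#' recovery experiment needs: clean and noisy displacements, the true
#' elasticity fields, the load (and its total force) and the grid.
#'
#' Because the forward problem is linear, the datasets generated from
#' (c * E, c * F) are identical for every c > 0 -- the identifiability gap
#' that Phase-2 calibration resolves.
#'
#' @param phantom a `phantom` from [make_phantom()] (or an
#'   [elasticity_field()])
#' @param grid node [grid2d()]
#' @param load a [boundary_load()]
#' @param noise a [noise_spec()] or NULL for clean data
#' @return an object of class `elast_dataset`
#' @examples
#' g <- grid2d(12, 12, t = 1/11, h = 1/11)
#' ds <- make_dataset(make_phantom("inclusion", g), g,
#'                    boundary_load("uniform_load", F = 0.01),
#'                    noise_spec("gaussian", snr = 100, seed = 7))
#' @export
make_dataset <- function(phantom, grid, load = boundary_load("uniform_load", F = 1),
                         noise = NULL) {
  u_clean <- forward_solve(phantom, load, grid)
  u_obs <- if (is.null(noise)) u_clean else add_noise(u_clean, noise)
  elast <- if (inherits(phantom, "phantom")) phantom$elast else phantom
  structure(list(u_clean = u_clean, u_obs = u_obs, elast_true = elast,
                 phantom = phantom, load = load, F = attr(u_clean, "F"),
                 noise = noise, grid = grid),
            class = "elast_dataset")
}

#' @export
print.elast_dataset <- function(x, ...) {
  cat(sprintf("<elast_dataset> %d x %d grid, load %s F=%g, noise %s\n",
              x$grid$nx, x$grid$ny, x$load$profile, x$F,
              if (is.null(x$noise)) "none"
              else sprintf("%s SNR=%g seed=%d", x$noise$kind, x$noise$snr,
                           x$noise$seed)))
  invisible(x)
}
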