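#' Plane-stress constitutive relation
#'
#' Maps strain to stress pointwise through the isotropic plane-stress law
#' \deqn{\sigma_{xx} = \frac{E}{1-\nu^2}(\varepsilon_{xx} + \nu\,\varepsilon_{yy}),\quad
#'       \sigma_{yy} = \frac{E}{1-\nu^2}(\nu\,\varepsilon_{xx} + \varepsilon_{yy}),\quad
#'       \tau_{xy} = \frac{E}{2(1+\nu)}\,\gamma_{xy}.}
#' E and nu may vary cell by cell; strain and elasticity share the cell grid
#' so the relation applies without interpolation.
#'
#' @param strain a [strain_field()]
#' @param elast an [elasticity_field()] on the same grid
#' @return a [stress_field()]
#' @examples
#' g <- grid2d(4, 4)
#' s <- strain_field(matrix(0.01, 3, 3), matrix(0, 3, 3), matrix(0, 3, 3), g)
#' el <- elasticity_field(matrix(1, 3, 3), matrix(0.3, 3, 3), g)
#' stress_from_strain(s, el)$sxx[1, 1]  # 0.01/0.91
#' @export
stress_from_strain <- function(strain, elast) {
  if (!identical(dim(strain$exx), dim(elast$E))) {
    stop("stress_from_strain: strain and elasticity shapes differ")
  }
  check_poisson(elast$nu)
  k <- elast$E / (1 - elast$nu^2)
  stress_field(
    sxx = k * (strain$exx + elast$nu * strain$eyy),
    syy = k * (elast$nu * strain$exx + strain$eyy),
    txy = k * (1 - elast$nu) / 2 * strain$gxy,
    grid = strain$grid
  )
}

#' Field error metrics
#'
#' `mae()` is the mean absolute pointwise difference; `mre()` the mean
#' relative difference in percent, `100 * mean(|est - truth| / truth)`.
#' Both accept plain matrices (or vectors) of matching shape.
#'
#' @param est,truth numeric arrays of identical shape
#' @return a single number (percent for `mre`)
#' @examples
#' mae(c(1, 2, 3, 4), c(0, 2, 4, 4))  # 0.5
#' mre(c(1, 3), c(2, 2))              # 50
#' @export
mae <- function(est, truth) {
  if (!identical(dim(est), dim(truth)) || length(est) != length(truth)) {
    stop("mae: shape mismatch")
  }
  mean(abs(est - truth))
}

#' @rdname mae
#' @export
mre <- function(est, truth) {
  if (!identical(dim(est), dim(truth)) || length(est) != length(truth)) {
    stop("mre: shape mismatch")
  }
  if (any(truth == 0)) stop("mre: truth contains zeros")
  100 * mean(abs(est - truth) / truth)
}
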