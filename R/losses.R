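#' Training loss terms
#'
#' The four L1 loss terms combined (with non-negative weights) into the
#' Phase-1 objective
#' `L = lam_u L_u + lam_eps L_eps + lam_r L_r + lam_E L_E`:
#' \describe{
#'   \item{`loss_displacement`}{mean over the node grid of
#'     `|dux| + |duy|` between predicted and observed displacements.}
#'   \item{`loss_strain`}{mean over the cell grid of the summed absolute
#'     differences of the three strain components.}
#'   \item{`loss_pde`}{stress from the constitutive law, equilibrium
#'     residuals by the 3x3 finite-difference kernels, then the mean of
#'     `(|rx| + |ry|) / E_tilde` over the residual grid, where `E_tilde`
#'     is the 3x3 neighborhood sum of the modulus. The normalization makes
#'     the term invariant to a global rescaling of E (and hence of stress),
#'     which is exactly the non-identifiability Phase 2 resolves.}
#'   \item{`loss_modulus`}{anchors the arbitrary modulus scale:
#'     `"pointwise"` (default) is the mean of `|E_hat - Ec|`;
#'     `"mean_anchor"` penalizes `|mean(E_hat) - Ec|` only.}
#' }
#'
#' @param pred_u,obs_u [displacement_field()]s on the same grid
#' @return each loss returns a single non-negative number
#' @name losses
NULL

#' @rdname losses
#' @export
loss_displacement <- function(pred_u, obs_u) {
  if (!identical(dim(pred_u$ux), dim(obs_u$ux))) stop("loss_displacement: shape mismatch")
  mean(abs(pred_u$ux - obs_u$ux) + abs(pred_u$uy - obs_u$uy))
}

#' @rdname losses
#' @param net_strain,fd_strain [strain_field()]s on the same cell grid
#' @export
loss_strain <- function(net_strain, fd_strain) {
  if (!identical(dim(net_strain$exx), dim(fd_strain$exx))) stop("loss_strain: shape mismatch")
  mean(abs(net_strain$exx - fd_strain$exx) +
         abs(net_strain$eyy - fd_strain$eyy) +
         abs(net_strain$gxy - fd_strain$gxy))
}

#' @rdname losses
#' @param strain a [strain_field()]
#' @param elast an [elasticity_field()]
#' @param grid a [grid2d()] (defaults to the strain's grid)
#' @param spacing_mode passed to [equilibrium_residual_fd()]
#' @export
loss_pde <- function(strain, elast, grid = strain$grid,
                     spacing_mode = c("physical", "paper_literal")) {
  spacing_mode <- match.arg(spacing_mode)
  sigma <- stress_from_strain(strain, elast)
  res <- equilibrium_residual_fd(sigma, elast, grid, spacing_mode)
  mean(attr(res, "normalized"))
}

#' @rdname losses
#' @param E_hat modulus matrix (cell grid)
#' @param Ec positive anchor value
#' @param mode `"pointwise"` or `"mean_anchor"`
#' @export
loss_modulus <- function(E_hat, Ec, mode = c("pointwise", "mean_anchor")) {
  mode <- match.arg(mode)
  if (!is.finite(Ec) || Ec <= 0) stop("loss_modulus: Ec must be > 0")
  if (mode == "pointwise") mean(abs(E_hat - Ec)) else abs(mean(E_hat) - Ec)
}
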