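#' Boundary stress profile from a Phase-1 result
#'
#' Samples the predicted relative normal stress along the loaded boundary.
#' The stress lives on cell centers, so for the right side the outermost
#' stress-grid column is used (offset t/2 inward from the physical edge;
#' boundary normal (nx, ny) = (1, 0)), giving Ny - 1 samples at spacing h.
#' The stress is the Phase-1 predicted stress (strain network x elasticity
#' network through the constitutive law), not a finite difference of the
#' denoised displacements.
#'
#' @param result a `phase1_result` (or any list with a [stress_field()] in
#'   `$stress`)
#' @param side must be `"right"` (the loaded side)
#' @return numeric vector of sigma_xx samples along the boundary column
#' @export
boundary_stress_profile <- function(result, side = "right") {
  if (!identical(side, "right")) {
    stop("boundary_stress_profile: loads are applied on the right side only")
  }
  sxx <- result$stress$sxx
  sxx[nrow(sxx), ]
}

#' Absolute-scale calibration factor
#'
#' The equilibrium equations determine the modulus only up to a global
#' factor c. Given the known total boundary force F, the factor is
#' recovered by matching the integrated predicted boundary stress to F:
#' \deqn{\hat c = F \Big/ \sum_i \hat\sigma_{xx}(x_b, y_i)\, h}
#' (rectangle rule by default, matching the discrete force balance;
#' trapezoid available).
#'
#' @param profile boundary sigma_xx samples from [boundary_stress_profile()]
#' @param F total applied boundary force per unit thickness, > 0
#' @param h sample spacing along the boundary
#' @param rule `"rectangle"` (default) or `"trapezoid"`
#' @return the scale factor c_hat (> 0)
#' @examples
#' calibrate_scale(rep(0.5, 10), F = 1, h = 0.1)  # 2
#' @export
calibrate_scale <- function(profile, F, h, rule = c("rectangle", "trapezoid")) {
  rule <- match.arg(rule)
  if (!is.finite(F) || F <= 0) stop("calibrate_scale: F must be > 0")
  denom <- if (rule == "rectangle") {
    sum(profile) * h
  } else {
    sum((profile[-1] + profile[-length(profile)]) / 2) * h
  }
  if (!is.finite(denom) || denom <= 0) {
    stop("calibrate_scale: integrated boundary stress is not positive; ",
         "predicted stress is sign-inconsistent with the applied force")
  }
  F / denom
}

#' Apply the scale calibration
#'
#' Scales the relative modulus and stress by c_hat; Poisson's ratio is a
#' dimensionless ratio and is left untouched. The recomputed boundary
#' force at c_hat equals F by construction (exact self-consistency).
#'
#' @param result a `phase1_result`
#' @param c_hat scale factor from [calibrate_scale()], > 0
#' @param F optional force used for the consistency check field
#' @return an object of class `calibration_result` with `c_hat`,
#'   `E_absolute` (matrix), `nu` (unchanged), `stress` (rescaled) and
#'   `boundary_force_check`
#' @export
apply_calibration <- function(result, c_hat, F = NULL) {
  if (!is.finite(c_hat) || c_hat <= 0) stop("apply_calibration: c_hat must be > 0")
  g <- result$grid
  stress <- stress_field(result$stress$sxx * c_hat,
                         result$stress$syy * c_hat,
                         result$stress$txy * c_hat, g)
  force_check <- sum(stress$sxx[nrow(stress$sxx), ]) * g$h
  structure(list(c_hat = c_hat,
                 E_absolute = result$E_hat * c_hat,
                 nu = result$nu_hat,
                 stress = stress,
                 boundary_force_check = force_check,
                 Ec = result$Ec),
            class = "calibration_result")
}

#' Full Phase-2 pipeline
#'
#' Convenience wrapper: boundary profile, scale factor, calibrated fields.
#'
#' @param result a `phase1_result`
#' @param F total applied boundary force per unit thickness
#' @param side loaded side (`"right"`)
#' @param rule quadrature rule for [calibrate_scale()]
#' @return a `calibration_result`
#' @export
calibrate <- function(result, F, side = "right", rule = "rectangle") {
  prof <- boundary_stress_profile(result, side)
  c_hat <- calibrate_scale(prof, F, result$grid$h, rule)
  apply_calibration(result, c_hat, F)
}

#' @export
print.calibration_result <- function(x, ...) {
  cat(sprintf("<calibration_result> c_hat = %.6g (Ec was %g)\n", x$c_hat, x$Ec))
  cat(sprintf("  E_absolute in [%.4g, %.4g]; boundary force check = %.6g\n",
              min(x$E_absolute), max(x$E_absolute), x$boundary_force_check))
  invisible(x)
}
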