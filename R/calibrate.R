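# Analytic calibration of generator links to a target regression summary.
#
# A published simple-regression caption (slope b, R2, RMSE) fully determines
# a bivariate-normal generating mechanism:
#   Var(y)  = RMSE^2 / (1 - R2)            (RMSE = sd of y about the line)
#   "inverse" link  p = c + a*(y - mu_y) + eps:
#     a        = R2 / b                    (from b = Cov/Var(p), R2 = Cov^2/(Vy*Vp))
#     Var(p)   = Var(y) * R2 / b^2
#     Var(eps) = Var(p) * (1 - R2)
#   "forward" design  y = c + b*x + eps:
#     Var(x)   = RMSE^2 * R2 / ((1 - R2) * b^2)
#     sd(eps)  = RMSE
# Regressing y on p (or y on x) then recovers (b, R2, RMSE) in expectation,
# because a bivariate normal is linear in either direction.

#' Calibrate an inverse latent link to a target regression summary
#'
#' Solves the coefficient and noise SD of a latent link
#' `p = intercept + a * (y - mean(y)) + eps` such that the forward simple
#' regression of the trait `y` on the latent variable `p` reproduces a
#' target `(slope, r2, rmse)` triple exactly in expectation. Used to pin
#' the chemistry-to-NMR links to published figure captions.
#'
#' @param slope Target slope of y on p.
#' @param r2 Target coefficient of determination, in (0, 1).
#' @param rmse Target residual standard error, > 0.
#' @return List with `trait_var` (implied Var(y)), `coef` (a), `resid_sd`
#'   (sd of eps), and `latent_var` (implied Var(p)).
#' @examples
#' cal <- calibrate_link(slope = -10.5, r2 = 0.287, rmse = 0.094)
#' # round-trip through the forward identities
#' vy <- cal$trait_var; vp <- cal$coef^2 * vy + cal$resid_sd^2
#' c(slope = cal$coef * vy / vp, r2 = cal$coef^2 * vy / vp)
#' @export
calibrate_link <- function(slope, r2, rmse) {
  check_target_triple(slope, r2, rmse)
  trait_var <- rmse^2 / (1 - r2)
  a <- r2 / slope
  latent_var <- trait_var * r2 / slope^2
  resid_var <- latent_var * (1 - r2)
  if (resid_var <= 0) abort("infeasible target triple: implied residual variance <= 0")
  list(trait_var = trait_var, coef = a, resid_sd = sqrt(resid_var),
       latent_var = latent_var)
}

#' Calibrate a forward regression design to a target summary
#'
#' Solves the predictor variance and residual SD of the direct design
#' `y = intercept + slope * x + eps` so that the fitted regression of y on
#' x reproduces a target `(slope, r2, rmse)` triple in expectation. Used to
#' pin the NIRS-to-chemistry structure to published captions.
#'
#' @inheritParams calibrate_link
#' @return List with `x_var`, `resid_sd` (= rmse) and implied `y_var`.
#' @export
calibrate_regression <- function(slope, r2, rmse) {
  check_target_triple(slope, r2, rmse)
  x_var <- rmse^2 * r2 / ((1 - r2) * slope^2)
  list(x_var = x_var, resid_sd = rmse, y_var = rmse^2 / (1 - r2))
}

#' Calibrate the NIRS link to a target regression summary
#'
#' Solves the device slope and between-sample noise SD of the NIRS link
#' (latent reading = intercept + slope * IMF + between-sample noise; each
#' replicate adds replicate noise) so that regressing chemical IMF on the
#' mean of `n_replicates` readings reproduces the target triple, given the
#' generator's actual IMF variance.
#'
#' @inheritParams calibrate_link
#' @param imf_var Variance of chemical IMF in the population the regression
#'   will be run on (for a pooled two-muscle cohort, the pooled variance).
#' @param replicate_sd Within-sample replicate noise SD, held fixed.
#' @param n_replicates Readings averaged per sample (default 3).
#' @return List with `slope` (device slope), `between_sd`, and the implied
#'   latent-reading variance `x_var`.
#' @export
calibrate_nirs <- function(slope, r2, rmse, imf_var,
                           replicate_sd = 0, n_replicates = 3L) {
  check_target_triple(slope, r2, rmse)
  if (imf_var <= 0) abort("`imf_var` must be > 0")
  gamma <- r2 / slope
  x_var <- gamma * imf_var / slope
  noise_var <- x_var * (1 - r2) - replicate_sd^2 / n_replicates
  if (noise_var <= 0) {
    abort("infeasible NIRS target: replicate noise alone exceeds the implied total noise")
  }
  list(slope = gamma, between_sd = sqrt(noise_var), x_var = x_var)
}

check_target_triple <- function(slope, r2, rmse) {
  if (!is.finite(slope) || slope == 0) abort("target slope must be finite and nonzero")
  if (!is.finite(r2) || r2 <= 0 || r2 >= 1) abort("target R2 must lie in (0, 1)")
  if (!is.finite(rmse) || rmse <= 0) abort("target RMSE must be > 0")
  invisible(TRUE)
}
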