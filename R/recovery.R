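# Parameter-recovery experiment builders: each published regression
# caption (slope, R2, RMSE) is inverted analytically into a generating
# mechanism, data are drawn at the study size, and the estimators are run
# on them. Recovery of the caption values exercises the estimators, not
# the generator alone.

#' Simulate a caption-calibrated simple regression data set
#'
#' Draws `(x, y)` with `y = intercept + slope * x + noise`, where the
#' predictor variance and noise SD are solved analytically from the target
#' triple by [calibrate_regression()]. The fitted regression of y on x
#' recovers the target slope, R2 and RMSE in expectation.
#'
#' @param slope,r2,rmse Target regression summary.
#' @param n Samples.
#' @param x_mean,intercept Location parameters (do not affect recovery).
#' @param seed Integer seed.
#' @return Tibble with columns `x`, `y`.
#' @export
simulate_regression_cohort <- function(slope, r2, rmse, n,
                                       x_mean = 0, intercept = 0, seed = 1L) {
  cal <- calibrate_regression(slope, r2, rmse)
  with_seed(seed, {
    x <- rnorm(n, x_mean, sqrt(cal$x_var))
    y <- intercept + slope * x + rnorm(n, 0, cal$resid_sd)
    tibble::tibble(x = x, y = y)
  })
}

#' Simulate a caption-calibrated trait-to-NMR link data set
#'
#' Draws a chemical trait and a latent NMR parameter linked to it with the
#' inverse-link coefficients from [calibrate_link()], so that regressing
#' the trait on the NMR parameter recovers the target triple in
#' expectation. This mirrors the direction the instrument link works in
#' (chemistry drives the relaxation parameter; the analyst regresses
#' chemistry on it).
#'
#' @param slope,r2,rmse Target regression summary of trait on parameter.
#' @param n Samples.
#' @param trait_mean Trait location.
#' @param param_mean NMR-parameter location.
#' @param seed Integer seed.
#' @return Tibble with columns `param` (predictor), `trait` (response).
#' @export
simulate_link_cohort <- function(slope, r2, rmse, n,
                                 trait_mean = 0, param_mean = 0.05, seed = 1L) {
  cal <- calibrate_link(slope, r2, rmse)
  with_seed(seed, {
    trait <- rnorm(n, trait_mean, sqrt(cal$trait_var))
    param <- param_mean + cal$coef * (trait - trait_mean) +
      rnorm(n, 0, cal$resid_sd)
    tibble::tibble(param = param, trait = trait)
  })
}

#' Average recovered regression summary over repeated cohorts
#'
#' Repeats a cohort-generating function and [ols_regression()] fit
#' `n_cohorts` times under derived seeds and averages the recovered slope,
#' R2 and RMSE.
#'
#' @param generator Function `(seed) -> tibble` with predictor in column 1
#'   and response in column 2.
#' @param n_cohorts Repetitions.
#' @param seed Base seed; cohort `i` uses `seed + i`.
#' @return One-row tibble `(mean_slope, mean_r2, mean_rmse, n_cohorts)`.
#' @export
recover_regression <- function(generator, n_cohorts = 200, seed = 1L) {
  fits <- purrr::map_dfr(seq_len(n_cohorts), function(i) {
    d <- generator((seed + i) %% 2147483647)
    ols_regression(d[[1]], d[[2]])
  })
  tibble::tibble(
    mean_slope = mean(fits$slope),
    mean_r2 = mean(fits$r2),
    mean_rmse = mean(fits$rmse),
    n_cohorts = n_cohorts
  )
}
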