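#' Simple linear regression summary
#'
#' Closed-form ordinary least squares of `y` on `x` with the summary
#' quantities reported throughout meat-quality regression tables: slope
#' with standard error, intercept, coefficient of determination, two-sided
#' p-value from the t distribution with `n - 2` degrees of freedom, and
#' RMSE. RMSE defaults to the residual standard error
#' `sqrt(SSE / (n - 2))`; `rmse_df_adjust = FALSE` gives `sqrt(SSE / n)`
#' (the two differ by under 1% at typical cohort sizes).
#'
#' Can be called either on two numeric vectors or data-frame-first with
#' bare column names: `ols_regression(cohort, nirs_mean, imf_pct)`.
#'
#' @param x Numeric predictor, or a data frame.
#' @param y Numeric response, or (data-frame form) the predictor column.
#' @param ... Data-frame form only: the response column.
#' @param rmse_df_adjust Use `n - 2` in the RMSE denominator (default).
#' @return One-row tibble: `slope`, `slope_se`, `intercept`, `r2`,
#'   `p_value`, `rmse`, `n`.
#' @export
ols_regression <- function(x, y, ..., rmse_df_adjust = TRUE) {
  if (is.data.frame(x)) {
    data <- x
    vars <- rlang::enquos(y, ...)
    if (length(vars) != 2) abort("data-frame form needs predictor and response columns")
    xv <- rlang::eval_tidy(vars[[1]], data)
    yv <- rlang::eval_tidy(vars[[2]], data)
    return(ols_regression(xv, yv, rmse_df_adjust = rmse_df_adjust))
  }
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 3 || length(y) != n) abort("need equal-length x and y with n >= 3")
  sxx <- sum((x - mean(x))^2)
  if (sxx == 0) abort("degenerate design: x is constant")
  sxy <- sum((x - mean(x)) * (y - mean(y)))
  slope <- sxy / sxx
  intercept <- mean(y) - slope * mean(x)
  resid <- y - intercept - slope * x
  sse <- sum(resid^2)
  sst <- sum((y - mean(y))^2)
  sigma2 <- sse / (n - 2)
  se <- sqrt(sigma2 / sxx)
  tval <- slope / se
  tibble::tibble(
    slope = slope,
    slope_se = se,
    intercept = intercept,
    r2 = if (sst > 0) 1 - sse / sst else NA_real_,
    p_value = 2 * pt(-abs(tval), df = n - 2),
    rmse = if (rmse_df_adjust) sqrt(sigma2) else sqrt(sse / n),
    n = n
  )
}

#' Aggregate a NIRS reading triplet
#'
#' The three replicate device readings per sample are summarised as their
#' arithmetic mean, geometric mean and highest value.
#'
#' @param x A numeric vector of exactly three positive readings, or a data
#'   frame with columns `nirs_1`, `nirs_2`, `nirs_3`.
#' @return For a triplet, a one-row tibble `(mean, geometric_mean,
#'   highest)`; for a data frame, the input with columns `nirs_mean`,
#'   `nirs_geomean`, `nirs_max` appended.
#' @export
aggregate_nirs <- function(x) {
  if (is.data.frame(x)) {
    r <- as.matrix(x[, c("nirs_1", "nirs_2", "nirs_3")])
    if (any(!is.finite(r)) || any(r <= 0)) {
      bad <- which(apply(r, 1, function(v) any(!is.finite(v)) || any(v <= 0)))
      abort(paste0("non-positive NIRS reading(s) in row(s): ",
                   paste(utils::head(bad, 5), collapse = ", ")))
    }
    x$nirs_mean <- rowMeans(r)
    x$nirs_geomean <- exp(rowMeans(log(r)))
    x$nirs_max <- apply(r, 1, max)
    return(x)
  }
  if (length(x) != 3) abort("a NIRS triplet must have exactly three readings")
  bad <- which(!is.finite(x) | x <= 0)
  if (length(bad) > 0) {
    abort(paste0("non-positive NIRS reading at position ", bad[1]))
  }
  tibble::tibble(mean = mean(x), geometric_mean = prod(x)^(1 / 3), highest = max(x))
}

#' Pairwise Pearson correlation matrix with p-values
#'
#' Pairwise-complete Pearson correlations between the selected numeric
#' columns, with two-sided p-values from the t transform of r on `n - 2`
#' degrees of freedom. Diagonal entries have r = 1 and no p-value.
#'
#' @param data A data frame.
#' @param columns Character vector of column names (default: all numeric
#'   columns).
#' @return A long tibble `(var1, var2, r, p_value, n)`, symmetric in
#'   `(var1, var2)`.
#' @export
pearson_matrix <- function(data, columns = NULL) {
  if (is.null(columns)) {
    columns <- names(data)[vapply(data, is.numeric, logical(1))]
  }
  grid <- expand.grid(var1 = columns, var2 = columns,
                      stringsAsFactors = FALSE)
  purrr::pmap_dfr(grid, function(var1, var2) {
    x <- data[[var1]]; y <- data[[var2]]
    ok <- is.finite(x) & is.finite(y)
    n <- sum(ok)
    if (var1 == var2) {
      return(tibble::tibble(var1 = var1, var2 = var2, r = 1,
                            p_value = NA_real_, n = n))
    }
    r <- cor(x[ok], y[ok])
    tval <- r * sqrt((n - 2) / (1 - r^2))
    tibble::tibble(var1 = var1, var2 = var2, r = r,
                   p_value = 2 * pt(-abs(tval), df = n - 2), n = n)
  })
}

#' Two-muscle trait contrast
#'
#' Compares a trait between the two muscles with a two-group linear model
#' (a fixed muscle term only; with no random terms this is the two-sample
#' comparison with pooled variance). Reports per-muscle means and SEMs and
#' the two-sided p-value of the muscle effect.
#'
#' @param data Cohort-style data frame with a `muscle` column.
#' @param trait Name of the trait column.
#' @return Tibble with one row per muscle (`muscle`, `mean`, `sem`, `n`)
#'   and the contrast p-value in column `p_value` (repeated).
#' @export
muscle_contrast <- function(data, trait) {
  y <- data[[trait]]
  m <- factor(data$muscle)
  if (nlevels(m) != 2) abort("`data` must contain exactly two muscle labels")
  fit <- lm(y ~ m)
  p <- summary(fit)$coefficients[2, 4]
  sigma <- summary(fit)$sigma
  dplyr::summarise(
    dplyr::group_by(tibble::tibble(muscle = as.character(m), y = y), .data$muscle),
    mean = mean(.data$y), n = dplyr::n(), .groups = "drop"
  ) |>
    dplyr::mutate(sem = sigma / sqrt(.data$n), p_value = p) |>
    dplyr::select("muscle", "mean", "sem", "n", "p_value")
}

#' Cross-muscle trait regressions
#'
#' Regresses each topside (SM) trait on the matching loin (LTL) trait
#' across carcasses: one [ols_regression()] per trait with SM as response
#' and LTL as predictor.
#'
#' @param cohort Cohort tibble with both muscles per carcass.
#' @param traits Trait columns to regress.
#' @return Tibble with one row per trait and all regression-summary
#'   columns.
#' @export
cross_muscle_regression <- function(cohort,
                                    traits = c("pH", "collagen_mg_g",
                                               "collagen_solubility_pct",
                                               "imf_pct")) {
  wide <- tidyr::pivot_wider(
    dplyr::select(cohort, "carcass_id", "muscle", dplyr::all_of(traits)),
    names_from = "muscle", values_from = dplyr::all_of(traits),
    names_glue = "{.value}_{muscle}"
  )
  purrr::map_dfr(traits, function(tr) {
    ltl <- wide[[paste0(tr, "_LTL")]]
    sm <- wide[[paste0(tr, "_SM")]]
    dplyr::bind_cols(tibble::tibble(trait = tr), ols_regression(ltl, sm))
  })
}
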