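# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths: the OLS oracle goes through the raw normal
# equations, and the tri-exponential grid oracle is an exhaustive search.

# Textbook normal-equation solution for simple linear regression.
ols_oracle <- function(x, y) {
  X <- cbind(1, x)
  beta <- solve(t(X) %*% X, t(X) %*% y)
  n <- length(y)
  resid <- y - X %*% beta
  sse <- sum(resid^2)
  sst <- sum((y - mean(y))^2)
  sigma2 <- sse / (n - 2)
  cov_beta <- sigma2 * solve(t(X) %*% X)
  tval <- beta[2] / sqrt(cov_beta[2, 2])
  list(intercept = beta[1], slope = beta[2], slope_se = sqrt(cov_beta[2, 2]),
       r2 = 1 - sse / sst, rmse = sqrt(sigma2),
       p_value = 2 * pt(-abs(tval), df = n - 2))
}

default_params <- function() {
  list(p_2f = 0.05, p_21 = 0.85, p_22 = 0.10,
       t_2f_ms = 10, t_21_ms = 40, t_22_ms = 150)
}

# Exhaustive grid search over (T_21, T_22) at 1 ms resolution and the
# amplitude simplex at 0.01 resolution (scale fixed at its known value).
# The amplitude grid is restricted to a physically sensible window around
# the fast/intermediate/slow split; the optimum of the toy problems lies
# strictly inside it, so the restriction cannot favour either method.
grid_search_fit <- function(t, y, scale,
                            t21_grid = 30:50, t22_grid = 130:170,
                            p2f_grid = seq(0, 0.2, 0.01),
                            p21_grid = seq(0.6, 1, 0.01)) {
  amp <- expand.grid(p_2f = p2f_grid, p_21 = p21_grid)
  amp$p_22 <- 1 - amp$p_2f - amp$p_21
  amp <- amp[amp$p_22 >= -1e-12, ]
  amp$p_22 <- pmax(amp$p_22, 0)
  A <- t(as.matrix(amp)) * scale # 3 x C
  best <- list(rss = Inf)
  ef <- exp(-t / 10)
  for (t21 in t21_grid) {
    e1 <- exp(-t / t21)
    for (t22 in t22_grid) {
      M <- cbind(ef, e1, exp(-t / t22)) # n x 3
      rss <- colSums((y - M %*% A)^2)
      j <- which.min(rss)
      if (rss[j] < best$rss) {
        best <- list(rss = rss[j], t_21_ms = t21, t_22_ms = t22,
                     p_2f = amp$p_2f[j], p_21 = amp$p_21[j], p_22 = amp$p_22[j])
      }
    }
  }
  best
}

quiet_fit_chemistry_slopes <- function(...) {
  suppressWarnings(suppressMessages(fit_chemistry_slopes(...)))
}

quiet_single_slope <- function(...) {
  suppressWarnings(suppressMessages(fit_single_predictor_slope(...)))
}
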