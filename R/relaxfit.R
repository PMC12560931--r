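#' Fit the tri-exponential CPMG decay model
#'
#' Decomposes an echo train into three relaxation components
#' `I(t) = scale * (p_2f exp(-t/T_2f) + p_21 exp(-t/T_21) + p_22 exp(-t/T_22))`
#' with the fast time constant `T_2f` held fixed (default 10 ms, which
#' stabilises the fit) and fractional amplitudes constrained nonnegative
#' and summing to one.
#'
#' The problem is solved by variable projection: for any candidate pair
#' `(T_21, T_22)` the three component amplitudes enter linearly, so the
#' inner problem is an exact nonnegative least-squares solve (subset
#' enumeration, exact for three components); the outer bounded search over
#' `(log T_21, log T_22)` is run from a log-spaced multi-start grid and the
#' best objective is kept. Multi-exponential objectives are multimodal and
#' the multi-start is the standard guard.
#'
#' If the two fitted time constants agree within `collapse_rel_tol` the fit
#' is flagged degenerate and the merged amplitude is reported under `p_21`
#' (identifiability loss is surfaced, not silently returned).
#'
#' @param train An [echo_train()] (or data frame with `echo_time_ms`,
#'   `intensity`), at least 10 echoes.
#' @param options A [fit_options()].
#' @return An object of class `relax_fit`: fitted `params` (fractional
#'   amplitudes and time constants, `t_2f_ms` echoed from the fixed
#'   input), `scale` (model intensity at t = 0), `residual_rms`,
#'   `converged`, `degenerate`, `n_starts_used`.
#' @export
fit_triexponential <- function(train, options = fit_options()) {
  t <- train$echo_time_ms
  y <- train$intensity
  if (length(t) < 10) abort("input error: need at least 10 echoes to fit 6 parameters")
  if (length(t) != length(y) || any(!is.finite(t)) || any(!is.finite(y))) {
    abort("echo train must have finite, equal-length times and intensities")
  }

  ef <- exp(-t / options$fixed_t2f_ms)
  objective <- function(lt) {
    basis <- cbind(ef, exp(-t / exp(lt[1])), exp(-t / exp(lt[2])))
    nnls3(basis, y)$rss
  }

  lo <- log(c(options$t21_bounds[1], options$t22_bounds[1]))
  hi <- log(c(options$t21_bounds[2], options$t22_bounds[2]))
  g <- options$n_starts_grid
  s1 <- seq(lo[1] + 0.05, hi[1] - 0.05, length.out = g)
  s2 <- seq(lo[2] + 0.05, hi[2] - 0.05, length.out = g)
  starts <- expand.grid(s1, s2)

  best <- NULL
  any_ok <- FALSE
  for (i in seq_len(nrow(starts))) {
    res <- tryCatch(
      nlminb(as.numeric(starts[i, ]), objective, lower = lo, upper = hi,
             control = list(rel.tol = options$rel_tol,
                            iter.max = options$max_iter)),
      error = function(e) NULL
    )
    if (is.null(res)) next
    if (res$convergence == 0) any_ok <- TRUE
    if (is.null(best) || res$objective < best$objective) best <- res
  }
  if (is.null(best)) abort("all starts failed")

  t21 <- exp(best$par[1])
  t22 <- exp(best$par[2])
  basis <- cbind(ef, exp(-t / t21), exp(-t / t22))
  sol <- nnls3(basis, y)
  amps <- sol$coef
  scale <- sum(amps)
  if (scale <= 0) {
    return(new_relax_fit(c(0, 1, 0), options$fixed_t2f_ms, t21, t22, 0,
                         sqrt(sol$rss / length(y)), FALSE, FALSE,
                         nrow(starts)))
  }
  p <- amps / scale
  # label stability: component 2 must be the faster free pool
  if (t21 > t22) {
    tmp <- t21; t21 <- t22; t22 <- tmp
    p <- p[c(1, 3, 2)]
  }
  degenerate <- (t22 - t21) / t21 < options$collapse_rel_tol
  if (degenerate) {
    p <- c(p[1], p[2] + p[3], 0)
  }
  new_relax_fit(p, options$fixed_t2f_ms, t21, t22, scale,
                sqrt(sol$rss / length(y)), any_ok, degenerate, nrow(starts))
}

new_relax_fit <- function(p, t2f, t21, t22, scale, rms, converged,
                          degenerate, n_starts) {
  structure(
    list(
      params = list(p_2f = p[1], p_21 = p[2], p_22 = p[3],
                    t_2f_ms = t2f, t_21_ms = t21, t_22_ms = t22),
      scale = scale,
      residual_rms = rms,
      converged = converged,
      degenerate = degenerate,
      n_starts_used = n_starts
    ),
    class = "relax_fit"
  )
}

# Exact nonnegative least squares for a 3-column basis: the unconstrained
# solution is kept if feasible, otherwise every support subset is solved
# and the feasible minimum taken (exhaustive over 2^3 supports, exact).
nnls3 <- function(E, y) {
  ete <- crossprod(E)
  ety <- crossprod(E, y)
  full <- tryCatch(solve(ete, ety), error = function(e) NULL)
  if (!is.null(full) && all(full >= -1e-10)) {
    coef <- pmax(as.numeric(full), 0)
    r <- y - E %*% coef
    return(list(coef = coef, rss = sum(r * r)))
  }
  best <- list(coef = numeric(3), rss = sum(y * y))
  subsets <- list(1L, 2L, 3L, c(1L, 2L), c(1L, 3L), c(2L, 3L))
  for (s in subsets) {
    a <- tryCatch(solve(ete[s, s, drop = FALSE], ety[s, , drop = FALSE]),
                  error = function(e) NULL)
    if (is.null(a) || any(a < 0)) next
    coef <- numeric(3)
    coef[s] <- as.numeric(a)
    r <- y - E %*% coef
    rss <- sum(r * r)
    if (rss < best$rss) best <- list(coef = coef, rss = rss)
  }
  best
}

#' Estimate the noise SD of an echo train
#'
#' With a fit supplied, the noise SD is the standard deviation of the fit
#' residuals. Without one, it is estimated from the first differences of
#' the final 10% of echoes divided by `sqrt(2)` (differencing removes the
#' slowly varying decay and any constant offset).
#'
#' @param train An [echo_train()].
#' @param fit Optional [fit_triexponential()] result for the same train.
#' @return Estimated per-echo noise SD, intensity units.
#' @export
estimate_noise <- function(train, fit = NULL) {
  y <- train$intensity
  if (!is.null(fit)) {
    pred <- fit$scale * triexp_decay(train$echo_time_ms, fit$params)
    return(stats::sd(y - pred))
  }
  k <- max(10L, ceiling(0.1 * length(y)))
  tail_y <- utils::tail(y, k)
  stats::sd(diff(tail_y)) / sqrt(2)
}

#' Signal-to-noise ratio of an echo train
#'
#' Defined as the model intensity extrapolated to `t = 0` divided by the
#' per-echo noise SD. With a fit supplied, the t = 0 intensity is the
#' fitted `scale`; otherwise it is extrapolated by a log-quadratic fit to
#' the early echoes. A zero noise estimate yields `Inf`.
#'
#' @param train An [echo_train()].
#' @param fit Optional [fit_triexponential()] result (supplies both the
#'   t = 0 intensity and, if `noise_sd` is missing, the residual noise).
#' @param noise_sd Optional known or pre-estimated noise SD.
#' @param i0 Optional known t = 0 intensity (overrides extrapolation).
#' @return Positive scalar SNR (possibly `Inf`).
#' @export
compute_snr <- function(train, fit = NULL, noise_sd = NULL, i0 = NULL) {
  if (is.null(noise_sd)) {
    noise_sd <- if (!is.null(fit)) estimate_noise(train, fit) else {
      est <- attr(train, "noise_sd_estimate")
      if (!is.null(est) && !is.na(est)) est else estimate_noise(train)
    }
  }
  if (is.null(i0)) {
    i0 <- if (!is.null(fit)) fit$scale else extrapolate_i0(train)
  }
  if (noise_sd <= 0) return(Inf)
  i0 / noise_sd
}

# Log-quadratic extrapolation of the early decay to t = 0. Used where no
# model fit is available (e.g. inside the acquisition loop, where fitting
# every candidate average would be wasteful).
extrapolate_i0 <- function(train) {
  n <- min(100L, max(10L, floor(nrow(train) / 4)))
  t <- train$echo_time_ms[seq_len(n)]
  y <- train$intensity[seq_len(n)]
  pos <- y > 0
  if (sum(pos) < 5) return(max(y, 0))
  fit <- stats::lm(log(y[pos]) ~ poly(t[pos], 2, raw = TRUE))
  exp(unname(coef(fit)[1]))
}

#' Average three replicate fits of one sample
#'
#' Replicate measurements of the same sample are combined by taking the
#' arithmetic mean of each of the five free parameters (and the scale);
#' the fixed fast time constant is unchanged.
#'
#' @param fits List of exactly three converged `relax_fit` objects.
#' @return A `relax_fit` whose parameters are the replicate means.
#' @export
average_replicate_fits <- function(fits) {
  if (length(fits) != 3 || !all(vapply(fits, inherits, logical(1), "relax_fit"))) {
    abort("`fits` must be a list of exactly three relax_fit objects")
  }
  bad <- which(!vapply(fits, function(f) isTRUE(f$converged), logical(1)))
  if (length(bad) > 0) {
    abort(paste0("aggregation error: replicate(s) not converged: ",
                 paste(bad, collapse = ", ")))
  }
  t2f <- unique(vapply(fits, function(f) f$params$t_2f_ms, numeric(1)))
  if (length(t2f) != 1) abort("replicates fitted with different fixed T_2f")
  mean_of <- function(field) mean(vapply(fits, function(f) f$params[[field]], numeric(1)))
  p <- c(mean_of("p_2f"), mean_of("p_21"), mean_of("p_22"))
  new_relax_fit(
    p, t2f, mean_of("t_21_ms"), mean_of("t_22_ms"),
    mean(vapply(fits, function(f) f$scale, numeric(1))),
    mean(vapply(fits, function(f) f$residual_rms, numeric(1))),
    TRUE,
    any(vapply(fits, function(f) isTRUE(f$degenerate), logical(1))),
    sum(vapply(fits, function(f) f$n_starts_used, numeric(1)))
  )
}

#' @method tidy relax_fit
#' @export
tidy.relax_fit <- function(x, ...) {
  tibble::tibble(
    term = c("p_2f", "p_21", "p_22", "t_2f_ms", "t_21_ms", "t_22_ms", "scale"),
    estimate = c(unlist(x$params, use.names = FALSE), x$scale)
  )
}

#' @method glance relax_fit
#' @export
glance.relax_fit <- function(x, ...) {
  tibble::tibble(
    scale = x$scale,
    residual_rms = x$residual_rms,
    converged = x$converged,
    degenerate = x$degenerate,
    n_starts_used = x$n_starts_used
  )
}

#' @export
print.relax_fit <- function(x, ...) {
  p <- x$params
  cat("Tri-exponential CPMG fit\n")
  cat(sprintf("  amplitudes: p_2f = %.4f, p_21 = %.4f, p_22 = %.4f\n",
              p$p_2f, p$p_21, p$p_22))
  cat(sprintf("  time constants: T_2f = %g ms (fixed), T_21 = %.2f ms, T_22 = %.2f ms\n",
              p$t_2f_ms, p$t_21_ms, p$t_22_ms))
  cat(sprintf("  scale = %.4g, residual RMS = %.4g, converged = %s%s\n",
              x$scale, x$residual_rms, x$converged,
              if (isTRUE(x$degenerate)) " (degenerate: pools merged)" else ""))
  invisible(x)
}
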