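#' Plot an echo train
#'
#' Decay envelope on a linear or log intensity axis.
#'
#' @param object An [echo_train()].
#' @param log_y Log-scale the intensity axis (default TRUE; exponential
#'   decays are straight-ish on it).
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot echo_train
#' @export
autoplot.echo_train <- function(object, log_y = TRUE, ...) {
  p <- ggplot2::ggplot(object, ggplot2::aes(x = .data$echo_time_ms,
                                            y = .data$intensity)) +
    ggplot2::geom_line(linewidth = 0.3, colour = "grey40") +
    ggplot2::labs(
      x = "echo time (ms)", y = "intensity",
      subtitle = sprintf("%d scans averaged%s",
                         attr(object, "n_scans_averaged"),
                         if (isTRUE(attr(object, "below_snr"))) " (below SNR threshold)" else "")
    ) +
    ggplot2::theme_minimal()
  if (log_y) p <- p + ggplot2::scale_y_log10()
  p
}

#' Plot a tri-exponential fit over its echo train
#'
#' @param object A `relax_fit`.
#' @param train The [echo_train()] the fit was computed from.
#' @param ... Unused.
#' @return A ggplot object showing the data, the full model and the three
#'   components.
#' @method autoplot relax_fit
#' @export
autoplot.relax_fit <- function(object, train, ...) {
  t <- train$echo_time_ms
  p <- object$params
  comp <- tibble::tibble(
    echo_time_ms = rep(t, 4),
    intensity = c(
      object$scale * triexp_decay(t, p),
      object$scale * p$p_2f * exp(-t / p$t_2f_ms),
      object$scale * p$p_21 * exp(-t / p$t_21_ms),
      object$scale * p$p_22 * exp(-t / p$t_22_ms)
    ),
    component = rep(c("model", "fast (fixed T2f)", "intra-myofibrillar",
                      "inter-myofibrillar"), each = length(t))
  )
  ggplot2::ggplot(train, ggplot2::aes(x = .data$echo_time_ms,
                                      y = .data$intensity)) +
    ggplot2::geom_point(size = 0.2, alpha = 0.3) +
    ggplot2::geom_line(data = comp,
                       ggplot2::aes(colour = .data$component)) +
    ggplot2::labs(x = "echo time (ms)", y = "intensity", colour = NULL) +
    ggplot2::theme_minimal()
}

#' Scatter plot with fitted regression line and summary caption
#'
#' @param data A data frame.
#' @param x,y Bare column names of predictor and response.
#' @return A ggplot object; the caption carries the slope, R2, p and RMSE
#'   in the conventional figure-caption format.
#' @export
plot_regression <- function(data, x, y) {
  xq <- rlang::enquo(x)
  yq <- rlang::enquo(y)
  s <- ols_regression(rlang::eval_tidy(xq, data), rlang::eval_tidy(yq, data))
  ggplot2::ggplot(data, ggplot2::aes(x = !!xq, y = !!yq)) +
    ggplot2::geom_point(alpha = 0.6) +
    ggplot2::geom_smooth(method = "lm", formula = y ~ x, colour = "steelblue") +
    ggplot2::labs(caption = sprintf(
      "Slope = %.3g ± %.3g, R² = %.3f, p = %.3g, RMSE = %.3g",
      s$slope, s$slope_se, s$r2, s$p_value, s$rmse
    )) +
    ggplot2::theme_minimal()
}
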