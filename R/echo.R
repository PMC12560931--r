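#' Construct an echo-train object
#'
#' An echo train is a tibble of `(echo_time_ms, intensity)` carrying
#' acquisition metadata as attributes: scans averaged, a noise-SD estimate
#' (if any) and the below-SNR-threshold flag.
#'
#' @param echo_time_ms Strictly increasing positive echo times, ms.
#' @param intensity Averaged intensities, same length.
#' @param n_scans_averaged Scans averaged into this train.
#' @param noise_sd_estimate Estimated per-echo noise SD, or `NA`.
#' @param below_snr Was the SNR threshold not attained within the scan cap?
#' @return A tibble of class `echo_train`.
#' @export
echo_train <- function(echo_time_ms, intensity, n_scans_averaged = 1L,
                       noise_sd_estimate = NA_real_, below_snr = FALSE) {
  if (length(echo_time_ms) != length(intensity)) {
    abort("`echo_time_ms` and `intensity` must have equal length")
  }
  if (any(echo_time_ms <= 0) || is.unsorted(echo_time_ms, strictly = TRUE)) {
    abort("`echo_time_ms` must be positive and strictly increasing")
  }
  out <- tibble::tibble(echo_time_ms = echo_time_ms, intensity = intensity)
  attr(out, "n_scans_averaged") <- as.integer(n_scans_averaged)
  attr(out, "noise_sd_estimate") <- noise_sd_estimate
  attr(out, "below_snr") <- isTRUE(below_snr)
  class(out) <- c("echo_train", class(out))
  out
}

#' Simulate one CPMG scan
#'
#' Echo times are `k * echo_spacing_ms` for `k = 1..n_echoes`. The
#' noiseless envelope is `scale * sum_i p_2i * exp(-t / T_2i)` over the
#' three compartments. Each echo's recorded intensity is the arithmetic
#' mean of `points_per_echo` digitised points, each perturbed by Gaussian
#' noise of SD `noise_sd`.
#'
#' @param params Named list or one-row data frame with `p_2f`, `p_21`,
#'   `p_22`, `t_2f_ms`, `t_21_ms`, `t_22_ms` (amplitudes are fractions
#'   summing to 1).
#' @param acq An [acquisition_config()].
#' @param scale Intensity at `t = 0` (the overall signal amplitude).
#' @param seed Integer seed; the simulation is bit-reproducible under it.
#' @return An [echo_train()] with `n_scans_averaged = 1`.
#' @export
simulate_echo_train <- function(params, acq = acquisition_config(),
                                scale = 1000, seed = 1L) {
  stopifnot(inherits(acq, "acquisition_config"))
  check_nmr_params(params)
  t <- seq_len(acq$n_echoes) * acq$echo_spacing_ms
  clean <- scale * triexp_decay(t, params)
  intensity <- with_seed(seed, add_echo_noise(clean, acq))
  echo_train(t, intensity, n_scans_averaged = 1L)
}

add_echo_noise <- function(clean, acq) {
  if (acq$noise_sd == 0) return(clean)
  n <- length(clean)
  pts <- matrix(rnorm(n * acq$points_per_echo, 0, acq$noise_sd),
                nrow = n)
  clean + rowMeans(pts)
}

triexp_decay <- function(t, params) {
  params$p_2f * exp(-t / params$t_2f_ms) +
    params$p_21 * exp(-t / params$t_21_ms) +
    params$p_22 * exp(-t / params$t_22_ms)
}

check_nmr_params <- function(params) {
  need <- c("p_2f", "p_21", "p_22", "t_2f_ms", "t_21_ms", "t_22_ms")
  if (!all(need %in% names(params))) {
    abort(paste("params must contain:", paste(need, collapse = ", ")))
  }
  p <- c(params$p_2f, params$p_21, params$p_22)
  if (any(p < 0)) abort("amplitudes must be >= 0")
  if (abs(sum(p) - 1) > 1e-6) abort("amplitudes must sum to 1 (fractional convention)")
  if (!(params$t_2f_ms < params$t_21_ms && params$t_21_ms < params$t_22_ms)) {
    abort("time constants must satisfy t_2f < t_21 < t_22")
  }
  invisible(TRUE)
}

#' Acquire with adaptive signal averaging
#'
#' Repeatedly simulates scans and accumulates their running mean, stopping
#' at the first scan count whose estimated SNR (t = 0 signal over residual
#' noise SD, see [compute_snr()]) exceeds `acq$snr_threshold`. If the
#' threshold is not attained within `acq$max_scans` the returned train
#' carries the below-threshold flag instead of erroring.
#'
#' @inheritParams simulate_echo_train
#' @return An [echo_train()] with `n_scans_averaged` set, a noise-SD
#'   estimate attached, and `below_snr` flagged when the cap was hit.
#' @export
acquire_with_averaging <- function(params, acq = acquisition_config(),
                                   scale = 1000, seed = 1L) {
  stopifnot(inherits(acq, "acquisition_config"))
  check_nmr_params(params)
  t <- seq_len(acq$n_echoes) * acq$echo_spacing_ms
  clean <- scale * triexp_decay(t, params)
  with_seed(seed, {
    acc <- numeric(acq$n_echoes)
    k <- 0L
    repeat {
      k <- k + 1L
      acc <- acc + add_echo_noise(clean, acq)
      train <- echo_train(t, acc / k, n_scans_averaged = k)
      noise <- estimate_noise(train)
      snr <- compute_snr(train, noise_sd = noise)
      attr(train, "noise_sd_estimate") <- noise
      if (snr > acq$snr_threshold) {
        return(train)
      }
      if (k >= acq$max_scans) {
        attr(train, "below_snr") <- TRUE
        return(train)
      }
    }
  })
}
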