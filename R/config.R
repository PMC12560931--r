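#' Default per-muscle trait distribution table
#'
#' Means, standard deviations and admissible ranges for the four chemical
#' traits (pH, intramuscular fat, collagen content, collagen solubility) in
#' the loin (LTL) and topside (SM) of a commercial heavy-female pork cohort.
#' SDs are reconstructed from published standard errors at n = 60
#' (SD = SEM * sqrt(60)); ranges are the published observed ranges, used as
#' truncation bounds.
#'
#' @return A tibble with columns `trait`, `muscle`, `mean`, `sd`, `lower`,
#'   `upper`.
#' @export
default_traits <- function() {
  tibble::tribble(
    ~trait,                    ~muscle, ~mean, ~sem,  ~lower, ~upper,
    "pH",                      "LTL",   5.56,  0.014, 5.33,   5.88,
    "pH",                      "SM",    5.65,  0.018, 5.46,   5.99,
    "collagen_mg_g",           "LTL",   4.56,  0.073, 3.51,   5.57,
    "collagen_mg_g",           "SM",    4.73,  0.108, 3.21,   8.51,
    "collagen_solubility_pct", "LTL",   10.2,  0.258, 6.13,   18.5,
    "collagen_solubility_pct", "SM",    9.19,  0.239, 5.78,   13.4,
    "imf_pct",                 "LTL",   1.04,  0.051, 0.443,  2.25,
    "imf_pct",                 "SM",    1.38,  0.065, 0.579,  2.84
  ) |>
    dplyr::mutate(sd = .data$sem * sqrt(60), .after = "mean") |>
    dplyr::select(-"sem")
}

#' Cohort generator configuration
#'
#' Bundles every knob of the synthetic-cohort generator: trait distributions
#' per muscle, cross-muscle dependence targets, the latent links from
#' chemistry to NMR parameters and NIRS readings, the sensory-response
#' model, and the seed.
#'
#' @param n_carcasses Number of carcasses; each contributes one LTL and one
#'   SM sample.
#' @param traits Trait distribution table as from [default_traits()].
#' @param cross_muscle_r2 Named vector of target squared cross-muscle
#'   correlations per trait, each in `[0, 1)`. Dependence is induced by a
#'   shared-carcass latent factor giving correlation `sqrt(R2)`.
#' @param nmr_link Named list of per-parameter link specifications, each a
#'   list `(intercept, coef_imf, coef_ph, resid_sd)`; see [link_nmr()].
#' @param nirs_link List `(intercept, slope, between_sd, replicate_sd)`; see
#'   [generate_nirs()].
#' @param sensory Sensory model configuration from [sensory_config()].
#' @param seed Integer seed; all generator stages derive fixed child seeds
#'   from it.
#' @return An object of class `cohort_config`.
#' @export
cohort_config <- function(n_carcasses = 60,
                          traits = default_traits(),
                          cross_muscle_r2 = c(
                            pH = 0.273,
                            collagen_mg_g = 0.214,
                            collagen_solubility_pct = 0.104,
                            imf_pct = 0.044
                          ),
                          nmr_link = default_nmr_link(),
                          nirs_link = default_nirs_link(),
                          sensory = sensory_config(),
                          seed = 1L) {
  if (!is.numeric(n_carcasses) || n_carcasses < 2 || n_carcasses != round(n_carcasses)) {
    abort("`n_carcasses` must be an integer >= 2")
  }
  req <- c("trait", "muscle", "mean", "sd", "lower", "upper")
  if (!all(req %in% names(traits))) {
    abort("`traits` must have columns trait, muscle, mean, sd, lower, upper")
  }
  if (any(!is.finite(traits$sd)) || any(traits$sd < 0)) {
    abort("trait SDs must be finite and >= 0")
  }
  if (any(traits$mean < traits$lower | traits$mean > traits$upper)) {
    abort("every trait range must contain its mean")
  }
  if (any(cross_muscle_r2 < 0 | cross_muscle_r2 >= 1)) {
    abort("cross-muscle R2 targets must lie in [0, 1)")
  }
  for (nm in names(nmr_link)) {
    if (nmr_link[[nm]]$resid_sd < 0) abort("nmr_link resid_sd must be >= 0")
  }
  if (nirs_link$between_sd < 0 || nirs_link$replicate_sd < 0) {
    abort("nirs_link SDs must be >= 0")
  }
  structure(
    list(
      n_carcasses = as.integer(n_carcasses),
      traits = tibble::as_tibble(traits),
      cross_muscle_r2 = cross_muscle_r2,
      nmr_link = nmr_link,
      nirs_link = nirs_link,
      sensory = sensory,
      seed = as.integer(seed)
    ),
    class = "cohort_config"
  )
}

#' Default chemistry-to-NMR link coefficients
#'
#' Linear links from centred intramuscular fat and pH to each NMR parameter.
#' The `p_2f` coefficients are the analytic inversions of the published
#' marginal regressions of IMF and pH on `p_2f` (coefficient = R2 / slope);
#' the remaining parameters default to compartment-typical centres with
#' free residual spread and no chemistry dependence.
#'
#' @return Named list with one `(intercept, coef_imf, coef_ph, resid_sd)`
#'   entry per NMR parameter.
#' @export
default_nmr_link <- function() {
  list(
    p_2f  = list(intercept = 0.05, coef_imf = 0.124 / 26.5,
                 coef_ph = 0.287 / -10.5, resid_sd = 0.0041),
    p_21  = list(intercept = 0.85, coef_imf = 0, coef_ph = 0, resid_sd = 0.033),
    p_22  = list(intercept = 0.10, coef_imf = 0, coef_ph = 0, resid_sd = 0.033),
    t_21_ms = list(intercept = 40, coef_imf = 0, coef_ph = 0, resid_sd = 3),
    t_22_ms = list(intercept = 150, coef_imf = 0, coef_ph = 0, resid_sd = 10)
  )
}

#' Default chemistry-to-NIRS link
#'
#' The handheld device emits a predicted-IMF scalar; its latent value is
#' `intercept + slope * IMF` plus between-sample noise, and each of the
#' three replicate readings adds independent replicate noise. The default
#' slope is the analytic inversion of the published pooled regression of
#' chemical IMF on mean device output (slope = R2 / published slope).
#'
#' @return List `(intercept, slope, between_sd, replicate_sd)`.
#' @export
default_nirs_link <- function() {
  list(intercept = 0.59, slope = 0.258 / 0.502, between_sd = 0.38,
       replicate_sd = 0.30)
}

#' Sensory-response model configuration
#'
#' Defines how consumer responses are generated from a sample's chemistry:
#' each 0-100 line-scale score is a muscle intercept plus fixed chemistry
#' slopes plus session, participant-within-session and carcass random
#' intercepts plus residual noise, optionally truncated to the scale.
#' Off-flavor is Bernoulli on a logit scale; purchase intent (1-5) and
#' quality grade (1-4) are ordinal cuts of a latent normal.
#'
#' @param slopes Matrix-like list: per response, named chemistry slopes
#'   (score points per trait unit).
#' @param muscle_means Named list of target mean scores per muscle used to
#'   derive intercepts (intercept = target mean - slopes at trait means).
#' @param sd_session,sd_participant,sd_carcass,sd_residual Random-effect and
#'   residual SDs on the 0-100 score scale. Defaults are declared arbitrary
#'   (no published values exist) and fully overridable.
#' @param off_flavor_prob Named per-muscle probability of detecting an
#'   off-flavor.
#' @param purchase_success,quality_success Named per-muscle marginal
#'   probabilities of "success" (top-two purchase-intent boxes; top-two
#'   quality grades) used to place the ordinal thresholds.
#' @param sd_session_logit,sd_participant_logit,sd_carcass_logit
#'   Random-effect SDs on the logit scale shared by the binary/ordinal
#'   responses.
#' @param truncate Clamp scores to `[0, 100]`? Disable for exact
#'   slope-recovery simulations.
#' @param n_sessions,participants_per_session,consumers_per_sample Panel
#'   design: sessions (3 per day over 3 days), roster size per session, and
#'   consumers tasting each sample.
#' @return An object of class `sensory_config`.
#' @export
sensory_config <- function(slopes = default_sensory_slopes(),
                           muscle_means = list(
                             LTL = c(tenderness = 48.8, juiciness = 48.1,
                                     flavor = 52.0, overall = 52.0),
                             SM  = c(tenderness = 51.7, juiciness = 54.1,
                                     flavor = 54.0, overall = 54.7)
                           ),
                           sd_session = 3, sd_participant = 10,
                           sd_carcass = 5, sd_residual = 15,
                           off_flavor_prob = c(LTL = 0.004, SM = 0.008),
                           purchase_success = c(LTL = 0.298, SM = 0.351),
                           quality_success = c(LTL = 0.284, SM = 0.318),
                           sd_session_logit = 0.2,
                           sd_participant_logit = 0.5,
                           sd_carcass_logit = 0.3,
                           truncate = TRUE,
                           n_sessions = 9L,
                           participants_per_session = 20L,
                           consumers_per_sample = 10L) {
  sds <- c(sd_session, sd_participant, sd_carcass, sd_residual,
           sd_session_logit, sd_participant_logit, sd_carcass_logit)
  if (any(!is.finite(sds)) || any(sds < 0)) abort("all sensory SDs must be finite and >= 0")
  probs <- c(off_flavor_prob, purchase_success, quality_success)
  if (any(probs <= 0 | probs >= 1)) abort("sensory probabilities must lie in (0, 1)")
  if (consumers_per_sample > participants_per_session) {
    abort("consumers_per_sample cannot exceed participants_per_session")
  }
  structure(
    list(
      slopes = slopes, muscle_means = muscle_means,
      sd_session = sd_session, sd_participant = sd_participant,
      sd_carcass = sd_carcass, sd_residual = sd_residual,
      off_flavor_prob = off_flavor_prob,
      purchase_success = purchase_success,
      quality_success = quality_success,
      sd_session_logit = sd_session_logit,
      sd_participant_logit = sd_participant_logit,
      sd_carcass_logit = sd_carcass_logit,
      truncate = isTRUE(truncate),
      n_sessions = as.integer(n_sessions),
      participants_per_session = as.integer(participants_per_session),
      consumers_per_sample = as.integer(consumers_per_sample)
    ),
    class = "sensory_config"
  )
}

#' Default fixed chemistry slopes of the sensory model
#'
#' Score points per trait unit for each line-scale response, at the
#' published multi-predictor mixed-model estimates.
#'
#' @return Named list of named slope vectors.
#' @export
default_sensory_slopes <- function() {
  list(
    tenderness = c(pH = 14.1, collagen_mg_g = -3.86,
                   collagen_solubility_pct = -0.79, imf_pct = 0.40),
    juiciness  = c(pH = 12.6, collagen_mg_g = -2.76,
                   collagen_solubility_pct = -0.83, imf_pct = 0.88),
    flavor     = c(pH = 11.7, collagen_mg_g = -2.60,
                   collagen_solubility_pct = -0.68, imf_pct = 2.91),
    overall    = c(pH = 14.2, collagen_mg_g = -3.42,
                   collagen_solubility_pct = -0.69, imf_pct = 1.58)
  )
}

#' Compartment-typical NMR parameter set
#'
#' Fractional amplitudes and time constants at the package's default
#' compartment centres (fast/macromolecule-associated pool at the fixed
#' 10 ms, intra-myofibrillar water near 40 ms, inter-myofibrillar water
#' near 150 ms). These are implementation defaults motivated by the usual
#' compartment assignments in muscle, not measured values, and every
#' simulation accepts overrides.
#'
#' @return Named list `(p_2f, p_21, p_22, t_2f_ms, t_21_ms, t_22_ms)`.
#' @export
default_nmr_params <- function() {
  list(p_2f = 0.05, p_21 = 0.85, p_22 = 0.10,
       t_2f_ms = 10, t_21_ms = 40, t_22_ms = 150)
}

#' CPMG acquisition configuration
#'
#' @param n_echoes Number of echoes per scan (default 2000).
#' @param echo_spacing_ms Echo spacing in ms (default 0.3).
#' @param polarization_delay_ms Recovery delay between scans in ms
#'   (informational; default 750).
#' @param points_per_echo Points digitised and averaged within each echo.
#' @param noise_sd Gaussian noise SD per digitised point, intensity units.
#' @param snr_threshold Signal averaging continues until the estimated SNR
#'   of the averaged train exceeds this (default 200).
#' @param max_scans Hard cap on scans; reaching it without attaining the
#'   threshold flags the train rather than erroring.
#' @return An object of class `acquisition_config`.
#' @export
acquisition_config <- function(n_echoes = 2000L,
                               echo_spacing_ms = 0.3,
                               polarization_delay_ms = 750,
                               points_per_echo = 8L,
                               noise_sd = 40,
                               snr_threshold = 200,
                               max_scans = 256L) {
  if (n_echoes < 1) abort("`n_echoes` must be >= 1")
  if (echo_spacing_ms <= 0) abort("`echo_spacing_ms` must be > 0")
  if (snr_threshold <= 0) abort("`snr_threshold` must be > 0")
  if (max_scans < 1) abort("`max_scans` must be >= 1")
  if (points_per_echo < 1) abort("`points_per_echo` must be >= 1")
  if (noise_sd < 0 || !is.finite(noise_sd)) abort("`noise_sd` must be finite and >= 0")
  structure(
    list(
      n_echoes = as.integer(n_echoes),
      echo_spacing_ms = echo_spacing_ms,
      polarization_delay_ms = polarization_delay_ms,
      points_per_echo = as.integer(points_per_echo),
      noise_sd = noise_sd,
      snr_threshold = snr_threshold,
      max_scans = as.integer(max_scans)
    ),
    class = "acquisition_config"
  )
}

#' Tri-exponential fit options
#'
#' @param fixed_t2f_ms The fast time constant, held fixed during fitting
#'   (default 10 ms, the value that stabilises the fit).
#' @param t21_bounds,t22_bounds Search bounds in ms for the two free time
#'   constants; must be ordered, disjoint and above `fixed_t2f_ms`.
#' @param n_starts_grid Side of the log-spaced multi-start grid over
#'   (T21, T22); `n_starts_grid^2` starts in total.
#' @param rel_tol Convergence tolerance of the outer optimiser.
#' @param max_iter Iteration cap per start.
#' @param collapse_rel_tol If the two fitted time constants agree within
#'   this relative tolerance the fit is flagged degenerate and the merged
#'   amplitude is reported under `p_21`.
#' @param seed Seed for start-point jitter (jitter is off by default; the
#'   grid is deterministic).
#' @return An object of class `fit_options`.
#' @export
fit_options <- function(fixed_t2f_ms = 10,
                        t21_bounds = c(10, 100),
                        t22_bounds = c(100, 2000),
                        n_starts_grid = 4L,
                        rel_tol = 1e-10,
                        max_iter = 500L,
                        collapse_rel_tol = 0.05,
                        seed = 1L) {
  if (t21_bounds[1] < fixed_t2f_ms) abort("T21 lower bound must be >= fixed_t2f_ms")
  if (!(t21_bounds[1] < t21_bounds[2]) || !(t22_bounds[1] < t22_bounds[2])) {
    abort("bound intervals must be ordered")
  }
  if (t21_bounds[2] > t22_bounds[1]) abort("T21 and T22 bound intervals must be disjoint and ordered")
  structure(
    list(
      fixed_t2f_ms = fixed_t2f_ms,
      t21_bounds = t21_bounds,
      t22_bounds = t22_bounds,
      n_starts_grid = as.integer(n_starts_grid),
      rel_tol = rel_tol,
      max_iter = as.integer(max_iter),
      collapse_rel_tol = collapse_rel_tol,
      seed = as.integer(seed)
    ),
    class = "fit_options"
  )
}
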