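#' Generate a synthetic two-muscle cohort
#'
#' Draws `n_carcasses` carcasses, each with one loin (LTL) and one topside
#' (SM) sample, from per-muscle truncated-normal trait distributions.
#' Within-carcass cross-muscle dependence is induced by a shared-carcass
#' latent factor through a Gaussian copula, so each trait's marginal stays
#' exactly truncated normal while the cross-muscle correlation equals
#' `sqrt(target R2)` in expectation.
#'
#' @param config A [cohort_config()].
#' @param seed Optional integer overriding the config seed (the cohort
#'   stage child seed is derived from it).
#' @return A tibble with one row per (carcass, muscle): `carcass_id`,
#'   `muscle`, `pH`, `collagen_mg_g`, `collagen_solubility_pct`, `imf_pct`,
#'   and empty NIRS reading columns `nirs_1`..`nirs_3` to be filled by
#'   [generate_nirs()].
#' @export
generate_cohort <- function(config, seed = NULL) {
  stopifnot(inherits(config, "cohort_config"))
  seed <- child_seed(seed %||% config$seed, "cohort")
  n <- config$n_carcasses
  traits <- unique(config$traits$trait)
  muscles <- c("LTL", "SM")

  draws <- with_seed(seed, {
    out <- list()
    for (tr in traits) {
      r2 <- config$cross_muscle_r2[[tr]] %||% 0
      rho <- sqrt(r2)
      z_shared <- rnorm(n)
      vals <- list()
      for (m in muscles) {
        row <- config$traits[config$traits$trait == tr & config$traits$muscle == m, ]
        if (nrow(row) != 1) abort(paste0("missing trait spec for ", tr, " / ", m))
        z <- sqrt(rho) * z_shared + sqrt(1 - rho) * rnorm(n)
        # corr(z_LTL, z_SM) = rho = sqrt(R2); copula-map to the truncated
        # marginal, with the location mean-corrected so the truncated
        # distribution's expectation equals the configured mean even under
        # asymmetric bounds
        mu <- tnorm_mean_correct(row$mean, row$sd, row$lower, row$upper)
        vals[[m]] <- qtnorm(pnorm(z), mu, row$sd, row$lower, row$upper)
      }
      out[[tr]] <- vals
    }
    out
  })

  ids <- sprintf("C%03d", seq_len(n))
  purrr::map_dfr(muscles, function(m) {
    tibble::tibble(
      carcass_id = ids,
      muscle = m,
      pH = draws$pH[[m]],
      collagen_mg_g = draws$collagen_mg_g[[m]],
      collagen_solubility_pct = draws$collagen_solubility_pct[[m]],
      imf_pct = draws$imf_pct[[m]],
      nirs_1 = NA_real_, nirs_2 = NA_real_, nirs_3 = NA_real_
    )
  })
}

# Location of the untruncated normal whose [lower, upper]-truncated mean
# equals `target`; identity when sd = 0 or bounds are symmetric.
tnorm_mean_correct <- function(target, sd, lower, upper) {
  if (sd == 0) return(target)
  f <- function(m) tnorm_moments(m, sd, lower, upper)$mean - target
  stats::uniroot(f, interval = c(target - 4 * sd, target + 4 * sd),
                 tol = 1e-12)$root
}

# Truncated-normal quantile function (copula workhorse); sd = 0 collapses
# to the mean.
qtnorm <- function(u, mean, sd, lower, upper) {
  if (sd == 0) return(rep_len(mean, length(u)))
  plo <- pnorm(lower, mean, sd)
  phi <- pnorm(upper, mean, sd)
  qnorm(plo + u * (phi - plo), mean, sd)
}

#' Fill in NIRS replicate readings
#'
#' Each sample's latent device value is `intercept + slope * IMF` plus
#' between-sample noise; the three replicate readings add independent
#' replicate noise. Readings are floored at a small positive value (the
#' device reports predicted IMF, which cannot be negative).
#'
#' @param records Cohort tibble from [generate_cohort()].
#' @param config A [cohort_config()]; uses its `nirs_link` block.
#' @param seed Optional integer overriding the config seed.
#' @return `records` with `nirs_1`..`nirs_3` filled.
#' @export
generate_nirs <- function(records, config, seed = NULL) {
  stopifnot(inherits(config, "cohort_config"))
  lk <- config$nirs_link
  seed <- child_seed(seed %||% config$seed, "nirs")
  n <- nrow(records)
  with_seed(seed, {
    latent <- lk$intercept + lk$slope * records$imf_pct + rnorm(n, 0, lk$between_sd)
    for (j in 1:3) {
      records[[paste0("nirs_", j)]] <-
        pmax(latent + rnorm(n, 0, lk$replicate_sd), 1e-3)
    }
  })
  records
}

#' Attach latent NMR parameters to one muscle's samples
#'
#' For each sample, `p_2f` is a linear function of centred IMF and centred
#' pH plus Gaussian noise; `p_21` and `p_22` are drawn the same way and the
#' three amplitudes are then renormalised to sum to one while preserving
#' the drawn `p_2f` exactly (the remainder `1 - p_2f` is split between
#' `p_21` and `p_22` in their drawn proportion). The two free time
#' constants are drawn around their configured centres and ordered above
#' the fixed fast component.
#'
#' @param records Cohort rows for a single muscle (NMR was measured on the
#'   loin only in the motivating study).
#' @param config A [cohort_config()]; uses its `nmr_link` block.
#' @param seed Optional integer overriding the config seed.
#' @return A tibble keyed by `carcass_id` with columns `p_2f`, `p_21`,
#'   `p_22`, `t_2f_ms` (fixed at 10), `t_21_ms`, `t_22_ms`.
#' @export
link_nmr <- function(records, config, seed = NULL) {
  stopifnot(inherits(config, "cohort_config"))
  if (length(unique(records$muscle)) != 1) {
    abort("`records` must contain a single muscle; filter before calling link_nmr()")
  }
  lk <- config$nmr_link
  seed <- child_seed(seed %||% config$seed, "nmr")
  n <- nrow(records)
  imf_c <- records$imf_pct - mean(records$imf_pct)
  ph_c <- records$pH - mean(records$pH)

  draw <- function(spec) {
    spec$intercept + spec$coef_imf * imf_c + spec$coef_ph * ph_c +
      rnorm(n, 0, spec$resid_sd)
  }

  with_seed(seed, {
    p2f <- pmin(pmax(draw(lk$p_2f), 0), 0.999)
    p21_raw <- pmax(draw(lk$p_21), 1e-9)
    p22_raw <- pmax(draw(lk$p_22), 1e-9)
    w <- p21_raw / (p21_raw + p22_raw)
    t21 <- pmax(draw(lk$t_21_ms), 10.5)
    t22 <- pmax(draw(lk$t_22_ms), t21 * 1.05)
    tibble::tibble(
      carcass_id = records$carcass_id,
      p_2f = p2f,
      p_21 = (1 - p2f) * w,
      p_22 = (1 - p2f) * (1 - w),
      t_2f_ms = 10,
      t_21_ms = t21,
      t_22_ms = t22
    )
  })
}

`%||%` <- function(a, b) if (is.null(a)) b else a
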