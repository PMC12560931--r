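#' Generate consumer sensory responses for a cohort
#'
#' Emulates the grouping structure of a consumer panel: samples are
#' allocated across sessions (three per day over three days), each session
#' has a fixed participant roster, and each sample is tasted by
#' `consumers_per_sample` participants of its session. Each 0-100
#' line-scale score is
#' `muscle intercept + sum(slopes * chemistry) + session + participant +
#' carcass + residual`, truncated to the scale unless disabled. Off-flavor
#' is Bernoulli on a logit scale; purchase intent (1-5) and quality grade
#' (1-4) are ordinal cuts of a latent normal sharing the logit-scale random
#' effects. Serving order is not simulated; order effects are absorbed in
#' the residual.
#'
#' @param records Cohort tibble (chemistry must be present).
#' @param config A [cohort_config()]; uses its `sensory` block and trait
#'   table (trait means enter the intercept calculation).
#' @param seed Optional integer overriding the config seed.
#' @return A tibble with one row per (sample, consumer): `participant_id`,
#'   `session_id`, `day`, `carcass_id`, `muscle`, the four scores,
#'   `off_flavor` (logical), `purchase_intent` (1-5), `quality_grade`
#'   (1-4).
#' @export
generate_sensory <- function(records, config, seed = NULL) {
  stopifnot(inherits(config, "cohort_config"))
  sc <- config$sensory
  seed <- child_seed(seed %||% config$seed, "sensory")
  n_samp <- nrow(records)
  muscles_present <- unique(records$muscle)

  # intercepts chosen so the expected score at predictor reference means
  # hits the target per-muscle mean; reference means come from the trait
  # table where available, otherwise from the sample itself (e.g. for
  # latent NMR-parameter predictors attached to the records)
  intercept_for <- function(resp, m) {
    sl <- sc$slopes[[resp]]
    tr <- config$traits[config$traits$muscle == m, ]
    tm <- setNames(tr$mean, tr$trait)
    ref <- vapply(names(sl), function(v) {
      if (v %in% names(tm)) tm[[v]] else mean(records[[v]][records$muscle == m])
    }, numeric(1))
    sc$muscle_means[[m]][[resp]] - sum(sl * ref)
  }

  with_seed(seed, {
    session_of <- sample(rep_len(seq_len(sc$n_sessions), n_samp))
    day_of <- ((session_of - 1) %/% max(1L, ceiling(sc$n_sessions / 3))) + 1L

    roster <- function(s) sprintf("S%02d_P%02d", s, seq_len(sc$participants_per_session))
    consumers <- lapply(session_of, function(s) sample(roster(s), sc$consumers_per_sample))

    carcasses <- unique(records$carcass_id)
    eff_carc <- setNames(rnorm(length(carcasses), 0, sc$sd_carcass), carcasses)
    eff_sess <- rnorm(sc$n_sessions, 0, sc$sd_session)
    all_participants <- unlist(lapply(seq_len(sc$n_sessions), roster))
    eff_part <- setNames(rnorm(length(all_participants), 0, sc$sd_participant),
                         all_participants)
    # logit-scale random intercepts shared by the binary/ordinal responses
    leff_carc <- setNames(rnorm(length(carcasses), 0, sc$sd_carcass_logit), carcasses)
    leff_sess <- rnorm(sc$n_sessions, 0, sc$sd_session_logit)
    leff_part <- setNames(rnorm(length(all_participants), 0, sc$sd_participant_logit),
                          all_participants)

    idx <- rep(seq_len(n_samp), each = sc$consumers_per_sample)
    out <- tibble::tibble(
      participant_id = unlist(consumers),
      session_id = sprintf("S%02d", session_of[idx]),
      day = day_of[idx],
      carcass_id = records$carcass_id[idx],
      muscle = records$muscle[idx]
    )
    n_obs <- nrow(out)
    re_score <- eff_sess[session_of[idx]] + eff_part[out$participant_id] +
      eff_carc[out$carcass_id]
    re_logit <- leff_sess[session_of[idx]] + leff_part[out$participant_id] +
      leff_carc[out$carcass_id]

    responses <- names(sc$slopes)
    pred_cols <- unique(unlist(lapply(sc$slopes, names)))
    missing_cols <- setdiff(pred_cols, names(records))
    if (length(missing_cols) > 0) {
      abort(paste("sensory slope predictors absent from records:",
                  paste(missing_cols, collapse = ", ")))
    }
    chem <- records[idx, pred_cols, drop = FALSE]
    for (resp in responses) {
      sl <- sc$slopes[[resp]]
      fixed <- rep(0, n_obs)
      for (m in muscles_present) {
        fixed[out$muscle == m] <- intercept_for(resp, m)
      }
      for (v in names(sl)) fixed <- fixed + sl[[v]] * chem[[v]]
      score <- fixed + re_score + rnorm(n_obs, 0, sc$sd_residual)
      if (sc$truncate) score <- pmin(pmax(score, 0), 100)
      out[[resp]] <- score
    }

    # off-flavor: Bernoulli(inv-logit(muscle intercept + logit random effects))
    off_int <- qlogis(sc$off_flavor_prob)[out$muscle]
    out$off_flavor <- runif(n_obs) < plogis(off_int + re_logit)

    s_tot <- sqrt(1 + sc$sd_session_logit^2 + sc$sd_participant_logit^2 +
                    sc$sd_carcass_logit^2)
    out$purchase_intent <- ordinal_cut(
      re_logit + rnorm(n_obs),
      shift = ordinal_shift(sc$purchase_success, out$muscle, s_tot),
      cuts = c(qnorm(0.10, 0, s_tot), qnorm(0.35, 0, s_tot),
               qnorm(1 - sc$purchase_success[["LTL"]], 0, s_tot),
               qnorm(0.90, 0, s_tot))
    )
    out$quality_grade <- ordinal_cut(
      re_logit + rnorm(n_obs),
      shift = ordinal_shift(sc$quality_success, out$muscle, s_tot),
      cuts = c(qnorm(0.25, 0, s_tot),
               qnorm(1 - sc$quality_success[["LTL"]], 0, s_tot),
               qnorm(0.92, 0, s_tot))
    )
    out
  })
}

# Latent mean shift per muscle so the marginal success probability (mass
# above the success threshold, which is placed for LTL) matches the
# configured per-muscle value.
ordinal_shift <- function(success, muscle, s_tot) {
  ref <- qnorm(1 - success[["LTL"]], 0, s_tot)
  shifts <- vapply(success, function(p) ref - qnorm(1 - p, 0, s_tot), numeric(1))
  unname(shifts[muscle])
}

ordinal_cut <- function(latent, shift, cuts) {
  if (is.unsorted(cuts, strictly = TRUE)) {
    abort("configured success probabilities place ordinal thresholds out of order")
  }
  findInterval(latent + shift, cuts) + 1L
}
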