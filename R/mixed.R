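# Linear and binomial mixed-effects linkage of chemistry / instrument
# outputs to consumer responses. Estimation delegates to lme4; the module
# contract is the returned slope / probability tables, verified end to end
# by simulation recovery.

#' Join sensory responses to sample chemistry
#'
#' Every sensory record must match exactly one chemistry record on
#' `(carcass_id, muscle)`.
#'
#' @param sensory Sensory tibble.
#' @param chemistry Cohort tibble.
#' @return The joined tibble.
#' @export
join_sensory_chemistry <- function(sensory, chemistry) {
  dup <- chemistry |>
    dplyr::count(.data$carcass_id, .data$muscle) |>
    dplyr::filter(.data$n > 1)
  if (nrow(dup) > 0) {
    abort(paste0("chemistry has duplicate (carcass_id, muscle): ",
                 paste(utils::head(paste(dup$carcass_id, dup$muscle), 5),
                       collapse = ", ")))
  }
  joined <- dplyr::left_join(sensory, chemistry, by = c("carcass_id", "muscle"))
  miss <- joined |> dplyr::filter(is.na(.data$pH))
  if (nrow(miss) > 0) {
    abort(paste0("join error: sensory records with no chemistry match: ",
                 paste(unique(utils::head(paste(miss$carcass_id, miss$muscle), 5)),
                       collapse = ", ")))
  }
  joined
}

#' Fixed chemistry slopes on a sensory response
#'
#' Fits the multi-predictor linear mixed model
#' `response ~ muscle + IMF + collagen + solubility + pH` with random
#' intercepts for session, participant nested in session, and carcass, and
#' returns the fixed slopes with standard errors and two-sided p-values.
#' P-values use the residual-df t approximation (`df = n - rank(X)`); with
#' hundreds of residual degrees of freedom, as here, the choice of df
#' approximation is immaterial. A singular random-effects fit is refitted
#' without its smallest-variance term (with a warning).
#'
#' @param sensory Sensory tibble (see [generate_sensory()] for the schema).
#' @param chemistry Cohort tibble.
#' @param response Response column name (default `"tenderness"`).
#' @param predictors Chemistry predictor columns.
#' @param include_muscle Add the muscle fixed effect (default TRUE).
#' @return A slope-table tibble `(term, slope, se, t, p_value)`.
#' @export
fit_chemistry_slopes <- function(sensory, chemistry,
                                 response = "tenderness",
                                 predictors = c("imf_pct", "collagen_mg_g",
                                                "collagen_solubility_pct", "pH"),
                                 include_muscle = TRUE) {
  data <- join_sensory_chemistry(sensory, chemistry)
  fixed <- paste(c(if (include_muscle && length(unique(data$muscle)) > 1) "muscle",
                   predictors), collapse = " + ")
  fml <- stats::as.formula(paste0(
    response, " ~ ", fixed,
    " + (1 | session_id / participant_id) + (1 | carcass_id)"
  ))
  fit <- fit_lmm(fml, data)
  slope_table(fit, data)
}

#' Single-predictor slope on a sensory response
#'
#' Fits `response ~ predictor (+ muscle)` with the canonical random
#' structure (participant nested in session, plus carcass) and, alongside
#' it, the same fixed model by ordinary least squares with no random
#' terms. Both rows are returned because removing the random terms can
#' change which predictors reach significance, and the comparison is
#' informative.
#'
#' @param sensory Sensory tibble.
#' @param values Tibble with `carcass_id` (and optionally `muscle`) plus
#'   the predictor column, e.g. fitted NMR parameters per sample or NIRS
#'   aggregates.
#' @param predictor Predictor column name in `values`.
#' @param response Response column name.
#' @param include_muscle Add a muscle fixed effect (used for pooled
#'   two-muscle NIRS models; NMR models are single-muscle).
#' @return Slope-table tibble with a `method` column (`"mixed"`, `"ols"`),
#'   one row per method for the predictor term.
#' @export
fit_single_predictor_slope <- function(sensory, values, predictor,
                                       response = "tenderness",
                                       include_muscle = FALSE) {
  by <- intersect(c("carcass_id", "muscle"), names(values))
  data <- dplyr::inner_join(sensory, values, by = by)
  if (nrow(data) == 0) abort("join error: no sensory records match `values`")
  fixed <- paste(c(if (include_muscle) "muscle", predictor), collapse = " + ")
  fml <- stats::as.formula(paste0(
    response, " ~ ", fixed,
    " + (1 | session_id / participant_id) + (1 | carcass_id)"
  ))
  mixed <- slope_table(fit_lmm(fml, data), data) |>
    dplyr::filter(.data$term == predictor) |>
    dplyr::mutate(method = "mixed")
  ols_fit <- lm(stats::as.formula(paste0(response, " ~ ", fixed)), data = data)
  sm <- summary(ols_fit)$coefficients
  row <- grep(predictor, rownames(sm), fixed = TRUE)[1]
  ols <- tibble::tibble(
    term = predictor, slope = sm[row, 1], se = sm[row, 2],
    t = sm[row, 3], p_value = sm[row, 4], method = "ols"
  )
  dplyr::bind_rows(mixed, ols)
}

# Fits the linear mixed model, iteratively dropping the smallest-variance
# random term while the fit is singular; a fully degenerate random
# structure reduces to plain OLS (the GLS weights are then the identity).
fit_lmm <- function(fml, data) {
  repeat {
    fit <- suppressMessages(lme4::lmer(fml, data = data, REML = TRUE))
    if (!lme4::isSingular(fit, tol = 1e-5)) return(fit)
    vc <- as.data.frame(lme4::VarCorr(fit))
    vc <- vc[vc$grp != "Residual", ]
    drop_grp <- vc$grp[which.min(vc$vcov)]
    warn(paste0("singular random-effects fit; dropping smallest-variance term: ",
                drop_grp))
    grp_set <- sort(strsplit(drop_grp, ":", fixed = TRUE)[[1]])
    bars <- lme4::findbars(fml)
    keep <- bars[vapply(bars, function(b) {
      b_set <- sort(strsplit(gsub("[()` ]", "", deparse(b[[3]])), ":")[[1]])
      !identical(b_set, grp_set)
    }, logical(1))]
    if (length(keep) == length(bars)) return(fit) # could not match; stop
    if (length(keep) == 0) {
      return(lm(lme4::nobars(fml), data = data))
    }
    fixed_part <- paste(deparse(lme4::nobars(fml)), collapse = "")
    fml <- stats::as.formula(paste(
      fixed_part, "+",
      paste(vapply(keep, function(b) paste0("(", deparse(b), ")"), character(1)),
            collapse = " + ")
    ))
  }
}

slope_table <- function(fit, data) {
  if (inherits(fit, "lm")) {
    sm <- summary(fit)$coefficients
    return(tibble::tibble(
      term = rownames(sm), slope = sm[, 1], se = sm[, 2],
      t = sm[, 3], p_value = sm[, 4]
    ))
  }
  sm <- coef(summary(fit))
  df <- nrow(data) - qr(lme4::getME(fit, "X"))$rank
  tibble::tibble(
    term = rownames(sm),
    slope = sm[, "Estimate"],
    se = sm[, "Std. Error"],
    t = sm[, "t value"],
    p_value = 2 * pt(-abs(sm[, "t value"]), df = df)
  )
}

#' Per-muscle success probability from a binomial mixed model
#'
#' Collapses an ordinal or binary response to success/failure, fits a
#' logit-link binomial mixed model with a per-muscle fixed effect and
#' random intercepts for session, participant nested in session, and
#' carcass, and returns the inverse-link fixed-effect probability per
#' muscle with a delta-method standard error. Boundary cases (all
#' successes or all failures in a muscle) and degenerate random structures
#' fall back to the raw proportion.
#'
#' @param sensory Sensory tibble.
#' @param response Response column (`"purchase_intent"`, `"quality_grade"`
#'   or `"off_flavor"`).
#' @param success Values of the response counted as success, e.g. `4:5`
#'   for top-two purchase intent or `FALSE` for "no off-flavor".
#' @return Tibble `(muscle, probability, se, n)`.
#' @export
success_probability <- function(sensory, response, success) {
  y <- sensory[[response]] %in% success
  data <- dplyr::mutate(sensory, .success = y)
  muscles <- sort(unique(data$muscle))

  boundary <- data |>
    dplyr::group_by(.data$muscle) |>
    dplyr::summarise(p = mean(.data$.success), n = dplyr::n(), .groups = "drop")
  if (any(boundary$p %in% c(0, 1))) {
    return(dplyr::transmute(boundary, muscle = .data$muscle,
                            probability = .data$p, se = 0, n = .data$n))
  }

  fit <- tryCatch(
    suppressMessages(lme4::glmer(
      .success ~ 0 + muscle + (1 | session_id / participant_id) + (1 | carcass_id),
      data = data, family = stats::binomial()
    )),
    error = function(e) NULL, warning = function(w) NULL
  )
  if (is.null(fit)) {
    fit <- stats::glm(.success ~ 0 + muscle, data = data,
                      family = stats::binomial())
  }
  sm <- coef(summary(fit))
  purrr::map_dfr(muscles, function(m) {
    row <- paste0("muscle", m)
    eta <- sm[row, 1]
    se_eta <- sm[row, 2]
    p <- plogis(eta)
    tibble::tibble(muscle = m, probability = p,
                   se = se_eta * p * (1 - p),
                   n = sum(data$muscle == m))
  })
}
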