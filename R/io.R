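# Schema-validated CSV readers/writers for the three table kinds the
# pipeline exchanges, plus YAML configuration round-trip. Dialect: UTF-8,
# comma-separated, mandatory header, "." decimal, muscle labels exactly
# "LTL"/"SM".

cohort_schema <- list(
  carcass_id = "character", muscle = "character", pH = "numeric",
  collagen_mg_g = "numeric", collagen_solubility_pct = "numeric",
  imf_pct = "numeric", nirs_1 = "numeric", nirs_2 = "numeric",
  nirs_3 = "numeric"
)

sensory_schema <- list(
  participant_id = "character", session_id = "character", day = "numeric",
  carcass_id = "character", muscle = "character", tenderness = "numeric",
  juiciness = "numeric", flavor = "numeric", overall = "numeric",
  off_flavor = "logical", purchase_intent = "numeric",
  quality_grade = "numeric"
)

check_columns <- function(data, schema, file) {
  missing_cols <- setdiff(names(schema), names(data))
  if (length(missing_cols) > 0) {
    abort(paste0("parse error in ", file, ": missing column(s) ",
                 paste(missing_cols, collapse = ", ")))
  }
  invisible(TRUE)
}

fail_rows <- function(bad, file, what) {
  if (any(bad, na.rm = TRUE)) {
    rows <- which(bad)
    abort(paste0("range-validation error in ", file, ": ", what,
                 " in row(s) ", paste(utils::head(rows, 5), collapse = ", "),
                 if (length(rows) > 5) " ..." else ""))
  }
}

#' Read and validate a cohort CSV
#'
#' @param path CSV with the cohort schema (`carcass_id`, `muscle`, `pH`,
#'   `collagen_mg_g`, `collagen_solubility_pct`, `imf_pct`,
#'   `nirs_1`..`nirs_3`). NIRS columns may be empty.
#' @return A validated tibble.
#' @export
read_cohort_csv <- function(path) {
  data <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  check_columns(data, cohort_schema, path)
  fail_rows(!data$muscle %in% c("LTL", "SM"), path, "muscle not LTL/SM")
  fail_rows(data$pH < 4.5 | data$pH > 7.5, path, "pH outside plausible range [4.5, 7.5]")
  fail_rows(data$imf_pct < 0, path, "negative IMF")
  fail_rows(data$collagen_mg_g < 0, path, "negative collagen content")
  fail_rows(data$collagen_solubility_pct < 0 | data$collagen_solubility_pct > 100,
            path, "collagen solubility outside [0, 100]")
  data
}

#' Read and validate an echo-train CSV
#'
#' @param path CSV with columns `measurement_id`, `echo_time_ms`,
#'   `intensity` (one block of strictly increasing times per measurement).
#' @return A tibble; times validated strictly increasing within each
#'   measurement.
#' @export
read_echo_csv <- function(path) {
  data <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  check_columns(data, list(measurement_id = "character",
                           echo_time_ms = "numeric", intensity = "numeric"),
                path)
  bad <- data |>
    dplyr::group_by(.data$measurement_id) |>
    dplyr::summarise(ok = !is.unsorted(.data$echo_time_ms, strictly = TRUE) &&
                       all(.data$echo_time_ms > 0), .groups = "drop") |>
    dplyr::filter(!.data$ok)
  if (nrow(bad) > 0) {
    abort(paste0("ordering error in ", path,
                 ": non-increasing or non-positive echo times in measurement(s) ",
                 paste(utils::head(bad$measurement_id, 5), collapse = ", ")))
  }
  data
}

#' Read and validate a sensory CSV
#'
#' @param path CSV with the sensory schema (see [generate_sensory()]).
#' @return A validated tibble.
#' @export
read_sensory_csv <- function(path) {
  data <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  check_columns(data, sensory_schema, path)
  for (sc in c("tenderness", "juiciness", "flavor", "overall")) {
    fail_rows(data[[sc]] < 0 | data[[sc]] > 100, path,
              paste0(sc, " outside [0, 100]"))
  }
  fail_rows(!data$purchase_intent %in% 1:5, path, "purchase_intent outside 1-5")
  fail_rows(!data$quality_grade %in% 1:4, path, "quality_grade outside 1-4")
  fail_rows(!nzchar(data$participant_id) | !nzchar(data$carcass_id), path,
            "empty grouping id")
  data
}

#' Write a table as CSV
#'
#' Plain UTF-8 comma-separated output with a header row.
#'
#' @param data Tibble to write.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_table_csv <- function(data, path) {
  readr::write_csv(data, path, progress = FALSE)
  invisible(path)
}

#' Write echo trains as a long CSV
#'
#' @param trains Named list of [echo_train()] objects; names become
#'   `measurement_id`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_echo_csv <- function(trains, path) {
  long <- purrr::imap_dfr(trains, function(tr, id) {
    tibble::tibble(measurement_id = id,
                   echo_time_ms = tr$echo_time_ms,
                   intensity = tr$intensity)
  })
  readr::write_csv(long, path, progress = FALSE)
  invisible(path)
}

#' Read a pipeline configuration from YAML
#'
#' The YAML mirrors [cohort_config()], [acquisition_config()] and
#' [fit_options()] field for field under top-level keys `cohort`,
#' `acquisition`, `fit`, plus `seed`. Any omitted field keeps its default.
#'
#' @param path YAML file.
#' @return List with elements `cohort` (a `cohort_config`), `acquisition`
#'   (an `acquisition_config`), `fit` (a `fit_options`) and `seed`.
#' @export
read_config_yaml <- function(path) {
  raw <- yaml::read_yaml(path)
  seed <- raw$seed %||% 1L
  co <- raw$cohort %||% list()
  traits <- if (!is.null(co$traits)) {
    dplyr::bind_rows(lapply(co$traits, tibble::as_tibble))
  } else {
    default_traits()
  }
  sens_args <- co$sensory %||% list()
  sens_args$slopes <- if (!is.null(sens_args$slopes)) {
    lapply(sens_args$slopes, unlist)
  } else {
    default_sensory_slopes()
  }
  if (!is.null(sens_args$muscle_means)) {
    sens_args$muscle_means <- lapply(sens_args$muscle_means, unlist)
  }
  for (f in c("off_flavor_prob", "purchase_success", "quality_success")) {
    if (!is.null(sens_args[[f]])) sens_args[[f]] <- unlist(sens_args[[f]])
  }
  cohort <- cohort_config(
    n_carcasses = co$n_carcasses %||% 60,
    traits = traits,
    cross_muscle_r2 = unlist(co$cross_muscle_r2 %||%
                               list(pH = 0.273, collagen_mg_g = 0.214,
                                    collagen_solubility_pct = 0.104,
                                    imf_pct = 0.044)),
    nmr_link = modifyList(default_nmr_link(), co$nmr_link %||% list()),
    nirs_link = modifyList(default_nirs_link(), co$nirs_link %||% list()),
    sensory = do.call(sensory_config, sens_args),
    seed = seed
  )
  acq <- do.call(acquisition_config, raw$acquisition %||% list())
  fopt_args <- raw$fit %||% list()
  for (f in c("t21_bounds", "t22_bounds")) {
    if (!is.null(fopt_args[[f]])) fopt_args[[f]] <- unlist(fopt_args[[f]])
  }
  fit <- do.call(fit_options, fopt_args)
  list(cohort = cohort, acquisition = acq, fit = fit, seed = seed)
}

#' Write a pipeline configuration to YAML
#'
#' @param cohort A [cohort_config()].
#' @param acquisition An [acquisition_config()].
#' @param fit A [fit_options()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_config_yaml <- function(cohort, acquisition, fit, path) {
  co <- unclass(cohort)
  co$traits <- lapply(seq_len(nrow(cohort$traits)),
                      function(i) as.list(cohort$traits[i, ]))
  co$cross_muscle_r2 <- as.list(cohort$cross_muscle_r2)
  sens <- unclass(co$sensory)
  sens$slopes <- lapply(sens$slopes, as.list)
  sens$muscle_means <- lapply(sens$muscle_means, as.list)
  for (f in c("off_flavor_prob", "purchase_success", "quality_success")) {
    sens[[f]] <- as.list(sens[[f]])
  }
  co$sensory <- sens
  seed <- co$seed
  co$seed <- NULL
  yaml::write_yaml(
    list(seed = seed, cohort = co, acquisition = unclass(acquisition),
         fit = unclass(fit)),
    path,
    precision = 15
  )
  invisible(path)
}
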