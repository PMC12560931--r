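pipeline_stages <- c("cohort", "nirs", "nmr", "echoes", "fit",
                     "chemometrics", "sensory", "associations")

stage_deps <- list(
  cohort = character(),
  nirs = "cohort",
  nmr = c("cohort", "nirs"),
  echoes = "nmr",
  fit = "echoes",
  chemometrics = "nirs",
  sensory = "cohort",
  associations = "sensory"
)

#' Run the full simulate-acquire-fit-analyze pipeline
#'
#' Executes, in order: cohort generation, NIRS readings, latent NMR
#' parameters, CPMG acquisition with adaptive averaging (three replicate
#' measurements per loin sample), tri-exponential fitting with replicate
#' averaging, the correlation/regression layer, sensory-response
#' generation, and the mixed-model association layer. Identical
#' configuration and seed give identical outputs (timestamps live only in
#' the report object); every intermediate table is written to `outdir`.
#'
#' @param cohort A [cohort_config()].
#' @param acquisition An [acquisition_config()].
#' @param fit A [fit_options()].
#' @param outdir Output directory (created if needed); `NULL` disables
#'   file output.
#' @param seed Optional global seed overriding the config seed.
#' @param stages Character vector of enabled stages; must include each
#'   enabled stage's dependencies. Disabling `fit` (and its upstream
#'   stages) marks NMR tables as skipped and the chemistry/NIRS analysis
#'   still runs.
#' @param scale Simulated t = 0 signal amplitude, intensity units.
#' @return A `run_report`: per-stage status, all summary tables, the
#'   configuration echo, seed, package version and timestamps.
#' @export
run_pipeline <- function(cohort = cohort_config(),
                         acquisition = acquisition_config(),
                         fit = fit_options(),
                         outdir = NULL,
                         seed = NULL,
                         stages = pipeline_stages,
                         scale = 1000) {
  stopifnot(inherits(cohort, "cohort_config"))
  bad <- setdiff(stages, pipeline_stages)
  if (length(bad) > 0) abort(paste("unknown stage(s):", paste(bad, collapse = ", ")))
  for (s in stages) {
    missing_dep <- setdiff(stage_deps[[s]], stages)
    if (length(missing_dep) > 0) {
      abort(paste0("stage `", s, "` requires disabled stage(s): ",
                   paste(missing_dep, collapse = ", ")))
    }
  }
  seed <- seed %||% cohort$seed
  if (!is.null(outdir) && !dir.exists(outdir)) {
    dir.create(outdir, recursive = TRUE)
  }

  report <- list(
    status = setNames(
      ifelse(pipeline_stages %in% stages, "pending", "disabled"),
      pipeline_stages
    ),
    tables = list(),
    config = list(cohort = unclass_config(cohort),
                  acquisition = unclass(acquisition),
                  fit = unclass(fit)),
    seed = seed,
    version = as.character(utils::packageVersion("meatrelax")),
    started = format(Sys.time(), tz = "UTC")
  )
  env <- new.env(parent = emptyenv())

  run_stage <- function(name, fun) {
    if (!(name %in% stages)) return()
    upstream <- report$status[stage_deps[[name]]]
    if (any(upstream %in% c("failed", "skipped"))) {
      report$status[[name]] <<- "skipped"
      return()
    }
    res <- tryCatch(list(ok = TRUE, value = fun()),
                    error = function(e) list(ok = FALSE, error = conditionMessage(e)))
    if (res$ok) {
      report$status[[name]] <<- "ok"
    } else {
      report$status[[name]] <<- "failed"
      report$errors[[name]] <<- res$error
    }
  }

  run_stage("cohort", function() {
    env$cohort <- generate_cohort(cohort, seed = seed)
    write_out(env$cohort, outdir, "cohort.csv")
  })
  run_stage("nirs", function() {
    env$cohort <- generate_nirs(env$cohort, cohort, seed = seed)
    write_out(env$cohort, outdir, "cohort.csv")
  })
  run_stage("nmr", function() {
    env$nmr <- link_nmr(dplyr::filter(env$cohort, .data$muscle == "LTL"),
                        cohort, seed = seed)
    write_out(env$nmr, outdir, "nmr_params_latent.csv")
  })
  run_stage("echoes", function() {
    env$trains <- simulate_measurements(env$nmr, acquisition, scale, seed)
    if (!is.null(outdir)) {
      write_echo_csv(env$trains, file.path(outdir, "echoes.csv"))
    }
  })
  run_stage("fit", function() {
    env$fits <- fit_measurements(env$trains, fit)
    write_out(env$fits, outdir, "nmr_fits.csv")
  })
  run_stage("chemometrics", function() {
    report$tables <<- c(report$tables,
                        chemometrics_tables(env$cohort, env$fits))
  })
  run_stage("sensory", function() {
    env$sensory <- generate_sensory(env$cohort, cohort, seed = seed)
    write_out(env$sensory, outdir, "sensory.csv")
  })
  run_stage("associations", function() {
    report$tables <<- c(report$tables,
                        association_tables(env$sensory, env$cohort, env$fits))
  })

  if (!("fit" %in% stages) || report$status[["fit"]] != "ok") {
    for (nm in c("fig3_imf_on_p2f", "fig4_ph_on_p2f", "table6_nmr_slopes")) {
      if (is.null(report$tables[[nm]])) report$tables[[nm]] <- "skipped"
    }
  }

  report$finished <- format(Sys.time(), tz = "UTC")
  class(report) <- "run_report"
  if (!is.null(outdir)) {
    write_report_json(report, file.path(outdir, "report.json"))
    for (nm in names(report$tables)) {
      if (is.data.frame(report$tables[[nm]])) {
        write_table_csv(report$tables[[nm]],
                        file.path(outdir, paste0(nm, ".csv")))
      }
    }
  }
  report
}

write_out <- function(x, outdir, name) {
  if (!is.null(outdir)) write_table_csv(x, file.path(outdir, name))
  x
}

unclass_config <- function(cohort) {
  co <- unclass(cohort)
  co$traits <- as.data.frame(co$traits)
  co$sensory <- unclass(co$sensory)
  co
}

# Three replicate acquisitions per loin sample, child-seeded per
# measurement so replicate streams are independent and reproducible.
simulate_measurements <- function(nmr, acquisition, scale, seed,
                                  n_replicates = 3L) {
  trains <- list()
  base <- child_seed(seed, "echoes")
  for (i in seq_len(nrow(nmr))) {
    params <- as.list(nmr[i, ])
    for (r in seq_len(n_replicates)) {
      id <- paste0(nmr$carcass_id[i], "_rep", r)
      trains[[id]] <- acquire_with_averaging(
        params, acquisition, scale = scale,
        seed = (base + 31L * i + r) %% 2147483647
      )
    }
  }
  trains
}

fit_measurements <- function(trains, options) {
  ids <- names(trains)
  sample_id <- sub("_rep[0-9]+$", "", ids)
  replicate <- sub("^.*_rep", "", ids)
  per_rep <- purrr::map(trains, fit_triexponential, options = options)
  rep_rows <- purrr::imap_dfr(per_rep, function(f, id) {
    dplyr::bind_cols(
      tibble::tibble(sample_id = sub("_rep[0-9]+$", "", id),
                     replicate = sub("^.*_rep", "", id)),
      tibble::as_tibble(f$params),
      glance(f)[, c("scale", "residual_rms", "converged", "degenerate")]
    )
  })
  means <- purrr::map_dfr(unique(sample_id), function(sid) {
    fits <- per_rep[sample_id == sid]
    avg <- average_replicate_fits(unname(fits))
    dplyr::bind_cols(
      tibble::tibble(sample_id = sid, replicate = "mean"),
      tibble::as_tibble(avg$params),
      glance(avg)[, c("scale", "residual_rms", "converged", "degenerate")]
    )
  })
  dplyr::bind_rows(rep_rows, means)
}

chemometrics_tables <- function(cohort_data, fits) {
  cohort_data <- aggregate_nirs(cohort_data)
  traits <- c("pH", "collagen_mg_g", "collagen_solubility_pct", "imf_pct")
  out <- list(
    table1_muscle_contrasts = purrr::map_dfr(traits, function(tr) {
      dplyr::bind_cols(tibble::tibble(trait = tr),
                       muscle_contrast(cohort_data, tr))
    }),
    table4_cross_muscle = cross_muscle_regression(cohort_data),
    fig1_imf_on_nirs_pooled = ols_regression(cohort_data$nirs_mean,
                                             cohort_data$imf_pct),
    fig2_imf_on_nirs_by_muscle = purrr::map_dfr(c("LTL", "SM"), function(m) {
      sub <- dplyr::filter(cohort_data, .data$muscle == m)
      dplyr::bind_cols(tibble::tibble(muscle = m),
                       ols_regression(sub$nirs_mean, sub$imf_pct))
    }),
    correlation_matrix = pearson_matrix(
      cohort_data, c(traits, "nirs_mean", "nirs_geomean", "nirs_max")
    )
  )
  if (!is.null(fits)) {
    ltl <- dplyr::filter(cohort_data, .data$muscle == "LTL")
    m <- dplyr::filter(fits, .data$replicate == "mean")
    joined <- dplyr::inner_join(ltl, m, by = c(carcass_id = "sample_id"))
    out$fig3_imf_on_p2f <- ols_regression(joined$p_2f, joined$imf_pct)
    out$fig4_ph_on_p2f <- ols_regression(joined$p_2f, joined$pH)
    out$nmr_correlations <- pearson_matrix(
      joined, c("p_2f", "p_21", "p_22", "t_21_ms", "t_22_ms",
                "imf_pct", "pH", "nirs_mean")
    )
  }
  out
}

association_tables <- function(sensory, cohort_data, fits) {
  responses <- c("tenderness", "juiciness", "flavor", "overall")
  cohort_data <- aggregate_nirs(cohort_data)
  out <- list(
    table2_success_probabilities = dplyr::bind_rows(
      dplyr::mutate(success_probability(sensory, "off_flavor", FALSE),
                    response = "no_off_flavor"),
      dplyr::mutate(success_probability(sensory, "purchase_intent", 4:5),
                    response = "purchase_intent"),
      dplyr::mutate(success_probability(sensory, "quality_grade", 3:4),
                    response = "quality_grade")
    ),
    table3_chemistry_slopes = purrr::map_dfr(responses, function(resp) {
      dplyr::bind_cols(
        tibble::tibble(response = resp),
        fit_chemistry_slopes(sensory, cohort_data, response = resp)
      )
    }),
    table5_nirs_slopes = purrr::map_dfr(responses, function(resp) {
      dplyr::bind_cols(
        tibble::tibble(response = resp),
        fit_single_predictor_slope(
          sensory, dplyr::select(cohort_data, "carcass_id", "muscle", "nirs_mean"),
          predictor = "nirs_mean", response = resp, include_muscle = TRUE
        )
      )
    })
  )
  if (!is.null(fits)) {
    m <- dplyr::filter(fits, .data$replicate == "mean") |>
      dplyr::rename(carcass_id = "sample_id") |>
      dplyr::mutate(muscle = "LTL")
    params <- c("p_2f", "p_21", "p_22", "t_21_ms", "t_22_ms")
    out$table6_nmr_slopes <- purrr::map_dfr(responses, function(resp) {
      purrr::map_dfr(params, function(pp) {
        dplyr::bind_cols(
          tibble::tibble(response = resp),
          fit_single_predictor_slope(
            dplyr::filter(sensory, .data$muscle == "LTL"),
            dplyr::select(m, "carcass_id", "muscle", dplyr::all_of(pp)),
            predictor = pp, response = resp
          )
        )
      })
    })
  }
  out
}

write_report_json <- function(report, path) {
  out <- report
  out$tables <- purrr::map(out$tables, function(tb) {
    if (is.data.frame(tb)) tb else as.character(tb)
  })
  class(out) <- NULL
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows", pretty = TRUE, force = TRUE)
  invisible(path)
}

#' @export
print.run_report <- function(x, ...) {
  cat("meatrelax pipeline report (seed ", x$seed, ")\n", sep = "")
  for (s in names(x$status)) {
    cat(sprintf("  %-14s %s\n", s, x$status[[s]]))
  }
  cat("tables:", paste(names(x$tables), collapse = ", "), "\n")
  invisible(x)
}
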