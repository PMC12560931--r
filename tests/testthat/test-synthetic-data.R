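test_that("cohort generator reproduces configured trait means and is seed-deterministic", {
  cfg <- cohort_config(n_carcasses = 5000, seed = 42)
  co <- generate_cohort(cfg)
  expect_equal(nrow(co), 10000)
  expect_setequal(unique(co$muscle), c("LTL", "SM"))

  means <- tapply(co$pH, co$muscle, mean)
  expect_lt(abs(means[["LTL"]] - 5.56), 0.01)
  expect_lt(abs(means[["SM"]] - 5.65), 0.01)

  # bit-identical under the same config + seed
  expect_identical(co, generate_cohort(cfg))
  # and different under another seed
  expect_false(identical(co, generate_cohort(cfg, seed = 43)))

  # truncation respected for every trait
  for (i in seq_len(nrow(cfg$traits))) {
    row <- cfg$traits[i, ]
    vals <- co[[row$trait]][co$muscle == row$muscle]
    expect_true(all(vals >= row$lower & vals <= row$upper))
  }
})

test_that("zero-SD config collapses every record to the configured means", {
  traits <- default_traits()
  traits$sd <- 0
  cfg <- cohort_config(n_carcasses = 5, traits = traits, seed = 1)
  co <- generate_cohort(cfg)
  for (i in seq_len(nrow(traits))) {
    row <- traits[i, ]
    expect_true(all(co[[row$trait]][co$muscle == row$muscle] == row$mean))
  }
})

test_that("cross-muscle dependence hits the target squared correlation", {
  cfg <- cohort_config(n_carcasses = 5000, seed = 7)
  co <- generate_cohort(cfg)
  wide <- tidyr::pivot_wider(co[, c("carcass_id", "muscle", "pH")],
                             names_from = "muscle", values_from = "pH")
  expect_lt(abs(cor(wide$LTL, wide$SM)^2 - 0.273), 0.03)
})

test_that("invalid cohort configurations are rejected", {
  bad <- default_traits()
  bad$sd[1] <- -1
  expect_error(cohort_config(traits = bad), "SD")
  bad <- default_traits()
  bad$mean[1] <- bad$upper[1] + 1
  expect_error(cohort_config(traits = bad), "range")
  expect_error(cohort_config(n_carcasses = 1), "n_carcasses")
  expect_error(cohort_config(cross_muscle_r2 = c(pH = 1.2)), "R2")
})

test_that("NMR link renormalises amplitudes and degenerates correctly", {
  cfg <- cohort_config(n_carcasses = 200, seed = 3)
  ltl <- dplyr::filter(generate_cohort(cfg), muscle == "LTL")
  nmr <- link_nmr(ltl, cfg)
  expect_equal(nmr$p_2f + nmr$p_21 + nmr$p_22, rep(1, nrow(nmr)),
               tolerance = 1e-12)
  expect_true(all(nmr$p_2f >= 0 & nmr$p_21 >= 0 & nmr$p_22 >= 0))
  expect_true(all(nmr$t_2f_ms == 10))
  expect_true(all(nmr$t_2f_ms < nmr$t_21_ms & nmr$t_21_ms < nmr$t_22_ms))

  # zero link coefficients and zero noise: identical params for all samples
  link0 <- default_nmr_link()
  for (nm in names(link0)) {
    link0[[nm]]$coef_imf <- 0; link0[[nm]]$coef_ph <- 0; link0[[nm]]$resid_sd <- 0
  }
  cfg0 <- cohort_config(n_carcasses = 50, nmr_link = link0, seed = 3)
  nmr0 <- link_nmr(dplyr::filter(generate_cohort(cfg0), muscle == "LTL"), cfg0)
  expect_equal(length(unique(nmr0$p_2f)), 1)
  expect_equal(length(unique(nmr0$t_21_ms)), 1)

  # mixing muscles is an error
  expect_error(link_nmr(generate_cohort(cfg), cfg), "single muscle")
})

test_that("link calibration round-trips its target triple analytically", {
  targets <- list(c(-10.5, 0.287, 0.094), c(26.5, 0.124, 0.366),
                  c(0.5, 0.6, 1.2))
  for (tg in targets) {
    cal <- calibrate_link(tg[1], tg[2], tg[3])
    vy <- cal$trait_var
    vp <- cal$coef^2 * vy + cal$resid_sd^2
    expect_equal(cal$coef * vy / vp, tg[1], tolerance = 1e-10)
    expect_equal(cal$coef^2 * vy / vp, tg[2], tolerance = 1e-10)
    expect_equal(sqrt(vy * (1 - tg[2])), tg[3], tolerance = 1e-10)
    expect_equal(vp, cal$latent_var, tolerance = 1e-10)
  }
  expect_error(calibrate_link(0, 0.5, 1), "slope")
  expect_error(calibrate_link(1, 1.2, 1), "R2")
  expect_error(calibrate_regression(1, 0.5, -1), "RMSE")
})

test_that("calibrated generators reproduce their target triple at large n", {
  # forward design
  d <- simulate_regression_cohort(0.502, 0.258, 0.413, 10000, seed = 5)
  s <- ols_regression(d$x, d$y)
  expect_lt(abs(s$slope / 0.502 - 1), 0.03)
  expect_lt(abs(s$r2 / 0.258 - 1), 0.03)
  expect_lt(abs(s$rmse / 0.413 - 1), 0.03)
  # inverse link
  d <- simulate_link_cohort(-10.5, 0.287, 0.094, 10000, trait_mean = 5.56, seed = 6)
  s <- ols_regression(d$param, d$trait)
  expect_lt(abs(s$slope / -10.5 - 1), 0.03)
  expect_lt(abs(s$r2 / 0.287 - 1), 0.03)
  expect_lt(abs(s$rmse / 0.094 - 1), 0.03)
})

test_that("NIRS generation has the configured replicate structure", {
  cfg <- cohort_config(n_carcasses = 100, seed = 9)
  co <- generate_cohort(cfg)
  # zero replicate SD: identical readings
  link <- default_nirs_link(); link$replicate_sd <- 0
  cfg0 <- cohort_config(n_carcasses = 100, nirs_link = link, seed = 9)
  co0 <- generate_nirs(co, cfg0)
  expect_equal(co0$nirs_1, co0$nirs_2)
  expect_equal(co0$nirs_2, co0$nirs_3)
  # replicate mean is centred on the latent value: with between SD 0 the
  # mean of many replicate-noise draws converges to intercept + slope*IMF
  link <- default_nirs_link(); link$between_sd <- 0
  cfg1 <- cohort_config(n_carcasses = 2000, nirs_link = link, seed = 10)
  co1 <- generate_nirs(generate_cohort(cfg1), cfg1)
  latent <- link$intercept + link$slope * co1$imf_pct
  triple_mean <- (co1$nirs_1 + co1$nirs_2 + co1$nirs_3) / 3
  expect_lt(abs(mean(triple_mean - latent)), 0.02)
  expect_true(all(co1$nirs_1 > 0))
})

test_that("echo simulation matches the acquisition geometry and decay model", {
  p <- default_params()
  acq0 <- acquisition_config(noise_sd = 0)
  tr <- simulate_echo_train(p, acq0, scale = 1000, seed = 1)
  expect_equal(nrow(tr), 2000)
  expect_equal(max(tr$echo_time_ms), 600)
  expect_equal(diff(tr$echo_time_ms)[1], 0.3)

  # extrapolation to t = 0 equals the scale (amplitudes sum to 1)
  t <- tr$echo_time_ms
  model <- 1000 * (p$p_2f * exp(-t / 10) + p$p_21 * exp(-t / 40) +
                     p$p_22 * exp(-t / 150))
  expect_equal(tr$intensity, model, tolerance = 1e-12)

  # mono-exponential identity: I(T_21) = I(0)/e when only pool 1 is present
  p1 <- list(p_2f = 0, p_21 = 1, p_22 = 0, t_2f_ms = 10, t_21_ms = 40,
             t_22_ms = 150)
  tr1 <- simulate_echo_train(p1, acquisition_config(n_echoes = 400,
                                                    echo_spacing_ms = 1,
                                                    noise_sd = 0),
                             scale = 500, seed = 1)
  expect_equal(tr1$intensity[tr1$echo_time_ms == 40], 500 * exp(-1),
               tolerance = 1e-12)

  # determinism
  trn <- simulate_echo_train(p, acquisition_config(), seed = 11)
  expect_identical(trn, simulate_echo_train(p, acquisition_config(), seed = 11))
})

test_that("scan averaging obeys the 1/sqrt(k) noise law", {
  p <- default_params()
  acq <- acquisition_config(n_echoes = 20, noise_sd = 8, points_per_echo = 4)
  t <- seq_len(20) * 0.3
  clean <- 1000 * (p$p_2f * exp(-t / 10) + p$p_21 * exp(-t / 40) +
                     p$p_22 * exp(-t / 150))
  sd_single <- 8 / sqrt(4)
  for (k in c(1, 4, 16)) {
    dev <- replicate(500, {
      trains <- vapply(seq_len(k), function(j) {
        simulate_echo_train(p, acq, scale = 1000,
                            seed = sample.int(2^30, 1))$intensity
      }, numeric(20))
      rowMeans(matrix(trains, nrow = 20))[1] - clean[1]
    })
    expect_lt(abs(sd(dev) / (sd_single / sqrt(k)) - 1), 0.2)
  }
})

test_that("adaptive averaging stops at the SNR threshold and flags non-attainment", {
  p <- default_params()
  # noiseless: one scan, effectively infinite SNR
  tr0 <- acquire_with_averaging(p, acquisition_config(noise_sd = 0), seed = 1)
  expect_equal(attr(tr0, "n_scans_averaged"), 1L)
  expect_gt(compute_snr(tr0), 1e5)
  expect_false(attr(tr0, "below_snr"))

  # single-scan SNR ~ 30: scan count near the square-law prediction (200/30)^2
  acq30 <- acquisition_config(noise_sd = 1000 / 30 * sqrt(8))
  ks <- vapply(1:5, function(s) {
    tr <- acquire_with_averaging(p, acq30, scale = 1000, seed = s)
    expect_gt(compute_snr(tr), 200)
    expect_false(attr(tr, "below_snr"))
    attr(tr, "n_scans_averaged")
  }, integer(1))
  expect_gt(mean(ks), 45 * 0.65)
  expect_lt(mean(ks), 45 * 1.45)

  # unreachable threshold: flag, not exception
  acq_cap <- acquisition_config(noise_sd = 1000 / 30 * sqrt(8), max_scans = 3)
  tr_cap <- acquire_with_averaging(p, acq_cap, seed = 2)
  expect_true(attr(tr_cap, "below_snr"))
  expect_equal(attr(tr_cap, "n_scans_averaged"), 3L)
})

test_that("sensory generator honours its degenerate and variance contracts", {
  # all slopes and SDs zero: score equals the muscle intercept (= target mean)
  sc0 <- sensory_config(
    slopes = lapply(default_sensory_slopes(), function(s) s * 0),
    sd_session = 0, sd_participant = 0, sd_carcass = 0, sd_residual = 0
  )
  cfg0 <- cohort_config(n_carcasses = 10, sensory = sc0, seed = 21)
  co0 <- generate_cohort(cfg0)
  s0 <- generate_sensory(co0, cfg0)
  expect_equal(unique(s0$tenderness[s0$muscle == "LTL"]), 48.8)
  expect_equal(unique(s0$tenderness[s0$muscle == "SM"]), 51.7)
  expect_equal(unique(s0$overall[s0$muscle == "SM"]), 54.7)

  # variance decomposition in the untruncated, zero-slope regime
  scv <- sensory_config(
    slopes = lapply(default_sensory_slopes(), function(s) s * 0),
    truncate = FALSE
  )
  cfgv <- cohort_config(n_carcasses = 200, sensory = scv, seed = 22)
  sv <- generate_sensory(generate_cohort(cfgv), cfgv)
  expected_var <- 3^2 + 10^2 + 5^2 + 15^2
  expect_lt(abs(var(sv$tenderness) / expected_var - 1), 0.2)

  # grouping structure: each sample tasted by the configured number of consumers
  counts <- dplyr::count(sv, .data$carcass_id, .data$muscle)
  expect_true(all(counts$n == 10))

  # ordinal marginals near the configured success probabilities
  succ <- tapply(sv$purchase_intent >= 4, sv$muscle, mean)
  expect_lt(abs(succ[["LTL"]] - 0.298), 0.05)
  expect_lt(abs(succ[["SM"]] - 0.351), 0.05)

  # determinism
  expect_identical(sv, generate_sensory(generate_cohort(cfgv), cfgv))
})
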