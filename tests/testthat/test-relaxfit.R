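test_that("noiseless tri-exponential trains are recovered essentially exactly", {
  p <- default_params()
  tr <- simulate_echo_train(p, acquisition_config(noise_sd = 0),
                            scale = 1000, seed = 1)
  fit <- fit_triexponential(tr)
  expect_true(fit$converged)
  expect_equal(fit$params$t_2f_ms, 10) # fixed, exactly
  for (f in c("p_2f", "p_21", "p_22", "t_21_ms", "t_22_ms")) {
    expect_lt(abs(fit$params[[f]] / p[[f]] - 1), 1e-3)
  }
  expect_lt(fit$residual_rms, 1e-8 * 1000)
  expect_equal(fit$scale, 1000, tolerance = 1e-6)
})

test_that("the fixed fast time constant is echoed exactly for any input", {
  p <- default_params()
  for (seed in 1:3) {
    tr <- simulate_echo_train(p, acquisition_config(noise_sd = 30), seed = seed)
    expect_identical(fit_triexponential(tr)$params$t_2f_ms, 10)
  }
  opts <- fit_options(fixed_t2f_ms = 8, t21_bounds = c(9, 100))
  tr <- simulate_echo_train(p, acquisition_config(noise_sd = 0), seed = 1)
  expect_identical(fit_triexponential(tr, opts)$params$t_2f_ms, 8)
})

test_that("a pure mono-exponential train collapses onto the middle pool", {
  p1 <- list(p_2f = 0, p_21 = 1, p_22 = 0, t_2f_ms = 10, t_21_ms = 40,
             t_22_ms = 150)
  tr <- simulate_echo_train(p1, acquisition_config(noise_sd = 0),
                            scale = 750, seed = 1)
  fit <- fit_triexponential(tr)
  expect_gte(fit$params$p_21 + fit$params$p_2f * 0, 0.99)
  expect_lt(abs(fit$scale / 750 - 1), 1e-6)
  expect_lt(abs(fit$params$t_21_ms / 40 - 1), 1e-3)
})

test_that("multi-start fit agrees with the exhaustive grid-search oracle", {
  acq <- acquisition_config(n_echoes = 50, echo_spacing_ms = 12, noise_sd = 0)
  cases <- list(
    list(p_2f = 0.05, p_21 = 0.85, p_22 = 0.10, t_2f_ms = 10,
         t_21_ms = 40, t_22_ms = 150),
    list(p_2f = 0.10, p_21 = 0.75, p_22 = 0.15, t_2f_ms = 10,
         t_21_ms = 35, t_22_ms = 160),
    list(p_2f = 0.02, p_21 = 0.90, p_22 = 0.08, t_2f_ms = 10,
         t_21_ms = 45, t_22_ms = 140)
  )
  for (p in cases) {
    tr <- simulate_echo_train(p, acq, scale = 1000, seed = 1)
    fit <- fit_triexponential(tr)
    oracle <- grid_search_fit(tr$echo_time_ms, tr$intensity, 1000)
    expect_lte(abs(fit$params$t_21_ms - oracle$t_21_ms), 1)
    expect_lte(abs(fit$params$t_22_ms - oracle$t_22_ms), 1)
    expect_lte(abs(fit$params$p_2f - oracle$p_2f), 0.01)
    expect_lte(abs(fit$params$p_21 - oracle$p_21), 0.01)
    expect_lte(abs(fit$params$p_22 - oracle$p_22), 0.01)
  }
})

test_that("self-consistency: fitting simulated trains at SNR 200 recovers parameters within 2%", {
  p <- default_params()
  # per-echo noise for SNR 200 at scale 1000: sd = 5; points_per_echo = 4
  acq <- acquisition_config(noise_sd = 5 * sqrt(4), points_per_echo = 4)
  fields <- c("p_2f", "p_21", "p_22", "t_21_ms", "t_22_ms")
  est <- withr::with_seed(314, {
    vapply(1:200, function(i) {
      tr <- simulate_echo_train(p, acq, scale = 1000,
                                seed = sample.int(2^30, 1))
      fit <- fit_triexponential(tr)
      vapply(fields, function(f) fit$params[[f]], numeric(1))
    }, numeric(5))
  })
  bias <- rowMeans(est) / unlist(p[fields]) - 1
  expect_true(all(abs(bias) < 0.02))
})

test_that("parameter RMSE does not degrade as SNR grows", {
  p <- default_params()
  truth <- unlist(p[c("p_2f", "p_21", "p_22", "t_21_ms", "t_22_ms")])
  rmse_at <- function(snr, reps = 200) {
    acq <- acquisition_config(noise_sd = 1000 / snr * sqrt(4),
                              points_per_echo = 4)
    err <- withr::with_seed(1000 + snr, {
      vapply(seq_len(reps), function(i) {
        fit <- fit_triexponential(
          simulate_echo_train(p, acq, scale = 1000,
                              seed = sample.int(2^30, 1))
        )
        est <- unlist(fit$params[c("p_2f", "p_21", "p_22", "t_21_ms", "t_22_ms")])
        mean(((est - truth) / truth)^2)
      }, numeric(1))
    })
    sqrt(mean(err))
  }
  levels <- c(50, 100, 200, 400)
  rmses <- vapply(levels, rmse_at, numeric(1))
  # monotone non-increasing up to 20% sampling slack
  for (i in seq_len(length(levels) - 1)) {
    expect_lt(rmses[i + 1], rmses[i] * 1.2)
  }
  # and substantially better across the full range
  expect_lt(rmses[4], rmses[1])
})

test_that("label ordering and start permutation leave the fit unchanged", {
  p <- default_params()
  tr <- simulate_echo_train(p, acquisition_config(noise_sd = 20), seed = 5)
  f1 <- fit_triexponential(tr, fit_options(n_starts_grid = 4))
  expect_lt(f1$params$t_21_ms, f1$params$t_22_ms)
  # a different (denser) start set converges to the same labeled optimum
  f2 <- fit_triexponential(tr, fit_options(n_starts_grid = 5))
  expect_equal(f1$params$t_21_ms, f2$params$t_21_ms, tolerance = 1e-4)
  expect_equal(f1$params$p_21, f2$params$p_21, tolerance = 1e-5)
})

test_that("too-short trains are rejected", {
  tr <- echo_train(1:5, exp(-(1:5) / 3))
  expect_error(fit_triexponential(tr), "at least 10 echoes")
})

test_that("noise estimation tracks injected noise and constant offsets", {
  p <- default_params()
  # fit-based estimate on a noiseless train is numerically zero
  tr0 <- simulate_echo_train(p, acquisition_config(noise_sd = 0),
                             scale = 1000, seed = 1)
  fit0 <- fit_triexponential(tr0)
  expect_lt(estimate_noise(tr0, fit0), 1e-7)

  # difference-based estimate within 15% of injected sigma on average
  sigma <- 4 # per-echo after point averaging: 8/sqrt(4)
  acq <- acquisition_config(noise_sd = 8, points_per_echo = 4)
  est <- withr::with_seed(99, {
    vapply(1:100, function(i) {
      estimate_noise(simulate_echo_train(p, acq, seed = sample.int(2^30, 1)))
    }, numeric(1))
  })
  expect_lt(abs(mean(est) / sigma - 1), 0.15)

  # differencing is invariant to adding a constant to all intensities
  tr <- simulate_echo_train(p, acq, seed = 123)
  shifted <- echo_train(tr$echo_time_ms, tr$intensity + 500)
  expect_equal(estimate_noise(tr), estimate_noise(shifted), tolerance = 1e-12)
})

test_that("SNR follows its definition and the sqrt(k) averaging law", {
  # definitional check: known I0 and noise
  tr <- echo_train(1:100, 300 * exp(-(1:100) / 50))
  expect_equal(compute_snr(tr, noise_sd = 1, i0 = 300), 300)

  # averaging 4 scans doubles SNR within sampling error
  p <- default_params()
  acq <- acquisition_config(noise_sd = 1000 / 50 * sqrt(8))
  snr_of_k <- function(k, seed) {
    tr1 <- simulate_echo_train(p, acq, scale = 1000, seed = seed)
    acc <- tr1$intensity
    for (j in seq_len(k - 1)) {
      acc <- acc + simulate_echo_train(p, acq, scale = 1000,
                                       seed = seed + 1000 * j)$intensity
    }
    compute_snr(echo_train(tr1$echo_time_ms, acc / k))
  }
  r <- withr::with_seed(5150, {
    mean(vapply(1:30, function(i) {
      s <- sample.int(2^20, 1)
      snr_of_k(4, s) / snr_of_k(1, s + 7)
    }, numeric(1)))
  })
  expect_lt(abs(r / 2 - 1), 0.15)
})

test_that("replicate averaging reduces error and rejects non-converged input", {
  p <- default_params()
  f <- fit_triexponential(simulate_echo_train(p, acquisition_config(noise_sd = 0),
                                              seed = 1))
  # identical fits average to themselves
  avg <- average_replicate_fits(list(f, f, f))
  expect_equal(avg$params, f$params, tolerance = 1e-12)

  # arithmetic-mean contract
  mk <- function(p2f) {
    g <- f
    g$params$p_2f <- p2f
    g$params$p_21 <- 1 - p2f - g$params$p_22
    g
  }
  avg <- average_replicate_fits(list(mk(0.04), mk(0.05), mk(0.06)))
  expect_equal(avg$params$p_2f, 0.05, tolerance = 1e-12)

  # non-converged replicate is named
  bad <- f; bad$converged <- FALSE
  expect_error(average_replicate_fits(list(f, bad, f)), "replicate\\(s\\).*2")
  expect_error(average_replicate_fits(list(f, f)), "exactly three")

  # averaging replicate fits beats a single replicate on average
  acq <- acquisition_config(n_echoes = 1000, noise_sd = 1000 / 100 * sqrt(4),
                            points_per_echo = 4)
  truth <- unlist(p[c("p_2f", "p_21", "p_22", "t_21_ms", "t_22_ms")])
  res <- withr::with_seed(2718, {
    vapply(1:60, function(i) {
      fits <- lapply(1:3, function(j) {
        fit_triexponential(simulate_echo_train(p, acq, scale = 1000,
                                               seed = sample.int(2^30, 1)))
      })
      avg <- average_replicate_fits(fits)
      err <- function(ft) {
        est <- unlist(ft$params[c("p_2f", "p_21", "p_22", "t_21_ms", "t_22_ms")])
        mean(((est - truth) / truth)^2)
      }
      c(single = err(fits[[1]]), averaged = err(avg))
    }, numeric(2))
  })
  expect_lt(mean(res["averaged", ]), mean(res["single", ]))
})

test_that("tidy and glance expose the fit in broom form", {
  p <- default_params()
  f <- fit_triexponential(simulate_echo_train(p, acquisition_config(noise_sd = 0),
                                              seed = 1))
  td <- tidy(f)
  expect_s3_class(td, "tbl_df")
  expect_setequal(td$term, c("p_2f", "p_21", "p_22", "t_2f_ms", "t_21_ms",
                             "t_22_ms", "scale"))
  gl <- glance(f)
  expect_equal(nrow(gl), 1)
  expect_true(gl$converged)
})
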