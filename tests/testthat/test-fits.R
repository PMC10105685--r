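test_that("fit_hill recovers its noise-free forward model exactly", {
  truth <- hill_params(0.2, 660e-9, 1.8)
  x <- 10^seq(-7.5, -5, length.out = 8)
  fit <- fit_hill(data.frame(x = x, y = hill_po(x, truth)))
  expect_true(fit$converged)
  expect_equal(fit$params$pmax, 0.2, tolerance = 1e-6)
  expect_equal(fit$params$ec50, 660e-9, tolerance = 1e-6)
  expect_equal(fit$params$h, 1.8, tolerance = 1e-6)
  expect_lt(fit$rss, 1e-12)
})

test_that("fit_hill handles replicate noise and degenerate flat data", {
  set.seed(1)
  truth <- hill_params(0.2, 660e-9, 1.8)
  x <- rep(10^seq(-7.5, -5, length.out = 8), each = 6)
  y <- hill_po(x, truth) * (1 + rnorm(length(x), 0, 0.05))
  fit <- fit_hill(data.frame(x = x, y = y))
  expect_true(fit$converged)
  expect_equal(fit$params$ec50, 660e-9, tolerance = 0.15)
  # flat response: flagged unidentifiable, not an exception
  flat <- fit_hill(data.frame(x = 10^seq(-8, -5, length.out = 8),
                              y = rep(0.1, 8)))
  expect_false(flat$converged)
  expect_match(flat$flags, "unidentifiable")
})

test_that("hill EC50 estimator is calibrated (Monte-Carlo)", {
  # 6 replicates per level, additive noise at 5 percent of the ceiling
  # (the homoscedastic error model the unweighted fit assumes); CIs on the
  # log-EC50 scale, the fit's native parameterization
  set.seed(99)
  truth <- hill_params(0.2, 660e-9, 1.8)
  x <- rep(10^seq(-7.5, -5, length.out = 8), each = 6)
  rel_err <- numeric(200)
  covered <- logical(200)
  for (i in 1:200) {
    y <- hill_po(x, truth) + rnorm(length(x), 0, 0.05 * 0.2)
    f <- fit_hill(data.frame(x = x, y = y))
    rel_err[i] <- abs(f$params$ec50 - 660e-9) / 660e-9
    ci <- f$params$ec50 * exp(c(-1.96, 1.96) * f$se$ec50 / f$params$ec50)
    covered[i] <- ci[1] <= 660e-9 && 660e-9 <= ci[2]
  }
  expect_lt(median(rel_err), 0.05)
  expect_gte(mean(covered), 0.90)
  expect_lte(mean(covered), 0.99)
})

test_that("fit_biphasic_hill recovers exactly, under noise, and flags monotone data", {
  truth <- biphasic_hill_params(0.1, 78e-9, 2, 562e-9, 2)
  x <- 10^seq(-8, -5, length.out = 12)
  fit <- fit_biphasic_hill(data.frame(x = x, y = biphasic_po(x, truth)))
  expect_true(fit$converged)
  expect_equal(fit$params$ec50_act, 78e-9, tolerance = 1e-5)
  expect_equal(fit$params$ic50_inh, 562e-9, tolerance = 1e-5)
  expect_lt(fit$rss, 1e-12)

  set.seed(7)
  y <- biphasic_po(x, truth) * (1 + rnorm(12, 0, 0.03))
  noisy <- fit_biphasic_hill(data.frame(x = x, y = y))
  expect_equal(noisy$params$ec50_act, 78e-9, tolerance = 0.20)
  expect_equal(noisy$params$ic50_inh, 562e-9, tolerance = 0.20)

  # purely ascending data: inhibition limb unidentifiable
  mono <- fit_biphasic_hill(
    data.frame(x = x, y = hill_po(x, hill_params(0.1, 78e-9, 2))))
  expect_false(mono$converged)
  expect_match(paste(mono$flags, collapse = " "), "ic50 unidentifiable")
})

test_that("fit_linear_iv recovers the slope conductance", {
  v <- c(-40, -30, -20, 20, 30, 40)
  exact <- fit_linear_iv(data.frame(x = v, y = 0.248 * v))
  expect_equal(exact$params$conductance_pS, 248, tolerance = 1e-9)
  expect_equal(exact$params$reversal_mV, 0, tolerance = 1e-6)

  set.seed(3)
  noisy <- fit_linear_iv(data.frame(x = v, y = 0.248 * v + rnorm(6, 0, 0.2)))
  expect_lt(abs(noisy$params$conductance_pS - 248),
            2 * noisy$se$conductance_pS + 1e-9)

  # two points: exact interpolation
  two <- fit_linear_iv(data.frame(x = c(-20, 20), y = c(-4.96, 4.96)))
  expect_equal(two$params$conductance_pS, 248, tolerance = 1e-9)
  expect_error(fit_linear_iv(data.frame(x = c(10, 10, 10), y = c(1, 2, 3))),
               "distinct")
})

test_that("fit_linear_iv is invariant to point ordering", {
  set.seed(13)
  v <- c(-40, -30, -20, 20, 30, 40)
  y <- 0.248 * v + rnorm(6, 0, 0.2)
  a <- fit_linear_iv(data.frame(x = v, y = y))
  o <- sample(6)
  b <- fit_linear_iv(data.frame(x = v[o], y = y[o]))
  expect_equal(a$params$conductance_pS, b$params$conductance_pS)
})

test_that("fit_mot_edf recovers the double-Hill curve and flags one-limb data", {
  truth <- feedthrough_mot_params(2.5, 111.5, 7.8, 170.7, 3.7)
  x <- seq(60, 260, length.out = 12)
  fit <- fit_mot_edf(data.frame(x = x, y = mot_edf_model(x, truth)))
  expect_true(fit$converged)
  expect_equal(fit$params$va50, 111.5, tolerance = 1e-4)
  expect_equal(fit$params$vi50, 170.7, tolerance = 1e-4)
  expect_lt(fit$rss, 1e-10)

  set.seed(11)
  y <- mot_edf_model(x, truth) * (1 + rnorm(12, 0, 0.05))
  noisy <- fit_mot_edf(data.frame(x = x, y = y))
  expect_equal(noisy$params$va50, 111.5, tolerance = 0.10)

  # purely rising data (no inhibition in the generator): vi50 unidentifiable
  xa <- seq(60, 260, length.out = 10)
  rising <- 1 + 2.5 / (1 + (111.5 / xa)^7.8)
  mono <- fit_mot_edf(data.frame(x = xa, y = rising))
  expect_match(paste(mono$flags, collapse = " "), "vi50",
               info = "expected a vi50 identifiability flag")
  expect_error(
    fit_mot_edf(data.frame(x = c(-40, -30, -20, -10, 20, 30), y = rep(1, 6))),
    "EDF > 0")
})

test_that("mct_overlay recovers exact inversions and beats a constant fit", {
  truth <- feedthrough_mot_params(2.5, 111.5, 7.8, 170.7, 3.7)
  x <- seq(60, 260, length.out = 10)
  m <- mot_edf_model(x, truth)
  ov <- mct_overlay(truth, data.frame(x = x, y = 3 - 0.8 * m))
  expect_equal(ov$a, 3, tolerance = 1e-9)
  expect_equal(ov$b, 0.8, tolerance = 1e-9)
  expect_lt(ov$rss, 1e-18)

  const <- mct_overlay(truth, data.frame(x = x, y = rep(2, 10)))
  expect_equal(const$b, 0, tolerance = 1e-9)

  set.seed(5)
  noisy <- data.frame(x = x, y = 3 - 0.8 * m + rnorm(10, 0, 0.05))
  ovn <- mct_overlay(truth, noisy)
  expect_lt(ovn$rss, ovn$rss_const)
  expect_lt(ovn$f_p, 0.05)
})

test_that("dose_response_pipeline recovers the generating EC50 end to end", {
  set.seed(17)
  hill <- ip3r_params("wt_ip3")
  levels <- 10^seq(log10(30e-9), log10(10e-6), length.out = 7)
  cfg <- sim_config(duration = 20)
  trace_sets <- lapply(levels, function(ip3) {
    lapply(1:3, function(r)
      simulate_experiment(list(ip3 = ip3), hill, 8e-3, cfg)$trace)
  })
  res <- dose_response_pipeline(trace_sets, levels, unitary = 7.44,
                                dead_time = 300e-6, fit = "hill")
  expect_true(res$fit$converged)
  expect_equal(res$fit$params$ec50, 660e-9, tolerance = 0.25)
  expect_equal(nrow(res$points), 7)
  expect_true(all(res$points$n == 3))
})

test_that("dose_response_pipeline refuses single-condition fits but keeps points", {
  set.seed(18)
  cfg <- sim_config(duration = 5)
  traces <- list(list(simulate_experiment(list(ip3 = 1e-6),
                                          ip3r_params("wt_ip3"), 8e-3,
                                          cfg)$trace))
  expect_warning(res <- dose_response_pipeline(traces, 1e-6, unitary = 7.44),
                 "refused")
  expect_null(res$fit)
  expect_equal(nrow(res$points), 1)
  # zero-activity conditions are retained as zero-valued points
  quiet <- rep(0, 20000)
  qtrace <- structure(list(samples = quiet, sample_rate = 2e4, config = NULL),
                      class = "current_trace")
  sets <- c(lapply(10^seq(-7, -5.5, length.out = 4), function(ip3) {
    list(simulate_experiment(list(ip3 = ip3), ip3r_params("wt_ip3"), 8e-3,
                             sim_config(duration = 5))$trace)
  }), list(list(qtrace)))
  res2 <- dose_response_pipeline(sets, c(10^seq(-7, -5.5, length.out = 4), 1e-9),
                                 unitary = 7.44, fit = "hill")
  expect_equal(res2$points$y[5], 0)
})

test_that("dose-response CSV round-trips", {
  pts <- data.frame(x = c(1e-7, 1e-6), y = c(0.01, 0.09),
                    y_err = c(0.002, 0.01), n = c(3, 3))
  path <- withr::local_tempfile(fileext = ".csv")
  write_dose_response_csv(pts, path)
  expect_equal(read_dose_response_csv(path), pts)
})
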