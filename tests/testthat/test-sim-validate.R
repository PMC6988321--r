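# Synthetic series generator, quasi-Poisson first-stage fits, Monte-Carlo
# reference SEs and the percent-error validation tables.

test_that("exposure simulation is deterministic and has the stated moments", {
  cfg <- sim_config(n_days = 3650, amplitude = 0, noise_sd = 2, seed = 21)
  x1 <- simulate_exposure(cfg)
  x2 <- simulate_exposure(cfg)
  expect_identical(x1, x2)
  # pure noise: sample SD near sigma (3 MC SEs of a sample SD)
  expect_equal(sd(x1), 2, tolerance = 3 / sqrt(2 * 3649) * 3)

  flat <- simulate_exposure(sim_config(n_days = 100, amplitude = 0,
                                       noise_sd = 0, seed = 1))
  expect_equal(flat, rep(0, 100))

  seasonal <- simulate_exposure(sim_config(n_days = 36525, amplitude = 3,
                                           noise_sd = 1, seed = 22))
  expect_equal(sd(seasonal), sqrt(3^2 / 2 + 1), tolerance = 0.02)
})

test_that("Poisson counts reproduce the mean-variance identity", {
  cfg <- sim_config(n_days = 10000, baseline_rate = 20, beta_true = 0,
                    amplitude = 0, noise_sd = 1, seed = 23)
  s <- simulate_series(cfg)
  expect_true(all(s$counts >= 0 & s$counts == round(s$counts)))
  expect_equal(mean(s$counts), 20, tolerance = 3 * sqrt(20 / 10000) / 20)
  expect_equal(var(s$counts) / mean(s$counts), 1, tolerance = 0.05)
})

test_that("negative-binomial counts hit the target Pearson dispersion", {
  # phi = 1.5, constant mu = 20: moment estimate over 200 replicates
  disp <- vapply(1:200, function(r) {
    cfg <- sim_config(n_days = 500, baseline_rate = 20, beta_true = 0,
                      dispersion = 1.5, amplitude = 0, noise_sd = 0,
                      seed = 4000 + 2 * r)
    y <- simulate_counts(rep(0, 500), daily_dates(500), cfg)$counts
    sum((y - mean(y))^2 / mean(y)) / 499
  }, numeric(1))
  expect_equal(mean(disp), 1.5, tolerance = 3 * sd(disp) / sqrt(200) / 1.5)
})

test_that("expected event totals scale with series length", {
  a <- simulate_series(sim_config(n_days = 2000, baseline_rate = 10,
                                  amplitude = 0, seed = 24))
  b <- simulate_series(sim_config(n_days = 4000, baseline_rate = 10,
                                  amplitude = 0, seed = 25))
  expect_equal(sum(b$counts) / sum(a$counts), 2, tolerance = 0.05)
})

test_that("overflowing linear predictors are rejected with advice", {
  cfg <- sim_config(n_days = 100, baseline_rate = 5, beta_true = 10,
                    amplitude = 20, noise_sd = 0, seed = 1)
  expect_error(simulate_series(cfg), "baseline_rate")
})

test_that("the quasi-Poisson fit recovers the generating coefficient", {
  cfg <- sim_config(n_days = 3650, baseline_rate = 20, beta_true = 0.02,
                    dispersion = 1, confounder_coupling = 0.3, seed = 26)
  fit <- fit_series(simulate_series(cfg))
  expect_lt(abs(fit$beta_hat - 0.02), 3 * fit$se)
  expect_gt(fit$dispersion_hat, 0.9)
  expect_lt(fit$dispersion_hat, 1.1)
})

test_that("degenerate designs are rejected by the fit", {
  s <- simulate_series(sim_config(n_days = 400, seed = 27))
  s$exposure <- rep(0, 400)
  expect_error(fit_series(s), "no variation")
  s2 <- simulate_series(sim_config(n_days = 400, baseline_rate = 1e-6,
                                   seed = 28))
  expect_error(fit_series(s2), "no events")
})

test_that("the Monte-Carlo SE is reproducible and tracks the approximation", {
  cfg <- sim_config(n_days = 1000, baseline_rate = 10, beta_true = 0.02,
                    amplitude = 0, noise_sd = 1, seed = 29)
  e1 <- empirical_se(cfg, n_reps = 60)
  e2 <- empirical_se(cfg, n_reps = 60)
  expect_identical(as.numeric(e1), as.numeric(e2))
  expect_equal(attr(e1, "n_fail"), 0)
  # ~10,000 events, usable SD ~1: closed form predicts ~0.01
  expect_equal(as.numeric(e1), se_poisson(1000 * 10, 1), tolerance = 0.2)
  expect_error(empirical_se(cfg, n_reps = 10), "at least 50")
})

test_that("multi-city ensembles draw heterogeneous coefficients correctly", {
  tiny <- sim_config(n_days = 30, baseline_rate = 1, amplitude = 0,
                     noise_sd = 1)
  mc0 <- multicity_config(5, tau = 0, template = tiny, seed = 30)
  b0 <- attr(simulate_multicity(mc0), "beta_true")
  expect_equal(b0, rep(tiny$beta_true, 5))

  mc <- multicity_config(500, tau = 0.01, template = tiny, seed = 31)
  sims <- simulate_multicity(mc)
  b <- attr(sims, "beta_true")
  expect_equal(sd(b), 0.01, tolerance = 3 / sqrt(2 * 499))
  expect_equal(mean(b), tiny$beta_true, tolerance = 3 * 0.01 / sqrt(500) /
                 tiny$beta_true)
  # distinct sub-seeds: no two series share an exposure realisation
  expect_false(identical(sims[[1]]$exposure, sims[[2]]$exposure))
})

test_that("per-series overrides apply series by series", {
  tiny <- sim_config(n_days = 60, baseline_rate = 5, amplitude = 0)
  mc <- multicity_config(3, tau = 0, template = tiny,
                         overrides = list(baseline_rate = c(1, 5, 25)),
                         seed = 32)
  sims <- simulate_multicity(mc)
  totals <- vapply(sims, function(s) sum(s$counts), numeric(1))
  expect_true(all(diff(totals) > 0))
})

test_that("crude and adjusted approximators coincide without covariate coupling", {
  cfg <- sim_config(n_days = 1000, baseline_rate = 10, amplitude = 0,
                    noise_sd = 1, confounder_coupling = 0, seed = 33)
  rows <- validate_approximations(list(cfg), spline_df_per_year = 0,
                                  include_dow = FALSE)
  expect_true(all(is.na(rows$error)))
  crude <- rows$se_approx[rows$label == "poisson_crude"]
  pois <- rows$se_approx[rows$label == "poisson"]
  expect_equal(crude, pois)  # sd_raw == sd_usable under an intercept design
})

test_that("validation summaries report bias and spread per approximator", {
  cfgs <- list(sim_config(n_days = 1000, baseline_rate = 10, seed = 34),
               sim_config(n_days = 1500, baseline_rate = 5,
                          confounder_coupling = 0.3, seed = 35))
  rows <- validate_approximations(cfgs)
  expect_s3_class(rows, "validation_table")
  expect_equal(nrow(rows), 6)
  expect_equal(rows$pct_error,
               100 * (rows$se_approx - rows$se_true) / rows$se_true)
  s <- validation_summary(rows)
  expect_equal(s$label, c("poisson_crude", "poisson", "quasi_poisson"))
  expect_equal(s$n, rep(2, 3))
  expect_true(all(s$lowest <= s$mean & s$mean <= s$highest))
})

test_that("failed scenario fits are recorded, not fatal", {
  bad <- sim_config(n_days = 400, baseline_rate = 1e-6, seed = 36)
  ok <- sim_config(n_days = 1000, baseline_rate = 10, seed = 37)
  rows <- validate_approximations(list(bad, ok))
  expect_true(all(!is.na(rows$error[rows$scenario == 1])))
  expect_true(all(is.na(rows$error[rows$scenario == 2])))
  expect_equal(validation_summary(rows)$n, rep(1, 3))
})

test_that("heterogeneous multi-city validation shows the expected pattern", {
  # tau comparable to the per-series SE: ignoring heterogeneity (pooled
  # fixed-effects approximator) understates the random-effects reference,
  # while the full tau-based form lands close to it. The DL reference from
  # one J = 50 ensemble carries ~5% Monte-Carlo noise, so the accuracy
  # claim is checked on the mean over ensembles.
  template <- sim_config(n_days = 730, baseline_rate = 30, beta_true = 0.02,
                         amplitude = 0, noise_sd = 1)
  err_fe_fe <- i2 <- ref_re <- ap_fe <- ap_tau <- numeric(0)
  for (seed in c(38, 138, 238, 338, 438)) {
    mc <- multicity_config(50, tau = 0.007, template = template,
                           seed = seed)
    tab <- validate_multicity(mc)
    ref_re <- c(ref_re, attr(tab, "meta_re")$se_re)
    ap_fe <- c(ap_fe, tab$se_approx[tab$label == "fe_poisson"])
    ap_tau <- c(ap_tau, tab$se_approx[tab$label == "re_tau_full"])
    err_fe_fe <- c(err_fe_fe, tab$pct_error_fe[tab$label == "fe_poisson"])
    i2 <- c(i2, attr(tab, "meta_re")$i_squared)
    expect_gte(attr(tab, "meta_re")$se_re, attr(tab, "meta_fe")$se_fe)
  }
  # heterogeneity ignored: the pooled-events form understates the RE SE
  expect_lt(100 * (mean(ap_fe) - mean(ref_re)) / mean(ref_re), -20)
  expect_lt(mean(abs(err_fe_fe)), 15)  # but the FE SE itself is tracked
  # the tau-based form tracks the averaged RE reference closely
  expect_lt(100 * abs(mean(ap_tau) - mean(ref_re)) / mean(ref_re), 10)
  expect_gt(mean(i2), 0.3)
})
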