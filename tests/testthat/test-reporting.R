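# Planning reports, power-curve grids, CSV exposure profiling and the
# command-line front end. Reports must only repackage library calls.

london <- function(...) {
  plan_single(3888, 0.76, sd_raw = 0.97, beta_h1 = 0.06,
              target_power = 0.8, required_power = 0.9,
              events_per_year = 486, printed_z = TRUE, ...)
}

test_that("the single-series report reproduces the London PM2.5 planning numbers", {
  p <- london()
  expect_equal(round(p$se[["poisson"]], 3), 0.021)
  expect_equal(round(p$ci_width, 3), 0.082)
  expect_equal(round(100 * p$power), 82)
  expect_equal(round(p$smallest_detectable, 3), 0.059)
  expect_equal(round(p$required_events), 5048)
  expect_equal(round(p$years_required, 1), 10.4)
  out <- capture.output(print(p))
  expect_true(any(grepl("82%", out)))
  expect_true(any(grepl("5048", out)))
})

test_that("report numbers equal the underlying library calls bit-for-bit", {
  p <- london()
  expect_identical(p$se[["poisson"]], se_poisson(3888, 0.76))
  expect_identical(p$se[["poisson_crude"]], se_poisson_crude(3888, 0.97))
  expect_identical(p$vif, variance_inflation_ratio(0.97, 0.76))
  expect_identical(p$power, power_approx(0.06, 0.021, 0.05, TRUE))
  expect_identical(p$required_events,
                   required_events(0.06, 0.76, 0.05, 0.9, 1, TRUE))
})

test_that("optional report blocks appear only with their inputs", {
  p <- plan_single(3888, 0.76)
  expect_null(p$power)
  expect_null(p$required_events)
  expect_true(is.na(p$se[["poisson_crude"]]))
  expect_gt(p$ci_width, 0)
  expect_error(plan_single(3888, 0.9, sd_raw = 0.76), "cannot exceed")
})

test_that("dispersion inflates every reported SE by its square root", {
  p1 <- plan_single(5000, 0.8)
  p2 <- plan_single(5000, 0.8, dispersion = 1.2)
  expect_equal(p2$se[["quasi_poisson"]],
               sqrt(1.2) * p1$se[["quasi_poisson"]])
  expect_equal(p2$ci_width, sqrt(1.2) * p1$ci_width)
})

test_that("the ten-city report reproduces the pooled planning numbers", {
  m <- plan_multi(10, 9720, 0.76)
  expect_equal(round(m$se_fe, 3), 0.013)
  expect_equal(round(m$smallest_detectable, 3), 0.037)
  expect_equal(m$i2_sweep$se_re[m$i2_sweep$i_squared == 0], m$se_fe)
  expect_true(all(diff(m$i2_sweep$se_re) > 0))
})

test_that("heterogeneity inputs drive the random-effects block", {
  m <- plan_multi(10, 9720, 0.76, i_squared = 0.5)
  expect_equal(m$se_re[["i2"]], se_re_from_i2(m$se_fe, 0.5))
  mt <- plan_multi(10, 9720, 0.76, tau = 0.01, extreme_het = TRUE)
  expect_equal(mt$se_re[["tau_full"]],
               se_re_full(0.01, rep(se_poisson(972, 0.76), 10)))
  expect_equal(mt$se_re[["extreme_het"]], 0.01 / sqrt(10))
  expect_error(plan_multi(10, 9720, 0.76, random_effects = TRUE),
               "tau.*i_squared")
})

test_that("a single homogeneous series collapses to the single-series plan", {
  m <- plan_multi(1, 3888, 0.76, dispersion = 1.1)
  p <- plan_single(3888, 0.76, dispersion = 1.1)
  expect_identical(m$se_fe, p$se[["quasi_poisson"]])
  expect_identical(m$smallest_detectable, p$smallest_detectable)
})

test_that("power curves are monotone and ordered by dispersion", {
  pc <- power_curves(events = exp(seq(log(1000), log(1e6), length.out = 25)))
  expect_s3_class(pc, "power_curves")
  # ~80% power at 20,000 events for 2% per usable SD, no overdispersion
  p20 <- power_curves(events = 20000, coef_per_sd = 0.02, dispersion = 1)
  expect_equal(p20$power, 0.807, tolerance = 1e-3)
  expect_gte(p20$power, 0.80)
  for (cf in unique(pc$coef_per_sd)) {
    for (d in unique(pc$dispersion)) {
      cell <- pc[pc$coef_per_sd == cf & pc$dispersion == d, ]
      expect_true(all(diff(cell$power[order(cell$events)]) >= 0))
    }
  }
  lo <- pc[pc$dispersion == 1, ]
  hi <- pc[pc$dispersion == 1.5, ]
  expect_true(all(hi$power <= lo$power))
  expect_error(power_curves(events = numeric(0)), "empty grid")
})

test_that("power-curve cells equal the library calls bit-for-bit", {
  pc <- power_curves(events = c(5000, 20000), coef_per_sd = 0.02,
                     dispersion = c(1, 1.5))
  i <- which(pc$events == 20000 & pc$dispersion == 1.5)
  expect_identical(pc$se[i], se_quasipoisson(20000, 1, 1.5))
  expect_identical(pc$power[i],
                   power_approx(0.02, se_quasipoisson(20000, 1, 1.5)))
})

test_that("power curves render without error", {
  pdf(NULL)
  on.exit(dev.off())
  pc <- power_curves(events = c(1000, 10000, 1e5))
  expect_invisible(plot(pc))
})

test_that("CSV profiling recovers a known residual SD stage by stage", {
  path <- write_exposure_csv(n = 3653, sigma = 2, extra_covariate = TRUE)
  pr <- profile_exposure(path, exposure_col = "pm", extra_cols = "temp")
  expect_equal(pr$stages$stage, c("raw", "spline+dow", "+temp"))
  expect_equal(pr$stages$sd_usable[3], 2, tolerance = 0.02)
  expect_true(all(diff(pr$stages$sd_usable) <= 0))
  expect_gt(pr$stages$sd_usable[1], 7)  # seasonal amplitude dominates raw SD
  expect_equal(pr$final$sd_usable, pr$stages$sd_usable[3])
})

test_that("profiling without covariates reports the raw SD, scaled per increment", {
  path <- write_exposure_csv(n = 400, sigma = 1)
  pr <- profile_exposure(path, exposure_col = "pm", spline_df_per_year = 0,
                         include_dow = FALSE, per_increment = 10)
  expect_equal(nrow(pr$stages), 1)
  expect_equal(pr$stages$sd_per_increment, pr$stages$sd_usable / 10)
})

test_that("profiling reports missing rows and names bad columns", {
  path <- write_exposure_csv(n = 500, n_missing = 4)
  expect_message(pr <- profile_exposure(path, exposure_col = "pm"),
                 "4 incomplete")
  expect_equal(pr$n_dropped, 4)
  expect_error(profile_exposure(path, exposure_col = "no2"), "no2")
})

test_that("the command-line front end reports the library's numbers", {
  cli <- system.file("cli", "tspower.R", package = "tspower")
  expect_true(nzchar(cli))
  out <- system2("Rscript",
                 c(cli, "plan-single", "--events", "3888",
                   "--sd-usable", "0.76", "--beta", "0.06",
                   "--required-power", "0.9", "--events-per-year", "486",
                   "--printed-z"),
                 stdout = TRUE, stderr = TRUE,
                 env = paste0("R_LIBS=", paste(.libPaths(), collapse = ":")))
  expect_true(any(grepl("82%", out)))
  expect_true(any(grepl("5048", out)))
})
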