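# Synthetic (quasi-)Poisson daily series with known parameters, first-stage
# quasi-Poisson fits, and tabulation of percent error of the closed-form SE
# approximators against fitted or Monte-Carlo reference SEs.

#' Configuration for one synthetic count series
#'
#' Describes a log-linear count process
#' \eqn{E(Y_i) = \exp(\alpha + \beta x_i + \gamma s_i)} observed daily:
#' a seasonal-plus-noise exposure \eqn{x_i = A\cos(2\pi t_i/365.25 + phase)
#' + \epsilon_i}, an outcome seasonality term \eqn{s_i} (an annual cosine a
#' fitted time spline absorbs), and counts that are Poisson at
#' `dispersion = 1` or negative binomial parameterised so the variance is
#' `dispersion` times the mean. The closed-form expectations of the exposure
#' moments are \eqn{SD(x)^2 = A^2/2 + \sigma^2} and, once the seasonal
#' component is absorbed by covariates, \eqn{SD(x|z) \to \sigma}.
#'
#' @param n_days Series length in days (>= 30).
#' @param baseline_rate Expected events/day at zero exposure and mid-season
#'   (the \eqn{\exp(\alpha)} scale); positive.
#' @param beta_true True exposure coefficient, log-RR per exposure unit.
#' @param dispersion Target overdispersion \eqn{\phi \ge 1}.
#' @param amplitude,noise_sd,phase Seasonal amplitude, white-noise SD and
#'   phase of the exposure process.
#' @param confounder_coupling Coefficient \eqn{\gamma} on the outcome's
#'   annual cosine; nonzero values make exposure and outcome share
#'   seasonality, so covariate adjustment is needed and \eqn{R^2_{x|z} > 0}.
#' @param confounder_phase Phase of the outcome seasonality term.
#' @param start_date First calendar date of the series.
#' @param seed Integer seed; the exposure stream uses `seed`, the count
#'   stream `seed + 1`, so derived configurations should step seeds by 2.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_days = 3650, baseline_rate = 20, beta_true = 0.02,
                       dispersion = 1, amplitude = 1.5, noise_sd = 1,
                       phase = 0, confounder_coupling = 0,
                       confounder_phase = 0.3,
                       start_date = as.Date("2010-01-01"), seed = 1L) {
  if (!is.numeric(n_days) || n_days < 30) {
    stop("`n_days` must be at least 30", call. = FALSE)
  }
  .check_pos(baseline_rate, "baseline_rate")
  if (!is.numeric(dispersion) || dispersion < 1) {
    stop("`dispersion` must be >= 1 for simulation", call. = FALSE)
  }
  if (noise_sd < 0 || amplitude < 0) {
    stop("`noise_sd` and `amplitude` must be nonnegative", call. = FALSE)
  }
  structure(
    list(n_days = as.integer(n_days), baseline_rate = baseline_rate,
         beta_true = beta_true, dispersion = dispersion,
         amplitude = amplitude, noise_sd = noise_sd, phase = phase,
         confounder_coupling = confounder_coupling,
         confounder_phase = confounder_phase,
         start_date = as.Date(start_date), seed = as.integer(seed)),
    class = "sim_config"
  )
}

.sim_dates <- function(config) {
  seq(config$start_date, by = "day", length.out = config$n_days)
}

#' Simulate a seasonal exposure series
#'
#' Annual cosine plus Gaussian white noise, deterministic given
#' `config$seed`.
#'
#' @param config A [sim_config()].
#' @return Numeric vector of length `config$n_days`.
#' @export
simulate_exposure <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  day <- seq_len(config$n_days) - 1
  config$amplitude * cos(2 * pi * day / 365.25 + config$phase) +
    stats::rnorm(config$n_days, 0, config$noise_sd)
}

#' Simulate counts from a log-linear process with given exposure
#'
#' Forms \eqn{\mu_i = \exp(\log(rate) + \beta x_i + \gamma s_i)} with
#' \eqn{s_i} the outcome's annual cosine, then draws Poisson counts at
#' `dispersion = 1` or negative binomial counts with per-observation size
#' \eqn{\mu_i/(\phi - 1)} so that \eqn{Var(Y_i) = \phi\mu_i} exactly.
#' Deterministic given `config$seed` (count stream `seed + 1`).
#'
#' @param exposure Numeric exposure vector.
#' @param dates Dates aligned with `exposure`.
#' @param config A [sim_config()]; `beta_true`, `baseline_rate`,
#'   `dispersion`, `confounder_coupling` and `seed` are used.
#' @return An object of class `simulated_series`: `dates`, `exposure`,
#'   `counts`, and `truth` (the generating parameters).
#' @export
simulate_counts <- function(exposure, dates, config) {
  stopifnot(inherits(config, "sim_config"))
  dates <- .check_dates(dates)
  if (length(exposure) != length(dates)) {
    stop("`exposure` and `dates` lengths differ", call. = FALSE)
  }
  day <- as.numeric(dates - dates[1])
  s <- cos(2 * pi * day / 365.25 + config$confounder_phase)
  eta <- log(config$baseline_rate) + config$beta_true * exposure +
    config$confounder_coupling * s
  if (max(eta) > 30) {
    stop("linear predictor overflow (max eta = ", round(max(eta), 1),
         "); reduce baseline_rate, beta_true or the exposure scale",
         call. = FALSE)
  }
  mu <- exp(eta)
  set.seed(config$seed + 1L)
  counts <- if (config$dispersion == 1) {
    stats::rpois(length(mu), mu)
  } else {
    stats::rnbinom(length(mu), size = mu / (config$dispersion - 1), mu = mu)
  }
  structure(
    list(dates = dates, exposure = exposure, counts = counts,
         truth = config[c("beta_true", "dispersion", "baseline_rate")]),
    class = "simulated_series"
  )
}

#' Simulate a complete synthetic series from a configuration
#'
#' Convenience wrapper: dates from `start_date`, exposure from
#' [simulate_exposure()], counts from [simulate_counts()].
#'
#' @inheritParams simulate_exposure
#' @return A `simulated_series`.
#' @export
simulate_series <- function(config) {
  simulate_counts(simulate_exposure(config), .sim_dates(config), config)
}

#' @export
print.simulated_series <- function(x, ...) {
  cat("Simulated count series:", length(x$counts), "days,",
      sum(x$counts), "events (beta =", x$truth$beta_true,
      ", dispersion =", x$truth$dispersion, ")\n")
  invisible(x)
}

#' Export a simulated series as a data frame (date, exposure, count)
#'
#' @param x A `simulated_series`.
#' @param ... Unused.
#' @return A data.frame suitable for `write.csv`.
#' @export
as.data.frame.simulated_series <- function(x, ...) {
  data.frame(date = x$dates, exposure = x$exposure, count = x$counts)
}

#' Fit a quasi-Poisson regression to a count series
#'
#' First-stage analysis: log-link count regression of counts on exposure,
#' a natural cubic time spline and day-of-week indicators, with standard
#' errors scaled by the Pearson dispersion estimate
#' \eqn{\hat\phi = \sum r_i^2 / (n - p)} (i.e. `stats::glm` with
#' `family = quasipoisson`).
#'
#' @param series A `simulated_series`, or any list with `dates`, `exposure`,
#'   `counts`.
#' @param spline_df_per_year Time spline df per year (0 for none).
#' @param include_dow Include day-of-week indicators?
#' @return A list of class `series_fit`: `beta_hat`, `se` (Pearson-scaled),
#'   `dispersion_hat`, `total_events`, `n`, `df_residual`.
#' @export
fit_series <- function(series, spline_df_per_year = 7, include_dow = TRUE) {
  y <- series$counts
  x <- series$exposure
  dates <- .check_dates(series$dates)
  if (sum(y) < 1) stop("series has no events to fit", call. = FALSE)
  if (stats::sd(x) == 0) {
    stop("degenerate design: exposure has no variation", call. = FALSE)
  }
  Z <- cbind(.spline_cols(dates, spline_df_per_year),
             if (include_dow) dow_indicators(dates))
  fit <- if (is.null(Z)) {
    stats::glm(y ~ x, family = stats::quasipoisson())
  } else {
    stats::glm(y ~ x + Z, family = stats::quasipoisson())
  }
  if (!fit$converged) {
    stop("IWLS did not converge in ", fit$iter, " iterations", call. = FALSE)
  }
  if (anyNA(stats::coef(fit))) {
    stop("rank-deficient design: aliased coefficient(s) ",
         paste(names(stats::coef(fit))[is.na(stats::coef(fit))],
               collapse = ", "), call. = FALSE)
  }
  sm <- summary(fit)
  structure(
    list(beta_hat = unname(stats::coef(fit)["x"]),
         se = unname(sm$coefficients["x", "Std. Error"]),
         dispersion_hat = sm$dispersion,
         total_events = sum(y), n = length(y),
         df_residual = fit$df.residual),
    class = "series_fit"
  )
}

#' @export
print.series_fit <- function(x, digits = 4, ...) {
  cat("Quasi-Poisson fit:", x$n, "days,", x$total_events, "events\n")
  cat("  beta_hat:", format(x$beta_hat, digits = digits),
      " SE:", format(x$se, digits = digits),
      " dispersion:", format(x$dispersion_hat, digits = digits), "\n")
  invisible(x)
}

#' Monte-Carlo standard error of the fitted exposure coefficient
#'
#' Simulates `n_reps` independent series from `config` (replicate r uses
#' seed `config$seed + 2r`), fits each with [fit_series()], and returns the
#' SD of the fitted coefficients — an empirical reference against which the
#' closed-form approximators can be judged. Replicates whose fit fails are
#' excluded and counted; more than 10% failures is an error.
#'
#' @inheritParams simulate_exposure
#' @param n_reps Number of replicates (>= 50).
#' @param spline_df_per_year,include_dow Passed to [fit_series()].
#' @return The empirical SE, with attributes `n_ok` and `n_fail`.
#' @export
empirical_se <- function(config, n_reps = 200, spline_df_per_year = 7,
                         include_dow = TRUE) {
  stopifnot(inherits(config, "sim_config"))
  if (n_reps < 50) stop("`n_reps` must be at least 50", call. = FALSE)
  betas <- rep(NA_real_, n_reps)
  for (r in seq_len(n_reps)) {
    cfg <- config
    cfg$seed <- config$seed + 2L * r
    betas[r] <- tryCatch(
      fit_series(simulate_series(cfg), spline_df_per_year, include_dow)$beta_hat,
      error = function(e) NA_real_
    )
  }
  n_fail <- sum(is.na(betas))
  if (n_fail > 0.1 * n_reps) {
    stop(n_fail, " of ", n_reps, " replicate fits failed", call. = FALSE)
  }
  structure(stats::sd(betas, na.rm = TRUE), n_ok = n_reps - n_fail,
            n_fail = n_fail)
}

#' Configuration for a multi-city ensemble
#'
#' @param n_series Number of series J (>= 2 when `tau > 0`).
#' @param tau Between-series SD of true coefficients (log-RR scale).
#' @param template A [sim_config()] shared by all series; `beta_true` in the
#'   template is the mean coefficient around which series-specific
#'   coefficients are drawn.
#' @param overrides Optional named list of per-series value vectors (e.g.
#'   `list(baseline_rate = c(...))`, length `n_series`) overriding template
#'   fields series by series.
#' @param seed Master seed; series j simulates with seed
#'   `seed + 1000 + 2j`, the coefficient draws with `seed`.
#' @return A list of class `multicity_config`.
#' @export
multicity_config <- function(n_series, tau = 0, template = sim_config(),
                             overrides = NULL, seed = 1L) {
  stopifnot(inherits(template, "sim_config"))
  if (n_series < 1 || (tau > 0 && n_series < 2)) {
    stop("`n_series` must be >= 2 when tau > 0", call. = FALSE)
  }
  if (tau < 0) stop("`tau` must be nonnegative", call. = FALSE)
  if (!is.null(overrides)) {
    stopifnot(all(names(overrides) %in% names(template)),
              all(lengths(overrides) == n_series))
  }
  structure(
    list(n_series = as.integer(n_series), tau = tau, template = template,
         overrides = overrides, seed = as.integer(seed)),
    class = "multicity_config"
  )
}

#' Simulate a multi-city ensemble with heterogeneous true coefficients
#'
#' Draws series-specific true coefficients
#' \eqn{\beta_j \sim N(\beta_{mean}, \tau^2)} then simulates each series
#' independently with its own sub-seed.
#'
#' @param config A [multicity_config()].
#' @return A list of `simulated_series`, with the drawn coefficients in
#'   attribute `beta_true`.
#' @export
simulate_multicity <- function(config) {
  stopifnot(inherits(config, "multicity_config"))
  set.seed(config$seed)
  beta_j <- stats::rnorm(config$n_series, config$template$beta_true,
                         config$tau)
  out <- vector("list", config$n_series)
  for (j in seq_len(config$n_series)) {
    cfg <- config$template
    cfg$beta_true <- beta_j[j]
    cfg$seed <- config$seed + 1000L + 2L * j
    for (nm in names(config$overrides)) cfg[[nm]] <- config$overrides[[nm]][j]
    out[[j]] <- simulate_series(cfg)
  }
  attr(out, "beta_true") <- beta_j
  out
}

#' Default single-series validation scenario grid
#'
#' Twenty Poisson scenarios spanning series length (1000 and 3650 days, plus
#' intermediate lengths), event rate (5-50/day), exposure-confounder
#' coupling (none to moderate) and exposure shape (seasonal and pure-noise),
#' each with a fixed scenario-indexed seed derived from `seed`.
#'
#' @param seed Master seed; scenario s uses `seed + 100 * s`.
#' @return A list of 20 [sim_config()] objects.
#' @export
default_validation_grid <- function(seed = 1L) {
  g1 <- expand.grid(n_days = c(1000L, 3650L), rate = c(5, 20, 50),
                    coupling = c(0, 0.3), amplitude = 1.5)
  g2 <- expand.grid(n_days = c(1825L, 2920L), rate = c(10, 30),
                    coupling = 0.15, amplitude = 1.5)
  g3 <- expand.grid(n_days = c(1000L, 3650L), rate = c(10, 40),
                    coupling = 0, amplitude = 0)
  g <- rbind(g1, g2, g3)
  lapply(seq_len(nrow(g)), function(s) {
    sim_config(n_days = g$n_days[s], baseline_rate = g$rate[s],
               beta_true = 0.02, dispersion = 1, amplitude = g$amplitude[s],
               noise_sd = 1, confounder_coupling = g$coupling[s],
               seed = seed + 100L * s)
  })
}

#' Percent error of the single-series SE approximators over scenarios
#'
#' For each scenario: simulates one series, fits the quasi-Poisson
#' regression, profiles the realised exposure with [usable_sd()] under the
#' same covariate design, and compares the closed-form approximations
#' (crude-Poisson, Poisson, quasi-Poisson with the Pearson
#' \eqn{\hat\phi}) against the Pearson-scaled fitted SE as the reference.
#' Percent error is `100 * (approx - reference) / reference`.
#'
#' @param scenarios A list of [sim_config()] objects, e.g.
#'   [default_validation_grid()].
#' @param spline_df_per_year,include_dow Analysis design, passed to both the
#'   fit and the exposure profile.
#' @return A data.frame of class `validation_table`: `scenario`, `label`
#'   (`poisson_crude`, `poisson`, `quasi_poisson`), `se_true`, `se_approx`,
#'   `pct_error`, `error` (a message for scenarios whose fit failed, else
#'   `NA`).
#' @seealso [validation_summary()]
#' @export
validate_approximations <- function(scenarios, spline_df_per_year = 7,
                                    include_dow = TRUE) {
  stopifnot(length(scenarios) > 0)
  rows <- lapply(seq_along(scenarios), function(s) {
    cfg <- scenarios[[s]]
    labs <- c("poisson_crude", "poisson", "quasi_poisson")
    res <- tryCatch({
      ser <- simulate_series(cfg)
      fit <- fit_series(ser, spline_df_per_year, include_dow)
      ev <- usable_sd(ser$dates, ser$exposure, spline_df_per_year,
                      include_dow)
      n_ev <- fit$total_events
      # an estimated Pearson dispersion slightly below 1 is routine here;
      # the planning-input warning would only be noise
      appr <- c(se_poisson_crude(n_ev, ev$sd_raw),
                se_poisson(n_ev, ev$sd_usable),
                suppressWarnings(
                  se_quasipoisson(n_ev, ev$sd_usable, fit$dispersion_hat)))
      data.frame(scenario = s, label = labs, se_true = fit$se,
                 se_approx = appr,
                 pct_error = 100 * (appr - fit$se) / fit$se,
                 error = NA_character_)
    }, error = function(e) {
      data.frame(scenario = s, label = labs, se_true = NA_real_,
                 se_approx = NA_real_, pct_error = NA_real_,
                 error = conditionMessage(e))
    })
    res
  })
  out <- do.call(rbind, rows)
  class(out) <- c("validation_table", "data.frame")
  out
}

#' Summarise approximator percent errors across scenarios
#'
#' Mean (bias), mean absolute, minimum and maximum percent error per
#' approximator, over scenarios with successful fits.
#'
#' @param rows A `validation_table` from [validate_approximations()].
#' @return A data.frame with one row per approximator label.
#' @export
validation_summary <- function(rows) {
  ok <- rows[is.na(rows$error), , drop = FALSE]
  if (nrow(ok) == 0) stop("no successful scenarios to summarise",
                          call. = FALSE)
  agg <- lapply(split(ok, ok$label), function(d) {
    data.frame(label = d$label[1], n = nrow(d),
               mean = mean(d$pct_error),
               mean_abs = mean(abs(d$pct_error)),
               lowest = min(d$pct_error), highest = max(d$pct_error))
  })
  out <- do.call(rbind, agg)
  rownames(out) <- NULL
  out[order(match(out$label, c("poisson_crude", "poisson",
                               "quasi_poisson"))), ]
}

#' Percent error of the multi-series SE approximators against meta-analysis
#'
#' Simulates a heterogeneous multi-city ensemble, fits each series, pools
#' the estimates by fixed-effects and DerSimonian-Laird random-effects
#' meta-analysis, and tabulates the approximators: pooled-events
#' fixed-effects (with and without the average Pearson dispersion), the full
#' tau-based random-effects form (using the generating tau), the
#' I-squared-corrected form (using the meta-analytic I-squared), and the
#' extreme-heterogeneity form. Percent errors are reported against both the
#' fitted fixed-effects SE and the fitted random-effects SE.
#'
#' @param config A [multicity_config()].
#' @param spline_df_per_year,include_dow Analysis design per series.
#' @return A data.frame with `label`, `se_approx`, `pct_error_fe`,
#'   `pct_error_re`, plus the fitted references in attributes `meta_fe` and
#'   `meta_re`.
#' @export
validate_multicity <- function(config, spline_df_per_year = 7,
                               include_dow = TRUE) {
  stopifnot(inherits(config, "multicity_config"))
  series <- simulate_multicity(config)
  fits <- lapply(series, fit_series, spline_df_per_year = spline_df_per_year,
                 include_dow = include_dow)
  beta <- vapply(fits, `[[`, numeric(1), "beta_hat")
  se <- vapply(fits, `[[`, numeric(1), "se")
  fe <- meta_fixed(beta, se)
  re <- meta_random(beta, se)

  total <- sum(vapply(fits, `[[`, numeric(1), "total_events"))
  phi <- mean(vapply(fits, `[[`, numeric(1), "dispersion_hat"))
  sd_us <- mean(vapply(series, function(s)
    usable_sd(s$dates, s$exposure, spline_df_per_year,
              include_dow)$sd_usable, numeric(1)))
  se_j <- vapply(vapply(fits, `[[`, numeric(1), "total_events"),
                 se_poisson, numeric(1), sd_usable = sd_us)

  appr <- c(fe_poisson = se_fe(total, sd_us, 1),
            fe_quasipoisson = suppressWarnings(se_fe(total, sd_us, phi)),
            re_tau_full = se_re_full(config$tau, se_j),
            re_i2 = se_re_from_i2(se_fe(total, sd_us, 1), re$i_squared),
            re_extreme_het = if (config$tau > 0)
              se_extreme_het(config$tau, config$n_series) else NA_real_)
  out <- data.frame(label = names(appr), se_approx = unname(appr),
                    pct_error_fe = 100 * (unname(appr) - fe$se_fe) / fe$se_fe,
                    pct_error_re = 100 * (unname(appr) - re$se_re) / re$se_re)
  attr(out, "meta_fe") <- fe
  attr(out, "meta_re") <- re
  out
}
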