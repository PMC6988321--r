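# Planning reports assembling the closed-form approximators into the
# summaries a study designer needs, power-curve grids, and exposure
# profiling from CSV. Every number in a report is produced by the
# corresponding exported function; the reporting layer only formats.

#' Single-series planning report
#'
#' Assembles the precision and power summary for a planned single-series
#' study: SE approximations (crude, Poisson, quasi-Poisson), CI width,
#' power at a hypothesised coefficient, smallest detectable coefficient,
#' and required events/years.
#'
#' With `printed_z = TRUE` the report reproduces hand arithmetic: normal
#' quantiles rounded to 2 decimals and the working SE rounded to 3 decimals
#' before the downstream quantities (so power at SE 0.021 rather than
#' 0.021104). Default is full precision throughout.
#'
#' @param total_events Expected total events over the study.
#' @param sd_usable Usable exposure SD, in the exposure increment the
#'   coefficient refers to (e.g. 0.76 per 10 ug/m3 when the daily SD is
#'   7.6 ug/m3).
#' @param sd_raw Optional raw exposure SD (same units) for the crude SE and
#'   variance inflation ratio.
#' @param dispersion Overdispersion factor; 1 for pure Poisson.
#' @param alpha Two-sided significance level.
#' @param beta_h1 Optional hypothesised coefficient (log-RR per increment);
#'   enables the power and required-events blocks.
#' @param target_power Power used for the smallest detectable coefficient.
#' @param required_power Power used for the required-events block.
#' @param events_per_year Optional accrual rate, to convert required events
#'   into years of series.
#' @param printed_z Paper-arithmetic mode (see Details).
#' @return A list of class `plan_single` with elements `inputs`, `se`
#'   (named: `poisson_crude`, `poisson`, `quasi_poisson`), `vif`,
#'   `ci_width`, `power`, `smallest_detectable`, `required_events`,
#'   `years_required` (the last four `NULL` when not computable).
#' @examples
#' plan_single(3888, 0.76, sd_raw = 0.97, beta_h1 = 0.06,
#'             required_power = 0.9, events_per_year = 486,
#'             printed_z = TRUE)
#' @export
plan_single <- function(total_events, sd_usable, sd_raw = NULL,
                        dispersion = 1, alpha = 0.05, beta_h1 = NULL,
                        target_power = 0.8, required_power = 0.9,
                        events_per_year = NULL, printed_z = FALSE) {
  if (!is.null(sd_raw) && sd_usable > sd_raw) {
    stop("`sd_usable` cannot exceed `sd_raw`", call. = FALSE)
  }
  se_p <- se_poisson(total_events, sd_usable)
  se_qp <- se_quasipoisson(total_events, sd_usable, dispersion)
  se_work <- if (printed_z) round(se_qp, 3) else se_qp

  out <- list(
    inputs = list(total_events = total_events, sd_usable = sd_usable,
                  sd_raw = sd_raw, dispersion = dispersion, alpha = alpha,
                  beta_h1 = beta_h1, target_power = target_power,
                  required_power = required_power,
                  events_per_year = events_per_year,
                  printed_z = printed_z),
    se = c(poisson_crude = if (!is.null(sd_raw))
             se_poisson_crude(total_events, sd_raw) else NA_real_,
           poisson = se_p, quasi_poisson = se_qp),
    vif = if (!is.null(sd_raw)) variance_inflation_ratio(sd_raw, sd_usable),
    ci_width = ci_width(se_work, alpha, printed_z),
    power = if (!is.null(beta_h1))
      power_approx(beta_h1, se_work, alpha, printed_z),
    smallest_detectable = smallest_detectable(se_work, alpha, target_power,
                                              printed_z),
    required_events = if (!is.null(beta_h1))
      required_events(beta_h1, sd_usable, alpha, required_power, dispersion,
                      printed_z)
  )
  out$years_required <- if (!is.null(out$required_events) &&
                            !is.null(events_per_year))
    years_required(out$required_events, events_per_year)
  class(out) <- "plan_single"
  out
}

#' @export
print.plan_single <- function(x, full_precision = FALSE, ...) {
  f3 <- function(v) if (full_precision) format(v) else sprintf("%.3f", v)
  inp <- x$inputs
  cat("Single-series planning report\n")
  cat("  total events:", inp$total_events, " usable SD:", inp$sd_usable,
      " dispersion:", inp$dispersion, " alpha:", inp$alpha,
      if (inp$printed_z) " [printed-z arithmetic]", "\n")
  if (!is.na(x$se["poisson_crude"])) {
    cat("  SE (crude Poisson, raw SD):", f3(x$se[["poisson_crude"]]), "\n")
  }
  cat("  SE (Poisson, usable SD):   ", f3(x$se[["poisson"]]), "\n")
  cat("  SE (quasi-Poisson):        ", f3(x$se[["quasi_poisson"]]), "\n")
  if (!is.null(x$vif)) {
    cat("  variance inflation ratio:  ", f3(x$vif), "\n")
  }
  cat("  ", 100 * (1 - inp$alpha), "% CI width: ", f3(x$ci_width), "\n",
      sep = "")
  if (!is.null(x$power)) {
    cat("  power at beta =", inp$beta_h1, ":",
        if (full_precision) format(x$power)
        else paste0(round(100 * x$power), "%"), "\n")
  }
  cat("  smallest detectable beta (power ", 100 * inp$target_power, "%): ",
      f3(x$smallest_detectable), "\n", sep = "")
  if (!is.null(x$required_events)) {
    cat("  required events (power ", 100 * inp$required_power, "%): ",
        if (full_precision) format(x$required_events)
        else round(x$required_events), "\n", sep = "")
    if (!is.null(x$years_required)) {
      cat("  years at ", inp$events_per_year, "/yr: ",
          if (full_precision) format(x$years_required)
          else sprintf("%.1f", x$years_required), "\n", sep = "")
    }
  }
  invisible(x)
}

#' Multi-series (multi-city) planning report
#'
#' Fixed-effects pooled SE from the pooled event count, random-effects SE
#' under a stated heterogeneity (the full tau-based form when `tau` and
#' per-series SEs are available, the I-squared-corrected form when
#' `i_squared` is given, and the extreme-heterogeneity form on request),
#' the smallest detectable coefficient from the (unrounded) pooled SE, and
#' an I-squared sensitivity sweep.
#'
#' @param n_series Number of series J.
#' @param total_events Events pooled over all series.
#' @inheritParams plan_single
#' @param tau Optional heterogeneity SD (log-RR scale).
#' @param i_squared Optional heterogeneity fraction in \[0, 1).
#' @param per_series_se Optional vector of predicted per-series SEs (length
#'   `n_series`) for the full tau-based form; defaults to equal split of
#'   the pooled events when `tau` is given without it.
#' @param random_effects Request a random-effects SE; requires `tau` or
#'   `i_squared`.
#' @param extreme_het Also report the tau/sqrt(J) extreme-heterogeneity SE
#'   (needs `tau`).
#' @param i2_sweep I-squared values for the sensitivity table.
#' @return A list of class `plan_multi`: `inputs`, `se_fe`, `se_re` (named
#'   by method, possibly empty), `smallest_detectable`, `power`,
#'   `i2_sweep` (data.frame).
#' @examples
#' plan_multi(10, 9720, 0.76)
#' plan_multi(10, 9720, 0.76, i_squared = 0.5)
#' @export
plan_multi <- function(n_series, total_events, sd_usable, dispersion = 1,
                       alpha = 0.05, tau = NULL, i_squared = NULL,
                       per_series_se = NULL,
                       random_effects = !is.null(tau) || !is.null(i_squared),
                       extreme_het = FALSE, beta_h1 = NULL,
                       target_power = 0.8, printed_z = FALSE,
                       i2_sweep = c(0, 0.1, 0.25, 0.5, 0.75)) {
  if (n_series < 1) stop("`n_series` must be >= 1", call. = FALSE)
  sefe <- se_fe(total_events, sd_usable, dispersion)
  if (random_effects && is.null(tau) && is.null(i_squared)) {
    stop("a random-effects SE needs `tau` or `i_squared`", call. = FALSE)
  }
  sere <- c()
  if (random_effects && !is.null(tau)) {
    if (is.null(per_series_se)) {
      per_series_se <- rep(se_quasipoisson(total_events / n_series,
                                           sd_usable, dispersion), n_series)
    }
    sere["tau_full"] <- se_re_full(tau, per_series_se)
  }
  if (random_effects && !is.null(i_squared)) {
    sere["i2"] <- se_re_from_i2(sefe, i_squared)
  }
  if (extreme_het) {
    if (is.null(tau)) stop("extreme-heterogeneity SE needs `tau`",
                           call. = FALSE)
    sere["extreme_het"] <- se_extreme_het(tau, n_series)
  }
  out <- list(
    inputs = list(n_series = n_series, total_events = total_events,
                  sd_usable = sd_usable, dispersion = dispersion,
                  alpha = alpha, tau = tau, i_squared = i_squared,
                  beta_h1 = beta_h1, target_power = target_power,
                  printed_z = printed_z),
    se_fe = sefe,
    se_re = sere,
    smallest_detectable = smallest_detectable(sefe, alpha, target_power,
                                              printed_z),
    power = if (!is.null(beta_h1))
      power_approx(beta_h1, sefe, alpha, printed_z),
    i2_sweep = data.frame(
      i_squared = i2_sweep,
      se_re = vapply(i2_sweep, se_re_from_i2, numeric(1), se_fe = sefe))
  )
  class(out) <- "plan_multi"
  out
}

#' @export
print.plan_multi <- function(x, full_precision = FALSE, ...) {
  f3 <- function(v) if (full_precision) format(v) else sprintf("%.3f", v)
  inp <- x$inputs
  cat("Multi-series planning report (J =", inp$n_series, ")\n")
  cat("  pooled events:", inp$total_events, " usable SD:", inp$sd_usable,
      " dispersion:", inp$dispersion, "\n")
  cat("  SE (fixed effects):", f3(x$se_fe), "\n")
  for (nm in names(x$se_re)) {
    cat("  SE (random effects, ", nm, "): ", f3(x$se_re[[nm]]), "\n",
        sep = "")
  }
  cat("  smallest detectable beta (power ", 100 * inp$target_power, "%): ",
      f3(x$smallest_detectable), "\n", sep = "")
  if (!is.null(x$power)) {
    cat("  power at beta =", inp$beta_h1, ":",
        if (full_precision) format(x$power)
        else paste0(round(100 * x$power), "%"), "\n")
  }
  cat("  I^2 sensitivity sweep:\n")
  sw <- x$i2_sweep
  for (i in seq_len(nrow(sw))) {
    cat(sprintf("    I^2 = %-5s SE_RE = %s\n", sw$i_squared[i],
                f3(sw$se_re[i])))
  }
  invisible(x)
}

#' Power-curve grid: power against total events
#'
#' Tabulates approximate power as a function of the total event count for a
#' grid of coefficient sizes (expressed per one unit of usable exposure SD,
#' so the usable SD is set to 1) and overdispersion values, using the
#' quasi-Poisson SE approximation inside the normal power formula. The
#' default grid uses coefficients of 5, 2, 1 and 0.5% per usable SD and
#' dispersions 1.0, 1.2, 1.5.
#'
#' @param events Vector of total event counts (default a log-spaced grid
#'   from 100 to 2,000,000).
#' @param coef_per_sd Coefficient sizes, log-RR per usable exposure SD.
#' @param dispersion Overdispersion values.
#' @param alpha Two-sided significance level.
#' @return A data.frame of class `power_curves` with columns `events`,
#'   `coef_per_sd`, `dispersion`, `se`, `power`; plot with [plot.power_curves()].
#' @examples
#' pc <- power_curves(events = c(5000, 20000, 80000))
#' subset(pc, coef_per_sd == 0.02 & dispersion == 1)
#' @export
power_curves <- function(events = exp(seq(log(100), log(2e6),
                                          length.out = 121)),
                         coef_per_sd = c(0.05, 0.02, 0.01, 0.005),
                         dispersion = c(1, 1.2, 1.5), alpha = 0.05) {
  if (length(events) == 0 || length(coef_per_sd) == 0 ||
      length(dispersion) == 0) {
    stop("empty grid", call. = FALSE)
  }
  g <- expand.grid(events = events, coef_per_sd = coef_per_sd,
                   dispersion = dispersion)
  g$se <- se_quasipoisson(g$events, 1, g$dispersion)
  g$power <- power_approx(g$coef_per_sd, g$se, alpha)
  class(g) <- c("power_curves", "data.frame")
  attr(g, "alpha") <- alpha
  g
}

#' Plot power curves
#'
#' One curve per (coefficient, dispersion) combination, events on a log
#' axis; colour distinguishes coefficient size, line type dispersion.
#'
#' @param x A `power_curves` data.frame.
#' @param ... Passed to `matplot`-style `plot`.
#' @return `x`, invisibly.
#' @export
plot.power_curves <- function(x, ...) {
  coefs <- sort(unique(x$coef_per_sd), decreasing = TRUE)
  disps <- sort(unique(x$dispersion))
  cols <- grDevices::hcl.colors(max(length(coefs), 2), "Dark 3")
  graphics::plot(range(x$events), c(0, 1), type = "n", log = "x",
                 xlab = "Total events", ylab = "Power", ...)
  graphics::abline(h = 0.8, col = "grey", lty = 3)
  for (i in seq_along(coefs)) {
    for (k in seq_along(disps)) {
      d <- x[x$coef_per_sd == coefs[i] & x$dispersion == disps[k], ]
      d <- d[order(d$events), ]
      graphics::lines(d$events, d$power, col = cols[i], lty = k)
    }
  }
  graphics::legend("bottomright",
                   legend = c(paste0(100 * coefs, "% per SD(x|z)"),
                              paste("dispersion", disps)),
                   col = c(cols[seq_along(coefs)],
                           rep("grey30", length(disps))),
                   lty = c(rep(1, length(coefs)), seq_along(disps)),
                   cex = 0.8, bty = "n")
  invisible(x)
}

#' Profile an exposure CSV: usable SD under incremental covariate blocks
#'
#' Reads a daily exposure series from a delimited file (ISO-8601 dates) and
#' reports the raw SD and the residual SD after each incremental covariate
#' block — none, seasonal spline + day-of-week, then each extra covariate
#' column in turn — mirroring the stepwise way usable variation is assessed
#' when planning (e.g. raw 9.7, spline+dow 8.5, +temperature 8.1,
#' +ozone 7.6 for London PM2.5).
#'
#' @param file Path to a CSV file.
#' @param date_col,exposure_col Column names for the date and exposure.
#' @param spline_df_per_year,include_dow Analysis design for the adjusted
#'   stages.
#' @param extra_cols Character vector of additional covariate columns, added
#'   cumulatively one at a time (linear terms).
#' @param per_increment Exposure increment the planning coefficient refers
#'   to (e.g. 10 for "per 10 ug/m3"); SDs are also reported divided by it.
#' @param sep Field separator.
#' @return A list of class `exposure_profile`: `stages` (data.frame with
#'   `stage`, `sd_usable`, `sd_per_increment`, `r2`), `final` (the full
#'   [usable_sd()] result), `n_dropped`.
#' @export
profile_exposure <- function(file, date_col = "date",
                             exposure_col = "exposure",
                             spline_df_per_year = 7, include_dow = TRUE,
                             extra_cols = NULL, per_increment = 1,
                             sep = ",") {
  d <- utils::read.table(file, header = TRUE, sep = sep,
                         stringsAsFactors = FALSE)
  for (col in c(date_col, exposure_col, extra_cols)) {
    if (!col %in% names(d)) {
      stop("column `", col, "` not found in ", file, call. = FALSE)
    }
  }
  dates <- as.Date(d[[date_col]])
  if (anyNA(dates)) {
    stop("column `", date_col, "` contains unparseable dates (expected ",
         "ISO-8601)", call. = FALSE)
  }
  x <- d[[exposure_col]]

  stage_fit <- function(label, df, dow, extra) {
    ev <- usable_sd(dates, x, df, dow, extra)
    data.frame(stage = label, sd_usable = ev$sd_usable,
               sd_per_increment = ev$sd_usable / per_increment, r2 = ev$r2)
  }
  stages <- stage_fit("raw", 0, FALSE, NULL)
  stages$stage <- "raw"
  if (spline_df_per_year > 0 || include_dow) {
    stages <- rbind(stages, stage_fit("spline+dow", spline_df_per_year,
                                      include_dow, NULL))
  }
  acc <- NULL
  for (col in extra_cols) {
    new_col <- as.matrix(d[, col, drop = FALSE])
    acc <- if (is.null(acc)) new_col else cbind(acc, new_col)
    stages <- rbind(stages, stage_fit(paste0("+", col), spline_df_per_year,
                                      include_dow, acc))
  }
  final <- usable_sd(dates, x, spline_df_per_year, include_dow, acc)
  if (final$n_dropped > 0) {
    message(final$n_dropped, " incomplete row(s) dropped")
  }
  structure(list(stages = stages, final = final,
                 n_dropped = final$n_dropped),
            class = "exposure_profile")
}

#' @export
print.exposure_profile <- function(x, digits = 4, ...) {
  cat("Exposure profile (", x$final$n_used, " complete cases",
      if (x$n_dropped > 0) paste0(", ", x$n_dropped, " dropped"), ")\n",
      sep = "")
  s <- x$stages
  for (i in seq_len(nrow(s))) {
    cat(sprintf("  %-12s SD = %-9s (per increment: %s)\n", s$stage[i],
                format(s$sd_usable[i], digits = digits),
                format(s$sd_per_increment[i], digits = digits)))
  }
  cat("  final R^2_x|z:", format(x$final$r2, digits = digits),
      " VIF:", format(x$final$vif, digits = digits), "\n")
  invisible(x)
}
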