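# Closed-form precision approximators for a single count time series and the
# planning quantities (CI width, power, smallest detectable coefficient,
# required events) derived from a standard error.

.check_pos <- function(x, name) {
  if (!is.numeric(x) || length(x) < 1L || anyNA(x) || any(!is.finite(x)) ||
      any(x <= 0)) {
    stop("`", name, "` must be positive and finite", call. = FALSE)
  }
  invisible(x)
}

.check_prob <- function(x, name) {
  if (!is.numeric(x) || length(x) < 1L || anyNA(x) ||
      any(x <= 0) || any(x >= 1)) {
    stop("`", name, "` must lie strictly between 0 and 1", call. = FALSE)
  }
  invisible(x)
}

.check_dispersion <- function(dispersion) {
  .check_pos(dispersion, "dispersion")
  if (any(dispersion < 1)) {
    warning("dispersion < 1 (underdispersion); standard errors will be ",
            "deflated accordingly", call. = FALSE)
  }
  invisible(dispersion)
}

# Upper-tail standard normal quantile; printed_z reproduces hand arithmetic
# done with 2-decimal z values (1.96, 1.28, 0.84).
.zq <- function(p, printed_z = FALSE) {
  z <- stats::qnorm(p, lower.tail = FALSE)
  if (printed_z) round(z, 2) else z
}

#' Crude Poisson standard error approximation
#'
#' Approximates the standard error of the exposure coefficient in a log-linear
#' Poisson time-series regression using only the total expected event count
#' and the raw (unconditional) exposure standard deviation:
#' \eqn{SE = 1 / (\sqrt{\Sigma Y} \times SD(x))}. It ignores the loss of
#' exposure variation to covariate adjustment and therefore understates the
#' standard error whenever the exposure is correlated with the covariates
#' (e.g. seasonal exposures adjusted by a time spline).
#'
#' @param total_events Total expected number of events over the study
#'   (\eqn{\Sigma Y_i}); positive.
#' @param sd_raw Unconditional standard deviation of the exposure, in exposure
#'   units; positive.
#' @return The approximate standard error, per unit of exposure.
#' @seealso [se_poisson()] for the covariate-adjusted version,
#'   [se_quasipoisson()] for overdispersed counts.
#' @examples
#' se_poisson_crude(100, 1)    # 0.1
#' se_poisson_crude(3888, 0.97)
#' @export
se_poisson_crude <- function(total_events, sd_raw) {
  .check_pos(total_events, "total_events")
  .check_pos(sd_raw, "sd_raw")
  1 / (sqrt(total_events) * sd_raw)
}

#' Poisson standard error approximation using the usable exposure SD
#'
#' Approximates the standard error of the exposure coefficient as
#' \eqn{SE = 1 / (\sqrt{\Sigma Y} \times SD(x|z))}, where \eqn{SD(x|z)} is the
#' "usable" exposure SD: the standard deviation of the residuals of the
#' exposure in a linear regression on the covariates the outcome model will
#' include (see [usable_sd()]). Precision depends on the total event count and
#' the usable exposure variation only, not on how many days the events are
#' spread over.
#'
#' @inheritParams se_poisson_crude
#' @param sd_usable Usable (covariate-conditional) exposure SD, in exposure
#'   units; positive.
#' @return The approximate standard error, per unit of exposure.
#' @examples
#' se_poisson(3888, 0.76)   # ~0.021 per 10 ug/m3, the London PM2.5 example
#' @export
se_poisson <- function(total_events, sd_usable) {
  .check_pos(total_events, "total_events")
  .check_pos(sd_usable, "sd_usable")
  1 / (sqrt(total_events) * sd_usable)
}

#' Quasi-Poisson standard error approximation
#'
#' As [se_poisson()] but inflated by \eqn{\sqrt{\phi}} for scale
#' overdispersion \eqn{\phi} (variance \eqn{\phi} times the mean):
#' \eqn{SE = \sqrt{\phi} / (\sqrt{\Sigma Y} \times SD(x|z))}. Reduces to the
#' Poisson approximation at \eqn{\phi = 1}. Underdispersion
#' (\eqn{\phi < 1}) is accepted with a warning.
#'
#' @inheritParams se_poisson
#' @param dispersion Overdispersion factor \eqn{\phi}; positive, typically
#'   \eqn{\ge 1}.
#' @return The approximate standard error, per unit of exposure.
#' @examples
#' se_quasipoisson(3888, 0.76, 1)    # equals se_poisson(3888, 0.76)
#' se_quasipoisson(3888, 0.76, 1.2)  # inflated by sqrt(1.2)
#' @export
se_quasipoisson <- function(total_events, sd_usable, dispersion = 1) {
  .check_dispersion(dispersion)
  sqrt(dispersion) * se_poisson(total_events, sd_usable)
}

#' Variance inflation ratio of covariate adjustment
#'
#' The factor \eqn{(SD(x)/SD(x|z))^2} by which covariate adjustment inflates
#' the sampling variance of the exposure coefficient, equivalently the squared
#' ratio of the crude to the adjusted SE approximation.
#'
#' @inheritParams se_poisson_crude
#' @inheritParams se_poisson
#' @return A number \eqn{\ge 1}.
#' @examples
#' variance_inflation_ratio(9.7, 7.6)
#' @export
variance_inflation_ratio <- function(sd_raw, sd_usable) {
  .check_pos(sd_raw, "sd_raw")
  .check_pos(sd_usable, "sd_usable")
  if (any(sd_usable > sd_raw)) {
    stop("`sd_usable` cannot exceed `sd_raw`: conditioning on covariates ",
         "cannot increase the exposure SD", call. = FALSE)
  }
  (sd_raw / sd_usable)^2
}

#' Width of the two-sided confidence interval for the coefficient
#'
#' @param se Standard error of the coefficient; positive.
#' @param alpha Two-sided significance level, in (0, 1).
#' @param printed_z Use 2-decimal normal quantiles (1.96 at alpha = 0.05)
#'   instead of full precision, reproducing hand arithmetic.
#' @return The CI width \eqn{2 z_{\alpha/2} \times SE}.
#' @examples
#' ci_width(0.021)  # ~0.082
#' @export
ci_width <- function(se, alpha = 0.05, printed_z = FALSE) {
  .check_pos(se, "se")
  .check_prob(alpha, "alpha")
  2 * .zq(alpha / 2, printed_z) * se
}

#' Approximate power to detect a coefficient
#'
#' Normal-approximation power of a two-sided level-\eqn{\alpha} test when the
#' true coefficient is `beta_h1` and the estimator's standard error is `se`:
#' \eqn{\Phi(|\beta_{H1}|/SE - z_{\alpha/2})}. At \eqn{\beta_{H1} = 0} this
#' returns \eqn{\alpha/2}, the one-tail rejection probability under the null.
#'
#' @param beta_h1 Hypothesised true coefficient (log relative rate per
#'   exposure unit); may be negative, power uses its magnitude.
#' @inheritParams ci_width
#' @return Power, in (0, 1).
#' @examples
#' power_approx(0.06, 0.021)  # ~0.82
#' @export
power_approx <- function(beta_h1, se, alpha = 0.05, printed_z = FALSE) {
  .check_pos(se, "se")
  .check_prob(alpha, "alpha")
  if (!is.numeric(beta_h1) || anyNA(beta_h1)) {
    stop("`beta_h1` must be numeric", call. = FALSE)
  }
  stats::pnorm(abs(beta_h1) / se - .zq(alpha / 2, printed_z))
}

#' Smallest coefficient detectable at given significance level and power
#'
#' \eqn{(z_{\alpha/2} + z_{1-power}) \times SE}; at \eqn{\alpha = 0.05} and
#' power 0.8 the multiplier is \eqn{1.96 + 0.84 \approx 2.8}.
#'
#' @inheritParams ci_width
#' @param target_power Desired power, in (0, 1).
#' @return The smallest detectable coefficient, same units as the SE.
#' @examples
#' smallest_detectable(0.021)                # ~0.059
#' smallest_detectable(0.021, target_power = 0.9)
#' @export
smallest_detectable <- function(se, alpha = 0.05, target_power = 0.8,
                                printed_z = FALSE) {
  .check_pos(se, "se")
  .check_prob(alpha, "alpha")
  .check_prob(target_power, "target_power")
  (.zq(alpha / 2, printed_z) + .zq(1 - target_power, printed_z)) * se
}

#' Number of events required for given power
#'
#' Inverts the usable-SD standard-error approximation to give the total event
#' count needed to detect `beta_h1` with the stated power:
#' \eqn{\phi \left[(z_{\alpha/2} + z_{1-power}) / (|\beta_{H1}| SD(x|z))\right]^2}.
#' The \eqn{\phi} multiplier extends the pure-Poisson formula to
#' overdispersed counts (substituting the quasi-Poisson SE); the default
#' \eqn{\phi = 1} gives the plain Poisson requirement.
#'
#' @inheritParams power_approx
#' @inheritParams se_quasipoisson
#' @inheritParams smallest_detectable
#' @return Required total number of events (a positive real; round up for
#'   planning).
#' @examples
#' required_events(0.06, 0.76, target_power = 0.9, printed_z = TRUE)  # ~5048
#' @export
required_events <- function(beta_h1, sd_usable, alpha = 0.05,
                            target_power = 0.8, dispersion = 1,
                            printed_z = FALSE) {
  if (!is.numeric(beta_h1) || anyNA(beta_h1) || any(beta_h1 == 0)) {
    stop("`beta_h1` must be nonzero: a null effect needs infinitely many ",
         "events", call. = FALSE)
  }
  .check_pos(sd_usable, "sd_usable")
  .check_prob(alpha, "alpha")
  .check_prob(target_power, "target_power")
  .check_dispersion(dispersion)
  mult <- .zq(alpha / 2, printed_z) + .zq(1 - target_power, printed_z)
  dispersion * (mult / (abs(beta_h1) * sd_usable))^2
}

#' Study length needed to accrue the required events
#'
#' @param required_events Total number of events needed; positive.
#' @param events_per_year Expected events per year; positive.
#' @return Years of series required.
#' @examples
#' years_required(5048, 486)  # ~10.4
#' @export
years_required <- function(required_events, events_per_year) {
  .check_pos(required_events, "required_events")
  .check_pos(events_per_year, "events_per_year")
  required_events / events_per_year
}
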