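# Precision approximators for the meta-analytic mean coefficient across J
# independent series, plus the fixed/random-effects meta-analysis machinery
# the validation harness needs.

#' Fixed-effects meta-analytic standard error approximation
#'
#' Approximate SE of the inverse-variance-weighted (fixed-effects) mean
#' coefficient across independent series sharing a common usable exposure SD
#' and overdispersion: \eqn{\sqrt{\phi} / (\sqrt{\Sigma\Sigma Y} \times
#' SD(x|z))}, with the event count pooled over all series. Numerically
#' identical to the single-series quasi-Poisson approximation applied to the
#' pooled events: under a fixed-effects analysis precision depends on the
#' total events only, not on how they are split across series.
#'
#' @param total_events Total events pooled over all series; positive.
#' @inheritParams se_quasipoisson
#' @return The approximate fixed-effects SE, per unit of exposure.
#' @examples
#' se_fe(9720, 0.76)  # ~0.013, the ten-city extension of the London example
#' @export
se_fe <- function(total_events, sd_usable, dispersion = 1) {
  se_quasipoisson(total_events, sd_usable, dispersion)
}

#' Random-effects meta-analytic SE from tau and per-series SEs
#'
#' Best closed-form approximation of the random-effects pooled-coefficient
#' SE when the heterogeneity SD \eqn{\tau} and the per-series standard errors
#' can be predicted: \eqn{\sqrt{1 / \sum_j (\tau^2 + SE_j^2)^{-1}}}.
#'
#' @param tau Between-series SD of true coefficients (log-RR scale);
#'   nonnegative.
#' @param per_series_se Vector of predicted per-series standard errors;
#'   positive, nonempty.
#' @return The approximate random-effects SE.
#' @examples
#' se_re_full(0, rep(0.02, 10))       # fixed-effects limit 0.02/sqrt(10)
#' se_re_full(0.0055, rep(0.005, 51))
#' @export
se_re_full <- function(tau, per_series_se) {
  if (length(per_series_se) == 0L) {
    stop("`per_series_se` must be a nonempty vector of standard errors",
         call. = FALSE)
  }
  .check_pos(per_series_se, "per_series_se")
  if (!is.numeric(tau) || length(tau) != 1L || is.na(tau) || tau < 0) {
    stop("`tau` must be a single nonnegative number", call. = FALSE)
  }
  sqrt(1 / sum(1 / (tau^2 + per_series_se^2)))
}

#' Random-effects SE from the fixed-effects SE and I-squared
#'
#' Heterogeneity-corrected approximation assuming constant per-series SEs:
#' \eqn{SE_{RE} = SE_{FE} / \sqrt{1 - I^2}}, where \eqn{I^2} is the fraction
#' of total variance in series estimates due to between-series heterogeneity.
#'
#' @param se_fe Fixed-effects pooled SE; positive.
#' @param i_squared Heterogeneity fraction \eqn{I^2}, in \[0, 1).
#' @return The approximate random-effects SE.
#' @examples
#' se_re_from_i2(0.050, 0.653)  # ~0.085
#' @export
se_re_from_i2 <- function(se_fe, i_squared) {
  .check_pos(se_fe, "se_fe")
  if (!is.numeric(i_squared) || length(i_squared) != 1L || is.na(i_squared) ||
      i_squared < 0 || i_squared >= 1) {
    stop("`i_squared` must lie in [0, 1)", call. = FALSE)
  }
  se_fe / sqrt(1 - i_squared)
}

#' Random-effects SE under extreme heterogeneity
#'
#' When \eqn{\tau} dwarfs every per-series SE the pooled coefficient behaves
#' like a simple sample mean of J draws: \eqn{SE \approx \tau / \sqrt{J}}.
#' Precision then depends only on the number of series and the heterogeneity,
#' not on the event counts.
#'
#' @param tau Between-series SD of true coefficients; positive.
#' @param n_series Number of series J; positive integer.
#' @return The approximate random-effects SE.
#' @examples
#' se_extreme_het(0.0055, 51)
#' @export
se_extreme_het <- function(tau, n_series) {
  .check_pos(tau, "tau")
  if (!is.numeric(n_series) || length(n_series) != 1L || is.na(n_series) ||
      n_series < 1 || n_series != round(n_series)) {
    stop("`n_series` must be a positive integer", call. = FALSE)
  }
  tau / sqrt(n_series)
}

.check_estimates <- function(beta, se, min_n = 1L) {
  if (length(beta) != length(se)) {
    stop("`beta` and `se` must have the same length", call. = FALSE)
  }
  if (length(beta) < min_n) {
    stop("at least ", min_n, " series estimate(s) required", call. = FALSE)
  }
  if (!is.numeric(beta) || anyNA(beta)) {
    stop("`beta` must be numeric without missing values", call. = FALSE)
  }
  .check_pos(se, "se")
}

.meta_result <- function(beta_pooled, se_fe, se_re, tau2, i_squared, q_stat,
                         n_series) {
  structure(
    list(beta_pooled = beta_pooled, se_fe = se_fe, se_re = se_re,
         tau2 = tau2, i_squared = i_squared, q_stat = q_stat,
         n_series = n_series),
    class = "meta_result"
  )
}

#' @export
print.meta_result <- function(x, digits = 4, ...) {
  cat("Meta-analysis of", x$n_series, "series estimates\n")
  cat("  pooled coefficient:", format(x$beta_pooled, digits = digits), "\n")
  cat("  SE (fixed effects):", format(x$se_fe, digits = digits), "\n")
  cat("  SE (random effects):", format(x$se_re, digits = digits), "\n")
  cat("  tau^2:", format(x$tau2, digits = digits),
      " I^2:", format(x$i_squared, digits = digits),
      " Q:", format(x$q_stat, digits = digits), "\n")
  invisible(x)
}

#' Fixed-effects (inverse-variance) meta-analysis of series coefficients
#'
#' Pools per-series coefficient estimates with weights \eqn{w_j = SE_j^{-2}}.
#' Cochran's Q and \eqn{I^2 = \max(0, (Q - (J-1))/Q)} are computed from the
#' fixed-effects fit as heterogeneity diagnostics; `tau2` is 0 and `se_re`
#' equals `se_fe` by construction.
#'
#' @param beta Vector of per-series coefficient estimates (log-RR scale).
#' @param se Vector of their standard errors; positive, same length.
#' @return A `meta_result` list: `beta_pooled`, `se_fe`, `se_re`, `tau2`,
#'   `i_squared`, `q_stat`, `n_series`.
#' @examples
#' meta_fixed(c(0, 2), c(1, 1))  # pooled 1, SE 1/sqrt(2), Q = 2
#' @export
meta_fixed <- function(beta, se) {
  .check_estimates(beta, se, min_n = 1L)
  w <- 1 / se^2
  bp <- sum(w * beta) / sum(w)
  sefe <- sqrt(1 / sum(w))
  q <- sum(w * (beta - bp)^2)
  i2 <- if (q > 0) max(0, (q - (length(beta) - 1)) / q) else 0
  .meta_result(bp, sefe, sefe, 0, i2, q, length(beta))
}

#' Random-effects meta-analysis (DerSimonian-Laird)
#'
#' Moment estimator of the between-series variance,
#' \eqn{\hat\tau^2 = \max(0, (Q - (J-1)) / (\sum w_j - \sum w_j^2 / \sum w_j))}
#' with fixed-effects weights \eqn{w_j = SE_j^{-2}}, then inverse-variance
#' pooling with weights \eqn{(\hat\tau^2 + SE_j^2)^{-1}}. With homogeneous
#' estimates \eqn{\hat\tau^2} truncates to zero and the result coincides with
#' [meta_fixed()].
#'
#' @inheritParams meta_fixed
#' @return A `meta_result` list (see [meta_fixed()]); `se_fe` is the
#'   fixed-effects SE from the same data, `se_re` the random-effects SE.
#' @examples
#' meta_random(c(0, 2), c(1, 1))  # tau2 = 1, RE SE = 1
#' @export
meta_random <- function(beta, se) {
  .check_estimates(beta, se, min_n = 2L)
  fe <- meta_fixed(beta, se)
  w <- 1 / se^2
  j <- length(beta)
  denom <- sum(w) - sum(w^2) / sum(w)
  tau2 <- if (denom > 0) max(0, (fe$q_stat - (j - 1)) / denom) else 0
  wre <- 1 / (tau2 + se^2)
  bp <- sum(wre * beta) / sum(wre)
  sere <- sqrt(1 / sum(wre))
  .meta_result(bp, fe$se_fe, sere, tau2, fe$i_squared, fe$q_stat, j)
}

#' Read per-series coefficient estimates from a delimited table
#'
#' Expects a header with columns `beta` and `se` (extra columns ignored), as
#' written by [write_series_estimates()], for interoperability with
#' externally run first-stage fits.
#'
#' @param file Path to a delimited text file.
#' @param sep Field separator (default comma).
#' @return A data.frame with columns `beta` and `se`.
#' @export
read_series_estimates <- function(file, sep = ",") {
  d <- utils::read.table(file, header = TRUE, sep = sep)
  if (!all(c("beta", "se") %in% names(d))) {
    stop("file must contain columns `beta` and `se`", call. = FALSE)
  }
  .check_estimates(d$beta, d$se)
  d[c("beta", "se")]
}

#' Write per-series coefficient estimates to a delimited table
#'
#' @param beta,se Per-series estimates and standard errors.
#' @param file Output path.
#' @param sep Field separator (default comma).
#' @return The path, invisibly.
#' @export
write_series_estimates <- function(beta, se, file, sep = ",") {
  .check_estimates(beta, se)
  utils::write.table(data.frame(beta = beta, se = se), file, sep = sep,
                     row.names = FALSE, quote = FALSE)
  invisible(file)
}
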