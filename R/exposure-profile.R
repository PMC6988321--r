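# Estimation of the "usable" exposure SD, SD(x|z): the standard deviation of
# the residuals of an exposure series regressed on the covariate design a
# final count-regression analysis would use (seasonal spline, day-of-week,
# optional extra covariates). Also the exposure transforms used in validation
# (linear-threshold "heat" exposure, running lag means).

.check_dates <- function(dates) {
  dates <- as.Date(dates)
  if (anyNA(dates)) stop("dates contain unparseable values", call. = FALSE)
  if (length(dates) > 1 && any(diff(as.numeric(dates)) <= 0)) {
    stop("dates must be strictly increasing", call. = FALSE)
  }
  dates
}

#' Natural cubic spline basis for calendar time
#'
#' Builds the seasonal/trend adjustment basis used in daily time-series
#' regressions: a natural cubic spline of the day number with a total of
#' `round(df_per_year * span_in_years)` degrees of freedom, boundary knots at
#' the first and last date and interior knots at equally spaced quantiles of
#' the observed dates. `df_per_year = 0` (or a span too short for 1 df)
#' yields an intercept-only design.
#'
#' @param dates Strictly increasing vector of dates (or anything
#'   `as.Date()` accepts).
#' @param df_per_year Spline degrees of freedom per year of span;
#'   nonnegative. 7 is conventional for daily mortality series.
#' @return An `n x k` basis matrix (columns `spline1..splinek`), or an `n x 1`
#'   column of ones when the total df rounds below 1.
#' @examples
#' d <- seq(as.Date("2010-01-01"), by = "day", length.out = 2922)  # 8 years
#' ncol(time_spline_basis(d, 7))  # 56
#' @export
time_spline_basis <- function(dates, df_per_year) {
  dates <- .check_dates(dates)
  if (!is.numeric(df_per_year) || length(df_per_year) != 1L ||
      is.na(df_per_year) || df_per_year < 0) {
    stop("`df_per_year` must be a single nonnegative number", call. = FALSE)
  }
  n <- length(dates)
  if (length(unique(dates)) < 2L) {
    stop("need at least 2 distinct dates", call. = FALSE)
  }
  span_years <- (as.numeric(max(dates) - min(dates)) + 1) / 365.25
  k <- round(df_per_year * span_years)
  if (k < 1) {
    return(matrix(1, n, 1, dimnames = list(NULL, "(Intercept)")))
  }
  if (length(unique(dates)) < k + 2) {
    stop("degenerate design: ", k, " spline df need at least ", k + 2,
         " distinct dates", call. = FALSE)
  }
  day <- as.numeric(dates - min(dates))
  b <- splines::ns(day, df = k)
  m <- matrix(as.numeric(b), n, k)
  colnames(m) <- paste0("spline", seq_len(k))
  m
}

#' Day-of-week indicator columns
#'
#' Six indicator columns for Tuesday through Sunday, with Monday as the
#' reference category (ISO weekday numbering, locale-independent). Full
#' column rank whenever at least 7 consecutive days are present.
#'
#' @inheritParams time_spline_basis
#' @return An `n x 6` 0/1 matrix with columns `dowTue..dowSun`.
#' @export
dow_indicators <- function(dates) {
  dates <- .check_dates(dates)
  if (length(dates) == 0L) stop("`dates` must be nonempty", call. = FALSE)
  u <- as.integer(format(dates, "%u"))  # 1 = Monday ... 7 = Sunday
  m <- vapply(2:7, function(d) as.numeric(u == d), numeric(length(dates)))
  m <- matrix(m, length(dates), 6)
  colnames(m) <- paste0("dow", c("Tue", "Wed", "Thu", "Fri", "Sat", "Sun"))
  m
}

# Spline columns for internal designs: NULL instead of the intercept-only
# fallback, since model intercepts are added separately.
.spline_cols <- function(dates, df_per_year) {
  b <- time_spline_basis(dates, df_per_year)
  if (identical(colnames(b), "(Intercept)")) NULL else b
}

#' Usable exposure SD after covariate adjustment
#'
#' Regresses the exposure on the covariate design (intercept, seasonal
#' spline, day-of-week, extra covariates) by ordinary least squares over
#' complete cases and summarises the exposure variation left for effect
#' estimation: the residual SD \eqn{SD(x|z)}, the raw SD \eqn{SD(x)}, the
#' fraction of exposure variance explained \eqn{R^2_{x|z}}, and the variance
#' inflation ratio \eqn{(SD(x)/SD(x|z))^2}. Raw and residual SDs share a
#' common denominator so that \eqn{SD(x|z) = SD(x)\sqrt{1 - R^2}} holds
#' exactly: residual degrees of freedom `n - p` by default (the unbiased-
#' sigma convention; `n - 1` optionally).
#'
#' @inheritParams time_spline_basis
#' @param values Exposure values aligned with `dates`; missing values allowed
#'   (complete-case analysis, dropped rows counted).
#' @param spline_df_per_year Seasonal spline df per year (0 for none).
#' @param include_dow Include day-of-week indicators?
#' @param extra Optional matrix/data.frame of additional covariate columns
#'   aligned with `dates` (entered linearly; pre-expand splines of covariates
#'   yourself, e.g. with `splines::ns`).
#' @param denominator `"resid-df"` (divide both sums of squares by `n - p`)
#'   or `"n-1"`.
#' @return An object of class `exposure_variation`: `sd_raw`, `sd_usable`,
#'   `r2`, `vif`, `n_used`, `n_dropped`, `df_model`.
#' @examples
#' d <- seq(as.Date("2010-01-01"), by = "day", length.out = 730)
#' x <- 5 * cospi(2 * as.numeric(d - d[1]) / 365.25) + rnorm(730)
#' usable_sd(d, x, spline_df_per_year = 7)
#' @export
usable_sd <- function(dates, values, spline_df_per_year = 7,
                      include_dow = TRUE, extra = NULL,
                      denominator = c("resid-df", "n-1")) {
  dates <- .check_dates(dates)
  denominator <- match.arg(denominator)
  if (length(values) != length(dates)) {
    stop("`values` and `dates` must have the same length", call. = FALSE)
  }
  extra <- if (!is.null(extra)) as.matrix(extra)
  if (!is.null(extra) && nrow(extra) != length(dates)) {
    stop("`extra` covariate rows must match `dates`", call. = FALSE)
  }

  keep <- !is.na(values)
  if (!is.null(extra)) keep <- keep & stats::complete.cases(extra)
  n_dropped <- sum(!keep)
  dates <- dates[keep]
  x <- values[keep]
  n <- length(x)

  X <- cbind(`(Intercept)` = rep(1, n),
             .spline_cols(dates, spline_df_per_year),
             if (include_dow) dow_indicators(dates),
             extra[keep, , drop = FALSE])
  p <- ncol(X)
  if (n < p + 2) {
    stop("insufficient data: ", n, " complete cases for ", p,
         " design columns", call. = FALSE)
  }
  qx <- qr(X)
  if (qx$rank < p) {
    bad <- colnames(X)[qx$pivot[(qx$rank + 1):p]]
    stop("rank-deficient covariate design; collinear column(s): ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  res <- stats::lm.fit(X, x)$residuals

  ss_tot <- sum((x - mean(x))^2)
  ss_res <- sum(res^2)
  if (ss_tot <= 0) stop("exposure has no variation", call. = FALSE)
  r2 <- 1 - ss_res / ss_tot
  if (r2 > 1 - 1e-10) {
    stop("degenerate: covariates explain the exposure exactly (R^2 = 1); ",
         "SD(x|z) is undefined", call. = FALSE)
  }
  d <- if (denominator == "resid-df") n - p else n - 1
  structure(
    list(sd_raw = sqrt(ss_tot / d), sd_usable = sqrt(ss_res / d),
         r2 = r2, vif = ss_tot / ss_res, n_used = n, n_dropped = n_dropped,
         df_model = p),
    class = "exposure_variation"
  )
}

#' @export
print.exposure_variation <- function(x, digits = 4, ...) {
  cat("Exposure variation profile (", x$n_used, " complete cases",
      if (x$n_dropped > 0) paste0(", ", x$n_dropped, " dropped"), ")\n",
      sep = "")
  cat("  SD(x)    :", format(x$sd_raw, digits = digits), "\n")
  cat("  SD(x|z)  :", format(x$sd_usable, digits = digits),
      " [", x$df_model, "design columns ]\n")
  cat("  R^2_x|z  :", format(x$r2, digits = digits), "\n")
  cat("  variance inflation ratio:", format(x$vif, digits = digits), "\n")
  invisible(x)
}

#' Linear-threshold exposure transform
#'
#' Recodes a series as the excess above an empirical percentile,
#' `pmax(value - q_p, 0)` — e.g. "heat" as daily mean temperature above its
#' 75th centile. The percentile uses linear interpolation between order
#' statistics (quantile type 7), computed over complete cases.
#'
#' @param values Numeric series; missing values propagate.
#' @param percentile Threshold percentile, in (0, 100).
#' @return The transformed series, same length as `values`.
#' @examples
#' threshold_exposure(c(1, 2, 3, 4), 75)  # 0 0 0 0.75
#' @export
threshold_exposure <- function(values, percentile = 75) {
  if (length(values) == 0L) stop("`values` must be nonempty", call. = FALSE)
  if (!is.numeric(percentile) || length(percentile) != 1L ||
      is.na(percentile) || percentile <= 0 || percentile >= 100) {
    stop("`percentile` must lie strictly between 0 and 100", call. = FALSE)
  }
  q <- stats::quantile(values, percentile / 100, na.rm = TRUE, names = FALSE,
                       type = 7)
  pmax(values - q, 0)
}

#' Running mean over a set of lags
#'
#' Mean of `values` at the stated lags; entries with insufficient history
#' (the first `max(lags)` positions) are `NA`. `lags = 0` is the identity.
#'
#' @param values Numeric series.
#' @param lags Vector of distinct nonnegative integer lags (e.g. `0:2` for a
#'   three-day running mean).
#' @return A series of the same length.
#' @examples
#' lagged_mean(c(1, 2, 3, 4), 0:2)  # NA NA 2 3
#' @export
lagged_mean <- function(values, lags) {
  n <- length(values)
  if (!is.numeric(lags) || length(lags) == 0L || anyNA(lags) ||
      any(lags < 0) || any(lags != round(lags)) || anyDuplicated(lags) ||
      max(lags) >= n) {
    stop("`lags` must be distinct nonnegative integers smaller than the ",
         "series length", call. = FALSE)
  }
  out <- rep(NA_real_, n)
  maxlag <- max(lags)
  for (i in seq.int(maxlag + 1, n)) out[i] <- mean(values[i - lags])
  out
}
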