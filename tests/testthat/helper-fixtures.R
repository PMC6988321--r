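# Shared fixtures: date sequences and a synthetic exposure CSV built in code.

daily_dates <- function(n, start = "2010-01-04") {  # 2010-01-04 is a Monday
  seq(as.Date(start), by = "day", length.out = n)
}

# Seasonal exposure with known residual SD, optionally with an extra
# covariate column (whose day-to-day anomaly the exposure partly tracks, so
# adjusting for it genuinely shrinks the residual SD) and missing rows;
# written to a temp CSV for the profiling tests.
write_exposure_csv <- function(n = 3653, sigma = 2, seed = 11,
                               n_missing = 0, extra_covariate = FALSE) {
  set.seed(seed)
  d <- daily_dates(n)
  day <- as.numeric(d - d[1])
  x <- 10 * sin(2 * pi * day / 365.25) + rnorm(n, 0, sigma)
  df <- data.frame(date = format(d), pm = x)
  if (extra_covariate) {
    anomaly <- rnorm(n)
    df$temp <- 12 + 8 * cos(2 * pi * day / 365.25 + 0.5) + anomaly
    df$pm <- df$pm + 0.8 * anomaly
  }
  if (n_missing > 0) df$pm[sample(n, n_missing)] <- NA
  path <- tempfile(fileext = ".csv")
  write.csv(df, path, row.names = FALSE)
  path
}
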