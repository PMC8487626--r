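#' Lagged meteorological predictors anchored at 14:00
#'
#' For every requested sampling date, computes the lag-n predictors used by
#' the regression models: the mean air temperature `T_n`, mean relative
#' humidity `H_n` and mean wind speed `W_n`, and the accumulated rainfall
#' `R_n`, over a trailing window ending at the 14:00 sampling anchor.
#' For `n >= 1` the window is the `n * 24` h interval
#' `(14:00 of date - n days, 14:00 of date]`; for `n = 0` it is the same-day
#' interval `(00:00, 14:00]`. A per-window coverage fraction (records
#' present / records expected, from the series' median record interval) is
#' reported; windows with coverage below `min_coverage` have their features
#' set to `NA` rather than silently extrapolated.
#'
#' @param weather a [weather_series()].
#' @param dates vector of sampling dates (`Date`).
#' @param n_max largest lag in days (default 10).
#' @param anchor_hour hour of day of the sampling anchor (default 14).
#' @param min_coverage minimum window coverage fraction below which features
#'   are marked missing (default 0.8).
#' @param tz time zone used to place the anchor (default taken from the
#'   weather timestamps).
#' @return data frame of class `lagged_features` with columns `date`,
#'   `T_0..T_n`, `H_0..H_n`, `W_0..W_n`, `R_0..R_n` and
#'   `coverage_0..coverage_n`.
#' @export
lagged_features <- function(weather, dates, n_max = 10, anchor_hour = 14,
                            min_coverage = 0.8, tz = NULL) {
  stopifnot(inherits(weather, "weather_series"), n_max >= 0)
  dates <- as.Date(dates)
  if (is.null(tz)) tz <- attr(weather$timestamp, "tzone")
  if (is.null(tz) || !nzchar(tz[1])) tz <- "UTC"
  ts <- as.numeric(weather$timestamp)
  step_s <- stats::median(diff(ts))
  anchor <- as.numeric(as.POSIXct(paste0(format(dates), " ",
                                         sprintf("%02d:00:00", anchor_hour)),
                                  tz = tz))
  midnight <- anchor - anchor_hour * 3600

  # cumulative sums let every window reduce to two index lookups
  csT <- c(0, cumsum(weather$temp_c))
  csH <- c(0, cumsum(weather$rh_pct))
  csW <- c(0, cumsum(weather$wind_ms))
  csR <- c(0, cumsum(weather$rain_mm))

  out <- data.frame(date = dates)
  lags <- 0:n_max
  cov_mat <- matrix(NA_real_, nrow = length(dates), ncol = length(lags))
  feat <- list()
  for (k in seq_along(lags)) {
    n <- lags[k]
    lo <- if (n == 0) midnight else anchor - n * 86400
    hi <- anchor
    i_lo <- findInterval(lo, ts)       # records with ts <= lo, excluded
    i_hi <- findInterval(hi, ts)       # records with ts <= hi, included
    cnt <- pmax(i_hi - i_lo, 0L)
    expected <- (hi - lo) / step_s
    coverage <- ifelse(expected > 0, cnt / expected, 0)
    ok <- cnt > 0 & coverage >= min_coverage
    mean_of <- function(cs) ifelse(ok, (cs[i_hi + 1] - cs[i_lo + 1]) / cnt, NA_real_)
    feat[[paste0("T_", n)]] <- mean_of(csT)
    feat[[paste0("H_", n)]] <- mean_of(csH)
    feat[[paste0("W_", n)]] <- mean_of(csW)
    feat[[paste0("R_", n)]] <- ifelse(ok, csR[i_hi + 1] - csR[i_lo + 1], NA_real_)
    cov_mat[, k] <- coverage
  }
  ord <- unlist(lapply(c("T", "H", "W", "R"), function(el) paste0(el, "_", lags)))
  out <- cbind(out, as.data.frame(feat)[, ord])
  colnames(cov_mat) <- paste0("coverage_", lags)
  out <- cbind(out, as.data.frame(cov_mat))
  attr(out, "n_max") <- n_max
  attr(out, "anchor_hour") <- anchor_hour
  attr(out, "min_coverage") <- min_coverage
  class(out) <- c("lagged_features", "data.frame")
  out
}

#' Predictor names of a lagged feature table
#'
#' @param features a [lagged_features()] table.
#' @return character vector `T_0..R_n` in the canonical candidate order
#'   (temperature, humidity, wind, rainfall; ascending lag).
#' @export
feature_names <- function(features) {
  n_max <- attr(features, "n_max")
  if (is.null(n_max)) {
    cand <- grep("^[THWR]_[0-9]+$", names(features), value = TRUE)
    return(cand)
  }
  unlist(lapply(c("T", "H", "W", "R"), function(el) paste0(el, "_", 0:n_max)))
}

#' Write a lagged feature table to comma-separated text
#'
#' @param features a [lagged_features()] table.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_features <- function(features, path) {
  out <- as.data.frame(features)
  out$date <- format(out$date, "%Y-%m-%d")
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Spearman lag-correlation profile between LMC and one weather element
#'
#' Rank correlation (mid-ranks for ties) between the daily moisture series
#' and each lagged predictor of one meteorological element, with a
#' two-sided p-value: exact for small samples without ties (n <= 10, via
#' [stats::cor.test()]), the t approximation otherwise. Lags whose paired
#' sample is all-tied (zero rank variance) are flagged undefined rather
#' than propagated as NaN.
#'
#' @param moisture a [moisture_series()].
#' @param features a [lagged_features()] table.
#' @param element one of `"T"`, `"H"`, `"W"`, `"R"`.
#' @param alpha significance level for the `significant` flag (default 0.05).
#' @return data frame of class `lag_correlation_profile` with columns
#'   `element`, `lag`, `n`, `rho`, `p_value`, `significant`, `defined`.
#' @export
spearman_lag_profile <- function(moisture, features, element = c("H", "T", "W", "R"),
                                 alpha = 0.05) {
  element <- match.arg(element)
  stopifnot(inherits(moisture, "moisture_series"))
  n_max <- attr(features, "n_max")
  if (is.null(n_max)) {
    n_max <- max(as.integer(sub("^[THWR]_", "",
                                grep("^[THWR]_[0-9]+$", names(features), value = TRUE))))
  }
  idx <- match(moisture$date, features$date)
  rows <- lapply(0:n_max, function(n) {
    x <- features[[paste0(element, "_", n)]][idx]
    y <- moisture$lmc_pct
    ok <- is.finite(x) & is.finite(y)
    x <- x[ok]; y <- y[ok]
    m <- length(x)
    if (m < 4) {
      return(data.frame(element = element, lag = n, n = m, rho = NA_real_,
                        p_value = NA_real_, significant = FALSE,
                        defined = FALSE))
    }
    if (stats::sd(x) == 0 || stats::sd(y) == 0) {
      return(data.frame(element = element, lag = n, n = m, rho = NA_real_,
                        p_value = NA_real_, significant = FALSE,
                        defined = FALSE))
    }
    ct <- suppressWarnings(stats::cor.test(x, y, method = "spearman",
                                           exact = m <= 10))
    data.frame(element = element, lag = n, n = m,
               rho = unname(ct$estimate), p_value = ct$p.value,
               significant = is.finite(ct$p.value) && ct$p.value < alpha,
               defined = TRUE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("lag_correlation_profile", "data.frame")
  out
}
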