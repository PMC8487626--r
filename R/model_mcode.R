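.FF_C <- 147.27   # FF scale constant shared with the FFMC moisture conversion

#' Convert between FFMC and fine fuel moisture
#'
#' The bookkeeping conversion between the 0-101 fine fuel moisture code and
#' a moisture percentage: `m = 147.27 * (101 - F) / (59.5 + F)` and its
#' exact algebraic inverse. The pair is a bijection on `F` in [0, 101]
#' (moisture 0 to 250 percent).
#'
#' @param f FFMC value in [0, 101].
#' @param m_pct fine fuel moisture, percent.
#' @return the converted value.
#' @export
ffmc_to_moisture <- function(f) {
  if (any(!is.finite(f)) || any(f < 0) || any(f > 101)) {
    stop("FFMC must lie in [0, 101]", call. = FALSE)
  }
  .FF_C * (101 - f) / (59.5 + f)
}

#' @rdname ffmc_to_moisture
#' @export
moisture_to_ffmc <- function(m_pct) {
  f <- (.FF_C * 101 - 59.5 * m_pct) / (.FF_C + m_pct)
  pmin(pmax(f, 0), 101)
}

#' One daily FFMC update
#'
#' The standard daily fine fuel moisture code calculation of the Canadian
#' Fire Weather Index System: yesterday's code is converted to a moisture
#' content, rainfall above the 0.5 mm canopy trap is added through the
#' rainfall wetting function (with the extra absorption term above 150
#' percent and a 250 percent cap), the moisture then moves toward the
#' drying or wetting equilibrium with log drying/wetting rates driven by
#' temperature, humidity and wind, and the result is converted back to the
#' 0-101 scale. Noon-type weather inputs are expected (here taken at the
#' 14:00 sampling anchor).
#'
#' @param f_prev yesterday's FFMC in [0, 101].
#' @param temp_c air temperature, deg C.
#' @param rh_pct relative humidity, percent in [0, 100].
#' @param wind_kmh wind speed, km/h (station m/s values are multiplied by
#'   3.6 upstream).
#' @param rain_mm 24 h rainfall, mm.
#' @return today's FFMC in [0, 101].
#' @export
ffmc_daily <- function(f_prev, temp_c, rh_pct, wind_kmh, rain_mm) {
  if (any(!is.finite(f_prev)) || any(f_prev < 0) || any(f_prev > 101)) {
    stop("previous FFMC must lie in [0, 101]", call. = FALSE)
  }
  stopifnot(is.finite(temp_c), is.finite(rh_pct), is.finite(wind_kmh),
            is.finite(rain_mm), rh_pct >= 0, rh_pct <= 100, wind_kmh >= 0,
            rain_mm >= 0)
  mo <- ffmc_to_moisture(f_prev)
  if (rain_mm > 0.5) {
    rf <- rain_mm - 0.5
    mr <- mo + 42.5 * rf * exp(-100 / (251 - mo)) * (1 - exp(-6.93 / rf))
    if (mo > 150) mr <- mr + 0.0015 * (mo - 150)^2 * sqrt(rf)
    mo <- min(mr, 250)
  }
  ed <- 0.942 * rh_pct^0.679 + 11 * exp((rh_pct - 100) / 10) +
    0.18 * (21.1 - temp_c) * (1 - exp(-0.115 * rh_pct))
  if (mo > ed) {
    ko <- 0.424 * (1 - (rh_pct / 100)^1.7) +
      0.0694 * sqrt(wind_kmh) * (1 - (rh_pct / 100)^8)
    kd <- ko * 0.581 * exp(0.0365 * temp_c)
    m <- ed + (mo - ed) * 10^(-kd)
  } else {
    ew <- 0.618 * rh_pct^0.753 + 10 * exp((rh_pct - 100) / 10) +
      0.18 * (21.1 - temp_c) * (1 - exp(-0.115 * rh_pct))
    if (mo < ew) {
      k1 <- 0.424 * (1 - ((100 - rh_pct) / 100)^1.7) +
        0.0694 * sqrt(wind_kmh) * (1 - ((100 - rh_pct) / 100)^8)
      kw <- k1 * 0.581 * exp(0.0365 * temp_c)
      m <- ew - (ew - mo) * 10^(-kw)
    } else {
      m <- mo
    }
  }
  moisture_to_ffmc(m)
}

#' Daily FFMC series from a sub-daily weather series
#'
#' Extracts daily inputs at the sampling anchor (the record closest to
#' `anchor_hour` within each day for temperature, humidity and wind; the
#' trailing 24 h rainfall sum ending at the anchor) and iterates
#' [ffmc_daily()] from `f_init`. The first `spinup_days` days are flagged
#' so downstream fits can discard the start-up transient.
#'
#' @param weather a [weather_series()].
#' @param f_init start-up FFMC (default 85).
#' @param spinup_days number of initial days to flag (default 3).
#' @param anchor_hour anchor hour (default 14).
#' @return data frame of class `ffmc_series`: `date`, `ffmc`, `spinup`.
#' @export
ffmc_series <- function(weather, f_init = 85, spinup_days = 3,
                        anchor_hour = 14) {
  stopifnot(inherits(weather, "weather_series"))
  tz <- attr(weather$timestamp, "tzone")
  if (is.null(tz) || !nzchar(tz[1])) tz <- "UTC"
  days <- sort(unique(as.Date(weather$timestamp - 1, tz = tz)))
  ts <- as.numeric(weather$timestamp)
  anchor <- as.numeric(as.POSIXct(paste0(format(days), " ",
                                         sprintf("%02d:00:00", anchor_hour)),
                                  tz = tz))
  f <- numeric(length(days))
  f_prev <- f_init
  for (i in seq_along(days)) {
    k <- which.min(abs(ts - anchor[i]))
    in_rain <- ts > anchor[i] - 86400 & ts <= anchor[i]
    f_prev <- ffmc_daily(f_prev,
                         temp_c = weather$temp_c[k],
                         rh_pct = weather$rh_pct[k],
                         wind_kmh = weather$wind_ms[k] * 3.6,
                         rain_mm = sum(weather$rain_mm[in_rain]))
    f[i] <- f_prev
  }
  out <- data.frame(date = days, ffmc = f,
                    spinup = seq_along(days) <= spinup_days)
  class(out) <- c("ffmc_series", "data.frame")
  out
}

#' Read or write a daily FFMC series as comma-separated text
#'
#' Lets users supply externally computed FFMC values and skip
#' [ffmc_series()].
#'
#' @param path file path with columns `date`, `ffmc`.
#' @return a data frame of class `ffmc_series` (spinup all FALSE).
#' @export
read_ffmc <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  missing <- setdiff(c("date", "ffmc"), names(df))
  if (length(missing) > 0) {
    stop("configuration error: FFMC file missing column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  bad <- which(!is.finite(df$ffmc) | df$ffmc < 0 | df$ffmc > 101)
  if (length(bad) > 0) {
    stop("FFMC outside [0, 101] at row(s): ", .row_list(bad), call. = FALSE)
  }
  out <- data.frame(date = as.Date(df$date), ffmc = df$ffmc, spinup = FALSE)
  class(out) <- c("ffmc_series", "data.frame")
  out
}

#' @rdname read_ffmc
#' @param ffmc a `ffmc_series` data frame.
#' @export
write_ffmc <- function(ffmc, path) {
  utils::write.csv(data.frame(date = format(ffmc$date, "%Y-%m-%d"),
                              ffmc = ffmc$ffmc),
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' FF / FX scale models: moisture percentage from FFMC
#'
#' Algebraic conversions from the fine fuel moisture code to a moisture
#' percentage. The FF variant, `147.27 (101 - F) / (59.5 + F)`, is the
#' standard conversion; the FX variant, `32.87 (101 - F) / (13.28 + F)`,
#' was calibrated for hot, dry regions. Both are strictly decreasing in
#' `F` and reach 0 at `F = 101`.
#'
#' @param f FFMC value(s) in [0, 101].
#' @param variant `"FF"` or `"FX"`.
#' @return predicted moisture content, percent.
#' @export
scale_model <- function(f, variant = c("FF", "FX")) {
  variant <- match.arg(variant)
  if (any(is.finite(f) & (f < 0 | f > 101))) {
    stop("FFMC must lie in [0, 101]", call. = FALSE)
  }
  switch(variant,
         FF = .FF_C * (101 - f) / (59.5 + f),
         FX = 32.87 * (101 - f) / (13.28 + f))
}

#' Paired t-test of measured against predicted moisture
#'
#' Two-sided paired t-test on the differences (measured - predicted); a
#' significant difference (p < `alpha`) means the prediction cannot be
#' used directly (verdict `"not applicable"`). Identical vectors give
#' t = 0, p = 1; a constant nonzero shift with zero difference variance
#' gives infinite t and p = 0 rather than an error.
#'
#' @param measured,predicted paired numeric vectors (or objects carrying
#'   `lmc_pct` / `lmc_pred` columns) of equal length >= 3.
#' @param alpha significance level (default 0.05).
#' @return list of class `applicability_ttest`: `t`, `p_value`, `n`,
#'   `mean_diff`, `verdict` (`"applicable"` / `"not applicable"`).
#' @export
applicability_ttest <- function(measured, predicted, alpha = 0.05) {
  x <- if (is.data.frame(measured)) measured$lmc_pct else measured
  y <- if (is.data.frame(predicted)) {
    if ("lmc_pred" %in% names(predicted)) predicted$lmc_pred else predicted$lmc_pct
  } else predicted
  if (length(x) != length(y)) stop("paired vectors of equal length required",
                                   call. = FALSE)
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 3) stop("need at least 3 paired observations", call. = FALSE)
  d <- x - y
  if (stats::sd(d) == 0) {
    if (mean(d) == 0) {
      t_stat <- 0; p <- 1
    } else {
      t_stat <- sign(mean(d)) * Inf; p <- 0
    }
  } else {
    tt <- stats::t.test(x, y, paired = TRUE)
    t_stat <- unname(tt$statistic); p <- tt$p.value
  }
  structure(list(t = t_stat, p_value = p, n = n, mean_diff = mean(d),
                 verdict = if (is.finite(p) && p < alpha) "not applicable"
                           else "applicable"),
            class = "applicability_ttest")
}

#' Fit the log-log moisture-code regression
#'
#' Regresses `ln(M)` on `ln(M_scale)` by ordinary least squares and
#' back-transforms to the power law `M = alpha * M_scale^beta`. The
#' variance of measured litter moisture grows with its level; the natural
#' log stabilizes it, which is why the fit is linear on the log scale. No
#' retransformation (smearing) bias correction is applied. Non-positive
#' values are excluded with a reported count.
#'
#' @param measured measured moisture, percent (vector or
#'   [moisture_series()]).
#' @param scale_pred scale-model moisture predictions, percent, paired with
#'   `measured`.
#' @param variant `"FF"` or `"FX"` (label only).
#' @return object of class `mcode_model`: `alpha`, `beta`, `r2`, `n`,
#'   `n_excluded`, `variant`.
#' @export
fit_mcode_regression <- function(measured, scale_pred, variant = c("FF", "FX")) {
  variant <- match.arg(variant)
  x <- if (is.data.frame(measured)) measured$lmc_pct else measured
  y <- if (is.data.frame(scale_pred)) {
    if ("lmc_pred" %in% names(scale_pred)) scale_pred$lmc_pred else scale_pred$lmc_pct
  } else scale_pred
  if (length(x) != length(y)) stop("paired vectors of equal length required",
                                   call. = FALSE)
  ok <- is.finite(x) & is.finite(y) & x > 0 & y > 0
  n_excluded <- sum(!ok)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 3) stop("need at least 3 positive pairs", call. = FALSE)
  if (stats::sd(log(y)) == 0) {
    # constant predictor: slope unidentifiable, collapse to the level fit
    alpha <- exp(mean(log(x)))
    beta <- 0
    fitted_r2 <- 0
  } else {
    fit <- stats::lm(log(x) ~ log(y))
    alpha <- exp(unname(stats::coef(fit)[1]))
    beta <- unname(stats::coef(fit)[2])
    # R2 computed directly: summary.lm warns on numerically perfect fits
    tss <- sum((log(x) - mean(log(x)))^2)
    fitted_r2 <- if (tss > 0) 1 - sum(stats::residuals(fit)^2) / tss else 0
  }
  structure(list(alpha = alpha, beta = beta, r2 = fitted_r2,
                 n = length(x), n_excluded = n_excluded, variant = variant),
            class = "mcode_model")
}

#' @export
print.mcode_model <- function(x, ...) {
  cat(sprintf("Moisture-code regression (%s scale): M = %.4f * M_%s^%.4f\n",
              x$variant, x$alpha, x$variant, x$beta))
  cat(sprintf("  R2 = %.3f on log scale, n = %d (%d excluded non-positive)\n",
              x$r2, x$n, x$n_excluded))
  invisible(x)
}

#' Predict litter moisture with a fitted moisture-code regression
#'
#' @param model an `mcode_model` from [fit_mcode_regression()].
#' @param scale_pred scale-model moisture values (percent).
#' @return predicted moisture `alpha * scale_pred^beta`, percent.
#' @export
predict_mcode <- function(model, scale_pred) {
  stopifnot(inherits(model, "mcode_model"))
  model$alpha * scale_pred^model$beta
}
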