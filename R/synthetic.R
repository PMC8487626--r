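#' Configuration for the synthetic dry-season weather generator
#'
#' Defaults emulate the dry-season regime of the Yunnan field campaign the
#' package's reference tables come from: daily mean temperature 22.74 deg C,
#' mean relative humidity 37.18 percent, mean wind 2.78 m/s, sparse rain
#' days averaging 1.34 mm. Day-level anomalies follow an AR(1); within the
#' day, temperature follows a sinusoid peaking at 14:00 with relative
#' humidity in anti-phase.
#'
#' @param n_days number of simulated days.
#' @param records_per_day sub-daily records per day (default 48, i.e. 30-min).
#' @param temp_mean_c,temp_daily_sd,temp_diurnal_amp daily-mean level, SD of
#'   day-level anomalies, and diurnal half-amplitude of temperature (deg C).
#' @param rh_mean_pct,rh_daily_sd,rh_diurnal_amp same for relative humidity
#'   (percent); records are clipped to [5, 100].
#' @param wind_mean_ms mean wind speed (m/s); winds are gamma-distributed,
#'   hence non-negative.
#' @param rain_day_prob probability that a day receives rain.
#' @param rain_day_mean_mm mean daily rainfall total on rain days (mm).
#' @param ar1 lag-1 autocorrelation of day-level anomalies.
#' @param start_date first simulated date.
#' @param seed RNG seed; identical seeds give identical series.
#' @return a list of class `weather_gen_config`.
#' @export
weather_gen_config <- function(n_days = 100, records_per_day = 48,
                               temp_mean_c = 22.74, temp_daily_sd = 4.5,
                               temp_diurnal_amp = 6,
                               rh_mean_pct = 37.18, rh_daily_sd = 15,
                               rh_diurnal_amp = 12,
                               wind_mean_ms = 2.78,
                               rain_day_prob = 0.15, rain_day_mean_mm = 1.34,
                               ar1 = 0.6,
                               start_date = as.Date("2014-02-10"),
                               seed = 1L) {
  stopifnot(n_days >= 1, records_per_day >= 1,
            temp_daily_sd > 0, rh_daily_sd > 0, wind_mean_ms > 0,
            rain_day_prob >= 0, rain_day_prob <= 1, rain_day_mean_mm > 0,
            abs(ar1) < 1)
  structure(list(n_days = n_days, records_per_day = records_per_day,
                 temp_mean_c = temp_mean_c, temp_daily_sd = temp_daily_sd,
                 temp_diurnal_amp = temp_diurnal_amp,
                 rh_mean_pct = rh_mean_pct, rh_daily_sd = rh_daily_sd,
                 rh_diurnal_amp = rh_diurnal_amp,
                 wind_mean_ms = wind_mean_ms,
                 rain_day_prob = rain_day_prob,
                 rain_day_mean_mm = rain_day_mean_mm,
                 ar1 = ar1, start_date = as.Date(start_date),
                 seed = as.integer(seed)),
            class = "weather_gen_config")
}

.with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      old <- get(".Random.seed", envir = globalenv())
      on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
    } else {
      on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
    }
    set.seed(seed)
  }
  expr
}

.ar1_series <- function(n, phi, sd_marginal) {
  innov_sd <- sd_marginal * sqrt(1 - phi^2)
  z <- numeric(n)
  z[1] <- stats::rnorm(1, 0, sd_marginal)
  if (n > 1) {
    eps <- stats::rnorm(n - 1, 0, innov_sd)
    for (i in 2:n) z[i] <- phi * z[i - 1] + eps[i - 1]
  }
  z
}

#' Generate a seeded synthetic sub-daily weather series
#'
#' @param cfg a [weather_gen_config()].
#' @return a [weather_series()] with `n_days * records_per_day` records;
#'   record k of a day carries the interval ending at `k * 24 /
#'   records_per_day` hours, so a day spans (00:00, 24:00].
#' @export
generate_weather <- function(cfg = weather_gen_config()) {
  stopifnot(inherits(cfg, "weather_gen_config"))
  .with_seed(cfg$seed, {
    nd <- cfg$n_days; rpd <- cfg$records_per_day
    step_s <- 86400 / rpd
    t0 <- as.POSIXct(paste(format(cfg$start_date), "00:00:00"), tz = "UTC")
    ts <- t0 + seq_len(nd * rpd) * step_s
    hour <- (as.numeric(ts) - as.numeric(t0)) %% 86400 / 3600
    hour[hour == 0] <- 24
    day_idx <- rep(seq_len(nd), each = rpd)

    t_anom <- .ar1_series(nd, cfg$ar1, cfg$temp_daily_sd)
    h_anom <- .ar1_series(nd, cfg$ar1, cfg$rh_daily_sd)
    diurnal <- cos(2 * pi * (hour - 14) / 24)

    temp <- cfg$temp_mean_c + t_anom[day_idx] + cfg$temp_diurnal_amp * diurnal
    rh <- cfg$rh_mean_pct + h_anom[day_idx] - cfg$rh_diurnal_amp * diurnal
    rh <- pmin(pmax(rh, 5), 100)

    wind_day <- stats::rgamma(nd, shape = 4, rate = 4 / cfg$wind_mean_ms)
    wind <- stats::rgamma(nd * rpd, shape = 3, rate = 3 / wind_day[day_idx])

    rain <- numeric(nd * rpd)
    rainy <- stats::runif(nd) < cfg$rain_day_prob
    for (d in which(rainy)) {
      total <- stats::rexp(1, rate = 1 / cfg$rain_day_mean_mm)
      k <- min(stats::rpois(1, 4) + 1, rpd)
      start <- sample.int(rpd - k + 1, 1)
      w <- stats::rexp(k)
      rows <- (d - 1) * rpd + start + seq_len(k) - 1
      rain[rows] <- rain[rows] + total * w / sum(w)
    }

    weather_series(data.frame(timestamp = ts, temp_c = temp, rh_pct = rh,
                              wind_ms = wind, rain_mm = rain))
  })
}

#' Configuration for the synthetic moisture simulator
#'
#' Truth parameters for the Nelson/diffusion forward model used to
#' manufacture litter moisture series with known parameters for recovery
#' tests.
#'
#' @param true_alpha,true_beta Nelson equilibrium moisture parameters
#'   (percent intercept, percent per ln(J/g) slope).
#' @param true_lambda diffusion recursion weight in (0, 1).
#' @param noise_sd_pct SD of the additive Gaussian observation noise
#'   (percent moisture); results are truncated at 0.
#' @param initial_lmc_pct moisture on the first simulated day.
#' @param plot_id label attached to the simulated series.
#' @param seed RNG seed.
#' @return a list of class `moisture_gen_config`.
#' @export
moisture_gen_config <- function(true_alpha = 30, true_beta = -5,
                                true_lambda = 0.4, noise_sd_pct = 1,
                                initial_lmc_pct = 25, plot_id = "SYN1",
                                seed = 1L) {
  stopifnot(true_lambda > 0, true_lambda < 1, noise_sd_pct >= 0,
            initial_lmc_pct >= 0)
  structure(list(true_alpha = true_alpha, true_beta = true_beta,
                 true_lambda = true_lambda, noise_sd_pct = noise_sd_pct,
                 initial_lmc_pct = initial_lmc_pct,
                 plot_id = plot_id, seed = as.integer(seed)),
            class = "moisture_gen_config")
}

#' Forward-simulate a daily 14:00 litter moisture series
#'
#' Drives the discretized diffusion recursion with the Nelson equilibrium
#' moisture content computed from the trailing 24 h (lag-1) daily mean
#' temperature and relative humidity — the same convention [fit_direct()]
#' uses — and adds truncated Gaussian observation noise day by day. Noise
#' enters the recursion (each day starts from the previous *observed*
#' value), matching the one-step-ahead structure of the direct estimation
#' method.
#'
#' @param weather a [weather_series()] spanning the simulated days.
#' @param cfg a [moisture_gen_config()].
#' @param threshold_pct flagging threshold passed to [moisture_series()].
#' @return a [moisture_series()]; the first day of the weather span is used
#'   only to form the first lag-1 window, so the series starts on day 2.
#' @export
simulate_moisture <- function(weather, cfg = moisture_gen_config(),
                              threshold_pct = 35) {
  stopifnot(inherits(weather, "weather_series"),
            inherits(cfg, "moisture_gen_config"))
  days <- sort(unique(as.Date(weather$timestamp - 1, tz = "UTC")))
  days <- days[-1]                      # need a full lag-1 window
  feats <- lagged_features(weather, days, n_max = 1)
  ok <- is.finite(feats$T_1) & is.finite(feats$H_1)
  days <- days[ok]; feats <- feats[ok, , drop = FALSE]
  e <- nelson_emc(temp_k = feats$T_1 + 273.15, rh_frac = feats$H_1 / 100,
                  alpha = cfg$true_alpha, beta = cfg$true_beta)
  .with_seed(cfg$seed, {
    n <- length(e)
    lam <- cfg$true_lambda
    m <- numeric(n)
    noise <- if (cfg$noise_sd_pct > 0) stats::rnorm(n, 0, cfg$noise_sd_pct) else numeric(n)
    m[1] <- max(cfg$initial_lmc_pct + noise[1], 0)
    if (n > 1) {
      for (i in 2:n) {
        m[i] <- max(diffusion_step(m[i - 1], e[i - 1], e[i], lam) + noise[i], 0)
      }
    }
    moisture_series(cfg$plot_id, days, m, threshold_pct = threshold_pct)
  })
}
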