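# In-code fixture builders shared across the suite.

# Regular 30-min weather grid with constant or user-supplied fields.
make_weather <- function(n_days = 5, start = as.Date("2014-02-10"),
                         temp_c = 20, rh_pct = 40, wind_ms = 2, rain_mm = 0,
                         records_per_day = 48) {
  n <- n_days * records_per_day
  t0 <- as.POSIXct(paste(format(start), "00:00:00"), tz = "UTC")
  ts <- t0 + seq_len(n) * (86400 / records_per_day)
  weather_series(data.frame(
    timestamp = ts,
    temp_c = rep_len(temp_c, n),
    rh_pct = rep_len(rh_pct, n),
    wind_ms = rep_len(wind_ms, n),
    rain_mm = rep_len(rain_mm, n)))
}

weather_dates <- function(weather) {
  sort(unique(as.Date(weather$timestamp - 1, tz = "UTC")))
}

# Brute-force Spearman: mid-ranks then Pearson on the ranks.
spearman_bruteforce <- function(x, y) {
  rx <- rank(x); ry <- rank(y)
  sum((rx - mean(rx)) * (ry - mean(ry))) /
    sqrt(sum((rx - mean(rx))^2) * sum((ry - mean(ry))^2))
}

# Independent-noise feature table for stepwise selection tests: the 44
# canonical candidate names, each an iid N(0, 1) column.
make_noise_features <- function(n, n_max = 10) {
  nms <- unlist(lapply(c("T", "H", "W", "R"), function(el)
    paste0(el, "_", 0:n_max)))
  f <- as.data.frame(matrix(rnorm(n * length(nms)), nrow = n,
                            dimnames = list(NULL, nms)))
  f <- cbind(date = as.Date("2014-02-10") + seq_len(n) - 1, f)
  attr(f, "n_max") <- n_max
  class(f) <- c("lagged_features", "data.frame")
  f
}

make_moisture <- function(lmc, start = as.Date("2014-02-10"), plot = "P1") {
  moisture_series(plot, start + seq_along(lmc) - 1, lmc)
}
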