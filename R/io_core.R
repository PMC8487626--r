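#' littermoist: litter moisture content modelling for daily fire danger rating
#'
#' Models the daily moisture content of surface leaf litter (LMC, percent of
#' oven-dry mass) from sub-daily weather records. Three model families are
#' provided: stepwise multiple regression on lagged meteorological predictors
#' ([fit_stepwise()]), FFMC scale models and the log-log moisture-code
#' regression ([ffmc_series()], [scale_model()], [fit_mcode_regression()]),
#' and the semiphysical direct estimation method built on the Nelson
#' equilibrium moisture content model and an exponential time-lag diffusion
#' recursion ([fit_direct()]). A seeded synthetic generator
#' ([generate_weather()], [simulate_moisture()]) emulates the dry-season
#' regime of a Yunnan pine-forest field campaign so the full pipeline is
#' testable without field data, and [error_metrics()], [cross_validate()] and
#' [extrapolation_matrix()] implement the evaluation protocol.
#'
#' @keywords internal
"_PACKAGE"

.weather_cols <- c("timestamp", "temp_c", "rh_pct", "wind_ms", "rain_mm")
.moisture_cols <- c("plot_id", "date", "lmc_pct")

#' Construct and validate a weather series
#'
#' A weather series is a data frame of sub-daily meteorological records for
#' one site: `timestamp` (POSIXct), `temp_c` (air temperature, deg C),
#' `rh_pct` (relative humidity, 0-100), `wind_ms` (wind speed, m/s, >= 0)
#' and `rain_mm` (rainfall accumulated over the record interval, mm, >= 0).
#'
#' @param x data frame with the five weather columns.
#' @return the validated data frame with class `weather_series`.
#' @export
weather_series <- function(x) {
  stopifnot(is.data.frame(x))
  missing <- setdiff(.weather_cols, names(x))
  if (length(missing) > 0) {
    stop("configuration error: missing weather column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  x <- as.data.frame(x)[, .weather_cols]
  if (!inherits(x$timestamp, "POSIXct")) {
    stop("timestamp column must be POSIXct", call. = FALSE)
  }
  bad <- which(!is.finite(x$temp_c))
  if (length(bad) > 0) {
    stop("non-finite temperature at row(s): ", .row_list(bad), call. = FALSE)
  }
  bad <- which(!is.finite(x$rh_pct) | x$rh_pct < 0 | x$rh_pct > 100)
  if (length(bad) > 0) {
    stop("relative humidity outside [0, 100] at row(s): ", .row_list(bad),
         call. = FALSE)
  }
  bad <- which(!is.finite(x$wind_ms) | x$wind_ms < 0)
  if (length(bad) > 0) {
    stop("negative or non-finite wind speed at row(s): ", .row_list(bad),
         call. = FALSE)
  }
  bad <- which(!is.finite(x$rain_mm) | x$rain_mm < 0)
  if (length(bad) > 0) {
    stop("negative or non-finite rainfall at row(s): ", .row_list(bad),
         call. = FALSE)
  }
  dt <- diff(as.numeric(x$timestamp))
  bad <- which(dt <= 0)
  if (length(bad) > 0) {
    stop("timestamps not strictly increasing at row(s): ",
         .row_list(bad + 1L), call. = FALSE)
  }
  rownames(x) <- NULL
  class(x) <- c("weather_series", "data.frame")
  x
}

.row_list <- function(idx, max_show = 10L) {
  shown <- utils::head(idx, max_show)
  out <- paste(shown, collapse = ", ")
  if (length(idx) > max_show) out <- paste0(out, ", ... (", length(idx), " total)")
  out
}

.apply_column_map <- function(df, column_map, required, what) {
  if (!is.null(column_map)) {
    for (std in names(column_map)) {
      src <- column_map[[std]]
      if (!src %in% names(df)) {
        stop("configuration error: ", what, " file has no column '", src,
             "' (mapped to '", std, "')", call. = FALSE)
      }
      names(df)[names(df) == src] <- std
    }
  }
  missing <- setdiff(required, names(df))
  if (length(missing) > 0) {
    stop("configuration error: ", what, " file missing required column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  df
}

#' Read a weather series from delimited text
#'
#' Reads a comma-separated file with a header row and ISO-8601 timestamps.
#' Column names can be remapped via `column_map`, a named list/character
#' vector whose names are the standard names (`timestamp`, `temp_c`,
#' `rh_pct`, `wind_ms`, `rain_mm`) and whose values are the names used in
#' the file. Rows with unparseable fields raise an error naming the rows;
#' nothing is silently dropped.
#'
#' @param path file path.
#' @param column_map optional named list remapping file columns.
#' @param tz time zone for timestamps (default UTC).
#' @return a [weather_series()].
#' @export
read_weather <- function(path, column_map = NULL, tz = "UTC") {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  df <- .apply_column_map(df, column_map, .weather_cols, "weather")
  ts <- as.POSIXct(df$timestamp, tz = tz,
                   tryFormats = c("%Y-%m-%dT%H:%M:%OS", "%Y-%m-%d %H:%M:%OS",
                                  "%Y-%m-%dT%H:%M", "%Y-%m-%d %H:%M"))
  bad <- which(is.na(ts) & !is.na(df$timestamp))
  if (length(bad) > 0) {
    stop("unparseable timestamp at row(s): ", .row_list(bad), call. = FALSE)
  }
  df$timestamp <- ts
  for (col in setdiff(.weather_cols, "timestamp")) {
    v <- suppressWarnings(as.numeric(df[[col]]))
    bad <- which(is.na(v) & !is.na(df[[col]]))
    if (length(bad) > 0) {
      stop("unparseable ", col, " at row(s): ", .row_list(bad), call. = FALSE)
    }
    df[[col]] <- v
  }
  weather_series(df)
}

#' Write a weather series to comma-separated text
#'
#' @param weather a [weather_series()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_weather <- function(weather, path) {
  out <- as.data.frame(weather)
  out$timestamp <- format(out$timestamp, "%Y-%m-%dT%H:%M:%S")
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Construct and validate a daily litter moisture series for one plot
#'
#' @param plot_id plot label.
#' @param date vector of calendar dates (`Date`), strictly increasing.
#' @param lmc_pct litter moisture content, percent of oven-dry mass, >= 0.
#' @param threshold_pct analysis threshold used to flag low-moisture days
#'   (default 35); days with `lmc_pct < threshold_pct` get
#'   `below_threshold = TRUE`.
#' @return data frame (`plot_id`, `date`, `lmc_pct`, `below_threshold`) with
#'   class `moisture_series`.
#' @export
moisture_series <- function(plot_id, date, lmc_pct, threshold_pct = 35) {
  date <- as.Date(date)
  stopifnot(length(date) == length(lmc_pct))
  bad <- which(!is.finite(lmc_pct) | lmc_pct < 0)
  if (length(bad) > 0) {
    stop("negative or non-finite LMC at row(s): ", .row_list(bad),
         call. = FALSE)
  }
  if (anyDuplicated(date)) {
    stop("duplicate observation date(s) for plot '", plot_id[1], "': ",
         paste(utils::head(unique(date[duplicated(date)]), 5), collapse = ", "),
         call. = FALSE)
  }
  o <- order(date)
  x <- data.frame(plot_id = as.character(plot_id)[1],
                  date = date[o],
                  lmc_pct = as.numeric(lmc_pct)[o],
                  below_threshold = as.numeric(lmc_pct)[o] < threshold_pct,
                  stringsAsFactors = FALSE)
  attr(x, "threshold_pct") <- threshold_pct
  class(x) <- c("moisture_series", "data.frame")
  x
}

#' Read daily litter moisture observations, one series per plot
#'
#' Expects comma-separated text with a header and columns `plot_id`, `date`
#' (ISO-8601) and `lmc_pct` (remappable via `column_map`). Duplicate
#' (plot, date) pairs and negative moisture values are errors.
#'
#' @inheritParams read_weather
#' @param threshold_pct flagging threshold passed to [moisture_series()].
#' @return named list of [moisture_series()], one element per plot, in order
#'   of first appearance.
#' @export
read_moisture <- function(path, column_map = NULL, threshold_pct = 35) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  df <- .apply_column_map(df, column_map, .moisture_cols, "moisture")
  d <- as.Date(df$date, tryFormats = c("%Y-%m-%d", "%Y/%m/%d"))
  bad <- which(is.na(d) & !is.na(df$date))
  if (length(bad) > 0) {
    stop("unparseable date at row(s): ", .row_list(bad), call. = FALSE)
  }
  v <- suppressWarnings(as.numeric(df$lmc_pct))
  bad <- which(is.na(v) & !is.na(df$lmc_pct))
  if (length(bad) > 0) {
    stop("unparseable lmc_pct at row(s): ", .row_list(bad), call. = FALSE)
  }
  plots <- unique(df$plot_id)
  out <- lapply(plots, function(p) {
    sel <- df$plot_id == p
    moisture_series(p, d[sel], v[sel], threshold_pct = threshold_pct)
  })
  names(out) <- plots
  out
}

#' Write one or more moisture series to comma-separated text
#'
#' @param moisture a [moisture_series()] or a list of them.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_moisture <- function(moisture, path) {
  if (inherits(moisture, "moisture_series")) moisture <- list(moisture)
  out <- do.call(rbind, lapply(moisture, function(m) {
    data.frame(plot_id = m$plot_id, date = format(m$date, "%Y-%m-%d"),
               lmc_pct = m$lmc_pct, stringsAsFactors = FALSE)
  }))
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Litter moisture content from wet and dry weights
#'
#' Gravimetric moisture content as a percentage of oven-dry mass:
#' `100 * (wet_g - dry_g) / dry_g`.
#'
#' @param wet_g fresh (wet) weight, g, >= 0.
#' @param dry_g oven-dry weight, g, > 0.
#' @return moisture content in percent.
#' @examples
#' lmc_from_weights(60, 50) # 20
#' @export
lmc_from_weights <- function(wet_g, dry_g) {
  if (any(!is.finite(dry_g)) || any(dry_g <= 0)) {
    stop("dry weight must be finite and > 0", call. = FALSE)
  }
  if (any(!is.finite(wet_g)) || any(wet_g < 0)) {
    stop("wet weight must be finite and >= 0", call. = FALSE)
  }
  100 * (wet_g - dry_g) / dry_g
}

#' Restrict a moisture series to fire-relevant (dry) days
#'
#' Fires are unlikely to ignite in litter wetter than about 35 percent, so
#' the analysis is restricted to days with `lmc_pct` strictly below the
#' threshold. The comparison is strict (`<`), configurable via
#' `threshold_pct`; dates are preserved so gaps left by removed wet days
#' remain detectable downstream.
#'
#' @param moisture a [moisture_series()].
#' @param threshold_pct threshold in percent (default 35).
#' @return the filtered [moisture_series()].
#' @export
filter_below_threshold <- function(moisture, threshold_pct = 35) {
  stopifnot(inherits(moisture, "moisture_series"))
  keep <- moisture$lmc_pct < threshold_pct
  out <- moisture[keep, , drop = FALSE]
  rownames(out) <- NULL
  out$below_threshold <- out$lmc_pct < threshold_pct
  attr(out, "threshold_pct") <- threshold_pct
  class(out) <- c("moisture_series", "data.frame")
  out
}

#' Packaged reference tables from the Yunnan field campaign
#'
#' Machine-readable copies of the published summary tables of a 100-day
#' dry-season litter moisture campaign in eight pine/cypress plots near
#' Kunming (Yunnan Province, China), used as validation fixtures:
#' \describe{
#'   \item{weather_summary}{mean/median/max/min of daily temperature,
#'     relative humidity, wind speed and rainfall over the campaign.}
#'   \item{plot_lmc_stats}{per-plot day counts and LMC summary statistics
#'     after the 35 percent filter.}
#'   \item{scale_model_direct_use}{paired t-tests and errors of the raw FF
#'     and FX scale-model predictions against measured LMC.}
#'   \item{mcode_regression_fits}{fitted power-law moisture-code regressions
#'     (alpha, beta, R2) and their errors, per plot and scale variant.}
#'   \item{met_regression_fits}{stepwise meteorological regressions: the
#'     intercept, single selected lagged predictor and its coefficient,
#'     with errors.}
#'   \item{direct_estimation_fits}{Nelson/diffusion direct-estimation fits:
#'     alpha, beta, lambda, the implied time lag tau (h), and errors.}
#' }
#'
#' @param name which table to load.
#' @return a data frame.
#' @export
reference_table <- function(name = c("weather_summary", "plot_lmc_stats",
                                     "scale_model_direct_use",
                                     "mcode_regression_fits",
                                     "met_regression_fits",
                                     "direct_estimation_fits")) {
  name <- match.arg(name)
  path <- system.file("extdata", paste0(name, ".csv"),
                      package = "littermoist", mustWork = TRUE)
  utils::read.csv(path, stringsAsFactors = FALSE)
}
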