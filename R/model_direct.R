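#' Nelson equilibrium moisture content
#'
#' The Nelson model expresses the equilibrium moisture content (EMC) of a
#' dead fuel as a linear function of the log of the Gibbs free energy of
#' the water vapour exchange:
#' `E = alpha + beta * ln( -(R * T / m) * ln(H) )`,
#' with `R = 8.314` J/(K mol), `m = 18.0153` g/mol, `T` the air temperature
#' in Kelvin and `H` the relative humidity as a fraction. `H` is clamped to
#' `[0.001, 0.999]` so the inner logarithm stays finite at the dry and
#' saturated extremes.
#'
#' @param temp_k air temperature, Kelvin (> 0).
#' @param rh_frac relative humidity as a fraction; clamped to [0.001, 0.999].
#' @param alpha EMC at a Gibbs free energy of 1 J/g (percent).
#' @param beta EMC change per ln(J/g) (percent); its magnitude measures how
#'   sensitively the fuel tracks the atmosphere.
#' @return equilibrium moisture content, percent.
#' @examples
#' nelson_emc(298.15, 0.5, alpha = 28.57, beta = -4.83)
#' @export
nelson_emc <- function(temp_k, rh_frac, alpha, beta) {
  if (any(!is.finite(temp_k)) || any(temp_k <= 0)) {
    stop("temperature must be finite and > 0 K", call. = FALSE)
  }
  h <- pmin(pmax(rh_frac, 0.001), 0.999)
  alpha + beta * log(gibbs_energy(temp_k, h))
}

#' Gibbs free-energy term of the Nelson model
#'
#' `-(R * T / m) * ln(H)` in J/g, the quantity whose natural log the Nelson
#' EMC is linear in.
#'
#' @inheritParams nelson_emc
#' @return free energy, J/g.
#' @export
gibbs_energy <- function(temp_k, rh_frac) {
  h <- pmin(pmax(rh_frac, 0.001), 0.999)
  -(8.314 * temp_k / 18.0153) * log(h)
}

#' One step of the discretized water diffusion recursion
#'
#' Daily update of litter moisture toward equilibrium:
#' `M_i = lambda^2 * M_{i-1} + lambda * (1 - lambda) * E_{i-1} +
#' (1 - lambda) * E_i`. The three coefficients sum to one for every
#' `lambda`, so the prediction is a convex combination of the previous
#' moisture and the two equilibrium values.
#'
#' @param m_prev_pct previous-day moisture, percent.
#' @param e_prev_pct,e_cur_pct previous-day and current-day equilibrium
#'   moisture content, percent.
#' @param lambda_ recursion weight in (0, 1); related to the fuel time lag
#'   by [lambda_from_tau()].
#' @return current-day moisture, percent.
#' @export
diffusion_step <- function(m_prev_pct, e_prev_pct, e_cur_pct, lambda_) {
  if (any(lambda_ < 0) || any(lambda_ > 1)) {
    stop("lambda must lie in [0, 1]", call. = FALSE)
  }
  lambda_^2 * m_prev_pct + lambda_ * (1 - lambda_) * e_prev_pct +
    (1 - lambda_) * e_cur_pct
}

#' Convert between the diffusion weight lambda and the fuel time lag tau
#'
#' The recursion weight of the discretized diffusion equation relates to
#' the exponential response time lag by `lambda = exp(-dt / (2 * tau))`,
#' i.e. `tau = -dt / (2 * ln(lambda))`, with `dt` the model time step in
#' hours. `tau` is the time the fuel takes to close `1 - 1/e` of the gap to
#' equilibrium.
#'
#' @param lambda_ recursion weight in (0, 1), exclusive.
#' @param dt_h time step in hours (default 24).
#' @return `tau_from_lambda`: time lag in hours. `lambda_from_tau`: the
#'   recursion weight.
#' @examples
#' tau_from_lambda(exp(-1), 24) # 12 h
#' @export
tau_from_lambda <- function(lambda_, dt_h = 24) {
  if (any(!is.finite(lambda_)) || any(lambda_ <= 0) || any(lambda_ >= 1)) {
    stop("lambda must lie strictly in (0, 1)", call. = FALSE)
  }
  stopifnot(dt_h > 0)
  -dt_h / (2 * log(lambda_))
}

#' @rdname tau_from_lambda
#' @param tau_h time lag in hours (> 0).
#' @export
lambda_from_tau <- function(tau_h, dt_h = 24) {
  if (any(!is.finite(tau_h)) || any(tau_h <= 0)) {
    stop("tau must be finite and > 0", call. = FALSE)
  }
  stopifnot(dt_h > 0)
  exp(-dt_h / (2 * tau_h))
}

.direct_design <- function(moisture, features) {
  idx <- match(moisture$date, features$date)
  t1 <- features$T_1[idx]
  h1 <- features$H_1[idx]
  g <- log(gibbs_energy(t1 + 273.15, h1 / 100))
  d <- data.frame(date = moisture$date, m = moisture$lmc_pct, g = g)
  prev <- match(d$date - 1, d$date)
  ok <- !is.na(prev) & is.finite(d$g) & is.finite(d$g[prev])
  data.frame(date = d$date[ok], m = d$m[ok], m_prev = d$m[prev[ok]],
             g = d$g[ok], g_prev = d$g[prev[ok]])
}

#' Fit the direct estimation model by nonlinear least squares
#'
#' Fits `(alpha, beta, lambda)` of the Nelson/diffusion model by minimizing
#' the sum of squared one-step-ahead errors
#' `sum( M_i - [lambda^2 M_{i-1} + lambda (1-lambda) E_{i-1} +
#' (1-lambda) E_i] )^2`, where the previous-day moisture is the *observed*
#' value (teacher forcing) and `E = alpha + beta * g` with `g` the
#' log-Gibbs-energy from the trailing 24 h (lag-1) daily mean temperature
#' and humidity. Only days whose previous calendar day is also observed and
#' has usable weather enter the sum. Because the model is linear in
#' `(alpha, beta)` for fixed `lambda`, the fit profiles them out with
#' ordinary least squares and minimizes the one-dimensional profiled SSE
#' over `lambda` (coarse grid then local refinement), which is
#' deterministic and cannot diverge.
#'
#' @param moisture a [moisture_series()] (typically already passed through
#'   [filter_below_threshold()]).
#' @param features a [lagged_features()] table covering the moisture dates
#'   (only the lag-1 columns are used).
#' @param dt_h model time step in hours (default 24; determines the
#'   reported time lag).
#' @param lambda_bounds search interval for lambda.
#' @param min_pairs minimum usable consecutive-day pairs (default 8).
#' @return an object of class `direct_model`: list with `alpha`, `beta`,
#'   `lambda`, `dt_h`, `tau_h`, `sse`, `n`, `converged`, `identifiable`.
#' @export
fit_direct <- function(moisture, features, dt_h = 24,
                       lambda_bounds = c(1e-6, 1 - 1e-6), min_pairs = 8) {
  stopifnot(inherits(moisture, "moisture_series"))
  d <- .direct_design(moisture, features)
  n <- nrow(d)
  if (n < min_pairs) {
    stop("insufficient data: ", n, " usable consecutive-day pairs (need >= ",
         min_pairs, ")", call. = FALSE)
  }
  identifiable <- stats::sd(d$g) > 1e-8 && stats::sd(c(d$m, d$m_prev)) > 1e-8

  profile_fit <- function(lam) {
    y <- d$m - lam^2 * d$m_prev
    X <- cbind(const = rep(1 - lam^2, n),
               g = lam * (1 - lam) * d$g_prev + (1 - lam) * d$g)
    fit <- stats::lm.fit(X, y)
    list(sse = sum(fit$residuals^2), coef = fit$coefficients)
  }
  sse_of <- function(lam) profile_fit(lam)$sse

  grid <- seq(max(lambda_bounds[1], 0.01), min(lambda_bounds[2], 0.99),
              by = 0.01)
  sse_grid <- vapply(grid, sse_of, numeric(1))
  lam0 <- grid[which.min(sse_grid)]
  lo <- max(lambda_bounds[1], lam0 - 0.02)
  hi <- min(lambda_bounds[2], lam0 + 0.02)
  opt <- stats::optimize(sse_of, interval = c(lo, hi), tol = 1e-10)
  lam <- opt$minimum
  best <- profile_fit(lam)
  coef <- best$coef
  structure(list(alpha = unname(coef["const"]), beta = unname(coef["g"]),
                 lambda = lam, dt_h = dt_h,
                 tau_h = tau_from_lambda(lam, dt_h),
                 sse = best$sse, n = n, converged = TRUE,
                 identifiable = identifiable),
            class = "direct_model")
}

#' @export
print.direct_model <- function(x, ...) {
  cat("Direct estimation model (Nelson EMC + diffusion recursion)\n")
  cat(sprintf("  alpha = %.4f  beta = %.4f  lambda = %.4f\n",
              x$alpha, x$beta, x$lambda))
  cat(sprintf("  time step %.0f h -> time lag tau = %.2f h\n", x$dt_h, x$tau_h))
  cat(sprintf("  SSE = %.4f over n = %d one-step pairs\n", x$sse, x$n))
  if (!x$identifiable) cat("  WARNING: parameters not identifiable (degenerate inputs)\n")
  invisible(x)
}

#' Equilibrium moisture content series implied by a direct model
#'
#' @param model a `direct_model`.
#' @param features a [lagged_features()] table.
#' @return data frame `date`, `emc_pct`.
#' @export
emc_series <- function(model, features) {
  g <- log(gibbs_energy(features$T_1 + 273.15, features$H_1 / 100))
  data.frame(date = features$date, emc_pct = model$alpha + model$beta * g)
}

#' Predict litter moisture with a fitted direct model
#'
#' `one_step` mode predicts each day from the *observed* previous-day
#' moisture (the operational forecasting setting: yesterday's measurement
#' plus today's weather); days without an observed previous day are NA.
#' `free_run` mode recurses on the model's own predictions starting from
#' `m_init_pct`. Negative predictions are clamped to 0 and flagged.
#'
#' @param model a `direct_model` from [fit_direct()].
#' @param features a [lagged_features()] table for the prediction days.
#' @param moisture a [moisture_series()] supplying observed previous-day
#'   values (required for `one_step`).
#' @param mode `"one_step"` or `"free_run"`.
#' @param m_init_pct starting moisture for `free_run`.
#' @return data frame of class `direct_prediction`: `date`, `lmc_pred`,
#'   `clamped`.
#' @export
predict_direct <- function(model, features, moisture = NULL,
                           mode = c("one_step", "free_run"),
                           m_init_pct = NULL) {
  mode <- match.arg(mode)
  stopifnot(inherits(model, "direct_model"))
  e <- emc_series(model, features)
  e <- e[order(e$date), , drop = FALSE]
  lam <- model$lambda
  n <- nrow(e)
  pred <- rep(NA_real_, n)
  if (mode == "one_step") {
    if (is.null(moisture)) {
      stop("one_step prediction needs the observed moisture series", call. = FALSE)
    }
    prev_obs <- moisture$lmc_pct[match(e$date - 1, moisture$date)]
    e_prev <- e$emc_pct[match(e$date - 1, e$date)]
    pred <- diffusion_step(prev_obs, e_prev, e$emc_pct, lam)
  } else {
    if (is.null(m_init_pct)) {
      stop("free_run prediction needs m_init_pct", call. = FALSE)
    }
    m <- m_init_pct
    for (i in seq_len(n)) {
      if (i == 1 || !is.finite(e$emc_pct[i - 1])) {
        pred[i] <- if (is.finite(e$emc_pct[i])) {
          diffusion_step(m, e$emc_pct[i], e$emc_pct[i], lam)
        } else NA_real_
      } else {
        pred[i] <- diffusion_step(m, e$emc_pct[i - 1], e$emc_pct[i], lam)
      }
      if (is.finite(pred[i])) m <- pred[i]
    }
  }
  clamped <- is.finite(pred) & pred < 0
  pred[clamped] <- 0
  out <- data.frame(date = e$date, lmc_pred = pred, clamped = clamped)
  class(out) <- c("direct_prediction", "data.frame")
  out
}

#' Serialize a fitted model to a plain-text key-value file
#'
#' Works for `direct_model`, `metreg_model` and `mcode_model` objects; each
#' scalar field becomes a `key = value` line.
#'
#' @param model a fitted model object.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_model_kv <- function(model, path) {
  flat <- unlist(model)
  lines <- paste(names(flat), unname(vapply(flat, format, character(1),
                                            digits = 17)), sep = " = ")
  writeLines(c(paste0("# class: ", class(model)[1]), lines), path)
  invisible(path)
}
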