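test_that("Nelson equilibrium moisture content matches hand arithmetic", {
  # T = 298.15 K, H = 0.5: Gibbs term = (8.314 * 298.15 / 18.0153) * ln 2
  dg <- (8.314 * 298.15 / 18.0153) * log(2)
  expect_equal(gibbs_energy(298.15, 0.5), dg, tolerance = 1e-12)
  expect_equal(dg, 95.38, tolerance = 1e-3)
  expect_equal(nelson_emc(298.15, 0.5, 28.57, -4.83),
               28.57 - 4.83 * log(dg), tolerance = 1e-12)
  expect_equal(nelson_emc(298.15, 0.5, 28.57, -4.83), 6.55, tolerance = 0.01)

  # a Gibbs energy of exactly 1 J/g returns alpha
  # solve H from (RT/m) * (-ln H) = 1 at T = 298.15
  h1 <- exp(-1 / (8.314 * 298.15 / 18.0153))
  expect_equal(nelson_emc(298.15, h1, 28.57, -4.83), 28.57, tolerance = 1e-10)

  # near saturation the clamp keeps the result finite
  expect_equal(nelson_emc(298.15, 0.99, 28.57, -4.83), 27.0, tolerance = 0.01)
  expect_true(is.finite(nelson_emc(298.15, 1.0, 28.57, -4.83)))
  expect_true(is.finite(nelson_emc(298.15, 0, 28.57, -4.83)))
  expect_error(nelson_emc(-3, 0.5, 28.57, -4.83), "temperature")
})

test_that("diffusion step is a convex combination with coefficients summing to 1", {
  expect_equal(diffusion_step(20, 10, 10, 0.5), 12.5)
  for (lam in seq(0.05, 0.95, by = 0.1)) {
    expect_equal(diffusion_step(7, 7, 7, lam), 7, tolerance = 1e-12)
    expect_equal(lam^2 + lam * (1 - lam) + (1 - lam), 1, tolerance = 1e-15)
  }
  expect_equal(diffusion_step(20, 10, 13, 0), 13)  # lambda -> 0 limit
  set.seed(4)
  for (i in 1:50) {
    v <- runif(3, 0, 40); lam <- runif(1)
    m <- diffusion_step(v[1], v[2], v[3], lam)
    expect_gte(m, min(v) - 1e-12)
    expect_lte(m, max(v) + 1e-12)
  }
})

test_that("lambda <-> tau conversion round-trips and matches reference fits", {
  expect_equal(tau_from_lambda(exp(-1), 24), 12)
  set.seed(5)
  lams <- runif(50, 0.01, 0.99)
  expect_equal(lambda_from_tau(tau_from_lambda(lams, 24), 24), lams,
               tolerance = 1e-12)
  taus <- runif(50, 1, 100)
  expect_equal(tau_from_lambda(lambda_from_tau(taus, 24), 24), taus,
               tolerance = 1e-12)
  expect_error(tau_from_lambda(0), "lambda")
  expect_error(tau_from_lambda(1), "lambda")

  # the printed time lags of all eight reference fits are consistent with
  # tau = -dt / (2 ln lambda) up to the two-decimal rounding of lambda
  ref <- reference_table("direct_estimation_fits")
  tau_implied <- tau_from_lambda(ref$lambda, 24)
  expect_true(all(abs(tau_implied - ref$tau_h) / ref$tau_h < 0.016))
  expect_equal(tau_from_lambda(0.36, 24), 11.78, tolerance = 0.05)
  expect_equal(tau_from_lambda(0.41, 24), 13.54, tolerance = 0.09)
})

test_that("fit recovers truth exactly on noiseless simulated data", {
  w <- generate_weather(weather_gen_config(n_days = 120, seed = 7))
  truth <- moisture_gen_config(true_alpha = 30, true_beta = -5,
                               true_lambda = 0.4, noise_sd_pct = 0, seed = 7)
  m <- simulate_moisture(w, truth)
  f <- lagged_features(w, m$date, n_max = 1)
  fit <- fit_direct(m, f)
  expect_true(fit$converged)
  expect_true(fit$identifiable)
  expect_equal(fit$lambda, 0.4, tolerance = 1e-4)
  expect_equal(fit$alpha, 30, tolerance = 1e-4)
  expect_equal(fit$beta, -5, tolerance = 1e-4)
  expect_lt(fit$sse, 1e-8)
})

test_that("noisy recovery: lambda bias shrinks as noise shrinks", {
  w <- generate_weather(weather_gen_config(n_days = 100, seed = 17))
  errs <- vapply(c(2, 0.5, 0.05), function(sd) {
    m <- simulate_moisture(w, moisture_gen_config(noise_sd_pct = sd,
                                                  seed = 17))
    fit <- fit_direct(m, lagged_features(w, m$date, n_max = 1))
    abs(fit$lambda - 0.4)
  }, numeric(1))
  expect_lt(errs[3], 0.01)
  expect_lt(errs[3], errs[1] + 1e-9)
})

test_that("degenerate constant inputs are flagged non-identifiable", {
  w <- make_weather(30, temp_c = 25, rh_pct = 50)
  dates <- weather_dates(w)[-1]
  f <- lagged_features(w, dates, n_max = 1)
  m <- moisture_series("P", dates, rep(10, length(dates)))
  fit <- fit_direct(m, f)
  expect_false(fit$identifiable)
})

test_that("too few pairs raise an insufficient-data error", {
  w <- make_weather(6)
  dates <- weather_dates(w)[-1]
  m <- moisture_series("P", dates, 20 + seq_along(dates))
  f <- lagged_features(w, dates, n_max = 1)
  expect_error(fit_direct(m, f), "insufficient data")
})

test_that("one-step prediction on training data reproduces the fitted SSE", {
  w <- generate_weather(weather_gen_config(n_days = 60, seed = 19))
  m <- simulate_moisture(w, moisture_gen_config(noise_sd_pct = 1, seed = 19))
  f <- lagged_features(w, m$date, n_max = 1)
  fit <- fit_direct(m, f)
  pred <- predict_direct(fit, f, moisture = m, mode = "one_step")
  idx <- match(m$date, pred$date)
  resid <- m$lmc_pct - pred$lmc_pred[idx]
  expect_equal(sum(resid^2, na.rm = TRUE), fit$sse, tolerance = 1e-8)
})

test_that("free-run prediction approaches equilibrium geometrically", {
  w <- make_weather(30, temp_c = 25, rh_pct = 50)
  dates <- weather_dates(w)[-1]
  f <- lagged_features(w, dates, n_max = 1)
  model <- structure(list(alpha = 28.57, beta = -4.83, lambda = 0.6,
                          dt_h = 24, tau_h = tau_from_lambda(0.6),
                          sse = 0, n = 0, converged = TRUE,
                          identifiable = TRUE), class = "direct_model")
  e_const <- nelson_emc(298.15, 0.5, 28.57, -4.83)
  pred <- predict_direct(model, f, mode = "free_run", m_init_pct = 30)
  gaps <- abs(pred$lmc_pred - e_const)
  r <- (gaps[-1] / gaps[-length(gaps)])[1:10]
  expect_equal(r, rep(0.36, 10), tolerance = 1e-6)  # ratio lambda^2
  # lambda = 0 predicts today's equilibrium regardless of history
  model0 <- model; model0$lambda <- 0
  pred0 <- predict_direct(model0, f, mode = "free_run", m_init_pct = 99)
  expect_equal(pred0$lmc_pred, rep(e_const, nrow(pred0)), tolerance = 1e-12)
})

test_that("negative predictions are clamped and flagged", {
  w <- make_weather(10, temp_c = 30, rh_pct = 10)  # very dry: low EMC
  dates <- weather_dates(w)[-1]
  f <- lagged_features(w, dates, n_max = 1)
  model <- structure(list(alpha = -5, beta = -1, lambda = 0.3, dt_h = 24,
                          tau_h = tau_from_lambda(0.3), sse = 0, n = 0,
                          converged = TRUE, identifiable = TRUE),
                     class = "direct_model")
  pred <- predict_direct(model, f, mode = "free_run", m_init_pct = 1)
  expect_true(all(pred$lmc_pred >= 0))
  expect_true(any(pred$clamped))
})

test_that("model serialization writes readable key-value text", {
  path <- withr::local_tempfile(fileext = ".txt")
  model <- structure(list(alpha = 28.57, beta = -4.83, lambda = 0.41,
                          dt_h = 24, tau_h = tau_from_lambda(0.41), sse = 1.5,
                          n = 80, converged = TRUE, identifiable = TRUE),
                     class = "direct_model")
  write_model_kv(model, path)
  lines <- readLines(path)
  kv <- strsplit(grep(" = ", lines, value = TRUE), " = ")
  vals <- setNames(vapply(kv, `[`, character(1), 2),
                   vapply(kv, `[`, character(1), 1))
  expect_equal(as.numeric(vals[["alpha"]]), 28.57)
  expect_equal(as.numeric(vals[["lambda"]]), 0.41)
  expect_equal(as.numeric(vals[["tau_h"]]), tau_from_lambda(0.41))
})
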