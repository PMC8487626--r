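#' Stepwise multiple regression of LMC on lagged meteorological predictors
#'
#' Forward-entry / backward-removal stepwise ordinary least squares over
#' the candidate set of lagged predictors (`T_0..T_n`, `H_0..H_n`,
#' `W_0..W_n`, `R_0..R_n`). At each entry step the candidate with the
#' smallest partial-F p-value is introduced if that p-value clears
#' `p_enter` after a Bonferroni adjustment for the number of candidates
#' examined at the step, which keeps the per-step probability of admitting
#' a pure-noise predictor near `p_enter` regardless of how many candidates
#' compete. After every entry, predictors already in the model whose
#' partial-F p-value exceeds `p_remove` are eliminated (largest first)
#' until none remains, so the final model never carries a predictor with
#' p > `p_remove`. Candidates whose variance inflation factor against the
#' current model exceeds `vif_limit` are skipped, guarding against serious
#' multicollinearity. Ties are broken by the canonical candidate order
#' (temperature, humidity, wind, rainfall; ascending lag), so the
#' selection is deterministic and invariant to row order.
#'
#' @param moisture a [moisture_series()].
#' @param features a [lagged_features()] table.
#' @param p_enter entry threshold on the (adjusted) partial-F p-value
#'   (default 0.05).
#' @param p_remove removal threshold (default 0.10).
#' @param vif_limit variance inflation factor above which a candidate is
#'   skipped (default 10).
#' @param adjust_entry apply the Bonferroni adjustment at entry
#'   (default TRUE).
#' @return object of class `metreg_model`: `intercept`, named
#'   `coefficients`, `r2`, `n`, and a selection `trace` data frame.
#' @export
fit_stepwise <- function(moisture, features, p_enter = 0.05, p_remove = 0.10,
                         vif_limit = 10, adjust_entry = TRUE) {
  stopifnot(inherits(moisture, "moisture_series"))
  cand_all <- feature_names(features)
  cand_all <- cand_all[cand_all %in% names(features)]
  idx <- match(moisture$date, features$date)
  dat <- cbind(data.frame(lmc = moisture$lmc_pct),
               as.data.frame(features)[idx, cand_all, drop = FALSE])
  dat <- dat[stats::complete.cases(dat), , drop = FALSE]
  n <- nrow(dat)
  # drop constant candidates up front: no variance, nothing to test
  cand_all <- cand_all[vapply(cand_all, function(v) stats::sd(dat[[v]]) > 0,
                              logical(1))]

  selected <- character(0)
  trace <- list()
  step_no <- 0L

  partial_p <- function(vars, var) {
    fit <- stats::lm(stats::reformulate(vars, "lmc"), data = dat)
    cf <- summary(fit)$coefficients
    if (!var %in% rownames(cf)) return(NA_real_)  # aliased
    cf[var, 4]
  }

  repeat {
    changed <- FALSE
    pool <- setdiff(cand_all, selected)
    if (n > length(selected) + 2 && length(pool) > 0) {
      usable <- character(0)
      pvals <- numeric(0)
      for (v in pool) {
        if (length(selected) > 0) {
          r2v <- summary(stats::lm(stats::reformulate(selected, v),
                                   data = dat))$r.squared
          if (r2v > 1 - 1 / vif_limit) next  # VIF = 1/(1-R2) > limit
        }
        p <- partial_p(c(selected, v), v)
        if (is.na(p)) next
        usable <- c(usable, v)
        pvals <- c(pvals, p)
      }
      if (length(usable) > 0) {
        best <- which.min(pvals)  # which.min takes the first: canonical order
        thr <- if (adjust_entry) p_enter / length(usable) else p_enter
        if (pvals[best] < thr) {
          selected <- c(selected, usable[best])
          step_no <- step_no + 1L
          trace[[length(trace) + 1]] <- data.frame(
            step = step_no, action = "enter", variable = usable[best],
            p_value = pvals[best])
          changed <- TRUE
        }
      }
    }
    # backward removal until all retained predictors clear p_remove
    repeat {
      if (length(selected) == 0) break
      fit <- stats::lm(stats::reformulate(selected, "lmc"), data = dat)
      cf <- summary(fit)$coefficients
      ps <- cf[selected[selected %in% rownames(cf)], 4]
      ps <- ps[ps > p_remove]
      if (length(ps) == 0) break
      worst <- names(ps)[which.max(ps)]
      selected <- setdiff(selected, worst)
      step_no <- step_no + 1L
      trace[[length(trace) + 1]] <- data.frame(
        step = step_no, action = "remove", variable = worst,
        p_value = max(ps))
      changed <- TRUE
    }
    if (!changed) break
  }

  if (length(selected) == 0) {
    warning("no candidate met the entry criterion; returning intercept-only model")
    fit <- stats::lm(lmc ~ 1, data = dat)
  } else {
    fit <- stats::lm(stats::reformulate(selected, "lmc"), data = dat)
  }
  cf <- stats::coef(fit)
  trace_df <- if (length(trace) > 0) do.call(rbind, trace) else
    data.frame(step = integer(0), action = character(0),
               variable = character(0), p_value = numeric(0))
  structure(list(intercept = unname(cf["(Intercept)"]),
                 coefficients = cf[setdiff(names(cf), "(Intercept)")],
                 r2 = summary(fit)$r.squared, n = n,
                 p_enter = p_enter, p_remove = p_remove,
                 trace = trace_df),
            class = "metreg_model")
}

#' @export
print.metreg_model <- function(x, ...) {
  cat("Meteorological-element stepwise regression model\n")
  cat(sprintf("  intercept b0 = %.4f, R2 = %.3f, n = %d\n", x$intercept,
              x$r2, x$n))
  if (length(x$coefficients) == 0) {
    cat("  (intercept-only model)\n")
  } else {
    for (v in names(x$coefficients)) {
      cat(sprintf("  %-6s %.4f\n", v, x$coefficients[[v]]))
    }
  }
  invisible(x)
}

#' Predict litter moisture with a stepwise regression model
#'
#' Linear prediction `b0 + sum(b_i * X_i)`; negative predictions are
#' clamped to 0 and flagged.
#'
#' @param model a `metreg_model` from [fit_stepwise()].
#' @param features a [lagged_features()] table containing every predictor
#'   named by the model (a missing column is an error naming it).
#' @return data frame of class `metreg_prediction`: `date` (if present in
#'   `features`), `lmc_pred`, `clamped`.
#' @export
predict_metreg <- function(model, features) {
  stopifnot(inherits(model, "metreg_model"))
  vars <- names(model$coefficients)
  missing <- setdiff(vars, names(features))
  if (length(missing) > 0) {
    stop("feature table lacks model predictor(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  pred <- rep(model$intercept, nrow(features))
  for (v in vars) pred <- pred + model$coefficients[[v]] * features[[v]]
  clamped <- is.finite(pred) & pred < 0
  pred[clamped] <- 0
  out <- data.frame(lmc_pred = pred, clamped = clamped)
  if ("date" %in% names(features)) out <- cbind(date = features$date, out)
  class(out) <- c("metreg_prediction", "data.frame")
  out
}
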