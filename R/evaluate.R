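#' MAE, MRE and RMSE of paired moisture predictions
#'
#' The three error metrics of the evaluation protocol, with the measured
#' value in the MRE denominator:
#' `MAE = mean(|M_i - M_j|)`, `MRE = mean(|M_i - M_j| / M_i) * 100`,
#' `RMSE = sqrt(mean((M_i - M_j)^2))`, where `M_i` is measured and `M_j`
#' predicted. Pairs with a zero measured value are excluded from the MRE
#' only, with a reported count.
#'
#' @param measured,predicted paired numeric vectors (or data frames with
#'   `lmc_pct` / `lmc_pred` columns) of equal length; pairs with
#'   non-finite entries are dropped.
#' @return object of class `error_report`: `mae_pct`, `mre_pct`,
#'   `rmse_pct`, `n`, `n_mre` (pairs entering the MRE).
#' @examples
#' error_metrics(c(20, 30), c(18, 33))
#' @export
error_metrics <- function(measured, predicted) {
  x <- if (is.data.frame(measured)) measured$lmc_pct else measured
  y <- if (is.data.frame(predicted)) {
    if ("lmc_pred" %in% names(predicted)) predicted$lmc_pred else predicted$lmc_pct
  } else predicted
  if (length(x) != length(y)) {
    stop("measured and predicted must have equal length", call. = FALSE)
  }
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 1) stop("no finite paired observations", call. = FALSE)
  abs_err <- abs(x - y)
  nz <- x != 0
  structure(list(mae_pct = mean(abs_err),
                 mre_pct = if (any(nz)) mean(abs_err[nz] / x[nz]) * 100 else NA_real_,
                 rmse_pct = sqrt(mean((x - y)^2)),
                 n = n, n_mre = sum(nz)),
            class = "error_report")
}

#' @export
print.error_report <- function(x, ...) {
  cat(sprintf("MAE %.3f%%  MRE %.3f%%  RMSE %.3f%%  (n = %d)\n",
              x$mae_pct, x$mre_pct, x$rmse_pct, x$n))
  invisible(x)
}

#' N-fold cross-validation with contiguous time folds
#'
#' Partitions the moisture series into `n_folds` contiguous-in-time blocks
#' (random folds would break the one-step-ahead structure of the direct
#' model, which needs the previous calendar day), fits on the held-in
#' data, predicts the held-out block, and pools all held-out predictions
#' into one [error_metrics()] report. The default `n_folds = NULL` means
#' leave-one-out.
#'
#' @param moisture a [moisture_series()].
#' @param features a [lagged_features()] table.
#' @param fit_fn function `(moisture, features) -> model`.
#' @param predict_fn function `(model, moisture_test, features) -> numeric`
#'   returning one prediction per held-out row (NA allowed).
#' @param n_folds number of folds in `[2, n]`; `NULL` for leave-one-out.
#' @return list of class `cv_report`: the pooled `error_report` plus
#'   `n_folds`, `n_skipped`, and the held-out `predictions` data frame.
#' @export
cross_validate <- function(moisture, features, fit_fn, predict_fn,
                           n_folds = NULL) {
  stopifnot(inherits(moisture, "moisture_series"))
  n <- nrow(moisture)
  if (is.null(n_folds)) n_folds <- n
  if (n_folds < 2 || n_folds > n) {
    stop("n_folds must lie in [2, n]", call. = FALSE)
  }
  fold_id <- cut(seq_len(n), breaks = n_folds, labels = FALSE)
  preds <- rep(NA_real_, n)
  n_skipped <- 0L
  for (k in seq_len(n_folds)) {
    test <- fold_id == k
    train_m <- moisture[!test, , drop = FALSE]
    class(train_m) <- class(moisture)
    test_m <- moisture[test, , drop = FALSE]
    class(test_m) <- class(moisture)
    res <- tryCatch({
      model <- fit_fn(train_m, features)
      predict_fn(model, test_m, features)
    }, error = function(e) {
      warning("fold ", k, " skipped: ", conditionMessage(e), call. = FALSE)
      NULL
    })
    if (is.null(res)) n_skipped <- n_skipped + 1L else preds[test] <- res
  }
  ok <- is.finite(preds)
  rep_out <- error_metrics(moisture$lmc_pct[ok], preds[ok])
  structure(list(mae_pct = rep_out$mae_pct, mre_pct = rep_out$mre_pct,
                 rmse_pct = rep_out$rmse_pct, n = rep_out$n,
                 n_mre = rep_out$n_mre,
                 n_folds = n_folds, n_skipped = n_skipped,
                 predictions = data.frame(date = moisture$date,
                                          lmc_pct = moisture$lmc_pct,
                                          lmc_pred = preds,
                                          fold = fold_id)),
            class = c("cv_report", "error_report"))
}

#' Operational applicability rule on the mean relative error
#'
#' A moisture model is considered usable for daily fire danger forecasting
#' when its MRE does not exceed the limit (default 15 percent; the
#' boundary counts as a pass).
#'
#' @param report an `error_report` (or a bare MRE value).
#' @param mre_limit limit in percent (default 15).
#' @return `"pass"` or `"fail"`.
#' @export
applicability_verdict <- function(report, mre_limit = 15) {
  mre <- if (inherits(report, "error_report")) report$mre_pct else report
  if (!is.finite(mre)) stop("MRE is undefined", call. = FALSE)
  if (mre <= mre_limit) "pass" else "fail"
}

#' Min / max / mean / coefficient of variation of a vector
#'
#' The summary used for extrapolation error grids. The coefficient of
#' variation is `sd / mean` with the sample (n-1) standard deviation.
#'
#' @param values numeric vector (NAs dropped).
#' @return list `min`, `max`, `mean`, `cv`, `n`.
#' @export
summarize_table <- function(values) {
  v <- values[is.finite(values)]
  if (length(v) == 0) stop("no finite values to summarize", call. = FALSE)
  m <- mean(v)
  list(min = min(v), max = max(v), mean = m,
       cv = if (length(v) > 1 && m != 0) stats::sd(v) / m else 0,
       n = length(v))
}

#' Cross-plot extrapolation error matrix
#'
#' Applies the model fitted on each source plot to the data of every other
#' plot (model parameters from the source, features and measured moisture
#' from the target) and collects MAE/MRE/RMSE per ordered pair. The
#' diagonal (self-prediction) is excluded from the min/max/mean/CV
#' summaries; unusable cells are flagged missing and excluded with a
#' count.
#'
#' @param models named list of fitted models, one per plot.
#' @param data named list (same names) of lists with elements `moisture`
#'   (a [moisture_series()]) and `features` (a [lagged_features()] table).
#' @param predict_fn function `(model, moisture, features) -> numeric`
#'   giving one prediction per moisture row.
#' @return object of class `extrapolation_matrix`: `cells` data frame
#'   (`source`, `target`, `mae_pct`, `mre_pct`, `rmse_pct`, `n`),
#'   `summaries` (per-metric [summarize_table()] over off-diagonal cells)
#'   and `n_missing`.
#' @export
extrapolation_matrix <- function(models, data, predict_fn) {
  plots <- names(models)
  stopifnot(length(plots) >= 2, !is.null(names(data)),
            all(plots %in% names(data)))
  cells <- list()
  n_missing <- 0L
  for (src in plots) {
    for (tgt in plots) {
      rep_k <- tryCatch({
        pred <- predict_fn(models[[src]], data[[tgt]]$moisture,
                           data[[tgt]]$features)
        error_metrics(data[[tgt]]$moisture$lmc_pct, pred)
      }, error = function(e) NULL)
      if (is.null(rep_k)) {
        n_missing <- n_missing + (src != tgt)
        cells[[length(cells) + 1]] <- data.frame(
          source = src, target = tgt, mae_pct = NA_real_, mre_pct = NA_real_,
          rmse_pct = NA_real_, n = NA_integer_)
      } else {
        cells[[length(cells) + 1]] <- data.frame(
          source = src, target = tgt, mae_pct = rep_k$mae_pct,
          mre_pct = rep_k$mre_pct, rmse_pct = rep_k$rmse_pct, n = rep_k$n)
      }
    }
  }
  cells <- do.call(rbind, cells)
  off <- cells$source != cells$target
  summaries <- lapply(c(mae_pct = "mae_pct", mre_pct = "mre_pct",
                        rmse_pct = "rmse_pct"),
                      function(col) summarize_table(cells[[col]][off]))
  structure(list(cells = cells, summaries = summaries,
                 n_missing = n_missing),
            class = "extrapolation_matrix")
}

#' @export
print.extrapolation_matrix <- function(x, ...) {
  np <- length(unique(x$cells$source))
  cat(sprintf("Cross-plot extrapolation matrix over %d plots\n", np))
  for (m in names(x$summaries)) {
    s <- x$summaries[[m]]
    cat(sprintf("  %-8s min %.2f  max %.2f  mean %.2f  CV %.2f\n",
                m, s$min, s$max, s$mean, s$cv))
  }
  if (x$n_missing > 0) cat("  missing off-diagonal cells:", x$n_missing, "\n")
  invisible(x)
}

#' Export extrapolation cells to comma-separated text
#'
#' @param x an `extrapolation_matrix`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_extrapolation <- function(x, path) {
  utils::write.csv(x$cells, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
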