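# Regression metrics with seeded percentile-bootstrap confidence intervals,
# and the matched-pair lipophilicity shift.

check_pairs <- function(obs, pred) {
  if (length(obs) != length(pred))
    stop(sprintf("length mismatch: %d observations vs %d predictions",
                 length(obs), length(pred)))
  if (length(obs) == 0L) stop("empty input")
  if (anyNA(obs) || anyNA(pred)) stop("missing values are not allowed")
  invisible(TRUE)
}

#' Root-mean-square error
#' @param obs,pred Numeric vectors of equal length, no missing values.
#' @return Non-negative scalar.
#' @export
rmse <- function(obs, pred) {
  check_pairs(obs, pred)
  sqrt(mean((obs - pred)^2))
}

#' Mean absolute error
#' @inheritParams rmse
#' @return Non-negative scalar.
#' @export
mae <- function(obs, pred) {
  check_pairs(obs, pred)
  mean(abs(obs - pred))
}

#' Coefficient of determination
#'
#' `1 - SS_res / SS_tot`; can be negative for predictors worse than the
#' observed mean.
#'
#' @inheritParams rmse
#' @return Scalar `<= 1`.
#' @export
r_squared <- function(obs, pred) {
  check_pairs(obs, pred)
  if (length(obs) < 2L) stop("r_squared needs at least 2 observations")
  ss_tot <- sum((obs - mean(obs))^2)
  if (ss_tot == 0) stop("r_squared undefined: zero variance in observations")
  1 - sum((obs - pred)^2) / ss_tot
}

#' Spearman rank correlation
#'
#' Pearson correlation of mid-ranks (average ranks on ties).
#'
#' @inheritParams rmse
#' @return Scalar in `[-1, 1]`.
#' @export
spearman_rho <- function(obs, pred) {
  check_pairs(obs, pred)
  if (length(obs) < 2L) stop("spearman_rho needs at least 2 pairs")
  if (stats::sd(obs) == 0 || stats::sd(pred) == 0)
    stop("spearman_rho undefined for a constant vector")
  stats::cor(obs, pred, method = "spearman")
}

#' Percentile bootstrap confidence interval for a metric
#'
#' Paired resampling with replacement: indices are resampled, keeping each
#' (obs, pred) pair together. Resamples on which the metric is undefined
#' (e.g. zero variance) are redrawn; if more than half of the resamples fail
#' the interval is refused.
#'
#' @param metric Function `(obs, pred) -> scalar`, e.g. [rmse()].
#' @param obs,pred Numeric vectors.
#' @param n_boot Number of bootstrap resamples (>= 100).
#' @param level Coverage level (default 0.95).
#' @param seed Integer seed.
#' @return Numeric `c(lower, upper)`; attribute `n_redrawn` counts redrawn
#'   resamples.
#' @export
bootstrap_ci <- function(metric, obs, pred, n_boot = 1000L, level = 0.95,
                         seed = 0L) {
  check_pairs(obs, pred)
  stopifnot(n_boot >= 100L, level > 0, level < 1)
  n <- length(obs)
  stats_ <- numeric(n_boot)
  n_redrawn <- 0L
  withr::with_seed(as.integer(seed), {
    for (b in seq_len(n_boot)) {
      val <- NA_real_
      for (attempt in seq_len(100L)) {
        idx <- sample.int(n, n, replace = TRUE)
        val <- tryCatch(metric(obs[idx], pred[idx]),
                        error = function(e) NA_real_)
        if (is.finite(val)) break
        n_redrawn <- n_redrawn + 1L
      }
      if (!is.finite(val))
        stop("bootstrap_ci: metric undefined on too many resamples")
      stats_[b] <- val
    }
  })
  if (n_redrawn > n_boot / 2)
    stop("bootstrap_ci: metric undefined on more than half of the resamples")
  if (n_redrawn > 0L)
    message(sprintf("bootstrap_ci: redrew %d degenerate resamples", n_redrawn))
  alpha <- (1 - level) / 2
  ci <- unname(stats::quantile(stats_, probs = c(alpha, 1 - alpha)))
  attr(ci, "n_redrawn") <- n_redrawn
  ci
}

#' Full metric report with bootstrap confidence intervals
#'
#' R^2, RMSE, MAE and Spearman rho, each with a percentile-bootstrap
#' confidence interval at the requested level.
#'
#' @param obs,pred Numeric vectors (pairs with missing values are dropped
#'   with a message).
#' @param n_boot Bootstrap resamples.
#' @param level CI coverage.
#' @param seed Integer seed for the bootstrap.
#' @return Object of class `mt_metric_report`: data frame with columns
#'   `metric`, `estimate`, `lower`, `upper`, plus attributes `n`, `n_boot`,
#'   `seed`.
#' @export
metric_report <- function(obs, pred, n_boot = 1000L, level = 0.95,
                          seed = 0L) {
  ok <- is.finite(obs) & is.finite(pred)
  if (any(!ok)) {
    message(sprintf("metric_report: dropping %d pairs with missing values",
                    sum(!ok)))
    obs <- obs[ok]; pred <- pred[ok]
  }
  fns <- list(r2 = r_squared, rmse = rmse, mae = mae,
              spearman = spearman_rho)
  rows <- lapply(names(fns), function(nm) {
    est <- fns[[nm]](obs, pred)
    ci <- bootstrap_ci(fns[[nm]], obs, pred, n_boot = n_boot, level = level,
                       seed = seed)
    data.frame(metric = nm, estimate = est, lower = ci[1L], upper = ci[2L],
               stringsAsFactors = FALSE)
  })
  rep_ <- do.call(rbind, rows)
  attr(rep_, "n") <- length(obs)
  attr(rep_, "n_boot") <- n_boot
  attr(rep_, "seed") <- seed
  class(rep_) <- c("mt_metric_report", "data.frame")
  rep_
}

#' @export
print.mt_metric_report <- function(x, ...) {
  cat(sprintf("Performance on n = %d pairs (bootstrap n = %d):\n",
              attr(x, "n"), attr(x, "n_boot")))
  for (i in seq_len(nrow(x))) {
    cat(sprintf("  %-9s %6.2f [%0.2f,%0.2f]\n", x$metric[i], x$estimate[i],
                x$lower[i], x$upper[i]))
  }
  invisible(x)
}

#' Matched-pair shift
#'
#' Signed difference `value(id_a) - value(id_b)` between two compounds in a
#' named value vector -- the Delta-logP of a structural transformation,
#' reported side by side for experimental and predicted columns.
#'
#' @param values Named numeric vector, or data frame with `id` plus one
#'   value column.
#' @param id_a,id_b Compound identifiers.
#' @return Signed difference.
#' @export
pair_shift <- function(values, id_a, id_b) {
  if (is.data.frame(values)) {
    stopifnot("id" %in% names(values))
    val_col <- setdiff(names(values), "id")[1L]
    v <- stats::setNames(values[[val_col]], values$id)
  } else v <- values
  if (!(id_a %in% names(v))) stop(sprintf("unknown id '%s'", id_a))
  if (!(id_b %in% names(v))) stop(sprintf("unknown id '%s'", id_b))
  unname(v[[id_a]] - v[[id_b]])
}
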