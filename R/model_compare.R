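#' Widely Applicable Information Criterion
#'
#' From a pointwise log-likelihood matrix (posterior draws in rows, data
#' rows in columns): `lppd = sum_i log mean_s exp(ll_si)` (computed with a
#' stable log-sum-exp), `p_waic = sum_i var_s(ll_si)`, and
#' `waic = -2 * (lppd - p_waic)` with a standard error over rows.
#'
#' @param pointwise_loglik draws x rows matrix of log-likelihood values.
#' @return a `waic_result`: list with `lppd`, `p_waic`, `waic`, `se`,
#'   `pointwise` (per-row WAIC contributions), `n_draws`, `n_rows`.
#' @export
waic <- function(pointwise_loglik) {
  m <- as.matrix(pointwise_loglik)
  if (nrow(m) < 2L || ncol(m) < 1L) {
    stop("need at least 2 draws and 1 row")
  }
  bad <- which(!apply(is.finite(m), 2, all))
  if (length(bad) > 0L) {
    stop("non-finite log-likelihood in row(s): ",
         paste(utils::head(bad, 5), collapse = ", "))
  }
  lppd_i <- apply(m, 2, log_mean_exp)
  p_i <- apply(m, 2, stats::var)
  pw <- -2 * (lppd_i - p_i)
  res <- list(lppd = sum(lppd_i), p_waic = sum(p_i),
              waic = sum(pw), se = sqrt(ncol(m) * stats::var(pw)),
              pointwise = pw, n_draws = nrow(m), n_rows = ncol(m))
  class(res) <- "waic_result"
  res
}

log_mean_exp <- function(x) {
  mx <- max(x)
  mx + log(mean(exp(x - mx)))
}

#' @export
print.waic_result <- function(x, ...) {
  cat(sprintf("WAIC %.1f (SE %.1f), lppd %.1f, p_waic %.1f, n = %d rows\n",
              x$waic, x$se, x$lppd, x$p_waic, x$n_rows))
  invisible(x)
}

#' WAIC model-comparison table
#'
#' Ranks models by WAIC, reporting the difference to the best model, the
#' standard error of each difference (from the pointwise contributions) and
#' Akaike-style weights proportional to exp(-delta/2).
#'
#' Note: WAIC-based comparison is less robust for time-series-structured
#' data such as yearly song cohorts; inference should rest on the full
#' models' coefficients, with the comparison table read as descriptive. A
#' warning to this effect is always attached.
#'
#' @param results list of `waic_result` objects computed on identical rows.
#' @param labels model names (defaults to list names or M1, M2, ...).
#' @return a `comparison_table` data.frame: model, waic, se, d_waic, d_se,
#'   weight (sorted by WAIC; weights sum to 1).
#' @export
compare_waic <- function(results, labels = NULL) {
  if (is.null(labels)) {
    labels <- names(results)
    if (is.null(labels)) labels <- paste0("M", seq_along(results))
  }
  stopifnot(length(labels) == length(results))
  nr <- vapply(results, function(r) r$n_rows, integer(1))
  if (length(unique(nr)) != 1L) {
    stop("all models must be computed on identical row sets (row counts: ",
         paste(nr, collapse = ", "), ")")
  }
  w <- vapply(results, function(r) r$waic, numeric(1))
  best <- which.min(w)
  d <- w - w[best]
  d_se <- vapply(seq_along(results), function(i) {
    if (i == best) return(0)
    diff <- results[[i]]$pointwise - results[[best]]$pointwise
    sqrt(length(diff) * stats::var(diff))
  }, numeric(1))
  wt <- exp(-d / 2)
  wt <- wt / sum(wt)
  out <- data.frame(model = labels, waic = w, se = vapply(results, `[[`,
                                                          numeric(1), "se"),
                    d_waic = d, d_se = d_se, weight = wt)
  out <- out[order(out$waic), ]
  rownames(out) <- NULL
  attr(out, "caveat") <- paste(
    "WAIC comparison is unstable for time-series data;",
    "interpret full-model coefficients, not table order.")
  class(out) <- c("comparison_table", "data.frame")
  warning("WAIC comparison on time-series data is unstable; ",
          "interpret full-model coefficients.", call. = FALSE)
  out
}

#' Write a comparison table as CSV
#' @param tab a `comparison_table`.
#' @param path output CSV path.
#' @export
write_comparison <- function(tab, path) {
  utils::write.csv(as.data.frame(tab), path, row.names = FALSE)
  invisible(path)
}
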