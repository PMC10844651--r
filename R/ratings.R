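#' Accuracy of a synchrony estimate
#'
#' Accuracy is quantified as a difference value on the 0-100 slider scale:
#' the objectively measured similarity (rescaled from `[0, 1]` to `[0, 100]`)
#' minus the observer's synchrony estimate. Zero means a perfect estimate;
#' positive values mean the observer underestimated the synchrony, negative
#' values mean overestimation.
#'
#' @param measured_similarity measured similarity in `[0, 1]`.
#' @param sync_estimate observer's slider response in `[0, 100]`.
#' @return Difference value in `[-100, 100]`.
#' @export
compute_accuracy <- function(measured_similarity, sync_estimate) {
  if (any(!is.finite(measured_similarity)) ||
      any(measured_similarity < 0 | measured_similarity > 1))
    stop_dyadsync("measured_similarity must lie in [0, 1]")
  if (any(!is.finite(sync_estimate)) ||
      any(sync_estimate < 0 | sync_estimate > 100))
    stop_dyadsync("sync_estimate must lie in [0, 100]")
  100 * measured_similarity - sync_estimate
}

#' Z-score predictor columns
#'
#' Standardizes the named numeric columns of a table to mean 0, standard
#' deviation 1 (denominator n - 1), the convention used for every model
#' predictor so coefficient scales are comparable. Trait predictors should
#' be standardized across participants (one row per participant) and
#' trial-level covariates across trials — pass the table at the matching
#' grain.
#'
#' @param table a data frame.
#' @param cols character vector of columns to standardize (default: all
#'   numeric columns).
#' @return The table with the named columns standardized.
#' @export
zscore_predictors <- function(table, cols = NULL) {
  stopifnot(is.data.frame(table))
  if (is.null(cols)) cols <- names(table)[vapply(table, is.numeric, TRUE)]
  for (cl in cols) {
    v <- table[[cl]]
    if (!is.numeric(v)) stop_dyadsync("column '", cl, "' is not numeric")
    s <- stats::sd(v)
    if (!is.finite(s) || s == 0)
      stop_dyadsync("cannot z-score zero-variance column '", cl, "'")
    table[[cl]] <- (v - mean(v)) / s
  }
  table
}

#' Highest-posterior-density interval
#'
#' The shortest interval containing at least `mass` of the draws: among all
#' windows of `ceiling(mass * n)` consecutive sorted draws, the narrowest.
#' For skewed posteriors this is shorter than the equal-tailed interval.
#'
#' @param draws numeric vector of at least 100 posterior draws.
#' @param mass interval probability mass (default 0.95).
#' @return Named numeric vector `c(lower, upper)`.
#' @export
hpd_interval <- function(draws, mass = 0.95) {
  draws <- draws[is.finite(draws)]
  n <- length(draws)
  if (n < 100) stop_dyadsync("need at least 100 draws for an HPD interval")
  stopifnot(mass > 0, mass <= 1)
  x <- sort(draws)
  k <- ceiling(mass * n)
  if (k >= n) return(c(lower = x[1], upper = x[n]))
  starts <- seq_len(n - k + 1L)
  widths <- x[starts + k - 1L] - x[starts]
  i <- which.min(widths)
  c(lower = x[i], upper = x[i + k - 1L])
}

#' Posterior mass on the dominant side of zero
#'
#' The larger of `P(draw < 0)` and `P(draw > 0)`; used to report the
#' direction-consistency of an effect (e.g. "88% of the posterior below 0").
#' Always in `[0.5, 1]` up to ties at exactly zero.
#'
#' @param draws numeric vector of at least 100 posterior draws.
#' @return Fraction in `[0, 1]`.
#' @export
posterior_mass_beyond_zero <- function(draws) {
  draws <- draws[is.finite(draws)]
  if (length(draws) < 100) stop_dyadsync("need at least 100 draws")
  max(mean(draws < 0), mean(draws > 0))
}

#' Widely applicable information criterion (WAIC)
#'
#' Computes `WAIC = -2 * (lppd - p_waic)` from a matrix of pointwise
#' log-likelihood draws, with `lppd = sum_i log mean_s exp(ll[s, i])` and
#' `p_waic = sum_i var_s(ll[s, i])`. Lower values indicate better expected
#' out-of-sample fit.
#'
#' @param loglik draws-by-observations matrix of log-likelihood values.
#' @return A list: `waic`, `lppd`, `p_waic`.
#' @export
compute_waic <- function(loglik) {
  loglik <- as.matrix(loglik)
  if (any(!is.finite(loglik)))
    stop_dyadsync("log-likelihood matrix contains non-finite values")
  # column-wise log-mean-exp, stabilized
  mx <- apply(loglik, 2, max)
  lppd <- sum(mx + log(colMeans(exp(sweep(loglik, 2, mx)))))
  p_waic <- sum(apply(loglik, 2, stats::var))
  list(waic = -2 * (lppd - p_waic), lppd = lppd, p_waic = p_waic)
}
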