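# Hierarchical Bayesian models of observers' accuracy and enjoyment.

# standardize covariates at their natural grain: columns constant within
# participant are z-scored across participants, everything else across rows
standardize_covariates <- function(data, covariates, id_col = "participant_id") {
  for (cv in covariates) {
    v <- data[[cv]]
    if (is.null(v)) stop_dyadsync("missing covariate column '", cv, "'")
    per_id <- tapply(v, data[[id_col]], function(x) length(unique(x)))
    if (all(per_id == 1)) {
      ids <- !duplicated(data[[id_col]])
      mu <- mean(v[ids]); s <- stats::sd(v[ids])
    } else {
      mu <- mean(v); s <- stats::sd(v)
    }
    if (!is.finite(s) || s == 0)
      stop_dyadsync("cannot z-score zero-variance column '", cv, "'")
    data[[cv]] <- (v - mu) / s
  }
  data
}

#' Fit the distributional accuracy model
#'
#' Models accuracy difference values (measured-minus-estimated synchrony on
#' the 0-100 scale) with a Gaussian likelihood whose mean and residual SD
#' both depend on the synchrony condition:
#' \deqn{d_{ijk} \sim N(\alpha_c + \sum_p \beta_{c,p} x_p + u_j + v_k,\ \sigma_c)}
#' with condition-specific intercepts and covariate slopes, per-condition
#' residual SDs (the "distributional" part), and participant (`u_j`) and
#' clip (`v_k`) random intercepts. Covariates are z-scored internally
#' (traits across participants, trial covariates across trials).
#'
#' @param data data frame with columns `difference`, `condition`
#'   (`"high"`/`"low"`), `participant_id`, `clip_id`, and the covariates.
#' @param covariates character vector of covariate column names (may be
#'   empty for an intercept-only model).
#' @param config a [model_config()].
#' @return An object of class `dyadsync_fit` (see [posterior_summary()]).
#' @export
fit_accuracy_model <- function(data, covariates = character(), config = model_config()) {
  stopifnot(is.data.frame(data),
            all(c("difference", "condition", "participant_id", "clip_id")
                %in% names(data)))
  if (!all(data$condition %in% c("high", "low")))
    stop_dyadsync("condition must be 'high' or 'low'")
  if (length(unique(data$condition)) < 2)
    stop_dyadsync("both synchrony conditions must be present")
  if (length(unique(data$participant_id)) < 2 || length(unique(data$clip_id)) < 2)
    stop_dyadsync("need at least 2 participants and 2 clips")
  data <- standardize_covariates(data, covariates)
  cond <- factor(data$condition, levels = c("high", "low"))
  X <- cbind(`alpha[high]` = as.numeric(cond == "high"),
             `alpha[low]` = as.numeric(cond == "low"))
  prior_sd <- rep(config$prior_sd_intercept, 2)
  for (cv in covariates) {
    for (cc in c("high", "low")) {
      X <- cbind(X, data[[cv]] * (cond == cc))
      colnames(X)[ncol(X)] <- sprintf("beta[%s,%s]", cc, cv)
      prior_sd <- c(prior_sd, config$prior_sd_slope)
    }
  }
  g1 <- as.integer(factor(data$participant_id))
  g2 <- as.integer(factor(data$clip_id))
  # column groups: the intercept pair, then each covariate's condition pair
  col_groups <- c(list(1:2), lapply(seq_along(covariates),
                                    function(p) 2L + 2L * (p - 1L) + 1:2))
  res <- gibbs_gaussian(data$difference, X, prior_sd,
                        sigma_group = as.integer(cond), g1 = g1, g2 = g2,
                        cfg = config, col_groups = col_groups)
  nm <- res$par_names
  nm[nm == "sigma_1"] <- "sigma[high]"
  nm[nm == "sigma_2"] <- "sigma[low]"
  dimnames(res$draws)[[3]] <- res$par_names <- nm
  new_fit("accuracy", res, config,
          data = list(y = data$difference, X = X, g1 = g1, g2 = g2,
                      sigma_group = as.integer(cond)))
}

#' Fit the two-part ("zero-inflated Gaussian") enjoyment model
#'
#' Enjoyment slider ratings show a spike of very low values; ratings at or
#' below `cut` (default 10) are modelled as a separate "very low enjoyment"
#' category. The hurdle indicator follows a Bernoulli-logit regression with
#' participant random intercepts,
#' \deqn{P(r \le 10) = \mathrm{logit}^{-1}(\gamma_0 + \sum_p \gamma_p x_p + u'_j),}
#' and the remaining ratings ("enjoyment per se", `cut`+1 to 100) a Gaussian
#' regression with participant and clip random intercepts,
#' \deqn{r \mid r > 10 \sim N(\delta_0 + \sum_p \delta_p x_p + u''_j + v''_k,\ \sigma_e).}
#' The two parts share covariates but are estimated independently.
#'
#' @param data data frame with columns `rating` (0-100), `participant_id`,
#'   `clip_id`, and the covariates.
#' @param covariates character vector of covariate column names.
#' @param config a [model_config()].
#' @param cut hurdle threshold on the rating scale (default 10).
#' @return An object of class `dyadsync_fit` with `inflation` and
#'   `continuous` components.
#' @export
fit_enjoyment_model <- function(data, covariates = character(),
                                config = model_config(), cut = 10) {
  stopifnot(is.data.frame(data),
            all(c("rating", "participant_id", "clip_id") %in% names(data)))
  if (any(data$rating < 0 | data$rating > 100))
    stop_dyadsync("ratings must lie in [0, 100]")
  data <- standardize_covariates(data, covariates)
  z <- as.integer(data$rating <= cut)
  W <- cbind(`gamma[Intercept]` = rep(1, nrow(data)))
  prior_w <- config$prior_sd_intercept
  for (cv in covariates) {
    W <- cbind(W, data[[cv]])
    colnames(W)[ncol(W)] <- sprintf("gamma[%s]", cv)
    prior_w <- c(prior_w, config$prior_sd_slope)
  }
  g1 <- as.integer(factor(data$participant_id))
  degenerate <- length(unique(z)) < 2
  if (degenerate)
    warning("hurdle indicator is constant (all ratings ",
            if (all(z == 1)) "<= " else "> ", cut,
            "): inflation part is degenerate")
  infl <- metropolis_logit(z, W, prior_w, g1, config)

  keep <- z == 0
  cont <- NULL
  if (sum(keep) >= 10 && length(unique(data$participant_id[keep])) >= 2) {
    dc <- data[keep, , drop = FALSE]
    Xc <- cbind(`delta[Intercept]` = rep(1, nrow(dc)))
    prior_c <- config$prior_sd_intercept * 5 # intercept sits mid-scale, ~50
    for (cv in covariates) {
      Xc <- cbind(Xc, dc[[cv]])
      colnames(Xc)[ncol(Xc)] <- sprintf("delta[%s]", cv)
      prior_c <- c(prior_c, config$prior_sd_slope)
    }
    gc1 <- as.integer(factor(dc$participant_id))
    gc2 <- as.integer(factor(dc$clip_id))
    cont <- gibbs_gaussian(dc$rating, Xc, prior_c,
                           sigma_group = rep(1L, nrow(dc)),
                           g1 = gc1, g2 = gc2, cfg = config)
    cont_data <- list(y = dc$rating, X = Xc, g1 = gc1, g2 = gc2,
                      sigma_group = rep(1L, nrow(dc)))
  } else {
    warning("too few above-threshold ratings: continuous part not fitted")
    cont_data <- NULL
  }
  fit <- new_fit("enjoyment", infl, config,
                 data = list(z = z, W = W, g1 = g1))
  fit$continuous <- cont
  fit$continuous_data <- cont_data
  fit$cut <- cut
  fit$degenerate_inflation <- degenerate
  fit$summary <- posterior_summary(fit) # refresh with both parts
  fit$converged <- all(fit$summary$rhat <= config$rhat_max, na.rm = TRUE) &&
    all(fit$summary$ess >= config$ess_min, na.rm = TRUE)
  if (!fit$converged)
    warning("enjoyment model failed the convergence gate (rhat/ess); ",
            "inspect posterior_summary() before use")
  fit
}

new_fit <- function(kind, res, config, data) {
  fit <- structure(
    list(kind = kind, draws = res$draws, par_names = res$par_names,
         re_u = res$re_u, re_v = res$re_v, config = config, data = data,
         seed = config$seed),
    class = "dyadsync_fit"
  )
  fit$summary <- posterior_summary(fit)
  fit$converged <- all(fit$summary$rhat <= config$rhat_max, na.rm = TRUE) &&
    all(fit$summary$ess >= config$ess_min, na.rm = TRUE)
  if (kind != "enjoyment" && !fit$converged)
    warning(kind, " model failed the convergence gate (rhat/ess); ",
            "inspect posterior_summary() before use")
  fit
}

#' Posterior summaries for a fitted model
#'
#' One row per reported parameter: posterior mean, HPD bounds at the
#' configured mass, the posterior mass on the dominant side of zero, and
#' the split-R-hat and effective-sample-size diagnostics.
#'
#' @param fit a `dyadsync_fit`.
#' @return Data frame with columns `parameter`, `part`, `mean`, `hpd_lo`,
#'   `hpd_hi`, `mass_beyond_zero`, `rhat`, `ess`.
#' @export
posterior_summary <- function(fit) {
  stopifnot(inherits(fit, "dyadsync_fit"))
  summarize_block <- function(draws, names, part) {
    rows <- lapply(seq_along(names), function(i) {
      d <- as.numeric(draws[, , i])
      h <- hpd_interval(d, fit$config$hpd_mass)
      data.frame(parameter = names[i], part = part, mean = mean(d),
                 hpd_lo = h[["lower"]], hpd_hi = h[["upper"]],
                 mass_beyond_zero = posterior_mass_beyond_zero(d),
                 rhat = split_rhat(draws[, , i]),
                 ess = ess_basic(draws[, , i]),
                 stringsAsFactors = FALSE)
    })
    do.call(rbind, rows)
  }
  main_part <- if (fit$kind == "enjoyment") "inflation" else "location"
  out <- summarize_block(fit$draws, fit$par_names, main_part)
  if (!is.null(fit$continuous))
    out <- rbind(out, summarize_block(fit$continuous$draws,
                                      fit$continuous$par_names, "continuous"))
  rownames(out) <- NULL
  out
}

#' @export
print.dyadsync_fit <- function(x, ...) {
  cat(sprintf("<dyadsync_fit: %s model> %d chains x %d draws (seed %d)%s\n",
              x$kind, x$config$chains, x$config$draws, x$seed,
              if (isTRUE(x$converged)) "" else "  [NOT CONVERGED]"))
  print(x$summary, digits = 3)
  invisible(x)
}

#' @export
summary.dyadsync_fit <- function(object, ...) object$summary

#' Extract posterior draws for one parameter
#'
#' @param fit a `dyadsync_fit`.
#' @param parameter parameter name as listed in [posterior_summary()].
#' @return Numeric vector of pooled draws across chains.
#' @export
posterior_draws <- function(fit, parameter) {
  if (parameter %in% fit$par_names)
    return(as.numeric(fit$draws[, , match(parameter, fit$par_names)]))
  if (!is.null(fit$continuous) && parameter %in% fit$continuous$par_names)
    return(as.numeric(
      fit$continuous$draws[, , match(parameter, fit$continuous$par_names)]))
  stop_dyadsync("unknown parameter '", parameter, "'")
}

#' Pointwise log-likelihood draws for a Gaussian fit
#'
#' Returns the draws-by-observations log-likelihood matrix needed by
#' [compute_waic()]. Available for the accuracy model and the continuous
#' part of the enjoyment model.
#'
#' @param fit a `dyadsync_fit`.
#' @param part `"location"` (accuracy) or `"continuous"` (enjoyment).
#' @return Matrix of log-likelihood values, draws x observations.
#' @export
log_lik_matrix <- function(fit, part = c("location", "continuous")) {
  part <- match.arg(part)
  if (part == "location") {
    stopifnot(fit$kind == "accuracy")
    res <- list(draws = fit$draws, re_u = fit$re_u, re_v = fit$re_v,
                par_names = fit$par_names)
    dat <- fit$data
  } else {
    stopifnot(!is.null(fit$continuous))
    res <- fit$continuous
    dat <- fit$continuous_data
  }
  S <- dim(res$draws)[1] * dim(res$draws)[2]
  flat <- function(a) matrix(a, nrow = S) # (iter*chain) x npar
  P <- ncol(dat$X)
  beta <- flat(res$draws[, , seq_len(P), drop = FALSE])
  n_sigma <- max(dat$sigma_group)
  sig <- flat(res$draws[, , P + seq_len(n_sigma), drop = FALSE])
  u <- flat(res$re_u)
  v <- if (!is.null(res$re_v)) flat(res$re_v) else NULL
  mu <- beta %*% t(dat$X) + u[, dat$g1, drop = FALSE]
  if (!is.null(v)) mu <- mu + v[, dat$g2, drop = FALSE]
  sd_mat <- sig[, dat$sigma_group, drop = FALSE]
  stats::dnorm(matrix(dat$y, nrow = S, ncol = length(dat$y), byrow = TRUE),
               mu, sd_mat, log = TRUE)
}

#' Write a tidy posterior-summary CSV
#'
#' @param fit a `dyadsync_fit` or its [posterior_summary()] data frame.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_posterior_csv <- function(fit, path) {
  tab <- if (inherits(fit, "dyadsync_fit")) fit$summary else fit
  utils::write.csv(tab, path, row.names = FALSE)
  invisible(path)
}
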