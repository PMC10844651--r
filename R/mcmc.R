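# MCMC engines for the hierarchical rating models.
#
# The Gaussian (possibly distributional, i.e. per-condition residual SD)
# mixed model is sampled by Gibbs: regression coefficients and random
# intercepts have conjugate normal full conditionals; scale parameters
# (residual SDs, random-effect SDs), which carry Exponential priors on the
# SD scale, are updated by adaptive random-walk Metropolis on log(sd).
# The Bernoulli (logit) part of the hurdle model is sampled by adaptive
# Metropolis-within-Gibbs with several inner updates per stored draw.

#' Model configuration for the Bayesian rating models
#'
#' Priors are weakly informative on the response scale of the 0-100 slider:
#' Normal(0, `prior_sd_intercept`) on intercepts, Normal(0, `prior_sd_slope`)
#' on slopes of z-scored covariates, Exponential(`sd_prior_rate`) on every
#' SD parameter. Reported fits require `chains * draws >= 2000`.
#'
#' @param chains number of MCMC chains (default 2).
#' @param draws post-warmup draws per chain (default 1000).
#' @param warmup warmup iterations per chain (default 500).
#' @param thin internal sampler iterations per stored draw (default 2).
#' @param seed RNG seed for the sampler.
#' @param hpd_mass credible-interval mass for summaries (default 0.95).
#' @param prior_sd_intercept,prior_sd_slope,sd_prior_rate prior scales.
#' @param rhat_max,ess_min convergence gate applied to reported parameters.
#' @return A list of class `model_config`.
#' @export
model_config <- function(chains = 2, draws = 1000, warmup = 500, seed = 1, thin = 2,
                         hpd_mass = 0.95, prior_sd_intercept = 20,
                         prior_sd_slope = 10, sd_prior_rate = 0.1,
                         rhat_max = 1.05, ess_min = 400) {
  if (chains * draws < 2000)
    warning("chains * draws < 2000: below the minimum for reported fits")
  structure(
    list(chains = chains, draws = draws, warmup = warmup, seed = seed,
         thin = thin,
         hpd_mass = hpd_mass, prior_sd_intercept = prior_sd_intercept,
         prior_sd_slope = prior_sd_slope, sd_prior_rate = sd_prior_rate,
         rhat_max = rhat_max, ess_min = ess_min),
    class = "model_config"
  )
}

# --- Gaussian mixed sampler -------------------------------------------------

# y: response; X: fixed-effect design (already including intercept columns);
# prior_sd: per-column prior SD; sigma_group: integer condition index per
# observation (1..n_sigma) for distributional residual SDs; g1, g2: integer
# group indices for the two random-intercept factors (g2 may be NULL).
# trans: list of translation moves (see make_translations) that shift mass
# between coefficient blocks and random intercepts without changing the
# likelihood; they break the posterior correlation that otherwise makes
# intercepts and group-constant slopes mix slowly.
# Returns list(draws = array iter x chain x npar, par_names, re_u, re_v).

# Build the translation moves for a design: for every covariate that is
# constant within a grouping factor (including the implicit constant 1,
# i.e. the intercept columns), shifting its coefficient(s) by m while
# subtracting m * covariate from that group's random intercepts leaves
# X beta + u + v unchanged. Each such move is a valid Metropolis update
# whose acceptance ratio involves only the priors.
make_translations <- function(X, col_groups, g1, g2) {
  # candidates: the declared groups plus every single column (a column
  # masked by condition is constant within clips when clips are nested in
  # condition, so singleton moves matter for the second factor)
  cand <- unique(c(col_groups, as.list(seq_len(ncol(X)))))
  moves <- list()
  seen <- character(0)
  add_moves_for <- function(g, which_re) {
    for (cg in cand) {
      key <- paste(which_re, paste(cg, collapse = ","))
      if (key %in% seen) next
      # covariate value shared by all columns of the group (they are the
      # same covariate masked by condition; their sum is the covariate)
      val_obs <- rowSums(X[, cg, drop = FALSE])
      val_g <- tapply(val_obs, g, function(x) x[1])
      const <- all(abs(val_obs - val_g[g]) < 1e-12)
      if (!const) next
      seen <<- c(seen, key)
      moves[[length(moves) + 1]] <<- list(cols = cg, re = which_re,
                                          val = as.numeric(val_g))
    }
  }
  add_moves_for(g1, "u")
  if (!is.null(g2)) add_moves_for(g2, "v")
  moves
}

gibbs_gaussian <- function(y, X, prior_sd, sigma_group, g1, g2,
                           cfg, keep_re = TRUE, col_groups = NULL) {
  n <- length(y); P <- ncol(X)
  n_sigma <- max(sigma_group)
  J <- max(g1)
  K <- if (is.null(g2)) 0L else max(g2)
  rate <- cfg$sd_prior_rate
  par_names <- c(colnames(X), paste0("sigma", if (n_sigma > 1)
    paste0("_", seq_len(n_sigma)) else ""), "tau_participant",
    if (K > 0) "tau_clip")
  npar <- length(par_names)
  thin <- cfg$thin %||% 1L
  total <- cfg$warmup + cfg$draws * thin
  out <- array(NA_real_, c(cfg$draws, cfg$chains, npar))
  re_u <- if (keep_re) array(NA_real_, c(cfg$draws, cfg$chains, J)) else NULL
  re_v <- if (keep_re && K > 0) array(NA_real_, c(cfg$draws, cfg$chains, K)) else NULL
  prior_prec <- diag(1 / prior_sd^2, P)
  log_sd_prior <- function(s) stats::dexp(s, rate, log = TRUE) + log(s)
  if (is.null(col_groups)) col_groups <- as.list(seq_len(P))
  trans <- make_translations(X, col_groups, g1, g2)

  for (ch in seq_len(cfg$chains)) {
    withr::local_seed(child_seed(cfg$seed, ch))
    beta <- rep(0, P)
    u <- rep(0, J); v <- rep(0, K)
    sigma <- rep(stats::sd(y) + 1e-6, n_sigma)
    tau_u <- stats::sd(y) / 2 + 1e-6
    tau_v <- if (K > 0) stats::sd(y) / 2 + 1e-6 else NA
    step <- rep(0.2, n_sigma + 1L + (K > 0))
    step_tr <- rep(1, length(trans))
    step_rs <- c(0.2, 0.2)
    for (it in seq_len(total)) {
      w <- 1 / sigma[sigma_group]^2
      vk <- if (K > 0) v[g2] else 0
      # beta | rest
      r <- y - u[g1] - vk
      Xw <- X * w
      A <- crossprod(Xw, X) + prior_prec
      b <- crossprod(Xw, r)
      U <- chol(A)
      mean_beta <- backsolve(U, forwardsolve(t(U), b))
      beta <- as.numeric(mean_beta + backsolve(U, stats::rnorm(P)))
      mu <- as.numeric(X %*% beta)
      # u | rest
      e <- y - mu - vk
      prec_j <- as.numeric(rowsum(w, g1, reorder = TRUE)) + 1 / tau_u^2
      m_j <- as.numeric(rowsum(w * e, g1, reorder = TRUE)) / prec_j
      u <- stats::rnorm(J, m_j, 1 / sqrt(prec_j))
      # v | rest
      if (K > 0) {
        e <- y - mu - u[g1]
        prec_k <- as.numeric(rowsum(w, g2, reorder = TRUE)) + 1 / tau_v^2
        m_k <- as.numeric(rowsum(w * e, g2, reorder = TRUE)) / prec_k
        v <- stats::rnorm(K, m_k, 1 / sqrt(prec_k))
      }
      # sigma_c | rest (RW Metropolis on log sd); the whole scale block is
      # swept twice per iteration -- scale parameters are the slowest movers
      res <- y - mu - u[g1] - (if (K > 0) v[g2] else 0)
      for (sweep_sc in 1:3) {
      for (c_ in seq_len(n_sigma)) {
        sel <- sigma_group == c_
        cur <- sigma[c_]
        prop <- exp(log(cur) + stats::rnorm(1, 0, step[c_]))
        ll_cur <- sum(stats::dnorm(res[sel], 0, cur, log = TRUE)) + log_sd_prior(cur)
        ll_prop <- sum(stats::dnorm(res[sel], 0, prop, log = TRUE)) + log_sd_prior(prop)
        acc <- log(stats::runif(1)) < ll_prop - ll_cur
        if (acc) sigma[c_] <- prop
        if (it <= cfg$warmup)
          step[c_] <- exp(log(step[c_]) + (min(1, exp(min(0, ll_prop - ll_cur))) - 0.44) / sqrt(it))
      }
      # tau_u | u
      si <- n_sigma + 1L
      cur <- tau_u
      prop <- exp(log(cur) + stats::rnorm(1, 0, step[si]))
      ll_cur <- sum(stats::dnorm(u, 0, cur, log = TRUE)) + log_sd_prior(cur)
      ll_prop <- sum(stats::dnorm(u, 0, prop, log = TRUE)) + log_sd_prior(prop)
      if (log(stats::runif(1)) < ll_prop - ll_cur) tau_u <- prop
      if (it <= cfg$warmup)
        step[si] <- exp(log(step[si]) + (min(1, exp(min(0, ll_prop - ll_cur))) - 0.44) / sqrt(it))
      # tau_v | v
      if (K > 0) {
        si <- n_sigma + 2L
        cur <- tau_v
        prop <- exp(log(cur) + stats::rnorm(1, 0, step[si]))
        ll_cur <- sum(stats::dnorm(v, 0, cur, log = TRUE)) + log_sd_prior(cur)
        ll_prop <- sum(stats::dnorm(v, 0, prop, log = TRUE)) + log_sd_prior(prop)
        if (log(stats::runif(1)) < ll_prop - ll_cur) tau_v <- prop
        if (it <= cfg$warmup)
          step[si] <- exp(log(step[si]) + (min(1, exp(min(0, ll_prop - ll_cur))) - 0.44) / sqrt(it))
      }
      # rescale (non-centered) moves: random-walk log(tau) holding the
      # standardized intercepts u/tau fixed, so tau mixes independently of
      # the realized intercept magnitudes; acceptance needs the likelihood
      res_base <- res
      w <- 1 / sigma[sigma_group]^2
      rescale <- function(tau_cur, re_cur, idx_obs, step) {
        c_ <- exp(stats::rnorm(1, 0, step))
        re_prop <- re_cur * c_
        delta <- (re_prop - re_cur)[idx_obs]
        ll_diff <- sum(-0.5 * w * ((res_base - delta)^2 - res_base^2))
        lr <- ll_diff + stats::dexp(tau_cur * c_, rate, log = TRUE) -
          stats::dexp(tau_cur, rate, log = TRUE) + log(c_)
        list(acc = log(stats::runif(1)) < lr, c_ = c_, lr = lr)
      }
      rs <- rescale(tau_u, u, g1, step_rs[1])
      if (rs$acc) {
        res_base <- res_base - (u * (rs$c_ - 1))[g1]
        u <- u * rs$c_; tau_u <- tau_u * rs$c_
      }
      if (it <= cfg$warmup)
        step_rs[1] <- exp(log(step_rs[1]) + (min(1, exp(min(0, rs$lr))) - 0.44) / sqrt(it))
      if (K > 0) {
        rs <- rescale(tau_v, v, g2, step_rs[2])
        if (rs$acc) {
          res_base <- res_base - (v * (rs$c_ - 1))[g2]
          v <- v * rs$c_; tau_v <- tau_v * rs$c_
        }
        if (it <= cfg$warmup)
          step_rs[2] <- exp(log(step_rs[2]) + (min(1, exp(min(0, rs$lr))) - 0.44) / sqrt(it))
      }
      res <- res_base
      } # end scale sweeps
      # translation moves: likelihood-invariant shifts between coefficient
      # blocks and the random intercepts they are confounded with
      for (ti in seq_along(trans)) {
        mv <- trans[[ti]]
        m <- stats::rnorm(1, 0, step_tr[ti])
        re_cur <- if (mv$re == "u") u else v
        tau_cur <- if (mv$re == "u") tau_u else tau_v
        re_prop <- re_cur - m * mv$val
        b_prop <- beta
        b_prop[mv$cols] <- b_prop[mv$cols] + m
        lr <- sum(stats::dnorm(b_prop[mv$cols], 0, prior_sd[mv$cols], log = TRUE)) -
          sum(stats::dnorm(beta[mv$cols], 0, prior_sd[mv$cols], log = TRUE)) +
          sum(stats::dnorm(re_prop, 0, tau_cur, log = TRUE)) -
          sum(stats::dnorm(re_cur, 0, tau_cur, log = TRUE))
        if (log(stats::runif(1)) < lr) {
          beta <- b_prop
          if (mv$re == "u") u <- re_prop else v <- re_prop
        }
        if (it <= cfg$warmup)
          step_tr[ti] <- exp(log(step_tr[ti]) +
                             (min(1, exp(min(0, lr))) - 0.44) / sqrt(it))
      }
      if (it > cfg$warmup && (it - cfg$warmup) %% thin == 0L) {
        s <- (it - cfg$warmup) %/% thin
        out[s, ch, ] <- c(beta, sigma, tau_u, if (K > 0) tau_v)
        if (keep_re) {
          re_u[s, ch, ] <- u
          if (K > 0) re_v[s, ch, ] <- v
        }
      }
    }
  }
  dimnames(out)[[3]] <- par_names
  list(draws = out, par_names = par_names, re_u = re_u, re_v = re_v)
}

# --- Bernoulli (logit) mixed sampler ---------------------------------------

# z: 0/1; W: design incl. intercept; group: participant index.
metropolis_logit <- function(z, W, prior_sd, group, cfg, inner = 4,
                             keep_re = TRUE) {
  n <- length(z); P <- ncol(W)
  J <- max(group)
  rate <- cfg$sd_prior_rate
  par_names <- c(colnames(W), "tau_participant")
  thin <- cfg$thin %||% 1L
  total <- cfg$warmup + cfg$draws * thin
  out <- array(NA_real_, c(cfg$draws, cfg$chains, P + 1L))
  re_u <- if (keep_re) array(NA_real_, c(cfg$draws, cfg$chains, J)) else NULL
  # proposal preconditioner from a ridge-penalized Fisher information at the
  # (penalized) MLE; fallback to identity if ill-conditioned
  prop_chol <- tryCatch({
    fit <- suppressWarnings(stats::glm.fit(W, z, family = stats::binomial()))
    p <- pmin(pmax(fit$fitted.values, 1e-4), 1 - 1e-4)
    info <- crossprod(W * (p * (1 - p)), W) + diag(1 / prior_sd^2, P)
    chol(solve(info))
  }, error = function(e) diag(1, P))
  loglik_eta <- function(eta) sum(z * eta - log1p(exp(eta)))
  log_sd_prior <- function(s) stats::dexp(s, rate, log = TRUE) + log(s)
  # translation moves for columns constant within participant
  trans <- make_translations(W, as.list(seq_len(P)), group, NULL)

  for (ch in seq_len(cfg$chains)) {
    withr::local_seed(child_seed(cfg$seed, 100 + ch))
    gamma <- rep(0, P)
    u <- rep(0, J)
    tau <- 0.5
    scale_g <- 1.0; step_u <- 0.4; step_t <- 0.3
    step_tr <- rep(0.5, length(trans))
    eta_fix <- as.numeric(W %*% gamma)
    for (it in seq_len(total)) {
      for (rep_ in seq_len(inner)) {
        # gamma block
        prop <- gamma + scale_g * as.numeric(crossprod(prop_chol, stats::rnorm(P)))
        eta_prop <- as.numeric(W %*% prop)
        lp_cur <- loglik_eta(eta_fix + u[group]) +
          sum(stats::dnorm(gamma, 0, prior_sd, log = TRUE))
        lp_prop <- loglik_eta(eta_prop + u[group]) +
          sum(stats::dnorm(prop, 0, prior_sd, log = TRUE))
        a <- min(1, exp(lp_prop - lp_cur))
        if (stats::runif(1) < a) { gamma <- prop; eta_fix <- eta_prop }
        if (it <= cfg$warmup)
          scale_g <- exp(log(scale_g) + (a - 0.234) / sqrt(it))
        # u block: independent accept/reject per participant
        u_prop <- u + stats::rnorm(J, 0, step_u)
        eta_cur <- eta_fix + u[group]
        eta_p <- eta_fix + u_prop[group]
        ll_obs_cur <- z * eta_cur - log1p(exp(eta_cur))
        ll_obs_prop <- z * eta_p - log1p(exp(eta_p))
        d_j <- as.numeric(rowsum(ll_obs_prop - ll_obs_cur, group, reorder = TRUE)) +
          stats::dnorm(u_prop, 0, tau, log = TRUE) -
          stats::dnorm(u, 0, tau, log = TRUE)
        acc_j <- log(stats::runif(J)) < d_j
        u[acc_j] <- u_prop[acc_j]
        if (it <= cfg$warmup)
          step_u <- exp(log(step_u) + (mean(pmin(1, exp(pmin(0, d_j)))) - 0.44) / sqrt(it))
        # tau
        prop_t <- exp(log(tau) + stats::rnorm(1, 0, step_t))
        d_t <- sum(stats::dnorm(u, 0, prop_t, log = TRUE)) + log_sd_prior(prop_t) -
          sum(stats::dnorm(u, 0, tau, log = TRUE)) - log_sd_prior(tau)
        if (log(stats::runif(1)) < d_t) tau <- prop_t
        if (it <= cfg$warmup)
          step_t <- exp(log(step_t) + (min(1, exp(min(0, d_t))) - 0.44) / sqrt(it))
        # rescale move for tau (non-centered; needs the Bernoulli likelihood)
        c_ <- exp(stats::rnorm(1, 0, 0.2))
        u_rs <- u * c_
        lr_rs <- loglik_eta(eta_fix + u_rs[group]) -
          loglik_eta(eta_fix + u[group]) +
          stats::dexp(tau * c_, rate, log = TRUE) -
          stats::dexp(tau, rate, log = TRUE) + log(c_)
        if (log(stats::runif(1)) < lr_rs) { u <- u_rs; tau <- tau * c_ }
        # translation moves (likelihood-invariant; priors only)
        for (ti in seq_along(trans)) {
          mv <- trans[[ti]]
          m <- stats::rnorm(1, 0, step_tr[ti])
          g_prop <- gamma
          g_prop[mv$cols] <- g_prop[mv$cols] + m
          u_prop2 <- u - m * mv$val
          lr <- sum(stats::dnorm(g_prop[mv$cols], 0, prior_sd[mv$cols], log = TRUE)) -
            sum(stats::dnorm(gamma[mv$cols], 0, prior_sd[mv$cols], log = TRUE)) +
            sum(stats::dnorm(u_prop2, 0, tau, log = TRUE)) -
            sum(stats::dnorm(u, 0, tau, log = TRUE))
          if (log(stats::runif(1)) < lr) {
            gamma <- g_prop
            u <- u_prop2
            eta_fix <- as.numeric(W %*% gamma)
          }
          if (it <= cfg$warmup)
            step_tr[ti] <- exp(log(step_tr[ti]) +
                               (min(1, exp(min(0, lr))) - 0.44) / sqrt(it))
        }
      }
      if (it > cfg$warmup && (it - cfg$warmup) %% thin == 0L) {
        s <- (it - cfg$warmup) %/% thin
        out[s, ch, ] <- c(gamma, tau)
        if (keep_re) re_u[s, ch, ] <- u
      }
    }
  }
  dimnames(out)[[3]] <- par_names
  list(draws = out, par_names = par_names, re_u = re_u)
}

# --- Diagnostics ------------------------------------------------------------

#' Split-chain R-hat
#'
#' Potential-scale-reduction statistic computed after splitting each chain
#' in half; values near 1 indicate between- and within-chain agreement.
#'
#' @param mat draws-by-chains matrix for one parameter.
#' @return Scalar R-hat.
#' @export
split_rhat <- function(mat) {
  mat <- as.matrix(mat)
  n <- nrow(mat) %/% 2L
  halves <- cbind(mat[seq_len(n), , drop = FALSE],
                  mat[(n + 1L):(2L * n), , drop = FALSE])
  m <- ncol(halves)
  means <- colMeans(halves)
  vars <- apply(halves, 2, stats::var)
  W <- mean(vars)
  B <- n * stats::var(means)
  if (W == 0) return(1)
  sqrt(((n - 1) / n * W + B / n) / W)
}

#' Effective sample size
#'
#' Autocorrelation-based ESS using Geyer's initial positive sequence,
#' combined across chains.
#'
#' @param mat draws-by-chains matrix for one parameter.
#' @return Scalar effective sample size.
#' @export
ess_basic <- function(mat) {
  mat <- as.matrix(mat)
  n <- nrow(mat); m <- ncol(mat)
  if (stats::var(as.numeric(mat)) == 0) return(n * m)
  rho_mean <- rep(0, n - 1)
  for (ch in seq_len(m)) {
    x <- mat[, ch] - mean(mat[, ch])
    ac <- stats::acf(x, lag.max = n - 1, plot = FALSE,
                     demean = FALSE)$acf[, 1, 1]
    rho_mean <- rho_mean + ac[-1] / m
  }
  # initial positive sequence on paired sums
  tau <- 1
  k <- 1
  while (k + 1 <= length(rho_mean)) {
    pair <- rho_mean[k] + rho_mean[k + 1]
    if (pair < 0) break
    tau <- tau + 2 * pair
    k <- k + 2
  }
  max(1, n * m / tau)
}
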