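# Bayesian longitudinal graded-response IRT (LIRT).
#
# Model: Y_{s,t,i} | theta_{s,t} ~ GRM(alpha_i, kappa_i.partial, kappa_i.total)
#        theta_{s,t} = gamma0_s + gamma1_s * t
#        gamma1_s = gamma1'_s + Z_s beta,  gamma1'_s ~ N(mu, slope_sd^2)
#        gamma0_s ~ N(0, 1)  (fixed; anchors the latent scale)
# Weakly informative priors on the rest:
#        alpha_i ~ LogNormal(0, 1); kappa_partial ~ N(0, 10^2);
#        kappa_total = kappa_partial + delta_i, delta_i ~ LogNormal(0, 1)
#        (ordering enforced by construction); mu, beta_j ~ N(0, 10^2);
#        slope_sd ~ HalfNormal(5).
#
# Sampler: Metropolis-within-Gibbs. Item blocks use adaptive multivariate
# random-walk proposals on (log alpha, kappa_partial, log gap), with the
# proposal covariance learned from burn-in draws (adaptation during burn-in
# only). Subjects are conditionally independent given the structural
# parameters, so the gamma updates are vectorized element-wise accept/reject
# sweeps. The subject slopes are sampled on the total-slope scale gamma1 with
# prior N(mu + Z beta, slope_sd^2), which makes (mu, beta) a conjugate normal
# regression block (joint Gibbs draw); gamma1' = gamma1 - Z beta is recovered
# per retained draw. Two likelihood-invariant parameter-expansion moves —
# a joint rescaling (theta, hyper, slope_sd scaled by c, discriminations by
# 1/c) and a joint translation (gamma0 shifted by d, thresholds by alpha d) —
# traverse the latent scale and location ridges that plain conditional
# updates cross slowly.

.PRIOR <- list(kappa_sd = 10, mu_sd = 10, beta_sd = 10, slope_sd_scale = 5)

#' Bundle a full set of LIRT parameters
#'
#' @param items an \code{\link{item_parameters}}-shaped data.frame (6 rows).
#' @param gamma0 per-subject baseline disability.
#' @param gamma1_raw per-subject residual slope gamma1' (total slope minus
#'   the covariate contribution Z beta).
#' @param mu population mean of gamma1'.
#' @param beta length-5 slope regression coefficients (canonical covariate
#'   order).
#' @param slope_sd SD of gamma1' around mu.
#' @return list of class \code{"lirt_parameters"}. Structural support
#'   violations (non-positive alpha or slope_sd, unordered thresholds) are
#'   not rejected here; \code{\link{log_prior}} maps them to \code{-Inf}.
#' @export
lirt_parameters <- function(items, gamma0, gamma1_raw, mu, beta, slope_sd) {
  items <- as.data.frame(items)
  stopifnot(all(c("item", "alpha", "kappa_partial", "kappa_total")
                %in% names(items)))
  if (length(gamma0) != length(gamma1_raw))
    stop("gamma0 and gamma1_raw must have equal length")
  if (length(beta) != 5L) stop("beta must have length 5")
  structure(list(items = items, gamma0 = as.numeric(gamma0),
                 gamma1_raw = as.numeric(gamma1_raw), mu = as.numeric(mu),
                 beta = stats::setNames(as.numeric(beta), .covariate_names),
                 slope_sd = as.numeric(slope_sd)),
            class = "lirt_parameters")
}

#' Log prior density of the LIRT parameters
#'
#' Sum of: N(0,1) on every gamma0; hierarchical N(mu, slope_sd^2) on every
#' gamma1'; LogNormal(0,1) on discriminations; N(0, 10^2) on kappa_partial;
#' LogNormal(0,1) on the threshold gap kappa_total - kappa_partial;
#' N(0, 10^2) on mu and each beta; HalfNormal(5) on slope_sd. Returns
#' \code{-Inf} when a structural constraint (alpha > 0, ordered thresholds,
#' slope_sd > 0) is violated.
#'
#' @param params a \code{\link{lirt_parameters}} object.
#' @return scalar log-density.
#' @export
log_prior <- function(params) {
  stopifnot(inherits(params, "lirt_parameters"))
  it <- params$items
  delta <- it$kappa_total - it$kappa_partial
  if (any(it$alpha <= 0) || any(delta <= 0) || params$slope_sd <= 0)
    return(-Inf)
  p <- .PRIOR
  sum(stats::dnorm(params$gamma0, 0, 1, log = TRUE)) +
    sum(stats::dnorm(params$gamma1_raw, params$mu, params$slope_sd,
                     log = TRUE)) +
    sum(stats::dlnorm(it$alpha, 0, 1, log = TRUE)) +
    sum(stats::dnorm(it$kappa_partial, 0, p$kappa_sd, log = TRUE)) +
    sum(stats::dlnorm(delta, 0, 1, log = TRUE)) +
    stats::dnorm(params$mu, 0, p$mu_sd, log = TRUE) +
    sum(stats::dnorm(params$beta, 0, p$beta_sd, log = TRUE)) +
    log(2) + stats::dnorm(params$slope_sd, 0, p$slope_sd_scale, log = TRUE)
}

#' Log posterior density of the LIRT
#'
#' \code{\link{log_prior}} plus the panel log-likelihood, with the latent
#' disability reconstructed as theta(s, t) = gamma0_s + gamma1_s t and
#' gamma1_s = gamma1'_s + Z_s beta. Subject order in \code{params} must match
#' \code{panel$subjects}.
#'
#' @param params a \code{\link{lirt_parameters}} object.
#' @param panel a standardized \code{\link{katz_panel}}.
#' @return scalar log-density.
#' @export
log_posterior <- function(params, panel) {
  stopifnot(inherits(params, "lirt_parameters"),
            inherits(panel, "katz_panel"))
  lp <- log_prior(params)
  if (!is.finite(lp)) return(lp)
  subj <- panel$subjects
  if (length(params$gamma0) != nrow(subj))
    stop("gamma0 length does not match the number of subjects")
  Z <- .design_Z(subj)
  gamma1 <- params$gamma1_raw + drop(Z %*% params$beta)
  visits <- unique(panel$responses[, c("subject_id", "visit_time")])
  si <- match(visits$subject_id, subj$subject_id)
  thetas <- data.frame(subject_id = visits$subject_id,
                       visit_time = visits$visit_time,
                       theta = params$gamma0[si] + gamma1[si] * visits$visit_time,
                       stringsAsFactors = FALSE)
  ip <- item_parameters(params$items$item, params$items$alpha,
                        params$items$kappa_partial, params$items$kappa_total)
  lp + panel_loglik(ip, thetas, panel)
}

#' MCMC configuration
#'
#' @param n_burnin adaptation/burn-in iterations discarded per chain.
#' @param n_keep retained draws per chain.
#' @param thin keep every \code{thin}-th post-burn-in draw.
#' @param n_chains number of independent chains.
#' @param seed integer RNG seed; chain c reseeds at \code{seed + c}.
#' @param adapt_interval proposal scales adapt every this many burn-in
#'   iterations.
#' @return list of class \code{"mcmc_config"}.
#' @export
mcmc_config <- function(n_burnin = 4000L, n_keep = 1000L, thin = 1L,
                        n_chains = 2L, seed = 1L, adapt_interval = 50L) {
  cfg <- list(n_burnin = as.integer(n_burnin), n_keep = as.integer(n_keep),
              thin = as.integer(thin), n_chains = as.integer(n_chains),
              seed = as.integer(seed), adapt_interval = as.integer(adapt_interval))
  if (cfg$n_burnin < 0L || cfg$n_keep <= 0L || cfg$n_chains <= 0L)
    stop("iteration counts must be positive")
  if (cfg$thin < 1L) stop("thin must be >= 1")
  class(cfg) <- "mcmc_config"
  cfg
}

# --- internal model data ----------------------------------------------------

.lirt_model_data <- function(panel) {
  subj <- panel$subjects
  if (nrow(subj) == 0L) stop("cannot fit the LIRT on an empty dataset")
  Z <- .design_Z(subj)
  resp <- panel$responses[!is.na(panel$responses$category), , drop = FALSE]
  list(S = nrow(subj), ids = subj$subject_id, Z = Z, X = cbind(1, Z),
       sidx = match(resp$subject_id, subj$subject_id),
       iidx = match(resp$item, katz_items),
       tt = resp$visit_time, y = as.integer(resp$category),
       item_rows = lapply(seq_along(katz_items),
                          function(i) which(match(resp$item, katz_items) == i)))
}

.gsum <- function(x, g, n) {
  out <- numeric(n)
  if (length(x)) {
    s <- rowsum(x, g)
    out[as.integer(rownames(s))] <- s[, 1L]
  }
  out
}

# one chain of the Metropolis-within-Gibbs sampler
.run_chain <- function(md, config, chain_seed, verbose = FALSE) {
  set.seed(chain_seed)
  S <- md$S
  n_item <- length(katz_items)
  p <- .PRIOR

  # state (items in sampling space: log alpha, kappa_partial, log delta)
  la <- rep(0, n_item)
  k1 <- rep(0, n_item)
  ld <- rep(0, n_item)
  g0 <- rep(0, S)
  g1 <- rep(0, S)            # total slope gamma1_s
  hyper <- rep(0, 6L)        # (mu, beta): regression of gamma1 on X = [1 Z]
  ssd <- 1

  alpha <- exp(la); k2 <- k1 + exp(ld)
  theta <- g0[md$sidx] + g1[md$sidx] * md$tt
  ll_r <- .grm_ll(alpha[md$iidx] * theta - k1[md$iidx],
                  alpha[md$iidx] * theta - k2[md$iidx], md$y)
  if (length(ll_r) && !all(is.finite(ll_r)))
    stop("non-finite log-likelihood at initialization")

  # adaptive proposal scales; item proposals use a learned 3x3 covariance
  sc_item <- rep(0.1, n_item)
  prop_L <- rep(list(NULL), n_item)     # chol factors of learned covariances
  sc_g0 <- 0.5
  sc_g1 <- 0.5
  sc_scale <- 0.1
  sc_trans <- 0.1
  acc_item <- rep(0, n_item); try_item <- rep(0, n_item)
  acc_g0 <- 0; acc_g1 <- 0; try_g <- 0
  acc_scale <- 0; acc_trans <- 0
  hist_items <- array(NA_real_, c(max(config$n_burnin, 1L), n_item, 3L))

  item_prior <- function(la_i, k1_i, ld_i)
    stats::dnorm(la_i, 0, 1, log = TRUE) +
    stats::dnorm(k1_i, 0, p$kappa_sd, log = TRUE) +
    stats::dnorm(ld_i, 0, 1, log = TRUE)

  n_iter <- config$n_burnin + config$n_keep * config$thin
  keep_at <- config$n_burnin + seq_len(config$n_keep) * config$thin
  draws <- list(
    items = array(NA_real_, c(config$n_keep, n_item, 3L),
                  dimnames = list(NULL, katz_items,
                                  c("alpha", "kappa_partial", "kappa_total"))),
    mu = numeric(config$n_keep),
    beta = matrix(NA_real_, config$n_keep, 5L,
                  dimnames = list(NULL, .covariate_names)),
    slope_sd = numeric(config$n_keep),
    gamma0 = matrix(NA_real_, config$n_keep, S),
    gamma1_raw = matrix(NA_real_, config$n_keep, S))
  k_out <- 0L
  XtX <- crossprod(md$X)

  for (iter in seq_len(n_iter)) {
    adapting <- iter <= config$n_burnin

    ## 1. item blocks: joint RW on (log alpha, kappa_partial, log delta)
    for (i in seq_len(n_item)) {
      idx <- md$item_rows[[i]]
      step3 <- if (is.null(prop_L[[i]])) stats::rnorm(3L) * sc_item[i]
               else sc_item[i] * drop(crossprod(prop_L[[i]], stats::rnorm(3L)))
      prop <- c(la[i], k1[i], ld[i]) + step3
      a_p <- exp(prop[1L]); k1_p <- prop[2L]; k2_p <- k1_p + exp(prop[3L])
      dlp <- item_prior(prop[1L], prop[2L], prop[3L]) -
        item_prior(la[i], k1[i], ld[i])
      if (length(idx)) {
        th <- theta[idx]
        ll_p <- .grm_ll(a_p * th - k1_p, a_p * th - k2_p, md$y[idx])
        dlp <- dlp + sum(ll_p) - sum(ll_r[idx])
      }
      try_item[i] <- try_item[i] + 1
      if (is.finite(dlp) && log(stats::runif(1)) < dlp) {
        la[i] <- prop[1L]; k1[i] <- prop[2L]; ld[i] <- prop[3L]
        alpha[i] <- a_p; k2[i] <- k2_p
        if (length(idx)) ll_r[idx] <- ll_p
        acc_item[i] <- acc_item[i] + 1
      }
    }

    ## 2. gamma0 sweep (vectorized element-wise MH)
    g0_p <- g0 + stats::rnorm(S) * sc_g0
    theta_p <- g0_p[md$sidx] + g1[md$sidx] * md$tt
    ll_p <- .grm_ll(alpha[md$iidx] * theta_p - k1[md$iidx],
                    alpha[md$iidx] * theta_p - k2[md$iidx], md$y)
    dls <- .gsum(ll_p - ll_r, md$sidx, S) +
      stats::dnorm(g0_p, 0, 1, log = TRUE) -
      stats::dnorm(g0, 0, 1, log = TRUE)
    acc <- log(stats::runif(S)) < dls
    if (any(acc)) {
      g0[acc] <- g0_p[acc]
      m <- acc[md$sidx]
      theta[m] <- theta_p[m]
      ll_r[m] <- ll_p[m]
    }
    acc_g0 <- acc_g0 + mean(acc)

    ## 3. gamma1 sweep; prior N(mu + Z beta, ssd^2) on the total slope
    prior_mean <- drop(md$X %*% hyper)
    g1_p <- g1 + stats::rnorm(S) * sc_g1
    theta_p <- g0[md$sidx] + g1_p[md$sidx] * md$tt
    ll_p <- .grm_ll(alpha[md$iidx] * theta_p - k1[md$iidx],
                    alpha[md$iidx] * theta_p - k2[md$iidx], md$y)
    dls <- .gsum(ll_p - ll_r, md$sidx, S) +
      stats::dnorm(g1_p, prior_mean, ssd, log = TRUE) -
      stats::dnorm(g1, prior_mean, ssd, log = TRUE)
    acc <- log(stats::runif(S)) < dls
    if (any(acc)) {
      g1[acc] <- g1_p[acc]
      m <- acc[md$sidx]
      theta[m] <- theta_p[m]
      ll_r[m] <- ll_p[m]
    }
    acc_g1 <- acc_g1 + mean(acc)
    try_g <- try_g + 1

    ## 4. (mu, beta) conjugate normal regression draw given gamma1, ssd
    prior_prec <- diag(1 / c(p$mu_sd^2, rep(p$beta_sd^2, 5L)))
    V_inv <- XtX / ssd^2 + prior_prec
    U <- chol(V_inv)
    m_h <- backsolve(U, backsolve(U, crossprod(md$X, g1) / ssd^2,
                                  transpose = TRUE))
    hyper <- drop(m_h + backsolve(U, stats::rnorm(6L)))

    ## 5. slope_sd MH on the log scale (HalfNormal(5) prior + Jacobian)
    res <- g1 - drop(md$X %*% hyper)
    ls_p <- log(ssd) + stats::rnorm(1L) * 0.1
    ssd_p <- exp(ls_p)
    dlp <- sum(stats::dnorm(res, 0, ssd_p, log = TRUE)) -
      sum(stats::dnorm(res, 0, ssd, log = TRUE)) +
      stats::dnorm(ssd_p, 0, p$slope_sd_scale, log = TRUE) -
      stats::dnorm(ssd, 0, p$slope_sd_scale, log = TRUE) +
      ls_p - log(ssd)
    if (is.finite(dlp) && log(stats::runif(1)) < dlp) ssd <- ssd_p

    ## 6. likelihood-invariant rescaling: theta -> c theta, alpha -> alpha/c
    ## (hyper and slope_sd scale with theta); crosses the latent-scale ridge
    cc <- exp(stats::rnorm(1L) * sc_scale)
    hsd <- c(p$mu_sd, rep(p$beta_sd, 5L))
    dlp <- sum(stats::dnorm(cc * g0, 0, 1, log = TRUE) -
                 stats::dnorm(g0, 0, 1, log = TRUE)) -
      S * log(cc) +
      sum(stats::dnorm(cc * hyper, 0, hsd, log = TRUE) -
            stats::dnorm(hyper, 0, hsd, log = TRUE)) +
      stats::dnorm(cc * ssd, 0, p$slope_sd_scale, log = TRUE) -
      stats::dnorm(ssd, 0, p$slope_sd_scale, log = TRUE) +
      sum(stats::dnorm(la - log(cc), 0, 1, log = TRUE) -
            stats::dnorm(la, 0, 1, log = TRUE)) +
      (2 * S + 1) * log(cc)
    if (is.finite(dlp) && log(stats::runif(1)) < dlp) {
      g0 <- cc * g0; g1 <- cc * g1; hyper <- cc * hyper; ssd <- cc * ssd
      la <- la - log(cc); alpha <- alpha / cc
      k1 <- k1  # thresholds unchanged
      theta <- cc * theta
      acc_scale <- acc_scale + 1
    }

    ## 7. likelihood-invariant translation: gamma0 + d, kappa_{i,.} + alpha_i d
    dd <- stats::rnorm(1L) * sc_trans
    dlp <- sum(stats::dnorm(g0 + dd, 0, 1, log = TRUE) -
                 stats::dnorm(g0, 0, 1, log = TRUE)) +
      sum(stats::dnorm(k1 + alpha * dd, 0, p$kappa_sd, log = TRUE) -
            stats::dnorm(k1, 0, p$kappa_sd, log = TRUE))
    if (is.finite(dlp) && log(stats::runif(1)) < dlp) {
      g0 <- g0 + dd
      k1 <- k1 + alpha * dd
      k2 <- k2 + alpha * dd
      theta <- theta + dd
      acc_trans <- acc_trans + 1
    }

    if (adapting) hist_items[iter, , ] <- cbind(la, k1, ld)

    ## adaptation (burn-in only; kernel is fixed afterwards)
    if (adapting && iter %% config$adapt_interval == 0L) {
      step <- min(0.25, 2 / sqrt(iter / config$adapt_interval))
      rate_i <- acc_item / pmax(try_item, 1)
      sc_item <- sc_item * exp(step * (rate_i - 0.3))
      sc_g0 <- sc_g0 * exp(step * (acc_g0 / try_g - 0.44))
      sc_g1 <- sc_g1 * exp(step * (acc_g1 / try_g - 0.44))
      sc_scale <- sc_scale * exp(step * (acc_scale / try_g - 0.44))
      sc_trans <- sc_trans * exp(step * (acc_trans / try_g - 0.44))
      acc_item[] <- 0; try_item[] <- 0
      acc_g0 <- 0; acc_g1 <- 0; try_g <- 0
      acc_scale <- 0; acc_trans <- 0
      # learn per-item proposal covariance from the later half of burn-in
      if (iter >= 400L) {
        lo <- max(1L, iter %/% 2L)
        for (i in seq_len(n_item)) {
          cv <- stats::cov(hist_items[lo:iter, i, ])
          ch <- tryCatch(chol(cv + diag(1e-8, 3L)), error = function(e) NULL)
          if (!is.null(ch) && is.null(prop_L[[i]])) sc_item[i] <- 1.5
          if (!is.null(ch)) prop_L[[i]] <- ch
        }
      }
    }

    if (iter %in% keep_at) {
      k_out <- k_out + 1L
      draws$items[k_out, , 1L] <- alpha
      draws$items[k_out, , 2L] <- k1
      draws$items[k_out, , 3L] <- k2
      draws$mu[k_out] <- hyper[1L]
      draws$beta[k_out, ] <- hyper[-1L]
      draws$slope_sd[k_out] <- ssd
      draws$gamma0[k_out, ] <- g0
      draws$gamma1_raw[k_out, ] <- g1 - drop(md$Z %*% hyper[-1L])
    }
    if (verbose && iter %% 500L == 0L)
      message(sprintf("iter %d/%d", iter, n_iter))
  }
  draws$accept <- list(item = acc_item / pmax(try_item, 1),
                       gamma0 = if (try_g > 0) acc_g0 / try_g else NA,
                       gamma1 = if (try_g > 0) acc_g1 / try_g else NA)
  draws
}

#' Fit the longitudinal graded-response IRT by MCMC
#'
#' Runs \code{n_chains} independent Metropolis-within-Gibbs chains (see the
#' header of this file for the blocking scheme). Proposal scales adapt only
#' during burn-in, so retained draws come from a fixed kernel. Chains are
#' bit-reproducible given \code{config$seed}.
#'
#' @param panel a \code{\link{katz_panel}} with standardized covariates.
#' @param config an \code{\link{mcmc_config}}.
#' @param verbose print progress every 500 iterations.
#' @return An object of class \code{"lirt_fit"}: per-chain draws of the item
#'   parameters, \code{mu}, \code{beta}, \code{slope_sd} and the
#'   subject-level \code{gamma0} / \code{gamma1_raw}.
#' @export
run_mcmc <- function(panel, config = mcmc_config(), verbose = FALSE) {
  stopifnot(inherits(panel, "katz_panel"), inherits(config, "mcmc_config"))
  md <- .lirt_model_data(panel)
  chains <- lapply(seq_len(config$n_chains), function(ch)
    .run_chain(md, config, chain_seed = config$seed + ch, verbose = verbose))
  structure(list(chains = chains, config = config, subject_ids = md$ids,
                 items = katz_items, n_responses = length(md$y)),
            class = "lirt_fit")
}

#' @export
print.lirt_fit <- function(x, ...) {
  cat(sprintf(
    "lirt_fit: %d chain(s) x %d draws, %d subjects, %d observed responses\n",
    length(x$chains), x$config$n_keep, length(x$subject_ids), x$n_responses))
  invisible(x)
}
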