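# Posterior summaries (mean, posterior SD, central 95% credible interval)
# and convergence diagnostics (split R-hat, effective sample size).

# named list of draw matrices (iterations x chains), structural params first
.fit_draw_matrices <- function(fit, include_subject_level = FALSE) {
  stopifnot(inherits(fit, "lirt_fit"))
  ch <- fit$chains
  grab <- function(f) do.call(cbind, lapply(ch, f))
  out <- list()
  for (i in seq_along(fit$items)) {
    it <- fit$items[i]
    out[[paste0("alpha[", it, "]")]] <- grab(function(c) c$items[, i, 1L])
    out[[paste0("kappa_partial[", it, "]")]] <- grab(function(c) c$items[, i, 2L])
    out[[paste0("kappa_total[", it, "]")]] <- grab(function(c) c$items[, i, 3L])
  }
  out[["mu"]] <- grab(function(c) c$mu)
  for (j in seq_along(.covariate_names))
    out[[paste0("beta[", .covariate_names[j], "]")]] <-
      grab(function(c) c$beta[, j])
  out[["slope_sd"]] <- grab(function(c) c$slope_sd)
  attr(out, "n_structural") <- length(out)
  if (include_subject_level) {
    for (s in seq_along(fit$subject_ids)) {
      id <- fit$subject_ids[s]
      out[[paste0("gamma0[", id, "]")]] <- grab(function(c) c$gamma0[, s])
      out[[paste0("gamma1_raw[", id, "]")]] <- grab(function(c) c$gamma1_raw[, s])
    }
  }
  out
}

#' Summarize an LIRT posterior
#'
#' Pools retained draws across chains and reports, per parameter, the
#' posterior mean, the posterior SD (the "SE" column of the reporting
#' format), the empirical 2.5% and 97.5% quantiles (R's default
#' linear-interpolation quantile, type 7), and a Monte Carlo standard error
#' (posterior SD / sqrt(ESS)) to disambiguate the two notions of "SE".
#'
#' @param fit a \code{\link{run_mcmc}} fit.
#' @param include_subject_level also summarize per-subject gamma0 and
#'   gamma1' (flagged by the \code{level} column).
#' @return data.frame with columns \code{parameter, mean, se, q2.5, q97.5,
#'   mcse, level}.
#' @export
summarize_posterior <- function(fit, include_subject_level = FALSE) {
  mats <- .fit_draw_matrices(fit, include_subject_level)
  n_struct <- attr(mats, "n_structural")
  if (nrow(mats[[1L]]) * ncol(mats[[1L]]) < 10L)
    stop("fewer than 10 retained draws; posterior summaries are meaningless")
  rows <- lapply(seq_along(mats), function(k) {
    m <- mats[[k]]
    x <- as.vector(m)
    q <- stats::quantile(x, c(0.025, 0.975), names = FALSE, type = 7)
    data.frame(parameter = names(mats)[k], mean = mean(x),
               se = stats::sd(x), q2.5 = q[1L], q97.5 = q[2L],
               mcse = stats::sd(x) / sqrt(max(1, .ess(m))),
               level = if (k <= n_struct) "structural" else "subject",
               stringsAsFactors = FALSE, check.names = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

# split each chain in half (dropping an odd leading draw)
.split_chains <- function(m) {
  n <- nrow(m)
  h <- n %/% 2L
  if (h < 1L) return(m)
  do.call(cbind, lapply(seq_len(ncol(m)), function(j)
    cbind(m[seq_len(h), j], m[n - h + seq_len(h), j])))
}

# split R-hat (between/within variance ratio on split chains)
.rhat <- function(m) {
  sp <- .split_chains(m)
  n <- nrow(sp); M <- ncol(sp)
  if (n < 2L || M < 2L) return(NA_real_)
  W <- mean(apply(sp, 2L, stats::var))
  B <- n * stats::var(colMeans(sp))
  if (!is.finite(W) || W == 0) return(NaN)
  sqrt(((n - 1) / n * W + B / n) / W)
}

# effective sample size via chain-averaged autocorrelations with Geyer's
# initial-monotone-positive truncation, on split chains
.ess <- function(m) {
  sp <- .split_chains(m)
  n <- nrow(sp); M <- ncol(sp)
  if (n < 4L) return(n * M)
  W <- mean(apply(sp, 2L, stats::var))
  if (!is.finite(W) || W == 0) return(NaN)
  max_lag <- min(n - 2L, 500L)
  acov <- sapply(seq_len(M), function(j) {
    a <- stats::acf(sp[, j], lag.max = max_lag, plot = FALSE,
                    type = "covariance", demean = TRUE)$acf[, 1L, 1L]
    a
  })
  acov <- rowMeans(acov)
  B_over_n <- stats::var(colMeans(sp))
  var_plus <- (n - 1) / n * W + B_over_n
  rho <- 1 - (W - acov[-1L]) / var_plus
  # pair sums; stop at the first non-positive pair, enforce monotonicity
  np <- length(rho) %/% 2L
  if (np == 0L) return(n * M)
  psum <- rho[2 * seq_len(np) - 1L] + rho[2 * seq_len(np)]
  tmax <- which(psum <= 0)[1L]
  if (is.na(tmax)) tmax <- np + 1L
  psum <- psum[seq_len(tmax - 1L)]
  if (length(psum) > 1L) psum <- cummin(psum)
  tau <- 1 + 2 * sum(psum)
  min(n * M, n * M / max(tau, 1e-12))
}

#' Convergence diagnostics for an LIRT fit
#'
#' Split-R-hat and effective sample size per structural parameter (pooled
#' subject-level parameters are excluded by default: there are two per
#' subject). Warns when any structural R-hat exceeds 1.05. Constant chains
#' make R-hat undefined and are reported as \code{NaN} with a warning.
#'
#' @param fit a \code{\link{run_mcmc}} fit with at least 2 chains or at
#'   least 200 retained draws.
#' @return data.frame with columns \code{parameter, rhat, ess}.
#' @export
convergence_diagnostics <- function(fit) {
  stopifnot(inherits(fit, "lirt_fit"))
  if (length(fit$chains) < 2L && fit$config$n_keep < 200L)
    stop("need at least 2 chains or 200 draws for diagnostics")
  mats <- .fit_draw_matrices(fit, include_subject_level = FALSE)
  out <- data.frame(parameter = names(mats),
                    rhat = vapply(mats, .rhat, numeric(1L)),
                    ess = vapply(mats, .ess, numeric(1L)),
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  if (any(is.nan(out$rhat)))
    warning("R-hat undefined (zero within-chain variance) for: ",
            paste(out$parameter[is.nan(out$rhat)], collapse = ", "))
  bad <- is.finite(out$rhat) & out$rhat > 1.05
  if (any(bad))
    warning("R-hat > 1.05 for structural parameter(s): ",
            paste(out$parameter[bad], collapse = ", "))
  out
}

#' Posterior means of the per-visit disability levels
#'
#' @param fit a \code{\link{run_mcmc}} fit.
#' @param panel the fitted \code{\link{katz_panel}}.
#' @return data.frame \code{subject_id, visit_time, theta}: posterior mean of
#'   gamma0_s + gamma1_s t at every measured visit.
#' @export
posterior_theta <- function(fit, panel) {
  stopifnot(inherits(fit, "lirt_fit"), inherits(panel, "katz_panel"))
  subj <- panel$subjects
  if (!identical(fit$subject_ids, subj$subject_id))
    stop("fit and panel subject sets differ")
  Z <- .design_Z(subj)
  g0 <- Reduce(`+`, lapply(fit$chains, function(c) colMeans(c$gamma0))) /
    length(fit$chains)
  g1r <- Reduce(`+`, lapply(fit$chains, function(c) colMeans(c$gamma1_raw))) /
    length(fit$chains)
  bbar <- Reduce(`+`, lapply(fit$chains, function(c) colMeans(c$beta))) /
    length(fit$chains)
  g1 <- g1r + drop(Z %*% bbar)
  visits <- unique(panel$responses[, c("subject_id", "visit_time")])
  si <- match(visits$subject_id, subj$subject_id)
  data.frame(subject_id = visits$subject_id, visit_time = visits$visit_time,
             theta = g0[si] + g1[si] * visits$visit_time,
             stringsAsFactors = FALSE, row.names = NULL)
}
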