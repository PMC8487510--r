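# Samejima graded-response model for 3-category Katz items.
#
# Orientation: P(Y >= k | theta) = plogis(alpha * theta - kappa_k), so that a
# larger kappa marks an ability lost later in the disability continuum and
# P(Y >= k) rises with theta (theta = latent disability, larger = worse).
# Boundary cumulatives P(Y >= 0) = 1 and P(Y >= 3) = 0 are identities.

# floor for log-probabilities: log of the smallest positive normal double
.LOG_FLOOR <- -745

#' Cumulative category probability of the graded response model
#'
#' Probability that a response is at or above threshold \code{kappa_k}:
#' \code{P(Y >= k | theta) = plogis(alpha * theta - kappa_k)}. Strictly
#' increasing in \code{theta}, and equal to 1/2 exactly where
#' \code{alpha * theta = kappa_k}.
#'
#' @param alpha discrimination, > 0.
#' @param kappa_k threshold on the latent scale.
#' @param theta latent disability value(s).
#' @return Probabilities in (0, 1), vectorized over the longest argument.
#' @export
cumulative_prob <- function(alpha, kappa_k, theta) {
  if (!all(is.finite(alpha)) || !all(is.finite(kappa_k)) ||
      !all(is.finite(theta)))
    stop("non-finite input to cumulative_prob")
  if (any(alpha <= 0)) stop("alpha must be strictly positive")
  stats::plogis(alpha * theta - kappa_k)
}

#' Category probabilities of a 3-category graded response item
#'
#' @param params single-row \code{\link{item_parameters}} object, or any list
#'   with elements \code{alpha}, \code{kappa_partial}, \code{kappa_total}.
#' @param theta latent disability value(s).
#' @return A matrix with columns \code{p0, p1, p2} (one row per theta); rows
#'   sum to 1.
#' @export
category_probs <- function(params, theta) {
  alpha <- params$alpha
  k1 <- params$kappa_partial
  k2 <- params$kappa_total
  if (length(alpha) != 1L) stop("category_probs expects a single item")
  if (k1 >= k2) stop("kappa_partial must be strictly below kappa_total")
  if (!all(is.finite(theta))) stop("non-finite theta")
  P1 <- cumulative_prob(alpha, k1, theta)  # P(Y >= 1)
  P2 <- cumulative_prob(alpha, k2, theta)  # P(Y >= 2)
  cbind(p0 = 1 - P1, p1 = P1 - P2, p2 = P2)
}

# vectorized log category probability; eta1 = alpha*theta - kappa_partial,
# eta2 = alpha*theta - kappa_total, y in {0,1,2}. Computed on the log scale
# (plogis(log.p = TRUE)) so extreme thetas underflow to the floor, not to -Inf.
.grm_ll <- function(eta1, eta2, y) {
  ll <- numeric(length(y))
  i0 <- y == 0L
  i1 <- y == 1L
  i2 <- y == 2L
  ll[i0] <- stats::plogis(eta1[i0], lower.tail = FALSE, log.p = TRUE)
  ll[i2] <- stats::plogis(eta2[i2], log.p = TRUE)
  if (any(i1)) {
    l1 <- stats::plogis(eta1[i1], log.p = TRUE)
    l2 <- stats::plogis(eta2[i1], log.p = TRUE)
    # log(P1 - P2) = log P1 + log(1 - P2/P1); ratio < 1 since eta2 < eta1
    ll[i1] <- l1 + log1p(-pmin(exp(l2 - l1), 1 - 1e-16))
  }
  pmax(ll, .LOG_FLOOR)
}

#' Log-likelihood of one Katz response
#'
#' Log of the graded-response category probability; a MISSING response
#' (\code{NA}) contributes exactly 0 (ignorable missingness). The result is
#' floored at log of the smallest normal double so extreme latent values stay
#' finite.
#'
#' @inheritParams category_probs
#' @param category integer in \{0, 1, 2\} or \code{NA}, vectorized.
#' @return Log-probabilities (0 for missing responses).
#' @export
response_loglik <- function(params, theta, category) {
  alpha <- params$alpha
  k1 <- params$kappa_partial
  k2 <- params$kappa_total
  if (length(alpha) != 1L) stop("response_loglik expects a single item")
  if (k1 >= k2) stop("kappa_partial must be strictly below kappa_total")
  n <- max(length(theta), length(category))
  theta <- rep_len(theta, n)
  category <- rep_len(category, n)
  ok <- is.na(category) | category %in% c(0L, 1L, 2L)
  if (!all(ok)) stop("category must be 0, 1, 2 or NA")
  out <- numeric(n)
  obs <- !is.na(category)
  if (any(obs)) {
    th <- theta[obs]
    out[obs] <- .grm_ll(alpha * th - k1, alpha * th - k2,
                        as.integer(category[obs]))
  }
  out
}

#' Panel log-likelihood of the graded response model
#'
#' Sums \code{\link{response_loglik}} over all non-missing responses of a
#' panel, with one latent disability value per (subject, visit). All six items
#' answered at the same visit share that theta.
#'
#' @param item_params \code{\link{item_parameters}} for every item occurring
#'   in the panel.
#' @param thetas data.frame with columns \code{subject_id}, \code{visit_time},
#'   \code{theta}: the latent disability at each measured visit.
#' @param panel a \code{\link{katz_panel}}.
#' @return Total log-likelihood (0 for an all-missing panel).
#' @export
panel_loglik <- function(item_params, thetas, panel) {
  stopifnot(inherits(item_params, "item_parameters"),
            inherits(panel, "katz_panel"))
  resp <- panel$responses
  resp <- resp[!is.na(resp$category), , drop = FALSE]
  if (nrow(resp) == 0L) return(0)
  key_r <- paste(resp$subject_id, format(resp$visit_time, digits = 15))
  key_t <- paste(thetas$subject_id, format(thetas$visit_time, digits = 15))
  pos <- match(key_r, key_t)
  if (anyNA(pos)) {
    miss <- resp[which(is.na(pos))[1L], ]
    stop(sprintf("no theta supplied for subject %s at visit %s",
                 miss$subject_id, format(miss$visit_time)))
  }
  th <- thetas$theta[pos]
  ii <- match(resp$item, item_params$item)
  if (anyNA(ii)) stop("item parameters missing for some panel items")
  a <- item_params$alpha[ii]
  k1 <- item_params$kappa_partial[ii]
  k2 <- item_params$kappa_total[ii]
  sum(.grm_ll(a * th - k1, a * th - k2, as.integer(resp$category)))
}
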