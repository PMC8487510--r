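# Second pipeline stage: rescale posterior disability scores, align them to
# time before death, fit the random-intercept/random-slope mixed model, and
# derive cross-group mean trajectories.

#' Scored visits on the years-before-death axis
#'
#' Takes the per-(subject, visit) latent disability levels from an LIRT fit,
#' rescales them affinely so the pooled minimum maps to -3 and the maximum
#' to +3 (order-preserving), and attaches each subject's covariates and the
#' time between the visit and death.
#'
#' With \code{method = "resample"} (the default) each visit's disability is
#' one posterior draw of gamma0 + gamma1 t, drawn independently across
#' visits: the scored values then carry the posterior uncertainty of the
#' latent trait, which becomes the residual variance of the second-stage
#' mixed model. \code{method = "mean"} uses posterior means instead; because
#' the trajectory model is linear in time, posterior-mean scores lie exactly
#' on each subject's line and leave the mixed model with a degenerate (zero)
#' residual variance, so this option is only useful for inspection.
#'
#' @param fit a \code{\link{run_mcmc}} fit, or a precomputed data.frame
#'   \code{subject_id, visit_time, theta} (as from
#'   \code{\link{posterior_theta}}).
#' @param panel the corresponding \code{\link{katz_panel}}.
#' @param method \code{"resample"} or \code{"mean"} (ignored for data.frame
#'   input).
#' @param seed RNG seed for the resampling.
#' @return data.frame with columns \code{subject_id, visit_time,
#'   years_before_death, theta_scaled} plus the covariate columns.
#' @export
extract_scored_visits <- function(fit, panel,
                                  method = c("resample", "mean"),
                                  seed = 1L) {
  stopifnot(inherits(panel, "katz_panel"))
  method <- match.arg(method)
  thetas <- if (inherits(fit, "lirt_fit")) {
    if (method == "mean") posterior_theta(fit, panel)
    else .resampled_theta(fit, panel, seed)
  } else as.data.frame(fit)
  stopifnot(all(c("subject_id", "visit_time", "theta") %in% names(thetas)))
  rng <- range(thetas$theta)
  if (diff(rng) == 0)
    stop("cannot rescale: all disability scores are equal")
  theta_scaled <- -3 + 6 * (thetas$theta - rng[1L]) / diff(rng)
  subj <- panel$subjects
  si <- match(thetas$subject_id, subj$subject_id)
  if (anyNA(si)) stop("scored visit references unknown subject")
  ybd <- subj$death_time[si] - thetas$visit_time
  if (any(ybd < 0))
    stop("visit after recorded death for subject ",
         thetas$subject_id[which(ybd < 0)[1L]])
  out <- data.frame(subject_id = thetas$subject_id,
                    visit_time = thetas$visit_time,
                    years_before_death = ybd,
                    theta_scaled = theta_scaled,
                    stringsAsFactors = FALSE)
  for (v in c("sex", "residence", "marital", "age_std", "education_std"))
    out[[v]] <- subj[[v]][si]
  out
}

# one independent posterior draw of theta(s, t) per scored visit
.resampled_theta <- function(fit, panel, seed) {
  subj <- panel$subjects
  if (!identical(fit$subject_ids, subj$subject_id))
    stop("fit and panel subject sets differ")
  Z <- .design_Z(subj)
  visits <- unique(panel$responses[, c("subject_id", "visit_time")])
  si <- match(visits$subject_id, subj$subject_id)
  n <- nrow(visits)
  set.seed(seed)
  ch <- sample.int(length(fit$chains), n, replace = TRUE)
  ii <- sample.int(fit$config$n_keep, n, replace = TRUE)
  th <- vapply(seq_len(n), function(v) {
    cc <- fit$chains[[ch[v]]]
    g1 <- cc$gamma1_raw[ii[v], si[v]] +
      drop(Z[si[v], ] %*% cc$beta[ii[v], ])
    cc$gamma0[ii[v], si[v]] + g1 * visits$visit_time[v]
  }, numeric(1))
  data.frame(subject_id = visits$subject_id, visit_time = visits$visit_time,
             theta = th, stringsAsFactors = FALSE, row.names = NULL)
}

.default_fixed <- c("years_before_death", "sex", "residence", "marital",
                    "age_std", "education_std", "sex:residence", "sex:marital")

#' Fit the mixed-effects disability trajectory model
#'
#' Maximum-likelihood fit of
#' \code{theta_scaled = X beta + b1_s + b2_s * t + e}, with subject-level
#' random intercept and slope \code{(b1, b2) ~ MVN(0, Sigma)} and residual
#' \code{e ~ N(0, sigma^2)}; \code{t} is years before death. Estimation uses
#' \code{lme4::lmer} with \code{REML = FALSE} (profiled marginal
#' log-likelihood). With \code{random = FALSE} the random effects are dropped
#' (Sigma = 0) and the model reduces exactly to ordinary least squares.
#'
#' @param visits output of \code{\link{extract_scored_visits}}.
#' @param fixed character vector of fixed-effect terms (default: time, the
#'   five covariates, and the sex-by-residence and sex-by-marital
#'   interactions).
#' @param random include the subject-level random intercept and slope.
#' @return list of class \code{"adl_mixed_fit"}: \code{fixed_effects}
#'   (data.frame \code{term, estimate, se}), \code{Sigma} (2x2), \code{sigma2},
#'   \code{logLik} and the underlying model object.
#' @export
fit_mixed_model <- function(visits, fixed = .default_fixed, random = TRUE) {
  visits <- as.data.frame(visits)
  stopifnot(all(c("subject_id", "years_before_death", "theta_scaled")
                %in% names(visits)))
  if (random) {
    nv <- table(visits$subject_id)
    if (!any(nv >= 2L))
      stop("random slope unidentifiable: no subject has 2 or more visits")
  }
  rhs <- paste(fixed, collapse = " + ")
  fml_fixed <- stats::as.formula(paste("theta_scaled ~", rhs))
  X <- stats::model.matrix(fml_fixed, visits)
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    aliased <- colnames(X)[qrX$pivot[(qrX$rank + 1L):ncol(X)]]
    stop("design matrix is rank deficient; aliased column(s): ",
         paste(aliased, collapse = ", "))
  }
  if (random) {
    fml <- stats::as.formula(
      paste("theta_scaled ~", rhs, "+ (years_before_death | subject_id)"))
    m <- lme4::lmer(fml, data = visits, REML = FALSE,
                    control = lme4::lmerControl(calc.derivs = FALSE,
                                                check.conv.singular = "ignore"))
    vc <- lme4::VarCorr(m)$subject_id
    Sigma <- matrix(as.numeric(vc[1:2, 1:2]), 2L, 2L,
                    dimnames = list(c("intercept", "slope"),
                                    c("intercept", "slope")))
    sigma2 <- stats::sigma(m)^2
    co <- summary(m)$coefficients
    fe <- data.frame(term = rownames(co), estimate = co[, "Estimate"],
                     se = co[, "Std. Error"], stringsAsFactors = FALSE)
  } else {
    m <- stats::lm(fml_fixed, data = visits)
    co <- summary(m)$coefficients
    Sigma <- matrix(0, 2L, 2L, dimnames = list(c("intercept", "slope"),
                                               c("intercept", "slope")))
    sigma2 <- summary(m)$sigma^2
    fe <- data.frame(term = rownames(co), estimate = co[, "Estimate"],
                     se = co[, "Std. Error"], stringsAsFactors = FALSE)
  }
  rownames(fe) <- NULL
  structure(list(fixed_effects = fe, Sigma = Sigma, sigma2 = sigma2,
                 logLik = as.numeric(stats::logLik(m)), model = m,
                 formula = fml_fixed, random = random),
            class = "adl_mixed_fit")
}

#' @export
print.adl_mixed_fit <- function(x, ...) {
  cat("Mixed-effects disability trajectory fit (ML)\n")
  print(x$fixed_effects, digits = 4)
  cat(sprintf("residual variance sigma2 = %.4f\n", x$sigma2))
  invisible(x)
}

.group_defs <- list(
  sex_residence = list(
    vars = c("sex", "residence"),
    labels = c(`0.0` = "MU", `1.0` = "FU", `0.1` = "MR", `1.1` = "FR"),
    adjusters = c("age_std", "education_std", "marital")),
  sex_marital = list(
    vars = c("sex", "marital"),
    labels = c(`0.0` = "MY", `1.0` = "FY", `0.1` = "MN", `1.1` = "FN"),
    adjusters = c("age_std", "education_std", "residence")))

#' Cross-group mean disability trajectories
#'
#' Forms the four sex-by-residence (MU, FU, MR, FR) or sex-by-marital-status
#' (MY, FY, MN, FN) groups, fits the trajectory model with a group-by-time
#' interaction and the remaining covariates as adjusters, and returns the
#' model-implied mean curve per group over years-before-death in
#' \code{[0, horizon]} with adjusters held at their sample means. Observed
#' group means per integer year are returned alongside.
#'
#' @param visits output of \code{\link{extract_scored_visits}}.
#' @param grouping \code{"sex_residence"} or \code{"sex_marital"}.
#' @param horizon upper end of the time axis in years before death.
#' @param step grid spacing of the model curves, years.
#' @return list with \code{curves} (data.frame \code{group,
#'   years_before_death, mean_theta}), \code{observed} (per integer year),
#'   and \code{fit}.
#' @export
group_trajectories <- function(visits, grouping = c("sex_residence",
                                                    "sex_marital"),
                               horizon = 19, step = 0.5) {
  grouping <- match.arg(grouping)
  gd <- .group_defs[[grouping]]
  visits <- as.data.frame(visits)
  key <- paste(visits[[gd$vars[1L]]], visits[[gd$vars[2L]]], sep = ".")
  visits$group <- unname(gd$labels[key])
  empty <- setdiff(gd$labels, unique(visits$group))
  if (length(empty))
    warning("empty group(s) omitted: ", paste(empty, collapse = ", "))
  visits$group <- factor(visits$group, levels = intersect(gd$labels,
                                                          unique(visits$group)))
  rhs <- paste(c("group * years_before_death", gd$adjusters), collapse = " + ")
  fml <- stats::as.formula(
    paste("theta_scaled ~", rhs, "+ (years_before_death | subject_id)"))
  m <- lme4::lmer(fml, data = visits, REML = FALSE,
                  control = lme4::lmerControl(calc.derivs = FALSE,
                                              check.conv.singular = "ignore"))
  grid <- expand.grid(group = levels(visits$group),
                      years_before_death = seq(0, horizon, by = step),
                      stringsAsFactors = FALSE)
  for (v in gd$adjusters) grid[[v]] <- mean(visits[[v]])
  grid$mean_theta <- stats::predict(m, newdata = grid, re.form = NA)
  obs <- stats::aggregate(
    theta_scaled ~ group + year,
    data = transform(visits, year = floor(pmin(years_before_death, horizon))),
    FUN = mean)
  names(obs) <- c("group", "years_before_death", "mean_theta")
  list(curves = grid[, c("group", "years_before_death", "mean_theta")],
       observed = obs[order(obs$group, obs$years_before_death), ],
       fit = m)
}
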