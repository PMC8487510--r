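# Synthetic mortality-truncated Katz panels drawn from a known LIRT truth.
#
# The generator emulates a mixed-longitudinal cohort of Chinese oldest-old
# followed until death: covariate marginals match the reference cohort
# (60.2% female, 63.1% rural, 80.8% without spouse, age 91.3 (9.6), education
# 1.4 (2.9) years), visits recur every ~2-3 years, follow-up is truncated at
# death (wave-censored median elapsed time ~3 years, range 0-19), and
# responses come from the graded-response LIRT with configurable truth.

#' Configuration for the synthetic panel generator
#'
#' Defaults reproduce the reference cohort's marginals and use
#' \code{\link{katz_reference_params}} / \code{\link{katz_reference_slopes}}
#' as the generating truth. The death-time law (exponential, mean
#' \code{death_mean}, capped at \code{max_followup}) and the visit jitter are
#' simulation conveniences calibrated to the cohort's follow-up summary, not
#' estimates.
#'
#' @param n_subjects number of subjects.
#' @param female_frac,rural_frac,no_spouse_frac binary covariate
#'   probabilities.
#' @param age_mean,age_sd baseline age distribution (normal, left-truncated
#'   at 60 years).
#' @param edu_mean,edu_sd education distribution (normal, left-truncated at
#'   0 years).
#' @param wave_interval_mean,wave_interval_jitter mean and SD of the gap
#'   between successive visits (years; gaps floored at 0.5).
#' @param death_mean mean of the exponential death-time law (years).
#' @param max_followup cap on death time (years).
#' @param item_truth generating \code{\link{item_parameters}}.
#' @param mu,beta,slope_sd slope truth: population mean annual disability
#'   increase, covariate coefficients (canonical order \code{sex, age_std,
#'   residence, education_std, marital}), and SD of the residual slope.
#' @param intercept_sd SD of the subject baseline disability gamma0.
#' @param missing_rate probability that any single response is missing
#'   (missing completely at random).
#' @param fixed_visits optional numeric vector of visit times shared by all
#'   subjects; when given, the schedule generator uses it verbatim and places
#'   death shortly after the last visit (for design-controlled recovery
#'   studies).
#' @param seed optional integer; when set, each generation stage reseeds
#'   deterministically from it.
#' @return A validated list of class \code{"generator_config"}.
#' @export
generator_config <- function(n_subjects = 1000L,
                             female_frac = 0.602, rural_frac = 0.631,
                             no_spouse_frac = 0.808,
                             age_mean = 91.3, age_sd = 9.6,
                             edu_mean = 1.4, edu_sd = 2.9,
                             wave_interval_mean = 2.5,
                             wave_interval_jitter = 0.5,
                             death_mean = 6.5, max_followup = 19,
                             item_truth = katz_reference_params(),
                             mu = 0.857,
                             beta = katz_reference_slopes()$beta,
                             slope_sd = 0.5, intercept_sd = 1,
                             missing_rate = 0.05,
                             fixed_visits = NULL, seed = NULL) {
  cfg <- list(n_subjects = as.integer(n_subjects),
              female_frac = female_frac, rural_frac = rural_frac,
              no_spouse_frac = no_spouse_frac,
              age_mean = age_mean, age_sd = age_sd,
              edu_mean = edu_mean, edu_sd = edu_sd,
              wave_interval_mean = wave_interval_mean,
              wave_interval_jitter = wave_interval_jitter,
              death_mean = death_mean, max_followup = max_followup,
              item_truth = item_truth, mu = mu, beta = beta,
              slope_sd = slope_sd, intercept_sd = intercept_sd,
              missing_rate = missing_rate, fixed_visits = fixed_visits,
              seed = if (is.null(seed)) NULL else as.integer(seed))
  probs <- c(cfg$female_frac, cfg$rural_frac, cfg$no_spouse_frac,
             cfg$missing_rate)
  if (any(probs < 0 | probs > 1)) stop("probabilities must lie in [0, 1]")
  if (cfg$n_subjects < 0L) stop("n_subjects must be non-negative")
  if (any(c(cfg$age_sd, cfg$edu_sd, cfg$wave_interval_jitter, cfg$slope_sd,
            cfg$intercept_sd) < 0)) stop("standard deviations must be >= 0")
  if (cfg$max_followup <= 0) stop("max_followup must be positive")
  if (cfg$death_mean <= 0) stop("death_mean must be positive")
  stopifnot(inherits(cfg$item_truth, "item_parameters"))
  if (length(cfg$beta) != 5L) stop("beta must have length 5")
  names(cfg$beta) <- .covariate_names
  class(cfg) <- "generator_config"
  cfg
}

.maybe_seed <- function(config, offset) {
  if (!is.null(config$seed)) set.seed(config$seed + offset)
}

# normal left-truncated at `lower`, by rejection (truncation mass is modest
# for all defaults: P(age < 60) ~ 6e-4, P(edu < 0) ~ 0.31)
.rtruncnorm <- function(n, mean, sd, lower) {
  if (n == 0L) return(numeric(0))
  if (sd == 0) {
    if (mean < lower) stop("degenerate truncated normal below its bound")
    return(rep(mean, n))
  }
  out <- numeric(n)
  todo <- seq_len(n)
  while (length(todo)) {
    draw <- stats::rnorm(length(todo), mean, sd)
    ok <- draw >= lower
    out[todo[ok]] <- draw[ok]
    todo <- todo[!ok]
  }
  out
}

#' Generate subject covariates
#'
#' Binary covariates are independent Bernoulli draws with the configured
#' fractions; baseline age is normal truncated below at 60 years, education
#' normal truncated below at 0.
#'
#' @param config a \code{\link{generator_config}}.
#' @return data.frame with columns \code{subject_id, sex, residence, marital,
#'   age_baseline, education}.
#' @export
generate_covariates <- function(config) {
  stopifnot(inherits(config, "generator_config"))
  .maybe_seed(config, 1L)
  n <- config$n_subjects
  data.frame(
    subject_id = sprintf("S%06d", seq_len(n)),
    sex = stats::rbinom(n, 1L, config$female_frac),
    residence = stats::rbinom(n, 1L, config$rural_frac),
    marital = stats::rbinom(n, 1L, config$no_spouse_frac),
    age_baseline = .rtruncnorm(n, config$age_mean, config$age_sd, 60),
    education = .rtruncnorm(n, config$edu_mean, config$edu_sd, 0),
    stringsAsFactors = FALSE
  )
}

#' Generate death times and visit schedules
#'
#' Death time is exponential with mean \code{death_mean}, capped at
#' \code{max_followup}. Every subject is interviewed at time 0; further
#' visits recur at jittered wave intervals and stop strictly before death.
#' With \code{fixed_visits} set, all subjects share that schedule and die
#' shortly after its last visit.
#'
#' @param config a \code{\link{generator_config}}.
#' @param covariates output of \code{\link{generate_covariates}}.
#' @return list with \code{death_time} (per subject) and \code{visits}
#'   (data.frame \code{subject_id, visit_time}).
#' @export
generate_visit_schedule <- function(config, covariates) {
  stopifnot(inherits(config, "generator_config"))
  .maybe_seed(config, 2L)
  n <- nrow(covariates)
  ids <- covariates$subject_id
  if (!is.null(config$fixed_visits)) {
    vt <- sort(config$fixed_visits)
    if (any(vt < 0)) stop("fixed_visits must be non-negative")
    death <- max(vt) + 0.5 + stats::rexp(n, rate = 2)
    visits <- data.frame(subject_id = rep(ids, each = length(vt)),
                         visit_time = rep(vt, n), stringsAsFactors = FALSE)
    return(list(death_time = death, visits = visits))
  }
  death <- pmin(stats::rexp(n, rate = 1 / config$death_mean),
                config$max_followup)
  vl <- vector("list", n)
  for (s in seq_len(n)) {
    t <- 0
    times <- 0
    repeat {
      gap <- max(0.5, stats::rnorm(1, config$wave_interval_mean,
                                   config$wave_interval_jitter))
      t <- t + gap
      if (t >= death[s]) break
      times <- c(times, t)
    }
    vl[[s]] <- times
  }
  visits <- data.frame(subject_id = rep(ids, lengths(vl)),
                       visit_time = unlist(vl), stringsAsFactors = FALSE)
  list(death_time = death, visits = visits)
}

#' Generate Katz responses from the LIRT truth
#'
#' Draws gamma0 ~ N(0, intercept_sd^2) and a residual slope
#' gamma1' ~ N(mu, slope_sd^2) per subject, sets the disability level
#' theta(s, t) = gamma0 + (gamma1' + Z beta) t, and samples each (visit, item)
#' category from the graded-response category probabilities. Each response is
#' then independently set missing with probability \code{missing_rate}.
#'
#' @param config a \code{\link{generator_config}}.
#' @param subjects data.frame of covariates including standardized columns
#'   \code{age_std, education_std} and \code{death_time}.
#' @param visits data.frame \code{subject_id, visit_time}.
#' @return list with the \code{responses} data.frame and the latent truth
#'   (\code{gamma0}, \code{gamma1_raw}, \code{gamma1}, \code{theta} per
#'   visit).
#' @export
generate_responses <- function(config, subjects, visits) {
  stopifnot(inherits(config, "generator_config"))
  it <- config$item_truth
  if (any(it$alpha <= 0)) stop("item_truth discriminations must be positive")
  if (any(it$kappa_partial >= it$kappa_total))
    stop("item_truth thresholds must be ordered (kappa_partial < kappa_total)")
  .maybe_seed(config, 3L)
  n <- nrow(subjects)
  Z <- .design_Z(subjects)
  gamma0 <- stats::rnorm(n, 0, config$intercept_sd)
  gamma1_raw <- stats::rnorm(n, config$mu, config$slope_sd)
  gamma1 <- gamma1_raw + drop(Z %*% config$beta)

  sidx <- match(visits$subject_id, subjects$subject_id)
  theta_v <- gamma0[sidx] + gamma1[sidx] * visits$visit_time
  nv <- nrow(visits)
  n_items <- nrow(it)
  # one row per (visit, item), items in canonical order within each visit
  ridx <- rep(seq_len(nv), each = n_items)
  iidx <- rep(seq_len(n_items), nv)
  th <- theta_v[ridx]
  a <- it$alpha[iidx]
  P1 <- stats::plogis(a * th - it$kappa_partial[iidx])
  P2 <- stats::plogis(a * th - it$kappa_total[iidx])
  u <- stats::runif(nv * n_items)
  category <- as.integer(u < P1) + as.integer(u < P2)
  if (config$missing_rate > 0)
    category[stats::runif(nv * n_items) < config$missing_rate] <- NA_integer_
  responses <- data.frame(subject_id = visits$subject_id[ridx],
                          visit_time = visits$visit_time[ridx],
                          item = it$item[iidx],
                          category = category, stringsAsFactors = FALSE)
  list(responses = responses,
       truth = list(gamma0 = gamma0, gamma1_raw = gamma1_raw,
                    gamma1 = gamma1,
                    theta = data.frame(subject_id = visits$subject_id,
                                       visit_time = visits$visit_time,
                                       theta = theta_v,
                                       stringsAsFactors = FALSE)))
}

#' Generate a complete synthetic panel with its generating truth
#'
#' Composes \code{\link{generate_covariates}},
#' \code{\link{generate_visit_schedule}} and
#' \code{\link{generate_responses}}; covariates are standardized within the
#' generated cohort before the slope regression is applied.
#'
#' @param config a \code{\link{generator_config}}.
#' @return list with \code{panel} (a \code{\link{katz_panel}} with
#'   standardized covariates) and \code{truth} (item parameters, slope truth
#'   and all latent draws).
#' @export
generate_dataset <- function(config) {
  stopifnot(inherits(config, "generator_config"))
  cov <- generate_covariates(config)
  sched <- generate_visit_schedule(config, cov)
  cov$death_time <- sched$death_time
  subj <- cov
  subj$age_std <- (subj$age_baseline - mean(subj$age_baseline)) /
    stats::sd(subj$age_baseline)
  subj$education_std <- (subj$education - mean(subj$education)) /
    stats::sd(subj$education)
  gen <- generate_responses(config, subj, sched$visits)
  panel <- katz_panel(subj, gen$responses)
  truth <- c(list(item_params = config$item_truth, mu = config$mu,
                  beta = config$beta, slope_sd = config$slope_sd,
                  intercept_sd = config$intercept_sd),
             gen$truth)
  list(panel = panel, truth = truth)
}
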