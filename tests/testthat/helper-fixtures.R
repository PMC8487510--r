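# Shared fixture builders: tiny hand-written panels and file writers.

make_subjects <- function(ids, death_time = 10,
                          sex = 0L, residence = 0L, marital = 0L,
                          age_baseline = 85, education = 2) {
  n <- length(ids)
  data.frame(subject_id = ids,
             sex = rep_len(sex, n), residence = rep_len(residence, n),
             marital = rep_len(marital, n),
             age_baseline = rep_len(age_baseline, n),
             education = rep_len(education, n),
             death_time = rep_len(death_time, n),
             stringsAsFactors = FALSE)
}

# full-grid responses for the given subjects/visits/items with fixed category
make_responses <- function(ids, visits = c(0, 2), items = katz_items,
                           category = 0L) {
  g <- expand.grid(item = items, visit_time = visits, subject_id = ids,
                   stringsAsFactors = FALSE)
  data.frame(subject_id = g$subject_id, visit_time = g$visit_time,
             item = g$item, category = rep_len(category, nrow(g)),
             stringsAsFactors = FALSE)
}

# a minimal valid two-subject panel: 2 subjects x 1 visit x 6 items
tiny_panel <- function() {
  subj <- make_subjects(c("S1", "S2"), age_baseline = c(80, 90),
                        education = c(0, 4))
  resp <- make_responses(c("S1", "S2"), visits = 0)
  resp$category <- rep(c(0L, 1L, 2L), length.out = nrow(resp))
  katz_panel(subj, resp)
}

write_fixture_files <- function(subj, resp, dir = NULL) {
  if (is.null(dir)) {
    dir <- tempfile("fixture")
    dir.create(dir)
  }
  rp <- file.path(dir, "responses.csv")
  sp <- file.path(dir, "subjects.csv")
  utils::write.table(resp, rp, sep = ",", row.names = FALSE, quote = FALSE,
                     na = "")
  utils::write.table(subj, sp, sep = ",", row.names = FALSE, quote = FALSE,
                     na = "")
  list(responses = rp, subjects = sp)
}

# independent brute-force panel log-likelihood: naive double loop, direct
# logistic formulas, no package internals
brute_force_loglik <- function(item_df, theta_df, panel) {
  total <- 0
  for (r in seq_len(nrow(panel$responses))) {
    row <- panel$responses[r, ]
    if (is.na(row$category)) next
    th <- theta_df$theta[theta_df$subject_id == row$subject_id &
                           abs(theta_df$visit_time - row$visit_time) < 1e-12]
    it <- item_df[item_df$item == row$item, ]
    P1 <- 1 / (1 + exp(-(it$alpha * th - it$kappa_partial)))
    P2 <- 1 / (1 + exp(-(it$alpha * th - it$kappa_total)))
    p <- switch(as.character(row$category),
                "0" = 1 - P1, "1" = P1 - P2, "2" = P2)
    total <- total + log(p)
  }
  total
}

# random valid item parameters for property tests
random_items <- function() {
  k1 <- stats::runif(6, -3, 2)
  item_parameters(katz_items, alpha = stats::runif(6, 0.3, 4),
                  kappa_partial = k1,
                  kappa_total = k1 + stats::runif(6, 0.2, 3))
}

# simulate random-slope trajectory data directly on the theta-scaled axis
simulate_mixed_visits <- function(n_subj = 300, n_visits = 5,
                                  beta = c(intercept = -1,
                                           years_before_death = 0.15,
                                           sex = 0.3, residence = -0.2,
                                           marital = 0.25, age_std = 0.1,
                                           education_std = -0.1),
                                  Sigma = matrix(c(0.5, 0.15, 0.15, 0.2), 2),
                                  sigma2 = 0.25, seed = 1) {
  set.seed(seed)
  ids <- sprintf("T%04d", seq_len(n_subj))
  sex <- rbinom(n_subj, 1, 0.6)
  residence <- rbinom(n_subj, 1, 0.6)
  marital <- rbinom(n_subj, 1, 0.8)
  age_std <- rnorm(n_subj)
  education_std <- rnorm(n_subj)
  b <- if (all(Sigma == 0)) matrix(0, n_subj, 2)
       else matrix(rnorm(2 * n_subj), n_subj) %*% chol(Sigma)
  t_grid <- seq(0, 8, length.out = n_visits)
  df <- expand.grid(subject_id = ids, years_before_death = t_grid,
                    stringsAsFactors = FALSE)
  i <- match(df$subject_id, ids)
  mu <- beta["intercept"] + beta["years_before_death"] * df$years_before_death +
    beta["sex"] * sex[i] + beta["residence"] * residence[i] +
    beta["marital"] * marital[i] + beta["age_std"] * age_std[i] +
    beta["education_std"] * education_std[i]
  df$theta_scaled <- mu + b[i, 1] + b[i, 2] * df$years_before_death +
    rnorm(nrow(df), 0, sqrt(sigma2))
  df$sex <- sex[i]; df$residence <- residence[i]; df$marital <- marital[i]
  df$age_std <- age_std[i]; df$education_std <- education_std[i]
  df$visit_time <- max(t_grid) - df$years_before_death
  df
}
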