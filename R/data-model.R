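# Canonical panel container and long-format tabular I/O.
#
# A katz_panel holds two data.frames:
#   subjects:  subject_id, sex, residence, marital, age_baseline, education,
#              age_std, education_std, death_time
#   responses: subject_id, visit_time, item, category (0/1/2 or NA = missing)
# Binary coding: sex 0 male / 1 female; residence 0 urban / 1 rural;
# marital 0 with spouse / 1 without spouse. visit_time is years since the
# subject's first interview; death_time is on the same clock.

.subject_cols <- c("subject_id", "sex", "residence", "marital",
                   "age_baseline", "education", "death_time")
.response_cols <- c("subject_id", "visit_time", "item", "category")

#' Construct a validated Katz panel
#'
#' @param subjects data.frame with columns \code{subject_id, sex, residence,
#'   marital, age_baseline, education, death_time} (and optionally
#'   \code{age_std, education_std}).
#' @param responses data.frame with columns \code{subject_id, visit_time,
#'   item, category}; \code{category} in \{0, 1, 2\} or \code{NA} for a
#'   missing response.
#' @return An object of class \code{"katz_panel"}.
#' @export
katz_panel <- function(subjects, responses) {
  subjects <- as.data.frame(subjects)
  responses <- as.data.frame(responses)
  miss_s <- setdiff(.subject_cols, names(subjects))
  if (length(miss_s))
    stop("subjects table is missing column(s): ", paste(miss_s, collapse = ", "))
  miss_r <- setdiff(.response_cols, names(responses))
  if (length(miss_r))
    stop("responses table is missing column(s): ", paste(miss_r, collapse = ", "))
  subjects$subject_id <- as.character(subjects$subject_id)
  responses$subject_id <- as.character(responses$subject_id)
  responses$item <- as.character(responses$item)
  if (anyDuplicated(subjects$subject_id))
    stop("duplicate subject_id in subjects table")
  if (!("age_std" %in% names(subjects)))
    subjects$age_std <- rep(NA_real_, nrow(subjects))
  if (!("education_std" %in% names(subjects)))
    subjects$education_std <- rep(NA_real_, nrow(subjects))

  bad_item <- setdiff(unique(responses$item), katz_items)
  if (length(bad_item))
    stop("unknown Katz item(s): ", paste(bad_item, collapse = ", "))
  cat_ok <- is.na(responses$category) | responses$category %in% c(0, 1, 2)
  if (!all(cat_ok))
    stop("invalid response category (must be 0, 1, 2 or missing): found ",
         paste(unique(responses$category[!cat_ok]), collapse = ", "))
  responses$category <- as.integer(responses$category)
  if (any(!is.finite(responses$visit_time)) || any(responses$visit_time < 0))
    stop("visit_time must be finite and non-negative")
  key <- paste(responses$subject_id, format(responses$visit_time, digits = 15),
               responses$item)
  if (anyDuplicated(key)) {
    d <- key[duplicated(key)][1L]
    stop("duplicate (subject, visit, item) record: ", d)
  }
  unknown <- setdiff(unique(responses$subject_id), subjects$subject_id)
  if (length(unknown))
    stop("response(s) reference unknown subject(s): ",
         paste(utils::head(unknown, 5L), collapse = ", "))
  dt <- subjects$death_time
  if (any(!is.na(dt) & dt <= 0))
    stop("death_time must be positive")
  # visits must precede death
  dt_r <- dt[match(responses$subject_id, subjects$subject_id)]
  late <- !is.na(dt_r) & responses$visit_time >= dt_r
  if (any(late))
    stop("visit at or after recorded death for subject ",
         responses$subject_id[which(late)[1L]])
  rownames(subjects) <- NULL
  rownames(responses) <- NULL
  structure(list(subjects = subjects, responses = responses),
            class = "katz_panel")
}

#' @export
print.katz_panel <- function(x, ...) {
  n_obs <- sum(!is.na(x$responses$category))
  cat(sprintf("katz_panel: %d subjects, %d response records (%d observed)\n",
              nrow(x$subjects), nrow(x$responses), n_obs))
  invisible(x)
}

.read_table_auto <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  utils::read.table(path, header = TRUE, sep = sep, stringsAsFactors = FALSE,
                    na.strings = c("NA", ""), check.names = TRUE)
}

#' Load a Katz panel from delimited files
#'
#' Reads a long-format responses file (\code{subject_id, visit_time, item,
#' category}) and a subjects file (\code{subject_id, sex, residence, marital,
#' age_baseline, education, death_time}); the delimiter is inferred from the
#' extension (.csv comma, otherwise tab). Missing responses are coded as an
#' empty field or \code{NA}. Out-of-range categories are rejected, never
#' coerced. Subjects without a known death time, and subjects with no
#' non-missing Katz response at any visit, are dropped with a warning (the
#' analysis covers decedents with at least one measurement).
#'
#' @param responses_path,subjects_path file paths.
#' @return A validated \code{\link{katz_panel}}.
#' @export
load_panel <- function(responses_path, subjects_path) {
  resp <- .read_table_auto(responses_path)
  subj <- .read_table_auto(subjects_path)
  miss_r <- setdiff(.response_cols, names(resp))
  if (length(miss_r))
    stop("responses file is missing column(s): ", paste(miss_r, collapse = ", "))
  miss_s <- setdiff(.subject_cols, names(subj))
  if (length(miss_s))
    stop("subjects file is missing column(s): ", paste(miss_s, collapse = ", "))
  subj$subject_id <- as.character(subj$subject_id)
  resp$subject_id <- as.character(resp$subject_id)

  no_death <- is.na(subj$death_time)
  if (any(no_death)) {
    warning(sum(no_death), " subject(s) without a known death time excluded")
    drop_ids <- subj$subject_id[no_death]
    subj <- subj[!no_death, , drop = FALSE]
    resp <- resp[!(resp$subject_id %in% drop_ids), , drop = FALSE]
  }
  obs_ids <- unique(resp$subject_id[!is.na(resp$category)])
  none <- !(subj$subject_id %in% obs_ids)
  if (any(none)) {
    warning(sum(none),
            " subject(s) with no non-missing Katz response excluded")
    drop_ids <- subj$subject_id[none]
    subj <- subj[!none, , drop = FALSE]
    resp <- resp[!(resp$subject_id %in% drop_ids), , drop = FALSE]
  }
  katz_panel(subj, resp)
}

#' Write a Katz panel to delimited files
#'
#' Inverse of \code{\link{load_panel}}: writes the responses and subjects
#' tables (delimiter inferred from extension), with missing categories as
#' empty fields. Standardized covariate columns are not written; they are
#' recomputed by \code{\link{standardize_covariates}} after reload.
#'
#' @param panel a \code{\link{katz_panel}}.
#' @param responses_path,subjects_path output paths.
#' @export
write_panel <- function(panel, responses_path, subjects_path) {
  stopifnot(inherits(panel, "katz_panel"))
  wr <- function(df, path) {
    sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
    utils::write.table(df, path, sep = sep, row.names = FALSE, quote = FALSE,
                       na = "")
  }
  wr(panel$responses[, .response_cols], responses_path)
  wr(panel$subjects[, .subject_cols], subjects_path)
  invisible(panel)
}

#' Apply the study inclusion filter
#'
#' Keeps subjects with baseline age strictly above \code{min_age}, a known
#' death time, at least one non-missing Katz response, and complete
#' covariates. Each excluded subject is counted under the first failing
#' criterion, in the order \code{below_min_age}, \code{missing_death_time},
#' \code{no_katz_response}, \code{incomplete_covariates}. The operation is
#' idempotent.
#'
#' @param panel a \code{\link{katz_panel}}.
#' @param min_age inclusion threshold in years (default 60; strict
#'   inequality).
#' @return A list with elements \code{panel} (the filtered panel) and
#'   \code{report} (named list of exclusion counts plus \code{retained}).
#' @export
apply_inclusion_filter <- function(panel, min_age = 60) {
  stopifnot(inherits(panel, "katz_panel"))
  subj <- panel$subjects
  resp <- panel$responses
  obs_ids <- unique(resp$subject_id[!is.na(resp$category)])
  cov_complete <- !is.na(subj$sex) & !is.na(subj$residence) &
    !is.na(subj$marital) & !is.na(subj$age_baseline) & !is.na(subj$education)
  reason <- rep(NA_character_, nrow(subj))
  reason[is.na(reason) & !(is.na(subj$age_baseline)) &
           subj$age_baseline <= min_age] <- "below_min_age"
  reason[is.na(reason) & is.na(subj$death_time)] <- "missing_death_time"
  reason[is.na(reason) & !(subj$subject_id %in% obs_ids)] <- "no_katz_response"
  reason[is.na(reason) & !cov_complete] <- "incomplete_covariates"
  keep <- is.na(reason)
  report <- list(
    below_min_age = sum(reason == "below_min_age", na.rm = TRUE),
    missing_death_time = sum(reason == "missing_death_time", na.rm = TRUE),
    no_katz_response = sum(reason == "no_katz_response", na.rm = TRUE),
    incomplete_covariates = sum(reason == "incomplete_covariates", na.rm = TRUE),
    retained = sum(keep)
  )
  keep_ids <- subj$subject_id[keep]
  out <- katz_panel(subj[keep, , drop = FALSE],
                    resp[resp$subject_id %in% keep_ids, , drop = FALSE])
  list(panel = out, report = report)
}

#' Write an exclusion report as JSON
#'
#' @param report the \code{report} element of
#'   \code{\link{apply_inclusion_filter}}.
#' @param path output path.
#' @export
write_exclusion_report <- function(report, path) {
  jsonlite::write_json(report, path, auto_unbox = TRUE)
  invisible(path)
}

#' Standardize continuous covariates
#'
#' Populates \code{age_std} and \code{education_std} by zero-centering and
#' scaling to unit sample standard deviation (n - 1 denominator). Binary
#' covariates are untouched.
#'
#' @param panel a \code{\link{katz_panel}} with at least two subjects and
#'   non-degenerate age and education distributions.
#' @return The panel with standardized covariate columns filled in.
#' @export
standardize_covariates <- function(panel) {
  stopifnot(inherits(panel, "katz_panel"))
  subj <- panel$subjects
  if (nrow(subj) < 2L)
    stop("need at least 2 subjects to standardize covariates")
  std <- function(x, label) {
    s <- stats::sd(x)
    if (!is.finite(s) || s == 0)
      stop("cannot standardize ", label, ": zero variance")
    (x - mean(x)) / s
  }
  subj$age_std <- std(subj$age_baseline, "age_baseline")
  subj$education_std <- std(subj$education, "education")
  panel$subjects <- subj
  panel
}

# covariate design matrix in canonical order (requires standardization)
.design_Z <- function(subjects) {
  if (anyNA(subjects$age_std) || anyNA(subjects$education_std))
    stop("covariates are not standardized; call standardize_covariates() first")
  Z <- as.matrix(subjects[, .covariate_names])
  storage.mode(Z) <- "double"
  Z
}
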