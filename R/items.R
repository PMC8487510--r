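#' Canonical Katz ADL items
#'
#' The six activities of daily living of the Katz scale, in the canonical
#' order used throughout the package for serialization and tie-breaking.
#'
#' @format Character vector of length 6.
#' @export
katz_items <- c("bathing", "dressing", "toileting", "transferring",
                "continence", "feeding")

#' Construct a validated set of graded-response item parameters
#'
#' Each Katz item carries a discrimination \code{alpha} (> 0) and two ordered
#' difficulty thresholds on the latent disability scale:
#' \code{kappa_partial} (no limitation to partial limitation) and
#' \code{kappa_total} (partial limitation to totally limited). Larger theta
#' means more severe disability; items with smaller kappa are lost earlier.
#'
#' @param item character vector of item names (subset of \code{katz_items}).
#' @param alpha positive discrimination parameters.
#' @param kappa_partial,kappa_total difficulty thresholds, with
#'   \code{kappa_partial < kappa_total} strictly for every item.
#' @return A \code{data.frame} of class \code{"item_parameters"} with one row
#'   per item, ordered canonically.
#' @export
item_parameters <- function(item, alpha, kappa_partial, kappa_total) {
  item <- as.character(item)
  if (anyDuplicated(item)) stop("duplicate item names")
  bad <- setdiff(item, katz_items)
  if (length(bad)) stop("unknown Katz item(s): ", paste(bad, collapse = ", "))
  if (length(alpha) != length(item) || length(kappa_partial) != length(item) ||
      length(kappa_total) != length(item))
    stop("item, alpha and kappas must have equal length")
  if (!all(is.finite(alpha)) || !all(is.finite(kappa_partial)) ||
      !all(is.finite(kappa_total)))
    stop("item parameters must be finite")
  if (any(alpha <= 0)) stop("alpha must be strictly positive")
  if (any(kappa_partial >= kappa_total))
    stop("kappa_partial must be strictly below kappa_total for every item")
  out <- data.frame(item = item, alpha = alpha,
                    kappa_partial = kappa_partial, kappa_total = kappa_total,
                    stringsAsFactors = FALSE)
  out <- out[order(match(out$item, katz_items)), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("item_parameters", "data.frame")
  out
}

#' Reference Katz item parameters from a large Chinese end-of-life cohort
#'
#' Posterior-mean discrimination and difficulty estimates for the six Katz
#' items, obtained from a graded-response LIRT fitted to a nationwide
#' longitudinal cohort of Chinese adults over 60 followed until death. They
#' serve as the default generating truth for the synthetic-panel simulator and
#' as inputs to the worked hierarchy examples.
#'
#' @return An \code{\link{item_parameters}} object with 6 rows.
#' @export
katz_reference_params <- function() {
  item_parameters(
    item          = c("bathing", "dressing", "toileting", "transferring",
                      "continence", "feeding"),
    alpha         = c(1.291, 2.877, 4.124, 3.682, 1.125, 2.137),
    kappa_partial = c(-1.396, -0.277, -0.904, -0.053, 1.371, 0.917),
    kappa_total   = c(-0.374, 0.482, 3.348, 3.454, 3.647, 3.440)
  )
}

#' Reference slope regression estimates
#'
#' Companion estimates to \code{\link{katz_reference_params}}: the population
#' mean annual increase in latent disability (\code{mu}) and the regression
#' coefficients of the subject-level slope on covariates, in the canonical
#' covariate order \code{sex, age_std, residence, education_std, marital}
#' (sex 0 male / 1 female; residence 0 urban / 1 rural; marital 0 with
#' spouse / 1 without; age and education standardized).
#'
#' @return A list with elements \code{mu} (scalar) and \code{beta}
#'   (named length-5 vector).
#' @export
katz_reference_slopes <- function() {
  list(mu = 0.857,
       beta = c(sex = 0.102, age_std = 0.889, residence = -0.591,
                education_std = -0.730, marital = 0.056))
}

# canonical covariate order for the slope regression design Z
.covariate_names <- c("sex", "age_std", "residence", "education_std", "marital")

#' Read / write item parameters as JSON
#'
#' @param params an \code{\link{item_parameters}} object.
#' @param path file path.
#' @return \code{read_item_parameters} returns a validated
#'   \code{item_parameters} object.
#' @export
write_item_parameters <- function(params, path) {
  stopifnot(inherits(params, "item_parameters"))
  jsonlite::write_json(as.data.frame(params), path, digits = NA)
  invisible(path)
}

#' @rdname write_item_parameters
#' @export
read_item_parameters <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  item_parameters(x$item, x$alpha, x$kappa_partial, x$kappa_total)
}
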