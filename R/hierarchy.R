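# From fitted item parameters to the substantive outputs: the ordered
# ADL-loss hierarchy, partial-to-total threshold gaps, and discrimination
# classification.

#' Build the 12-row threshold table from item parameters
#'
#' @param items an \code{\link{item_parameters}} object (optionally with
#'   \code{se_partial, q2.5_partial, ...} columns from a posterior summary).
#' @return data.frame with one row per (item, level), level in
#'   \code{partial, total}.
#' @export
threshold_entries <- function(items) {
  items <- as.data.frame(items)
  long <- rbind(
    data.frame(item = items$item, level = "partial",
               kappa = items$kappa_partial, stringsAsFactors = FALSE),
    data.frame(item = items$item, level = "total",
               kappa = items$kappa_total, stringsAsFactors = FALSE))
  rownames(long) <- NULL
  long
}

#' Rank the 12 difficulty thresholds: the ADL-loss hierarchy
#'
#' Sorts the (item, level) thresholds by ascending kappa; this ordering is
#' the hierarchy in which abilities are lost (small kappa = lost earlier).
#' Ties break by canonical item order, then partial before total, so the
#' output is deterministic.
#'
#' @param entries a data.frame with columns \code{item, level, kappa} holding
#'   exactly one row per (item, level) pair — 12 rows — as produced by
#'   \code{\link{threshold_entries}}.
#' @return The input rows sorted ascending by kappa, with a \code{rank}
#'   column added.
#' @export
rank_thresholds <- function(entries) {
  entries <- as.data.frame(entries)
  stopifnot(all(c("item", "level", "kappa") %in% names(entries)))
  want <- expand.grid(level = c("partial", "total"), item = katz_items,
                      stringsAsFactors = FALSE)
  have <- paste(entries$item, entries$level)
  missing <- !(paste(want$item, want$level) %in% have)
  if (any(missing)) {
    w <- want[which(missing)[1L], ]
    stop(sprintf("missing threshold entry: (%s, %s)", w$item, w$level))
  }
  if (nrow(entries) != 12L) stop("expected exactly 12 threshold entries")
  o <- order(entries$kappa, match(entries$item, katz_items),
             match(entries$level, c("partial", "total")))
  out <- entries[o, , drop = FALSE]
  out$rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  out
}

#' Gap between the partial and total thresholds of one item
#'
#' kappa_total - kappa_partial: the stretch of the disability continuum an
#' item spans between first (partial) and complete (total) loss. Computed on
#' the point estimates exactly.
#'
#' @param entries as in \code{\link{rank_thresholds}}.
#' @param item a Katz item name.
#' @return scalar gap (always positive for a valid fit).
#' @export
threshold_gap <- function(entries, item) {
  entries <- as.data.frame(entries)
  kp <- entries$kappa[entries$item == item & entries$level == "partial"]
  kt <- entries$kappa[entries$item == item & entries$level == "total"]
  if (length(kp) != 1L) stop("missing partial threshold for item ", item)
  if (length(kt) != 1L) stop("missing total threshold for item ", item)
  kt - kp
}

#' Posterior distribution of a threshold gap
#'
#' Optional chain-level companion to \code{\link{threshold_gap}}: computes
#' kappa_total - kappa_partial per retained draw and summarizes it, so the
#' gap carries posterior uncertainty instead of being a difference of point
#' estimates.
#'
#' @param fit a \code{\link{run_mcmc}} fit.
#' @param item a Katz item name.
#' @return list with \code{mean, se, q2.5, q97.5} of the gap.
#' @export
threshold_gap_posterior <- function(fit, item) {
  stopifnot(inherits(fit, "lirt_fit"))
  i <- match(item, fit$items)
  if (is.na(i)) stop("unknown item: ", item)
  g <- unlist(lapply(fit$chains,
                     function(c) c$items[, i, 3L] - c$items[, i, 2L]))
  q <- stats::quantile(g, c(0.025, 0.975), names = FALSE, type = 7)
  list(mean = mean(g), se = stats::sd(g), `q2.5` = q[1L], `q97.5` = q[2L])
}

# half-open discrimination bands on the logistic metric
.baker_bands <- list(
  baker_logistic = data.frame(
    lower = c(0, 0.01, 0.35, 0.65, 1.35, 1.70),
    label = c("none", "very_low", "low", "moderate", "high", "very_high"),
    stringsAsFactors = FALSE))

#' Classify a discrimination parameter
#'
#' Bands a discrimination value into \code{none < very_low < low < moderate
#' < high < very_high} under a named scheme. The default
#' \code{"baker_logistic"} scheme uses the common logistic-metric cut points
#' 0.01, 0.35, 0.65, 1.35, 1.70 (half-open on the left).
#'
#' @param alpha discrimination value(s), >= 0.
#' @param scheme classification scheme name.
#' @return character vector of band labels.
#' @export
classify_discrimination <- function(alpha, scheme = "baker_logistic") {
  if (!scheme %in% names(.baker_bands))
    stop("unknown discrimination classification scheme: ", scheme)
  if (any(alpha < 0)) stop("alpha must be non-negative")
  b <- .baker_bands[[scheme]]
  b$label[findInterval(alpha, b$lower)]
}

#' Check scale applicability via minimum discrimination
#'
#' An item is considered applicable when its discrimination strictly exceeds
#' \code{threshold} (default 0.3); the scale passes overall when every item
#' does.
#'
#' @param items an \code{\link{item_parameters}} object.
#' @param threshold minimum acceptable discrimination.
#' @return list with \code{per_item} (data.frame \code{item, alpha, pass})
#'   and \code{overall} (logical).
#' @export
applicability_check <- function(items, threshold = 0.3) {
  items <- as.data.frame(items)
  per <- data.frame(item = items$item, alpha = items$alpha,
                    pass = items$alpha > threshold, stringsAsFactors = FALSE)
  list(per_item = per, overall = all(per$pass))
}
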