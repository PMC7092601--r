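#' Score one WHOQOL domain from Likert items
#'
#' The WHOQOL-HIV BREF transform: the mean of a domain's 5-point Likert
#' items multiplied by 4, giving a score in `[4, 20]` comparable with the
#' WHOQOL-100 scale. A domain with fewer than `min_complete` of its items
#' present is not scorable and returns `NA` (a countable sentinel, not an
#' error), so the downstream completeness filter can act on it.
#'
#' @param items Numeric vector of item responses; values must be integers
#'   in 1..5 or `NA` for a skipped item.
#' @param min_complete Minimum fraction of items that must be present
#'   (default 0.8, common WHOQOL practice).
#' @return The domain score (4 x mean of present items), or `NA_real_`
#'   when the domain is not scorable.
#' @export
score_domain <- function(items, min_complete = 0.8) {
  if (!length(items)) {
    abort("`items` must contain at least one response.",
          class = "mvqol_validation_error")
  }
  present <- !is.na(items)
  x <- items[present]
  if (length(x) && (any(x < 1 | x > 5) || any(x != floor(x)))) {
    abort("item responses must be integers in 1..5.",
          class = "mvqol_validation_error")
  }
  if (mean(present) < min_complete) return(NA_real_)
  4 * mean(x)
}

#' Score every visit's four domains
#'
#' Applies [score_domain()] to the item columns `dom{k}_item{n}` (domain
#' order: physical health, psychological, level of independence, social
#' relationship) and appends the score columns `ph`, `psy`, `ind`, `soc`
#' plus a `qol_complete` flag. Rows that already carry the four score
#' columns and no item columns pass through unchanged apart from the flag.
#'
#' @param data Visit-level tibble.
#' @param min_complete Passed to [score_domain()].
#' @return `data` with score columns and a `qol_complete` logical column.
#' @export
score_visits <- function(data, min_complete = 0.8) {
  doms <- qol_domains()
  for (k in 1:4) {
    item_cols <- grep(sprintf("^dom%d_item\\d+$", k), names(data),
                      value = TRUE)
    if (length(item_cols)) {
      m <- as.matrix(data[item_cols])
      data[[doms[k]]] <- apply(m, 1L, score_domain,
                               min_complete = min_complete)
    } else if (!doms[k] %in% names(data)) {
      abort(sprintf(
        "no item columns `dom%d_item*` and no score column `%s` found.",
        k, doms[k]), class = "mvqol_validation_error")
    }
  }
  data$qol_complete <- stats::complete.cases(data[doms])
  data
}

#' Drop visits with incomplete QoL responses
#'
#' Removes visits on which any of the four domains could not be scored.
#' The number and percentage dropped are reported as attributes
#' (`n_dropped`, `pct_dropped`; the percentage rounded to one decimal)
#' and via a message, mirroring how longitudinal QoL analyses report
#' their visit exclusions.
#'
#' @param data A scored tibble (see [score_visits()]); a `qol_complete`
#'   column is used when present, otherwise completeness of the four
#'   score columns.
#' @return The complete-visit subset, with attributes `n_dropped` and
#'   `pct_dropped`.
#' @export
filter_complete_visits <- function(data) {
  if (!nrow(data)) {
    abort("`data` has no visits.", class = "mvqol_validation_error")
  }
  keep <- if ("qol_complete" %in% names(data)) data$qol_complete else
    stats::complete.cases(data[qol_domains()])
  n_dropped <- sum(!keep)
  pct <- round(100 * n_dropped / nrow(data), 1L)
  out <- data[keep, , drop = FALSE]
  attr(out, "n_dropped") <- n_dropped
  attr(out, "pct_dropped") <- pct
  message(sprintf("dropped %d of %d visits (%.1f%%) with incomplete QoL responses",
                  n_dropped, nrow(data), pct))
  out
}

#' Drop subjects with too few visits
#'
#' Subjects with fewer than `min_visits` remaining visits are removed
#' entirely (study-inclusion rule: at least two follow-up measurements).
#' Run after [filter_complete_visits()], since dropping incomplete visits
#' can push a subject below the threshold.
#'
#' @param data Visit-level tibble with a `subject_id` column.
#' @param min_visits Minimum retained visits per subject (default 2).
#' @param subject Subject identifier column name.
#' @return The filtered tibble with attribute `n_subjects_dropped`.
#' @export
filter_min_visits <- function(data, min_visits = 2L, subject = "subject_id") {
  min_visits <- assert_scalar_count(min_visits, "min_visits", min = 1L)
  counts <- table(data[[subject]])
  bad <- names(counts)[counts < min_visits]
  out <- data[!as.character(data[[subject]]) %in% bad, , drop = FALSE]
  attr(out, "n_subjects_dropped") <- length(bad)
  out
}
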