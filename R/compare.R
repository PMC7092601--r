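#' Information criteria of a fitted model
#'
#' Computes `AIC = -2LL + 2p`, `AICC = AIC + 2p(p+1)/(n - p - 1)` with
#' `n` the number of visits (level-1 units), and
#' `BIC = -2LL + p log(m)` with `m` the number of subjects (level-2
#' units) — the mixed-model conventions under which published
#' multivariate multilevel fit tables are internally consistent. `p`
#' counts fixed effects plus free covariance parameters.
#'
#' @param fit An `mvml_fit`, or a list with elements `neg2_loglik`,
#'   `n_params`, `n_visits`, `n_subjects` (so printed fit tables can be
#'   checked directly).
#' @return One-row tibble with the four criteria and the counts.
#' @export
fit_statistics <- function(fit) {
  m2ll <- fit$neg2_loglik
  p <- fit$n_params
  n <- fit$n_visits
  m <- fit$n_subjects
  aic <- m2ll + 2 * p
  aicc <- if (n - p - 1 > 0) aic + 2 * p * (p + 1) / (n - p - 1) else {
    warn("AICC undefined: n - p - 1 <= 0.")
    NA_real_
  }
  tibble::tibble(
    model = if (isTRUE(fit$related)) "related" else "independent",
    neg2_loglik = m2ll, aic = aic, aicc = aicc,
    bic = m2ll + p * log(m),
    n_params = p, n_subjects = m, n_visits = n)
}

#' @rdname fit_statistics
#' @param x An `mvml_fit`.
#' @param ... Unused.
#' @export
glance.mvml_fit <- function(x, ...) {
  dplyr::bind_cols(fit_statistics(x),
                   tibble::tibble(converged = x$converged))
}

#' Compare the related- and independent-outcome fits
#'
#' Emits the fit-statistics table for both models side by side, prefers
#' the model with the lower AIC (a tie is reported as such), and reports
#' the likelihood-ratio statistic with its degrees of freedom (the 30
#' cross-outcome covariance constraints for four outcomes: 24 in
#' `Omega_G`, 6 in `Omega_R`) as supplementary evidence.
#'
#' @param fit_related,fit_independent Fits of the two variants on the
#'   same data and fixed-effect structure (checked via column labels).
#' @return Tibble of criteria by model with attributes `preferred`,
#'   `lr_statistic`, `lr_df`, `lr_p`.
#' @export
compare_models <- function(fit_related, fit_independent) {
  same <- identical(fit_related$design$labels, fit_independent$design$labels) &&
    fit_related$n_visits == fit_independent$n_visits
  if (!same) {
    abort("fits have different data or fixed-effect structures.",
          class = "mvqol_validation_error")
  }
  a <- fit_statistics(fit_related)
  b <- fit_statistics(fit_independent)
  tab <- tibble::tibble(
    criterion = c("neg2_loglik", "aic", "aicc", "bic"),
    independent = c(b$neg2_loglik, b$aic, b$aicc, b$bic),
    related = c(a$neg2_loglik, a$aic, a$aicc, a$bic))
  d <- b$aic - a$aic
  preferred <- if (abs(d) < 1e-8) "tie" else if (d > 0) "related" else
    "independent"
  lr <- b$neg2_loglik - a$neg2_loglik
  df <- a$n_params - b$n_params
  structure(tab, preferred = preferred, lr_statistic = lr, lr_df = df,
            lr_p = stats::pchisq(lr, df, lower.tail = FALSE))
}

star_label <- function(p) {
  dplyr::case_when(p < 0.001 ~ "***", p < 0.01 ~ "**", p < 0.05 ~ "*",
                   TRUE ~ "")
}

#' Fixed-effect table with confidence intervals and significance stars
#'
#' One row per outcome-by-term coefficient: estimate, Wald 95% interval
#' (`estimate +/- 1.96 se`, normal reference), z statistic, two-sided
#' p-value and the conventional star annotation (* < 0.05, ** < 0.01,
#' *** < 0.001), with the baseline and time-slope blocks distinguished —
#' the layout of a longitudinal QoL effect table.
#'
#' @param fit An `mvml_fit`.
#' @param level Confidence level (default 0.95).
#' @return Tibble with block, outcome, term, estimate, std_error,
#'   ci_lower, ci_upper, statistic, p_value, stars.
#' @export
effect_table <- function(fit, level = 0.95) {
  z <- stats::qnorm(1 - (1 - level) / 2)
  fit$beta |>
    dplyr::mutate(
      ci_lower = .data$estimate - z * .data$std_error,
      ci_upper = .data$estimate + z * .data$std_error,
      statistic = .data$estimate / .data$std_error,
      p_value = 2 * stats::pnorm(-abs(.data$statistic)),
      stars = star_label(.data$p_value)) |>
    dplyr::arrange(factor(.data$block, c("baseline", "slope"))) |>
    dplyr::select("block", "outcome", "term", "estimate", "std_error",
                  "ci_lower", "ci_upper", "statistic", "p_value", "stars")
}

#' @rdname effect_table
#' @param x An `mvml_fit`.
#' @param ... Unused.
#' @export
tidy.mvml_fit <- function(x, ...) effect_table(x, ...)

#' Contrast a covariate's effect between two outcomes
#'
#' Wald test of `beta[outcome_a, term] - beta[outcome_b, term]` in the
#' baseline or time-slope block, using the joint fixed-effect covariance
#' of the multivariate fit — the cross-outcome comparison that a set of
#' separate univariate models cannot provide.
#'
#' @param fit An `mvml_fit`.
#' @param term Design-column name of the covariate effect (e.g.
#'   `"viral_load"`; for the slope block the bare term name, the
#'   `time:` prefix is added internally).
#' @param outcome_a,outcome_b Outcome names to compare.
#' @param block `"baseline"` or `"slope"`.
#' @return One-row tibble: label, block, estimate, std_error, statistic
#'   and two-sided normal p-value.
#' @export
contrast_effects <- function(fit, term, outcome_a, outcome_b,
                             block = c("baseline", "slope")) {
  block <- match.arg(block)
  stopifnot(inherits(fit, "mvml_fit"))
  lbl <- fit$beta
  full_term <- if (block == "slope" && !startsWith(term, "time")) {
    if (term == "time") "time" else paste0("time:", term)
  } else term
  ia <- which(lbl$outcome == outcome_a & lbl$term == full_term &
                lbl$block == block)
  ib <- which(lbl$outcome == outcome_b & lbl$term == full_term &
                lbl$block == block)
  if (length(ia) != 1L || length(ib) != 1L) {
    abort(sprintf("term `%s` (block %s) not present for both outcomes.",
                  full_term, block), class = "mvqol_validation_error")
  }
  cv <- numeric(nrow(lbl))
  cv[ia] <- 1
  cv[ib] <- -1
  est <- sum(cv * lbl$estimate)
  se <- sqrt(drop(t(cv) %*% fit$beta_cov %*% cv))
  stat <- est / se
  lab <- qol_domain_labels()
  nm_a <- if (outcome_a %in% names(lab)) lab[[outcome_a]] else outcome_a
  nm_b <- if (outcome_b %in% names(lab)) lab[[outcome_b]] else outcome_b
  tibble::tibble(
    label = sprintf("%s - %s", nm_a, nm_b),
    term = term, block = block, estimate = est, std_error = se,
    statistic = stat, p_value = 2 * stats::pnorm(-abs(stat)),
    stars = star_label(2 * stats::pnorm(-abs(stat))))
}
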