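#' Plot mean domain-score trajectories
#'
#' Group-mean trajectory of each QoL domain over time, optionally
#' stratified by a covariate — the plain trend summary of a longitudinal
#' QoL cohort.
#'
#' @param data Scored visit-level tibble.
#' @param by Optional stratifying covariate name.
#' @param time Time column name.
#' @return A ggplot object.
#' @export
plot_trajectories <- function(data, by = NULL, time = "time") {
  long <- tidyr::pivot_longer(
    data[c(time, by, intersect(qol_domains(), names(data)))],
    cols = dplyr::any_of(qol_domains()), names_to = "domain",
    values_to = "score")
  grp <- c(time, "domain", by)
  means <- long |>
    dplyr::group_by(dplyr::across(dplyr::all_of(grp))) |>
    dplyr::summarise(score = mean(.data$score, na.rm = TRUE),
                     .groups = "drop")
  p <- ggplot2::ggplot(means, ggplot2::aes(
    x = .data[[time]], y = .data$score,
    colour = if (is.null(by)) NULL else .data[[by]])) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~domain, labeller = ggplot2::as_labeller(
      qol_domain_labels())) +
    ggplot2::labs(x = "months since enrolment", y = "mean domain score",
                  colour = by) +
    ggplot2::theme_minimal()
  p
}

#' Scree plot of a factor model
#'
#' @param model A `qol_factor_model`.
#' @return A ggplot object showing eigenvalues against component index
#'   with the Kaiser threshold at 1.
#' @export
plot_scree <- function(model) {
  sd <- scree_data(model)
  ggplot2::ggplot(sd, ggplot2::aes(x = .data$component,
                                   y = .data$eigenvalue,
                                   colour = .data$retained)) +
    ggplot2::geom_point() + ggplot2::geom_line(colour = "grey40") +
    ggplot2::geom_hline(yintercept = 1, linetype = 2) +
    ggplot2::labs(title = model$group, x = "component",
                  y = "eigenvalue") +
    ggplot2::theme_minimal()
}

#' Normal Q-Q plot of transformed residuals
#'
#' @param residuals Output of [transformed_residuals()].
#' @return A ggplot object.
#' @export
plot_qq_residuals <- function(residuals) {
  ggplot2::ggplot(residuals, ggplot2::aes(x = .data$q_theoretical,
                                          y = .data$residual)) +
    ggplot2::geom_point(alpha = 0.4, size = 0.6) +
    ggplot2::geom_abline(slope = 1, intercept = 0, colour = "red") +
    ggplot2::labs(x = "standard normal quantiles",
                  y = "Cholesky-transformed residuals") +
    ggplot2::theme_minimal()
}

#' Heatmap of the random-effect correlation matrix
#'
#' @param object An `mvml_fit`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.mvml_fit <- function(object, ...) {
  rc <- unclass(random_effect_correlations(object))
  df <- tibble::tibble(
    row = rep(rownames(rc), ncol(rc)),
    col = rep(colnames(rc), each = nrow(rc)),
    r = as.vector(rc))
  df$row <- factor(df$row, levels = rev(rownames(rc)))
  df$col <- factor(df$col, levels = colnames(rc))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$col, y = .data$row,
                                   fill = .data$r)) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(label = sprintf("%.2f", .data$r)),
                       size = 2.6) +
    ggplot2::scale_fill_gradient2(limits = c(-1, 1)) +
    ggplot2::labs(x = NULL, y = NULL, fill = "corr") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45,
                                                       hjust = 1))
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
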