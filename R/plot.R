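#' Plot per-district congruence
#'
#' Lollipop chart of a congruence index across districts, ordered from most
#' to least congruent, with the zero line (no association) marked.
#'
#' @param congruence Output of [congruence_table()].
#' @param index `"kendall_tau"` or `"spearman_rho"`.
#' @return A ggplot object.
#' @export
plot_congruence <- function(congruence, index = c("kendall_tau",
                                                  "spearman_rho")) {
  index <- match.arg(index)
  df <- congruence |>
    filter(!is.na(.data[[index]])) |>
    mutate(district_id = stats::reorder(.data$district_id, .data[[index]]))
  ggplot2::ggplot(df, ggplot2::aes(x = .data[[index]],
                                   y = .data$district_id)) +
    ggplot2::geom_vline(xintercept = 0, linetype = "dashed",
                        colour = "grey50") +
    ggplot2::geom_segment(ggplot2::aes(x = 0, xend = .data[[index]],
                                       yend = .data$district_id),
                          colour = "grey70") +
    ggplot2::geom_point(ggplot2::aes(size = .data$n), colour = "#2c7fb8") +
    ggplot2::scale_size_continuous(range = c(1.5, 4)) +
    ggplot2::labs(x = if (index == "kendall_tau") "Kendall tau" else "Spearman rho",
                  y = NULL, size = "Clinics ranked",
                  title = "Crowd vs government ranking congruence by district") +
    ggplot2::theme_minimal()
}

#' Coefficient plot for a congruence regression
#'
#' Standardized coefficients (comparable across covariates: SDs of the
#' dependent index per SD of covariate) with approximate 95% intervals
#' rescaled from the raw standard errors.
#'
#' @param object A `congruence_ols` fit.
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.congruence_ols <- function(object, ...) {
  td <- tidy(object) |>
    filter(.data$term != "(Intercept)") |>
    mutate(scale_fct = .data$std_estimate / .data$estimate,
           lo = (.data$estimate - 1.96 * .data$std.error) * .data$scale_fct,
           hi = (.data$estimate + 1.96 * .data$std.error) * .data$scale_fct,
           term = stats::reorder(.data$term, .data$std_estimate))
  ggplot2::ggplot(td, ggplot2::aes(x = .data$std_estimate, y = .data$term)) +
    ggplot2::geom_vline(xintercept = 0, linetype = "dashed",
                        colour = "grey50") +
    ggplot2::geom_errorbarh(ggplot2::aes(xmin = .data$lo, xmax = .data$hi),
                            height = 0.2, colour = "grey60") +
    ggplot2::geom_point(colour = "#d95f02", size = 2.5) +
    ggplot2::labs(x = paste("Standardized coefficient on", object$dependent),
                  y = NULL,
                  title = "Sociodemographic effects on congruence") +
    ggplot2::theme_minimal()
}

#' Scatter of crowd versus government ranks
#'
#' One panel per district; perfectly congruent districts lie on the
#' diagonal.
#'
#' @param ranking Output of [align_rankings()].
#' @param districts Optional subset of district ids to show.
#' @return A ggplot object.
#' @export
plot_rank_agreement <- function(ranking, districts = NULL) {
  df <- ranking
  if ("excluded" %in% names(df)) df <- df |> filter(!.data$excluded)
  if (!is.null(districts)) {
    df <- df |> filter(.data$district_id %in% districts)
  }
  ggplot2::ggplot(df, ggplot2::aes(x = .data$gov_rank, y = .data$crowd_rank)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed",
                         colour = "grey60") +
    ggplot2::geom_point(alpha = 0.7, colour = "#2c7fb8") +
    ggplot2::facet_wrap(ggplot2::vars(.data$district_id), scales = "free") +
    ggplot2::labs(x = "Government rank (1 = lowest antibiotic rate)",
                  y = "Crowd rank (1 = most mentioned)") +
    ggplot2::theme_minimal()
}
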