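# ggplot2 views of the main result types.

#' Plot cohort average-degree curves
#'
#' Average degree against the correlation threshold, one line per cohort, on
#' a log10 degree scale (degree decays roughly geometrically in the
#' threshold).
#'
#' @param object a [degree_sweep()] result.
#' @param log_scale use a log10 y axis (zero degrees are dropped from the
#'   plot when `TRUE`).
#' @param ... unused.
#' @return A ggplot object.
#' @method autoplot degree_profile
#' @export
autoplot.degree_profile <- function(object, log_scale = TRUE, ...) {
  df <- object$avg |>
    tidyr::pivot_longer(-"threshold", names_to = "cohort",
                        values_to = "average_degree")
  if (log_scale) df <- dplyr::filter(df, .data$average_degree > 0)
  p <- ggplot2::ggplot(df, ggplot2::aes(.data$threshold,
                                        .data$average_degree,
                                        colour = .data$cohort)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::labs(x = "correlation threshold α", y = "average degree",
                  colour = NULL) +
    ggplot2::theme_minimal()
  if (log_scale) p <- p + ggplot2::scale_y_log10()
  p
}

#' Plot the screening cascade outcome
#'
#' Gene counts per route, filled by flag status.
#'
#' @param object a [screen_genes()] result.
#' @param ... unused.
#' @return A ggplot object.
#' @method autoplot gene_screen
#' @export
autoplot.gene_screen <- function(object, ...) {
  ggplot2::ggplot(object$records,
                  ggplot2::aes(.data$route, fill = .data$flagged)) +
    ggplot2::geom_bar() +
    ggplot2::labs(x = "cascade route", y = "genes", fill = "flagged") +
    ggplot2::theme_minimal()
}

#' Plot MD-G scores
#'
#' Mean absolute degree difference of the top-ranked genes.
#'
#' @param object an [md_scores()] result.
#' @param k how many leading genes to show.
#' @param ... unused.
#' @return A ggplot object.
#' @method autoplot mdg_ranking
#' @export
autoplot.mdg_ranking <- function(object, k = 20, ...) {
  df <- head(as_tibble(object), min(k, nrow(object)))
  ggplot2::ggplot(df, ggplot2::aes(stats::reorder(.data$gene_id,
                                                  .data$score),
                                   .data$score)) +
    ggplot2::geom_col() +
    ggplot2::coord_flip() +
    ggplot2::labs(x = NULL, y = "mean |degree difference|") +
    ggplot2::theme_minimal()
}

#' Plot function-level expression totals
#'
#' Side-by-side cohort totals per function, mirroring the function-level
#' expression comparison.
#'
#' @param levels a [function_levels()] table.
#' @return A ggplot object.
#' @export
plot_function_levels <- function(levels) {
  df <- levels |>
    tidyr::pivot_longer(c("total_control", "total_experimental"),
                        names_to = "cohort", values_to = "total") |>
    dplyr::mutate(cohort = sub("total_", "", .data$cohort))
  ggplot2::ggplot(df, ggplot2::aes(.data$function_id, .data$total,
                                   fill = .data$cohort)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::labs(x = NULL, y = "total expression level", fill = NULL) +
    ggplot2::theme_minimal()
}
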