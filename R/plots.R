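#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot per-tissue expression summaries
#'
#' Bar panels of the pooled normalized level (on the 1e-8 display scale),
#' the proportion of genes expressed, and the proportion of expressed genes
#' with their highest level in each tissue.
#'
#' @param object A [summarize_tissues()] result.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot tissue_summary
#' @export
autoplot.tissue_summary <- function(object, ...) {
  long <- object |>
    dplyr::select("tissue", "pooled_norm_scaled", "proportion_expressed",
                  "proportion_highest") |>
    tidyr::pivot_longer(-"tissue", names_to = "statistic") |>
    dplyr::mutate(statistic = factor(.data$statistic, levels = c(
      "pooled_norm_scaled", "proportion_expressed", "proportion_highest")))
  ggplot2::ggplot(long, ggplot2::aes(x = .data$tissue, y = .data$value)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::facet_wrap(ggplot2::vars(.data$statistic), scales = "free_y",
                        ncol = 1) +
    ggplot2::labs(x = NULL, y = NULL,
                  title = "Coding-region expression by tissue",
                  subtitle = "pooled normalized level (x1e-8), proportion expressed, proportion with highest level") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

#' Plot lineage-specific substitution-rate summaries
#'
#' Mean rate with a +1 SD whisker per lineage, side by side for the focal
#' and (when present) background gene sets.
#'
#' @param object A [summarize_rates()] result.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot rate_summary
#' @export
autoplot.rate_summary <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$lineage, y = .data$mean_rate,
                                       fill = .data$set)) +
    ggplot2::geom_col(position = ggplot2::position_dodge(0.8), width = 0.7) +
    ggplot2::geom_errorbar(
      ggplot2::aes(ymin = .data$mean_rate,
                   ymax = .data$mean_rate + .data$sd_rate),
      position = ggplot2::position_dodge(0.8), width = 0.2) +
    ggplot2::labs(x = "lineage", y = "substitutions/site (mean + SD)",
                  title = "Lineage-specific substitution rates") +
    ggplot2::theme_minimal()
}

#' Plot the screening funnel of a screen report
#'
#' Genes entering, passing, and failing each of the seven screen stages.
#'
#' @param object A [run_candidate_screen()] result.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot screen_report
#' @export
autoplot.screen_report <- function(object, ...) {
  long <- object$stage_counts |>
    tidyr::pivot_longer(c("entered", "passed"), names_to = "measure",
                        values_to = "n_genes") |>
    dplyr::mutate(stage_label = paste0(.data$stage, ". ", .data$name))
  ggplot2::ggplot(long, ggplot2::aes(x = stats::reorder(.data$stage_label,
                                                        .data$stage),
                                     y = .data$n_genes,
                                     fill = .data$measure)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::labs(x = NULL, y = "genes",
                  title = "Candidate screen funnel") +
    ggplot2::coord_flip() +
    ggplot2::theme_minimal()
}
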