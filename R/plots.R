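#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot an ensemble trajectory
#'
#' Performance panel: ensemble-mean fraction correct with SEM ribbon and
#' the 65%/100% tuning anchors at trials 70 and 120. Plasticity panel:
#' smoothed ensemble-mean sum of |dW| with SEM ribbon.
#'
#' @param object an `oc_trajectory` from [run_ensemble()].
#' @param which `"performance"` or `"plasticity"`.
#' @param ... unused.
#' @return a ggplot object.
#' @export
autoplot.oc_trajectory <- function(object, which = c("performance",
                                                     "plasticity"), ...) {
  which <- match.arg(which)
  if (which == "performance") {
    ggplot2::ggplot(object, ggplot2::aes(x = .data$trial,
                                         y = .data$mean_perf)) +
      ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$mean_perf - .data$sem_perf,
                                        ymax = .data$mean_perf + .data$sem_perf),
                           fill = "grey70", alpha = 0.5) +
      ggplot2::geom_line(linewidth = 0.6) +
      ggplot2::annotate("point", x = c(70, 120), y = c(0.65, 1.00),
                        shape = 4, size = 3, colour = "red") +
      ggplot2::scale_y_continuous(limits = c(0, 1.02)) +
      ggplot2::labs(x = "trial", y = "fraction correct",
                    title = "Ensemble performance",
                    subtitle = "crosses: 65% @ trial 70, 100% @ trial 120") +
      ggplot2::theme_minimal()
  } else {
    sm <- smooth_series(object$mean_plast)
    d <- dplyr::mutate(object, smoothed = sm)
    ggplot2::ggplot(d, ggplot2::aes(x = .data$trial)) +
      ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$mean_plast - .data$sem_plast,
                                        ymax = .data$mean_plast + .data$sem_plast),
                           fill = "grey70", alpha = 0.5) +
      ggplot2::geom_line(ggplot2::aes(y = .data$mean_plast),
                         colour = "grey40", linewidth = 0.3) +
      ggplot2::geom_line(ggplot2::aes(y = .data$smoothed), linewidth = 0.7) +
      ggplot2::labs(x = "trial", y = "sum |dW| per trial",
                    title = "Ensemble synaptic modification",
                    subtitle = "grey: per-trial mean; black: 11-trial moving average") +
      ggplot2::theme_minimal()
  }
}

#' Bar chart of a synthetic expression table
#'
#' Group mean with SEM bars per gene, the usual percent-of-control qPCR
#' presentation. Stars mark Tukey-significant comparisons against the
#' matching box control when `stats` is supplied.
#'
#' @param data an expression table (`gene`, `group`, `value`).
#' @param stats optional result of [expression_stats()] used to annotate
#'   significance of `50%CR` vs `BC50%CR` and `100%CR` vs `BC100%CR`.
#' @return a ggplot object.
#' @export
plot_expression <- function(data, stats = NULL) {
  summ <- data |>
    dplyr::group_by(.data$gene, .data$group) |>
    dplyr::summarise(mean = mean(.data$value),
                     sem = stats::sd(.data$value) / sqrt(dplyr::n()),
                     .groups = "drop") |>
    dplyr::mutate(group = factor(.data$group, levels = oc_groups))
  p <- ggplot2::ggplot(summ, ggplot2::aes(x = .data$group, y = .data$mean)) +
    ggplot2::geom_col(fill = "grey60") +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = .data$mean - .data$sem,
                                        ymax = .data$mean + .data$sem),
                           width = 0.3) +
    ggplot2::facet_wrap(~gene, nrow = 2) +
    ggplot2::labs(x = NULL, y = "% of control") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45,
                                                       hjust = 1))
  if (!is.null(stats)) {
    star <- function(p) {
      dplyr::case_when(p < 0.001 ~ "***", p < 0.01 ~ "**",
                       p < 0.05 ~ "*", TRUE ~ "")
    }
    key_pairs <- stats$tukey |>
      dplyr::filter((.data$group_a == "50%CR" & .data$group_b == "BC50%CR") |
                      (.data$group_a == "BC50%CR" & .data$group_b == "50%CR") |
                      (.data$group_a == "100%CR" & .data$group_b == "BC100%CR") |
                      (.data$group_a == "BC100%CR" & .data$group_b == "100%CR")) |>
      dplyr::mutate(group = ifelse(grepl("^50", .data$group_a) |
                                     grepl("^50", .data$group_b),
                                   "50%CR", "100%CR"),
                    label = star(.data$tukey_p)) |>
      dplyr::distinct(.data$gene, .data$group, .data$label)
    ann <- summ |>
      dplyr::inner_join(key_pairs, by = c("gene", "group"))
    p <- p + ggplot2::geom_text(data = ann,
                                ggplot2::aes(label = .data$label,
                                             y = .data$mean + .data$sem + 4))
  }
  p
}

#' Plot the scaled plasticity series against a gene's values
#'
#' @param scaled_traj trajectory from [scale_to_anchor()].
#' @param gene_values named numeric of the gene's learning/learned values.
#' @param trials trials at which the gene values apply.
#' @return a ggplot object.
#' @export
plot_match <- function(scaled_traj, gene_values, trials = c(70L, 120L)) {
  bars <- tibble::tibble(trial = trials, value = as.numeric(gene_values))
  ggplot2::ggplot(scaled_traj, ggplot2::aes(x = .data$trial,
                                            y = .data$plast_scaled)) +
    ggplot2::geom_line(linewidth = 0.7) +
    ggplot2::geom_col(data = bars,
                      ggplot2::aes(x = .data$trial, y = .data$value),
                      width = 4, fill = "steelblue", alpha = 0.5) +
    ggplot2::labs(x = "trial", y = "% of control (anchored)",
                  title = "Scaled plasticity vs gene expression") +
    ggplot2::theme_minimal()
}
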