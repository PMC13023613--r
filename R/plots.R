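#' Box-and-jitter plot of panel scores by group
#'
#' @param scores Score tibble from [score_samples()].
#' @param records Metadata tibble with `group`.
#' @param panels Panel columns to show.
#' @return A ggplot object, faceted by panel.
#' @export
plot_scores <- function(scores, records,
                        panels = intersect(panel_order(), names(scores))) {
  df <- join_scores(scores, records) |>
    tidyr::pivot_longer(dplyr::all_of(panels), names_to = "panel",
                        values_to = "score") |>
    dplyr::mutate(panel = factor(.data$panel, levels = panels))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$group, y = .data$score,
                                   colour = .data$group)) +
    ggplot2::geom_boxplot(outlier.shape = NA) +
    ggplot2::geom_jitter(width = 0.15, alpha = 0.6, size = 1) +
    ggplot2::facet_wrap(~panel, scales = "free_y") +
    ggplot2::labs(x = NULL, y = "panel score (log2 units)") +
    ggplot2::theme_bw() +
    ggplot2::theme(legend.position = "none",
                   axis.text.x = ggplot2::element_text(angle = 30, hjust = 1))
}

#' Composite score versus SOFA, with the decision-rule thresholds
#'
#' Scatter of the composite (NDrG - HLAd) score against SOFA, coloured by
#' outcome, with dashed lines at the rule thresholds. The lower-left
#' quadrant — low composite or low SOFA — is the region the combined rule
#' labels survivor.
#'
#' @param scores Score tibble with a `composite` column.
#' @param records Metadata tibble with `sofa` and `outcome`.
#' @param rule A [rule_spec()] supplying the threshold lines.
#' @return A ggplot object.
#' @export
plot_composite_sofa <- function(scores, records, rule = rule_spec()) {
  df <- join_scores(scores, records)
  df <- df[!is.na(df$sofa) & !is.na(df$composite), ]
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$sofa, y = .data$composite,
                                        colour = .data$outcome)) +
    ggplot2::geom_point(alpha = 0.8) +
    ggplot2::labs(x = "SOFA score", y = "composite (NDrG - HLAd)") +
    ggplot2::theme_bw()
  if (!is.null(rule$composite)) {
    p <- p + ggplot2::geom_hline(yintercept = rule$composite,
                                 linetype = "dashed")
  }
  if (!is.null(rule$sofa)) {
    p <- p + ggplot2::geom_vline(xintercept = rule$sofa,
                                 linetype = "dashed")
  }
  p
}

#' Spaghetti plot of per-subject panel trajectories
#'
#' @param scores Score tibble.
#' @param records Metadata tibble with `subject_id` and `timepoint`.
#' @param timepoints Ordered time-point labels.
#' @param panels Panel columns to show.
#' @return A ggplot object, one facet per panel, one line per subject.
#' @export
plot_trajectories <- function(scores, records, timepoints,
                              panels = intersect(panel_order(),
                                                 names(scores))) {
  df <- join_scores(scores, records) |>
    dplyr::filter(.data$timepoint %in% timepoints) |>
    tidyr::pivot_longer(dplyr::all_of(panels), names_to = "panel",
                        values_to = "score") |>
    dplyr::mutate(timepoint = factor(.data$timepoint, levels = timepoints),
                  panel = factor(.data$panel, levels = panels))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$timepoint, y = .data$score,
                                   group = .data$subject_id)) +
    ggplot2::geom_line(alpha = 0.4) +
    ggplot2::geom_point(size = 0.8, alpha = 0.6) +
    ggplot2::facet_wrap(~panel, scales = "free_y") +
    ggplot2::labs(x = NULL, y = "panel score (log2 units)") +
    ggplot2::theme_bw()
}

#' Plot a panel PCA
#'
#' @param object A `panel_pca` object from [pca_panels()].
#' @param records Optional metadata tibble; when given, points are
#'   coloured by `group`.
#' @param ... Unused.
#' @return A ggplot of the first two component scores.
#' @method autoplot panel_pca
#' @export
autoplot.panel_pca <- function(object, records = NULL, ...) {
  df <- object$scores
  if (!is.null(records)) {
    df <- dplyr::left_join(df, records[, c("sample_id", "group")],
                           by = "sample_id")
  }
  comp <- setdiff(names(df), c("sample_id", "group"))[1:2]
  ve <- sprintf("%.0f%%", 100 * object$variance_explained[1:2])
  aes <- if (!is.null(records)) {
    ggplot2::aes(x = .data[[comp[1]]], y = .data[[comp[2]]],
                 colour = .data$group)
  } else {
    ggplot2::aes(x = .data[[comp[1]]], y = .data[[comp[2]]])
  }
  ggplot2::ggplot(df, aes) +
    ggplot2::geom_point(alpha = 0.8) +
    ggplot2::labs(x = paste0(comp[1], " (", ve[1], ")"),
                  y = paste0(comp[2], " (", ve[2], ")")) +
    ggplot2::theme_bw()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' @importFrom rlang .data
NULL
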