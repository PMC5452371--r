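#' Plot per-cell-line consistency
#'
#' Dot plot of the matched-pair Spearman correlations in a
#' `consistency_report`, with the mean drawn as a dashed line.
#'
#' @param object A `consistency_report`.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot consistency_report
#' @export
autoplot.consistency_report <- function(object, ...) {
  df <- tidy(object)
  df$pair <- paste(df$cell_line_a, df$cell_line_b, sep = " / ")
  ggplot2::ggplot(df, ggplot2::aes(x = stats::reorder(.data$pair, .data$rho),
                                   y = .data$rho)) +
    ggplot2::geom_point() +
    ggplot2::geom_hline(yintercept = object$mean_rho, linetype = "dashed") +
    ggplot2::coord_flip() +
    ggplot2::labs(x = NULL, y = "Spearman rho",
                  title = paste0("Between-screen consistency (", object$level, " level)"),
                  subtitle = sprintf("mean rho = %.2f over %d matched pairs",
                                     object$mean_rho, nrow(df))) +
    ggplot2::theme_minimal()
}

#' Plot the family-size consistency curve
#'
#' Mean matched correlation of family-averaged scores against shRNA
#' family size, with SEM error bars and, when present, the
#' permuted-map reference trace.
#'
#' @param curve Tibble from [family_size_curve()].
#' @return A ggplot.
#' @export
plot_family_size_curve <- function(curve) {
  p <- ggplot2::ggplot(curve, ggplot2::aes(x = .data$family_size, y = .data$mean_rho)) +
    ggplot2::geom_line(color = "firebrick") +
    ggplot2::geom_point(color = "firebrick") +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = .data$mean_rho - .data$sem_rho,
                                        ymax = .data$mean_rho + .data$sem_rho),
                           width = 0.2, color = "firebrick") +
    ggplot2::labs(x = "shRNA family size", y = "mean Spearman rho",
                  title = "Consistency of family-averaged scores") +
    ggplot2::theme_minimal()
  if (any(!is.na(curve$perm_mean_rho))) {
    p <- p + ggplot2::geom_line(ggplot2::aes(y = .data$perm_mean_rho),
                                color = "grey30", linetype = "dashed")
  }
  p
}

#' Plot class-stratified consistency
#'
#' Bar chart of mean matched correlation per SPS/TA seed class, seed
#' window vs the position-12-18 control window.
#'
#' @param strat Tibble from [class_stratified_consistency()].
#' @return A ggplot.
#' @export
plot_class_consistency <- function(strat) {
  df <- strat[!is.na(strat$mean_rho), , drop = FALSE]
  df$label <- paste(df$axis, df$class, sep = ":")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$label, y = .data$mean_rho,
                                   fill = .data$window)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::labs(x = "seed class", y = "mean Spearman rho",
                  title = "Consistency by seed-property class") +
    ggplot2::theme_minimal()
}

#' Plot per-driver GI/SL overlap before vs after cleaning
#'
#' @param overlap Result of [overlap_analysis()].
#' @return A ggplot.
#' @export
plot_overlap <- function(overlap) {
  df <- tidyr::pivot_longer(overlap$per_driver,
                            cols = c("overlap_before", "overlap_after"),
                            names_to = "stage", values_to = "n_overlap")
  df$stage <- factor(sub("overlap_", "", df$stage), levels = c("before", "after"))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$driver, y = .data$n_overlap,
                                   fill = .data$stage)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::labs(x = NULL, y = "partners detected in both screens",
                  title = "Reproducible interaction partners, before vs after cleaning",
                  subtitle = sprintf("one-sided signed-rank p = %.3g",
                                     overlap$comparison$p_value)) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}
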