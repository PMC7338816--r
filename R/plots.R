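# ggplot2 graphics for agreement and per-epoch results.

#' @importFrom ggplot2 autoplot ggplot aes geom_point geom_hline labs
#'   geom_col facet_wrap theme_minimal position_dodge geom_errorbar
#' @export
ggplot2::autoplot

#' @describeIn bland_altman Bland-Altman plot: per-pair mean vs difference
#'   with bias and limits of agreement.
#' @param object An `rns_bland_altman`.
#' @export
autoplot.rns_bland_altman <- function(object, ...) {
  ggplot(object$pairs, aes(x = .data$mean, y = .data$difference)) +
    geom_hline(yintercept = object$bias, linetype = "solid") +
    geom_hline(yintercept = c(object$loa_low, object$loa_high),
               linetype = "dashed") +
    geom_point(alpha = 0.7) +
    labs(x = "Mean of standard and weighted",
         y = "Difference (standard - weighted)",
         title = sprintf("Bland-Altman: bias %.3f, LoA [%.3f, %.3f]",
                         object$bias, object$loa_low, object$loa_high)) +
    theme_minimal()
}

#' Standard-vs-weighted metric comparison plot
#'
#' Paired per-epoch values of the standard and weighted estimates, one facet
#' per metric.
#'
#' @param epoch_metrics Output of [epoch_metrics()].
#' @param metrics Metric stems to plot.
#' @return A ggplot object.
#' @export
plot_method_comparison <- function(epoch_metrics,
                                   metrics = c("accuracy", "sensitivity",
                                               "specificity")) {
  long <- map(metrics, function(m) {
    tibble(epoch_id = epoch_metrics$epoch_id, metric = m,
           standard = epoch_metrics[[paste0("standard_", m)]],
           weighted = epoch_metrics[[paste0("weighted_", m)]])
  }) |> list_rbind() |>
    tidyr::pivot_longer(c("standard", "weighted"), names_to = "method")
  ggplot(long, aes(x = .data$epoch_id, y = .data$value, fill = .data$method)) +
    geom_col(position = position_dodge()) +
    facet_wrap(~metric, ncol = 1) +
    labs(x = "Programming epoch", y = "Proportion", fill = NULL) +
    theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

#' Extrapolation weight profile plot
#'
#' Normalized per-stratum weights per epoch.
#'
#' @param wt An `rns_weights` from [compute_weight_table()].
#' @return A ggplot object.
#' @export
plot_weight_table <- function(wt) {
  ggplot(as_tibble(wt),
         aes(x = .data$pattern, y = .data$normalized_weight,
             fill = .data$episode_class)) +
    geom_col(position = position_dodge()) +
    facet_wrap(~epoch_id) +
    labs(x = "Second-order Pattern", y = "Normalized weight", fill = NULL) +
    theme_minimal()
}
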