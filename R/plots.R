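# ggplot2 displays for fits, selections and simulation-study summaries.

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot the BIC trace of a model selection
#'
#' BIC against the candidate number of clusters, with the selected k marked.
#' Lower BIC is better.
#'
#' @param object A [select_nbmix_k()] result.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot nbmix_selection
#' @export
autoplot.nbmix_selection <- function(object, ...) {
  tr <- object$bic_trace
  ggplot2::ggplot(tr, ggplot2::aes(x = .data$k, y = .data$bic)) +
    ggplot2::geom_line(color = "grey40") +
    ggplot2::geom_point(size = 2) +
    ggplot2::geom_point(data = tr[tr$k == object$k, ], color = "red",
                        size = 3) +
    ggplot2::scale_x_continuous(breaks = tr$k) +
    ggplot2::labs(x = "number of clusters k", y = "BIC",
                  title = sprintf("BIC selects k = %d", object$k)) +
    ggplot2::theme_minimal()
}

#' Plot posterior membership probabilities
#'
#' Heatmap of the posterior responsibility matrix with samples ordered by
#' their hard assignment; crisp block structure indicates confident
#' clustering.
#'
#' @param object An [fit_nbmix()] result.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot nbmix_fit
#' @export
autoplot.nbmix_fit <- function(object, ...) {
  df <- tidy(object) |>
    dplyr::select("sample_id", "cluster",
                  dplyr::starts_with(".posterior_")) |>
    tidyr::pivot_longer(dplyr::starts_with(".posterior_"),
                        names_to = "component", values_to = "probability",
                        names_prefix = ".posterior_") |>
    dplyr::arrange(.data$cluster)
  df$sample_id <- factor(df$sample_id, levels = unique(df$sample_id))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$component, y = .data$sample_id,
                                   fill = .data$probability)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_viridis_c(limits = c(0, 1)) +
    ggplot2::labs(x = "mixture component", y = NULL,
                  fill = "posterior") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.y = ggplot2::element_blank())
}

#' Plot mean ARI across simulation scenarios
#'
#' Mean adjusted Rand index per scenario and method, faceted by sample size
#' and gene count, with the number of clusters on the x axis and point shape
#' encoding the mean-shift step — the conventional layout for comparing
#' clustering methods across a simulation grid.
#'
#' @param summary A [summarize_ari()] tibble (or a raw
#'   [run_simulation_study()] tibble, which is summarized first).
#' @return A ggplot object.
#' @export
plot_ari_summary <- function(summary) {
  if (!inherits(summary, "nbmix_ari_summary")) {
    summary <- summarize_ari(summary)
  }
  ggplot2::ggplot(summary,
                  ggplot2::aes(x = factor(.data$k), y = .data$mean_ari,
                               color = .data$method,
                               shape = factor(.data$delta_mu),
                               group = interaction(.data$method,
                                                   .data$delta_mu))) +
    ggplot2::geom_point(size = 2) +
    ggplot2::geom_line(alpha = 0.6) +
    ggplot2::facet_grid(g ~ n, labeller = ggplot2::label_both) +
    ggplot2::labs(x = "true number of clusters K", y = "mean ARI",
                  shape = "mean shift", color = "method") +
    ggplot2::ylim(-0.1, 1) +
    ggplot2::theme_bw()
}

#' @method autoplot nbmix_ari_summary
#' @export
autoplot.nbmix_ari_summary <- function(object, ...) {
  plot_ari_summary(object)
}
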