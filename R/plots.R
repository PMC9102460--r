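## ggplot2 views of the main result types.

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Bar chart of stage-presence categories
#'
#' @param presence Output of [stage_presence()].
#' @return A ggplot.
#' @export
plot_stage_presence <- function(presence) {
  counts <- dplyr::count(presence, .data$category, name = "n")
  ggplot2::ggplot(counts, ggplot2::aes(x = .data$category, y = .data$n)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::labs(x = NULL, y = "transcripts",
                  title = "Stage-presence categories") +
    ggplot2::theme_minimal()
}

#' Up/down bar chart of differential-expression tallies
#'
#' @param sets Output of [comparison_sets()] (or its `tallies` tibble).
#' @return A ggplot.
#' @export
plot_de_tallies <- function(sets) {
  tallies <- if (is.data.frame(sets)) sets else sets$tallies
  long <- tidyr::pivot_longer(tallies, c("n_up", "n_down"),
                              names_to = "direction", values_to = "n") |>
    dplyr::mutate(direction = sub("^n_", "", .data$direction))
  ggplot2::ggplot(long, ggplot2::aes(x = .data$comparison, y = .data$n,
                                     fill = .data$direction)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::scale_fill_manual(values = c(down = "#4575b4", up = "#d73027")) +
    ggplot2::labs(x = NULL, y = "significant transcripts",
                  title = "Differentially expressed transcripts per comparison") +
    ggplot2::theme_minimal()
}

#' Stage profiles of K-means clusters
#'
#' @param clusters Output of [kmeans_profiles()].
#' @return A ggplot (one facet per cluster, member profiles plus the
#'   cluster mean).
#' @export
plot_cluster_profiles <- function(clusters) {
  long <- clusters |>
    tidyr::pivot_longer(dplyr::starts_with("profile_"),
                        names_to = "stage", values_to = "z") |>
    dplyr::mutate(stage = as.integer(sub("profile_S", "", .data$stage)))
  ggplot2::ggplot(long, ggplot2::aes(x = .data$stage, y = .data$z,
                                     group = .data$transcript_id)) +
    ggplot2::geom_line(alpha = 0.15) +
    ggplot2::stat_summary(ggplot2::aes(group = 1), fun = mean,
                          geom = "line", colour = "red", linewidth = 1) +
    ggplot2::facet_wrap(~cluster) +
    ggplot2::labs(x = "stage", y = "standardized profile",
                  title = "DEL expression clusters") +
    ggplot2::theme_minimal()
}

#' Module-trait correlation heatmap
#'
#' @param object A `coexpr_fit` (from [run_coexpr()]).
#' @param ... Unused.
#' @return A ggplot: one tile per module colored by trait correlation,
#'   annotated with correlation and p-value.
#' @export
autoplot.coexpr_fit <- function(object, ...) {
  mt <- object$module_trait
  if (nrow(mt) == 0) abort("autoplot.coexpr_fit: no modules to plot")
  mt <- dplyr::mutate(mt,
                      label = sprintf("%.2f\n(p=%.3g)", .data$trait_cor,
                                      .data$trait_p))
  ggplot2::ggplot(mt, ggplot2::aes(x = "trait", y = .data$module,
                                   fill = .data$trait_cor)) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(label = .data$label), size = 3) +
    ggplot2::scale_fill_gradient2(low = "#4575b4", mid = "white",
                                  high = "#d73027", limits = c(-1, 1)) +
    ggplot2::labs(x = NULL, y = NULL, fill = "cor",
                  title = "Module-trait relationships") +
    ggplot2::theme_minimal()
}

#' Per-miRNA target-degree chart of a ceRNA network
#'
#' @param object A `cerna_network` (from [build_network()]).
#' @param top_n Show the `top_n` highest-degree miRNAs (default 20).
#' @param ... Unused.
#' @return A ggplot of lncRNA vs mRNA target counts per miRNA.
#' @export
autoplot.cerna_network <- function(object, top_n = 20, ...) {
  deg <- object$mirna_degree |>
    dplyr::arrange(dplyr::desc(.data$n_total)) |>
    dplyr::slice_head(n = top_n) |>
    tidyr::pivot_longer(c("n_lncrna", "n_mrna"), names_to = "type",
                        values_to = "n") |>
    dplyr::mutate(type = ifelse(.data$type == "n_lncrna", "lncRNA", "mRNA"))
  ggplot2::ggplot(deg, ggplot2::aes(x = stats::reorder(.data$mirna_id, .data$n),
                                    y = .data$n, fill = .data$type)) +
    ggplot2::geom_col() +
    ggplot2::coord_flip() +
    ggplot2::labs(x = NULL, y = "targets", fill = NULL,
                  title = "miRNA target degrees") +
    ggplot2::theme_minimal()
}
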