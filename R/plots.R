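#' Heatmap of scaled centrality dynamics
#'
#' Blue-to-red tile heatmap of the min-max scaled centralities per stage,
#' faceted by metric — the standard visualization of centrality trajectories
#' over aggregation stages.
#'
#' @param object A `centrality_table` from [stage_centralities()].
#' @param nodes Optional node subset (e.g. prioritized targets).
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.centrality_table <- function(object, nodes = NULL, ...) {
  df <- as_tibble(object)
  if (!is.null(nodes)) df <- filter(df, .data$node %in% nodes)
  long <- df |>
    select("node", "stage", dc = "scaled_dc", bc = "scaled_bc",
           cc = "scaled_cc") |>
    tidyr::pivot_longer(c("dc", "bc", "cc"), names_to = "metric",
                        values_to = "scaled") |>
    mutate(stage = factor(.data$stage, levels = stage_levels()),
           metric = factor(toupper(.data$metric),
                           levels = c("DC", "BC", "CC")))
  ggplot(long, aes(x = .data$stage, y = .data$node, fill = .data$scaled)) +
    geom_tile() +
    facet_wrap(~metric) +
    scale_fill_gradient(low = "blue", high = "red", limits = c(0, 1),
                        name = "scaled\ncentrality") +
    labs(x = "aggregation stage", y = NULL)
}

#' Volcano plot of a DEG table
#'
#' @param object A [deg_table()].
#' @param ... Unused.
#' @return A ggplot object faceted by time-point, DEGs highlighted.
#' @exportS3Method ggplot2::autoplot
autoplot.deg_table <- function(object, ...) {
  df <- as_tibble(object)
  ggplot(df, aes(x = .data$log2fc, y = -log10(.data$p_value),
                 colour = .data$is_deg)) +
    geom_point(size = 0.6, alpha = 0.7) +
    facet_wrap(~time_point) +
    scale_colour_manual(values = c(`FALSE` = "grey60", `TRUE` = "firebrick"),
                        name = "DEG") +
    labs(x = "log2 fold change", y = "-log10 p-value")
}

#' Bar plot of motif z-scores
#'
#' @param object A `motif_zscore` from [motif_zscores()].
#' @param ... Unused.
#' @return A ggplot object; undefined classes (zero null sd) are omitted.
#' @exportS3Method ggplot2::autoplot
autoplot.motif_zscore <- function(object, ...) {
  df <- filter(as_tibble(object), !is.na(.data$z))
  ggplot(df, aes(x = .data$class, y = .data$z)) +
    geom_col(fill = "steelblue") +
    geom_hline(yintercept = 0, linetype = "dashed") +
    labs(x = "4-node motif class", y = "z-score vs degree-preserving null")
}

#' Gantt-style stage-membership plot of the union network
#'
#' One row per node, one tile per stage the node is present in, coloured by
#' the node's membership group.
#'
#' @param union A `union_network`.
#' @return A ggplot object.
#' @export
plot_stage_membership <- function(union) {
  stopifnot(inherits(union, "union_network"))
  long <- stage_membership(union) |>
    tidyr::pivot_longer(c("early", "middle", "late"), names_to = "stage",
                        values_to = "present") |>
    filter(.data$present) |>
    mutate(stage = factor(.data$stage, levels = stage_levels()))
  ggplot(long, aes(x = .data$stage, y = .data$node, fill = .data$group)) +
    geom_tile(colour = "white") +
    scale_fill_manual(values = c(
      "all" = "gold", "middle-specific" = "forestgreen",
      "late-specific" = "magenta3"), na.value = "grey70") +
    labs(x = "aggregation stage", y = NULL, fill = "group")
}
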