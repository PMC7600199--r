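#' Degree, betweenness and closeness centralities of a network
#'
#' Computes, for every node of an undirected simple graph (edge confidences
#' are ignored — paths are unweighted):
#'
#' * `dc` — degree centrality, the number of neighbors;
#' * `bc` — betweenness centrality, the sum over unordered node pairs
#'   (endpoints excluded) of the fraction of shortest paths between them that
#'   pass through the node, unnormalized;
#' * `farness` — the sum of shortest-path distances to the other nodes of the
#'   node's connected component (the raw closeness sum of the classical
#'   formula);
#' * `cc` — closeness centrality in the NetworkAnalyzer convention,
#'   `(n_c - 1) / farness` within the node's component of size `n_c`, so
#'   larger means more central; `NA` for isolated nodes.
#'
#' @param network A `stage_network`, `union_network` or igraph.
#' @param stage Optional stage label for the output (taken from a
#'   `stage_network` automatically).
#' @return Tibble with columns `node`, `stage`, `dc`, `bc`, `farness`, `cc`.
#' @export
centralities <- function(network, stage = NULL) {
  if (inherits(network, "stage_network") && is.null(stage)) {
    stage <- network$stage
  }
  g <- as_igraph(network)
  if (igraph::vcount(g) == 0L) {
    return(tibble(node = character(), stage = character(), dc = numeric(),
                  bc = numeric(), farness = numeric(), cc = numeric()))
  }
  nodes <- igraph::V(g)$name
  dc <- as.numeric(igraph::degree(g, loops = FALSE))
  bc <- as.numeric(igraph::betweenness(g, directed = FALSE, weights = NA,
                                       normalized = FALSE))
  d <- igraph::distances(g, weights = NA)
  comp <- igraph::components(g)
  farness <- numeric(length(nodes))
  cc <- rep(NA_real_, length(nodes))
  for (i in seq_along(nodes)) {
    same <- which(comp$membership == comp$membership[i])
    farness[i] <- sum(d[i, setdiff(same, i)])
    n_c <- length(same)
    if (n_c >= 2L) cc[i] <- (n_c - 1) / farness[i]
  }
  tibble(node = nodes, stage = stage %||% NA_character_,
         dc = dc, bc = bc, farness = farness, cc = cc)
}

#' Centrality table across the three aggregation stages
#'
#' Stacks [centralities()] for the early, middle and late networks and adds
#' the min-max scaled columns used for heatmaps (see [scale_for_heatmap()]).
#'
#' @param early,middle,late `stage_network`s.
#' @return A `centrality_table` tibble.
#' @export
stage_centralities <- function(early, middle, late) {
  out <- bind_rows(centralities(early, stage = "early"),
                   centralities(middle, stage = "middle"),
                   centralities(late, stage = "late"))
  scale_for_heatmap(out)
}

#' Min-max scale centralities per metric and stage
#'
#' Scales each of `dc`, `bc`, `cc` to `[0, 1]` across the nodes of each
#' stage (the colour axis of the centrality heatmaps). A constant column —
#' including a single-node stage — maps to 0.5.
#'
#' @param table Tibble with columns `node`, `stage`, `dc`, `bc`, `cc`.
#' @return The table with added `scaled_dc`, `scaled_bc`, `scaled_cc`
#'   columns, classed `centrality_table`.
#' @export
scale_for_heatmap <- function(table) {
  if (!nrow(table)) {
    out <- mutate(table, scaled_dc = numeric(), scaled_bc = numeric(),
                  scaled_cc = numeric())
  } else {
    minmax <- function(x) {
      rng <- range(x, na.rm = TRUE)
      if (!is.finite(rng[1]) || rng[1] == rng[2]) {
        return(ifelse(is.na(x), NA_real_, 0.5))
      }
      (x - rng[1]) / (rng[2] - rng[1])
    }
    out <- table |>
      group_by(.data$stage) |>
      mutate(scaled_dc = minmax(.data$dc),
             scaled_bc = minmax(.data$bc),
             scaled_cc = minmax(.data$cc)) |>
      ungroup()
  }
  structure(out, class = c("centrality_table", class(tibble())))
}

#' Top-ranked nodes for one metric at one stage
#'
#' @param table A `centrality_table`.
#' @param metric One of `"dc"`, `"bc"`, `"cc"`.
#' @param stage Stage label.
#' @param k Number of nodes to return (all nodes if fewer are present).
#' @return Tibble with columns `rank`, `node`, `value`, ordered by descending
#'   value with ties broken alphabetically.
#' @export
top_nodes <- function(table, metric = c("dc", "bc", "cc"), stage, k) {
  metric <- match.arg(metric)
  k <- check_count(k, "k", min = 1L)
  table |>
    filter(.data$stage == !!stage) |>
    mutate(value = .data[[metric]]) |>
    arrange(desc(.data$value), .data$node) |>
    slice_head(n = k) |>
    mutate(rank = row_number()) |>
    select("rank", "node", "value")
}

#' Classify centrality trajectories across stages
#'
#' For each node and metric, compares the scaled centrality at the earliest
#' and latest stage where the node is present: `increasing` when the change
#' exceeds `tolerance`, `decreasing` when it falls below `-tolerance`,
#' `stable` otherwise. Nodes missing from one or more stages are flagged
#' `absent-some-stages` (their `trend` still reports the partial comparison);
#' nodes present at fewer than two stages get no call.
#'
#' @param table A `centrality_table` from [stage_centralities()].
#' @param tolerance Dead band on the scaled `[0, 1]` axis (default 0.05).
#' @return Tibble with columns `node`, `metric`, `n_stages`,
#'   `scaled_early`, `scaled_middle`, `scaled_late`, `magnitude`, `trend`,
#'   `classification`.
#' @export
classify_trajectories <- function(table, tolerance = 0.05) {
  check_scalar_number(tolerance, "tolerance", min = 0)
  stages <- stage_levels()
  long <- table |>
    select("node", "stage", scaled_dc = "scaled_dc", scaled_bc = "scaled_bc",
           scaled_cc = "scaled_cc") |>
    tidyr::pivot_longer(cols = dplyr::starts_with("scaled_"),
                        names_to = "metric", names_prefix = "scaled_",
                        values_to = "scaled")
  wide <- long |>
    tidyr::pivot_wider(names_from = "stage", values_from = "scaled")
  for (s in stages) {
    if (!s %in% names(wide)) wide[[s]] <- NA_real_
  }
  calls <- wide |>
    mutate(
      n_stages = (!is.na(.data$early)) + (!is.na(.data$middle)) +
        (!is.na(.data$late)),
      first_val = dplyr::coalesce(.data$early, .data$middle, .data$late),
      last_val = dplyr::coalesce(.data$late, .data$middle, .data$early),
      magnitude = ifelse(.data$n_stages >= 2, .data$last_val - .data$first_val,
                         NA_real_),
      trend = dplyr::case_when(
        n_stages < 2 ~ NA_character_,
        magnitude > tolerance ~ "increasing",
        magnitude < -tolerance ~ "decreasing",
        TRUE ~ "stable"
      ),
      classification = dplyr::case_when(
        n_stages == 3 ~ trend,
        TRUE ~ "absent-some-stages"
      )
    )
  calls |>
    select("node", "metric", "n_stages",
           scaled_early = "early", scaled_middle = "middle",
           scaled_late = "late", "magnitude", "trend", "classification") |>
    arrange(.data$node, .data$metric)
}

#' Prioritize candidate intervention targets from centrality dynamics
#'
#' Nodes whose degree and betweenness both grow over aggregation are gaining
#' control of the network and are candidates for inhibition; nodes losing
#' betweenness and closeness are fading and are candidates for stimulation;
#' nodes that sit in the top closeness quantile at every stage are persistent
#' central anchors.
#'
#' @param calls Output of [classify_trajectories()].
#' @param table The `centrality_table` the calls were computed from.
#' @param cc_quantile Quantile (default 0.9) defining "top closeness" within
#'   each stage for the persistent-high-CC category.
#' @return A `target_report` tibble with columns `node`, `category`
#'   (`inhibition`, `stimulation`, `persistent-high-cc`) and `evidence`.
#' @export
prioritize_targets <- function(calls, table, cc_quantile = 0.9) {
  check_probability(cc_quantile, "cc_quantile")
  trend_of <- function(m) {
    calls |>
      filter(.data$metric == m, !is.na(.data$trend)) |>
      select("node", trend = "trend", magnitude = "magnitude")
  }
  dc <- trend_of("dc"); bc <- trend_of("bc"); cc <- trend_of("cc")
  inhibition <- inner_join(filter(dc, .data$trend == "increasing"),
                           filter(bc, .data$trend == "increasing"),
                           by = "node", suffix = c("_dc", "_bc")) |>
    mutate(category = "inhibition",
           evidence = sprintf("DC +%.2f, BC +%.2f (scaled)",
                              .data$magnitude_dc, .data$magnitude_bc)) |>
    select("node", "category", "evidence")
  stimulation <- inner_join(filter(bc, .data$trend == "decreasing"),
                            filter(cc, .data$trend == "decreasing"),
                            by = "node", suffix = c("_bc", "_cc")) |>
    mutate(category = "stimulation",
           evidence = sprintf("BC %.2f, CC %.2f (scaled)",
                              .data$magnitude_bc, .data$magnitude_cc)) |>
    select("node", "category", "evidence")
  # persistent-high-CC: in the top-q closeness quantile at every stage
  cutoffs <- table |>
    filter(!is.na(.data$cc)) |>
    group_by(.data$stage) |>
    summarise(cut = quantile(.data$cc, cc_quantile, names = FALSE),
              .groups = "drop")
  n_stages_present <- nrow(cutoffs)
  persistent <- table |>
    filter(!is.na(.data$cc)) |>
    left_join(cutoffs, by = "stage") |>
    group_by(.data$node) |>
    summarise(n_top = sum(.data$cc >= .data$cut), n_present = n(),
              .groups = "drop") |>
    filter(.data$n_present == n_stages_present,
           .data$n_top == n_stages_present) |>
    mutate(category = "persistent-high-cc",
           evidence = sprintf("top %.0f%% CC at all %d stages",
                              100 * (1 - cc_quantile), n_stages_present)) |>
    select("node", "category", "evidence")
  out <- bind_rows(inhibition, stimulation, persistent) |>
    arrange(.data$category, .data$node)
  structure(out, cc_quantile = cc_quantile,
            class = c("target_report", class(tibble())))
}
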