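#' Build a stage-specific PPI network with confidence and tissue filters
#'
#' Starting from the proteins of the common dysregulated pathways at one
#' aggregation stage, keeps only proteins whose tissue-expression score
#' reaches `tissue_threshold` (inclusive), induces the subgraph on them,
#' drops interactions below `edge_threshold` (inclusive, "or above"), and
#' finally deletes unconnected (degree-0) nodes. Node order is deterministic
#' (sorted ids).
#'
#' @param members Character vector of member proteins (non-empty).
#' @param edges PPI edge tibble (`node_a`, `node_b`, `confidence`).
#' @param tissue_scores Tibble (`node`, `score`); proteins absent from it are
#'   treated as failing the tissue filter.
#' @param stage Stage label attached to the network.
#' @param edge_threshold Minimum interaction confidence (default 0.950).
#' @param tissue_threshold Minimum tissue-expression score (default 4.8).
#' @return A `stage_network`: list with elements `stage`, `graph` (igraph),
#'   and `provenance` (inputs and thresholds).
#' @export
build_stage_network <- function(members, edges, tissue_scores,
                                stage = "stage",
                                edge_threshold = 0.950,
                                tissue_threshold = 4.8) {
  if (!length(members)) abort("Member protein list is empty.")
  edges <- validate_ppi_edges(edges)
  members <- unique(members)
  scored <- tissue_scores$score[match(members, tissue_scores$node)]
  kept <- members[!is.na(scored) & scored >= tissue_threshold]
  sub <- edges |>
    filter(.data$node_a %in% kept, .data$node_b %in% kept,
           .data$confidence >= edge_threshold)
  # building from surviving edges alone drops degree-0 nodes by construction
  g <- graph_from_edges(sub)
  new_stage_network(g, stage,
                    provenance = list(n_members = length(members),
                                      n_tissue_pass = length(kept),
                                      edge_threshold = edge_threshold,
                                      tissue_threshold = tissue_threshold))
}

new_stage_network <- function(graph, stage, provenance = list()) {
  structure(list(stage = stage, graph = graph, provenance = provenance),
            class = "stage_network")
}

#' @export
print.stage_network <- function(x, ...) {
  cat(sprintf("<stage_network '%s'>: %d nodes, %d edges\n",
              x$stage, igraph::vcount(x$graph), igraph::ecount(x$graph)))
  invisible(x)
}

# Empty network for degenerate pipeline states (no common pathways).
empty_stage_network <- function(stage, edge_threshold = 0.950,
                                tissue_threshold = 4.8) {
  new_stage_network(graph_from_edges(tibble(node_a = character(),
                                            node_b = character(),
                                            confidence = numeric())),
                    stage,
                    provenance = list(n_members = 0L, n_tissue_pass = 0L,
                                      edge_threshold = edge_threshold,
                                      tissue_threshold = tissue_threshold))
}

#' Merge stage networks into a stage-labelled union network
#'
#' Takes the union of the early, middle and late networks (nodes and edges;
#' an edge present at several stages keeps its maximum confidence) and labels
#' every node with its exact stage-membership set. The three named groups of
#' the union follow the usual colouring: present at all stages (`"all"`,
#' yellow), only at the middle stage (`"middle-specific"`, green), only at
#' the late stage (`"late-specific"`, magenta); any other pattern keeps its
#' literal `+`-joined membership label (grey).
#'
#' @param early,middle,late `stage_network`s on a shared protein namespace.
#' @return A `union_network`: list with `graph` (igraph with vertex
#'   attributes `stage_set`, `group`, `color`) and `membership`, a
#'   Gantt-style tibble (`node`, logical `early`/`middle`/`late`,
#'   `stage_set`, `group`, `color`).
#' @export
merge_stage_networks <- function(early, middle, late) {
  nets <- list(early = early, middle = middle, late = late)
  stopifnot(all(map_chr(nets, function(x) class(x)[1]) == "stage_network"))
  edge_tabs <- imap(nets, function(net, nm) {
    el <- igraph::as_edgelist(net$graph)
    if (!nrow(el)) {
      return(tibble(node_a = character(), node_b = character(),
                    confidence = numeric()))
    }
    tibble(node_a = pmin(el[, 1], el[, 2]), node_b = pmax(el[, 1], el[, 2]),
           confidence = igraph::edge_attr(net$graph, "confidence") %||%
             rep(NA_real_, nrow(el)))
  })
  all_edges <- bind_rows(edge_tabs)
  if (nrow(all_edges)) {
    all_edges <- all_edges |>
      group_by(.data$node_a, .data$node_b) |>
      summarise(confidence = max(.data$confidence), .groups = "drop")
  }
  node_sets <- map(nets, function(net) igraph::V(net$graph)$name)
  nodes <- sort(unique(unlist(node_sets)))
  membership <- tibble(
    node = nodes,
    early = nodes %in% node_sets$early,
    middle = nodes %in% node_sets$middle,
    late = nodes %in% node_sets$late
  ) |>
    mutate(
      stage_set = pmap_chr_stages(.data$early, .data$middle, .data$late),
      group = dplyr::case_when(
        early & middle & late ~ "all",
        !early & middle & !late ~ "middle-specific",
        !early & !middle & late ~ "late-specific",
        TRUE ~ stage_set
      ),
      color = dplyr::case_when(
        group == "all" ~ "yellow",
        group == "middle-specific" ~ "green",
        group == "late-specific" ~ "magenta",
        TRUE ~ "grey"
      )
    )
  g <- graph_from_edges(all_edges, nodes = nodes)
  ord <- match(igraph::V(g)$name, membership$node)
  g <- igraph::set_vertex_attr(g, "stage_set", value = membership$stage_set[ord])
  g <- igraph::set_vertex_attr(g, "group", value = membership$group[ord])
  g <- igraph::set_vertex_attr(g, "color", value = membership$color[ord])
  structure(list(graph = g, membership = membership), class = "union_network")
}

pmap_chr_stages <- function(early, middle, late) {
  vapply(seq_along(early), function(i) {
    paste(stage_levels()[c(early[i], middle[i], late[i])], collapse = "+")
  }, character(1))
}

#' @export
print.union_network <- function(x, ...) {
  cat(sprintf("<union_network>: %d nodes, %d edges\n",
              igraph::vcount(x$graph), igraph::ecount(x$graph)))
  print(dplyr::count(x$membership, .data$group))
  invisible(x)
}

#' Gantt-style stage-membership table of a union network
#'
#' @param x A `union_network`.
#' @return Tibble with one row per node and logical stage columns.
#' @export
stage_membership <- function(x) {
  stopifnot(inherits(x, "union_network"))
  x$membership
}

#' @exportS3Method generics::tidy
tidy.union_network <- function(x, ...) stage_membership(x)

#' @exportS3Method generics::glance
glance.union_network <- function(x, ...) {
  groups <- table(x$membership$group)
  tibble(
    n_nodes = igraph::vcount(x$graph),
    n_edges = igraph::ecount(x$graph),
    n_all = sum(x$membership$group == "all"),
    n_middle_specific = sum(x$membership$group == "middle-specific"),
    n_late_specific = sum(x$membership$group == "late-specific"),
    n_other = igraph::vcount(x$graph) - sum(groups[c("all", "middle-specific",
                                                     "late-specific")],
                                            na.rm = TRUE)
  )
}

#' Over-representation of a flagged gene list among network nodes
#'
#' Hypergeometric upper-tail test of whether the nodes of a network overlap a
#' flagged gene list (e.g. literature-mined aggregation genes) more than
#' expected from the background universe. This is [enrich()] with the network
#' node set as the gene list and the flagged list as a single set.
#'
#' @param network A `union_network` or `stage_network`.
#' @param flagged_genes Character vector, subset of `background`.
#' @param background Character vector, the gene universe.
#' @return One-row tibble in the [enrich()] output format.
#' @export
annotation_overrepresentation <- function(network, flagged_genes, background) {
  if (!all(flagged_genes %in% background)) {
    abort("`flagged_genes` must be a subset of `background`.")
  }
  nodes <- igraph::V(as_igraph(network))$name
  collection <- tibble(set_id = "flagged", name = "flagged gene list",
                       genes = list(unique(flagged_genes)))
  enrich(nodes, collection, background)
}
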