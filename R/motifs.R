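#' Exact census of connected 4-node induced subgraphs
#'
#' Counts every connected induced subgraph on 4 vertices by isomorphism
#' class: `path` (3 edges, max degree 2), `star` (3 edges, max degree 3),
#' `cycle` (4 edges, all degree 2), `triangle_pendant` (4 edges, a triangle
#' with a pendant vertex), `diamond` (5 edges) and `complete` (6 edges).
#'
#' The census is exact but does not enumerate subsets: non-induced copy
#' counts of the six patterns are computed in closed form from the adjacency
#' matrix (degree and codegree sums, per-edge triangle counts, clique
#' enumeration over edges) and converted to induced counts by
#' inclusion-exclusion over the pattern containment lattice. This makes the
#' census cheap enough to repeat over large null ensembles.
#'
#' @param graph Simple undirected igraph (no self-loops or multi-edges).
#' @return A `motif_census` tibble with columns `class` and `count`, plus a
#'   `total` attribute (the number of connected 4-subsets).
#' @export
census_4node <- function(graph) {
  graph <- as_igraph(graph)
  if (igraph::any_loop(graph) || igraph::any_multiple(graph)) {
    abort("Motif census requires a simple graph (no self-loops or multi-edges).")
  }
  n <- igraph::vcount(graph)
  m <- igraph::ecount(graph)
  counts <- setNames(numeric(6), motif_class_names())
  if (n >= 4L && m >= 3L) {
    a <- as.matrix(igraph::as_adjacency_matrix(graph, sparse = TRUE))
    storage.mode(a) <- "double"
    deg <- rowSums(a)
    a2 <- a %*% a                      # codegrees on the off-diagonal
    el <- igraph::as_edgelist(graph, names = FALSE)
    t_e <- a2[el]                      # triangles through each edge
    tri_v <- diag(a2 %*% a) / 2        # triangles through each vertex

    # non-induced copy counts of the six 4-node patterns
    ni_path <- sum((deg[el[, 1]] - 1) * (deg[el[, 2]] - 1) - t_e)
    ni_star <- sum(choose(deg, 3))
    upper <- upper.tri(a2)
    ni_cycle <- sum(choose(a2[upper], 2)) / 2
    ni_paw <- sum(tri_v * (deg - 2))
    ni_diamond <- sum(choose(t_e, 2))
    ni_k4 <- sum(vapply(seq_len(nrow(el)), function(i) {
      s <- which(a[el[i, 1], ] == 1 & a[el[i, 2], ] == 1)
      if (length(s) < 2) 0 else sum(a[s, s]) / 2
    }, numeric(1))) / 6

    # induced counts via the containment lattice, solved densest-first
    k4 <- ni_k4
    diamond <- ni_diamond - 6 * k4
    cycle <- ni_cycle - diamond - 3 * k4
    paw <- ni_paw - 4 * diamond - 12 * k4
    star <- ni_star - paw - 2 * diamond - 4 * k4
    path <- ni_path - 4 * cycle - 2 * paw - 6 * diamond - 12 * k4
    counts[] <- c(path, star, cycle, paw, diamond, k4)
  }
  structure(
    tibble(class = motif_class_names(), count = as.numeric(counts)),
    total = sum(counts),
    class = c("motif_census", class(tibble()))
  )
}

motif_class_names <- function() {
  c("path", "star", "cycle", "triangle_pendant", "diamond", "complete")
}

#' Degree-preserving randomization by double-edge swaps
#'
#' Rewires a graph with attempted double-edge swaps that preserve the degree
#' sequence exactly and never introduce self-loops or multi-edges (the
#' standard configuration-model null for motif statistics). Graphs admitting
#' no legal swap (e.g. a star) are returned unchanged.
#'
#' @param graph Simple undirected igraph.
#' @param n_swaps Number of attempted swaps; default 10 per edge.
#' @param seed Optional integer; when given, the result is reproducible and
#'   the caller's RNG state is left untouched.
#' @return A rewired igraph with the same vertices and degree sequence.
#' @export
randomize_preserving_degrees <- function(graph,
                                         n_swaps = 10 * igraph::ecount(graph),
                                         seed = NULL) {
  graph <- as_igraph(graph)
  if (igraph::ecount(graph) < 2L) {
    inform("Fewer than 2 edges; returning the graph unchanged.")
    return(graph)
  }
  with_seed(seed, {
    igraph::rewire(graph, igraph::keeping_degseq(loops = FALSE,
                                                 niter = max(1, n_swaps)))
  })
}

#' Motif z-scores against a degree-preserving null ensemble
#'
#' Compares the 4-node motif census of a network against an ensemble of
#' degree-preserving randomizations: for each class,
#' `z = (real - null_mean) / null_sd`, defined only where the null standard
#' deviation is positive. The aggregate statistic is the unweighted mean of
#' the defined per-class z values (`NA` when none is defined, e.g. when every
#' randomization returns the identical graph).
#'
#' @param graph Simple undirected igraph.
#' @param ensemble_size Number of randomized networks (default 1000).
#' @param n_swaps Attempted swaps per randomization (default 10 per edge).
#' @param seed Optional integer seed for the whole ensemble.
#' @return A `motif_zscore` object: tibble with columns `class`, `count`,
#'   `null_mean`, `null_sd`, `z`; attributes `aggregate_z`, `ensemble_size`,
#'   `n_swaps`, `seed`.
#' @export
motif_zscores <- function(graph, ensemble_size = 1000,
                          n_swaps = 10 * igraph::ecount(graph),
                          seed = NULL) {
  graph <- as_igraph(graph)
  ensemble_size <- check_count(ensemble_size, "ensemble_size", min = 2L)
  real <- census_4node(graph)$count
  null_counts <- with_seed(seed, {
    vapply(seq_len(ensemble_size), function(i) {
      census_4node(randomize_preserving_degrees(graph, n_swaps = n_swaps))$count
    }, numeric(6))
  })
  null_mean <- rowMeans(null_counts)
  null_sd <- apply(null_counts, 1, stats::sd)
  z <- ifelse(null_sd > 0, (real - null_mean) / null_sd, NA_real_)
  aggregate_z <- if (all(is.na(z))) NA_real_ else mean(z, na.rm = TRUE)
  structure(
    tibble(class = motif_class_names(), count = real,
           null_mean = null_mean, null_sd = null_sd, z = z),
    aggregate_z = aggregate_z,
    ensemble_size = ensemble_size,
    n_swaps = n_swaps,
    seed = seed,
    class = c("motif_zscore", class(tibble()))
  )
}

#' @exportS3Method generics::tidy
tidy.motif_zscore <- function(x, ...) as_tibble(x)

#' @exportS3Method generics::glance
glance.motif_zscore <- function(x, ...) {
  tibble(
    aggregate_z = attr(x, "aggregate_z"),
    n_classes_defined = sum(!is.na(x$z)),
    ensemble_size = attr(x, "ensemble_size"),
    n_swaps = attr(x, "n_swaps")
  )
}
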