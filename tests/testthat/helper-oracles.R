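# Independent brute-force oracles and shared fixtures for the test suite.
# Everything here is deliberately naive: correctness over speed, and no code
# shared with the implementation paths it checks.

# Random simple undirected graph with named vertices.
random_named_graph <- function(n, p) {
  g <- igraph::sample_gnp(n, p)
  igraph::V(g)$name <- sprintf("v%02d", seq_len(n))
  g
}

# --- naive 4-node census: examine every C(n, 4) vertex subset ---------------
oracle_census_4node <- function(g) {
  a <- as.matrix(igraph::as_adjacency_matrix(g))
  n <- nrow(a)
  counts <- c(path = 0, star = 0, cycle = 0, triangle_pendant = 0,
              diamond = 0, complete = 0)
  if (n < 4) return(counts)
  for (s in utils::combn(n, 4, simplify = FALSE)) {
    sub <- a[s, s]
    deg <- colSums(sub)
    m <- sum(deg) / 2
    if (m < 3) next
    reach <- 1L
    repeat {
      nxt <- union(reach, which(colSums(sub[reach, , drop = FALSE]) > 0))
      if (length(nxt) == length(reach)) break
      reach <- nxt
    }
    if (length(reach) < 4) next
    cls <- if (m == 3) {
      if (max(deg) == 3) "star" else "path"
    } else if (m == 4) {
      if (max(deg) == 3) "triangle_pendant" else "cycle"
    } else if (m == 5) "diamond" else "complete"
    counts[cls] <- counts[cls] + 1
  }
  counts
}

# --- brute-force centralities: explicit enumeration of all shortest paths ---
oracle_centralities <- function(g) {
  a <- as.matrix(igraph::as_adjacency_matrix(g)) > 0
  n <- nrow(a)
  d <- igraph::distances(g, weights = NA)
  bc <- numeric(n)
  # enumerate every shortest path between a pair by depth-first backtracking
  all_paths <- function(s, t) {
    if (!is.finite(d[s, t])) return(list())
    walk <- function(v) {
      if (v == s) return(list(s))
      preds <- which(a[, v] & d[s, ] == d[s, v] - 1)
      out <- list()
      for (p in preds) {
        for (pre in walk(p)) out <- c(out, list(c(pre, v)))
      }
      out
    }
    walk(t)
  }
  interm_total <- 0
  for (s in seq_len(n - 1)) {
    for (t in (s + 1):n) {
      paths <- all_paths(s, t)
      if (!length(paths)) next
      g_st <- length(paths)
      inner <- unlist(lapply(paths, function(p) p[-c(1, length(p))]))
      interm_total <- interm_total + length(inner)
      if (length(inner)) {
        tab <- table(inner)
        idx <- as.integer(names(tab))
        bc[idx] <- bc[idx] + as.numeric(tab) / g_st
      }
    }
  }
  comp <- igraph::components(g)
  farness <- numeric(n)
  cc <- rep(NA_real_, n)
  for (i in seq_len(n)) {
    same <- setdiff(which(comp$membership == comp$membership[i]), i)
    farness[i] <- sum(d[i, same])
    if (length(same)) cc[i] <- length(same) / farness[i]
  }
  list(node = igraph::V(g)$name, bc = bc, farness = farness, cc = cc,
       total_intermediate_incidences = interm_total)
}

# --- exhaustive hypergeometric tail for small backgrounds -------------------
# P(overlap >= k) by enumerating every n-subset of a size-N background.
oracle_hyper_tail <- function(N, K, n, k) {
  subsets <- utils::combn(N, n, simplify = FALSE)
  hits <- sum(vapply(subsets, function(s) sum(s <= K) >= k, logical(1)))
  hits / length(subsets)
}

# --- tiny expression study built from explicit replicate values -------------
# `case`, `control`: matrices genes x replicates.
toy_study <- function(case, control, genes = sprintf("g%d", seq_len(nrow(case)))) {
  fpkm <- tibble::tibble(gene = genes)
  for (r in seq_len(ncol(control))) fpkm[[paste0("ctl_", r)]] <- control[, r]
  for (r in seq_len(ncol(case))) fpkm[[paste0("case_", r)]] <- case[, r]
  samples <- tibble::tibble(
    sample = c(paste0("ctl_", seq_len(ncol(control))),
               paste0("case_", seq_len(ncol(case)))),
    condition = c(rep("ctl", ncol(control)), rep("case", ncol(case))),
    time_point = c(rep("T0", ncol(control)), rep("T1", ncol(case))),
    role = c(rep("control", ncol(control)), rep("case", ncol(case))),
    replicate = c(seq_len(ncol(control)), seq_len(ncol(case)))
  )
  contrasts <- tibble::tibble(stage = "early", time_point = "T1",
                              case_condition = "case",
                              control_condition = "ctl")
  expression_study(fpkm, samples, contrasts, model = "toy")
}

# --- planted centrality-dynamics fixture ------------------------------------
# Three stage networks over 13 proteins: two 4-cliques (a1..a4, b1..b4)
# bridged only through a 3-clique (k1..k3, each tied to a1 and b1, so their
# closeness stays at the top at every stage); a broker X that bridges the two
# sides early and degenerates to a leaf; a hub H that grows from a leaf into
# a cross-cluster hub.
planted_dynamics_networks <- function() {
  clique <- function(v) t(utils::combn(v, 2))
  core <- rbind(
    clique(paste0("a", 1:4)),
    clique(paste0("b", 1:4)),
    clique(paste0("k", 1:3)),
    cbind(paste0("k", 1:3), "a1"),
    cbind(paste0("k", 1:3), "b1")
  )
  stage_edges <- list(
    early = rbind(core,
                  cbind("X", c("a1", "a2", "b1", "b2")),
                  cbind("H", "a3")),
    middle = rbind(core,
                   cbind("X", c("a1", "b1")),
                   cbind("H", c("a1", "a2", "a3"))),
    late = rbind(core,
                 cbind("X", "a2"),
                 cbind("H", c("a1", "a2", "a3", "a4", "b1")))
  )
  nodes <- c(paste0("a", 1:4), paste0("b", 1:4), paste0("k", 1:3), "X", "H")
  tissue <- tibble::tibble(node = nodes, score = 5)
  lapply(names(stage_edges), function(s) {
    e <- stage_edges[[s]]
    edges <- tibble::tibble(node_a = e[, 1], node_b = e[, 2], confidence = 0.99)
    build_stage_network(nodes, edges, tissue, stage = s)
  }) |> setNames(names(stage_edges))
}
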