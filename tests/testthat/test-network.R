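toy_ppi <- function() {
  tibble::tibble(
    node_a = c("a", "a", "b", "c", "d"),
    node_b = c("b", "c", "c", "d", "e"),
    confidence = c(0.950, 0.949, 0.99, 0.96, 0.97)
  )
}
toy_tissue <- function(scores = c(a = 5, b = 5, c = 5, d = 5, e = 5)) {
  tibble::tibble(node = names(scores), score = unname(scores))
}

test_that("confidence filter is inclusive at 0.950 and drops below it", {
  nw <- build_stage_network(letters[1:5], toy_ppi(), toy_tissue(), "early")
  el <- igraph::as_edgelist(nw$graph)
  pairs <- paste(el[, 1], el[, 2])
  expect_true("a b" %in% pairs)        # 0.950 kept ("or above")
  expect_false("a c" %in% pairs)       # 0.949 dropped
})

test_that("tissue filter excludes low-scoring nodes with their edges", {
  tissue <- toy_tissue(c(a = 5, b = 4.7, c = 4.8, d = 5, e = 5))
  nw <- build_stage_network(letters[1:5], toy_ppi(), tissue, "early")
  expect_false("b" %in% igraph::V(nw$graph)$name)   # 4.7 < 4.8
  expect_true("c" %in% igraph::V(nw$graph)$name)    # 4.8 inclusive
})

test_that("members left without any connection are deleted", {
  # e's only edge partner d is removed by the tissue filter -> e unconnected
  tissue <- toy_tissue(c(a = 5, b = 5, c = 5, d = 4.0, e = 5))
  nw <- build_stage_network(letters[1:5], toy_ppi(), tissue, "early")
  expect_false("e" %in% igraph::V(nw$graph)$name)
  expect_error(build_stage_network(character(), toy_ppi(), toy_tissue()),
               "empty")
})

test_that("raising the edge threshold never adds nodes or edges", {
  set.seed(13)
  edges <- tibble::tibble(
    node_a = sprintf("n%02d", sample(1:15, 40, replace = TRUE)),
    node_b = sprintf("n%02d", sample(16:30, 40, replace = TRUE)),
    confidence = runif(40)
  ) |> dplyr::distinct(node_a, node_b, .keep_all = TRUE)
  tissue <- tibble::tibble(node = sprintf("n%02d", 1:30), score = 5)
  members <- sprintf("n%02d", 1:30)
  thresholds <- seq(0, 1, by = 0.1)
  sizes <- t(vapply(thresholds, function(th) {
    nw <- build_stage_network(members, edges, tissue, edge_threshold = th)
    c(igraph::vcount(nw$graph), igraph::ecount(nw$graph))
  }, numeric(2)))
  expect_true(all(diff(sizes[, 1]) <= 0))
  expect_true(all(diff(sizes[, 2]) <= 0))
})

test_that("tissue and confidence filters commute", {
  set.seed(17)
  nodes <- sprintf("n%02d", 1:20)
  edges <- tibble::tibble(
    node_a = sprintf("n%02d", sample(1:10, 30, replace = TRUE)),
    node_b = sprintf("n%02d", sample(11:20, 30, replace = TRUE)),
    confidence = runif(30, 0.9, 1)
  ) |> dplyr::distinct(node_a, node_b, .keep_all = TRUE)
  tissue <- tibble::tibble(node = nodes, score = runif(20, 4, 5))
  # tissue-first: restrict the member list before applying the edge filter
  pass <- tissue$node[tissue$score >= 4.8]
  direct <- build_stage_network(nodes, edges, tissue)
  pre_filtered <- build_stage_network(
    intersect(nodes, pass),
    dplyr::filter(edges, confidence >= 0.950), tissue)
  expect_equal(sort(igraph::V(direct$graph)$name),
               sort(igraph::V(pre_filtered$graph)$name))
  expect_equal(igraph::ecount(direct$graph), igraph::ecount(pre_filtered$graph))
})

test_that("union network labels stage membership groups and colors", {
  mk <- function(edges, stage) {
    tissue <- tibble::tibble(node = unique(c(edges$node_a, edges$node_b)),
                             score = 5)
    build_stage_network(tissue$node, edges, tissue, stage = stage)
  }
  e <- function(a, b) tibble::tibble(node_a = a, node_b = b, confidence = 0.99)
  early <- mk(e(c("u", "u"), c("v", "w")), "early")        # u, v, w
  middle <- mk(e(c("u", "m"), c("v", "u")), "middle")      # u, v, m
  late <- mk(e(c("u", "l"), c("v", "u")), "late")          # u, v, l
  un <- merge_stage_networks(early, middle, late)
  mem <- stage_membership(un)
  expect_equal(mem$group[mem$node == "u"], "all")
  expect_equal(mem$group[mem$node == "m"], "middle-specific")
  expect_equal(mem$group[mem$node == "l"], "late-specific")
  expect_equal(mem$group[mem$node == "w"], "early")        # residual pattern
  expect_equal(mem$color[mem$node == "u"], "yellow")
  expect_equal(mem$color[mem$node == "m"], "green")
  expect_equal(mem$color[mem$node == "l"], "magenta")

  # node and edge sets are exactly the unions; groups partition the node set
  expect_setequal(igraph::V(un$graph)$name, c("u", "v", "w", "m", "l"))
  expect_equal(sum(table(mem$group)), igraph::vcount(un$graph))
  all_edges <- unique(c(
    polyqnet:::pair_key(igraph::as_edgelist(early$graph)[, 1],
                        igraph::as_edgelist(early$graph)[, 2]),
    polyqnet:::pair_key(igraph::as_edgelist(middle$graph)[, 1],
                        igraph::as_edgelist(middle$graph)[, 2]),
    polyqnet:::pair_key(igraph::as_edgelist(late$graph)[, 1],
                        igraph::as_edgelist(late$graph)[, 2])))
  expect_equal(igraph::ecount(un$graph), length(all_edges))

  # a node present in early and middle keeps its literal pattern label
  early2 <- mk(e("p", "q"), "early")
  middle2 <- mk(e("p", "q"), "middle")
  late2 <- mk(e("x", "y"), "late")
  un2 <- merge_stage_networks(early2, middle2, late2)
  mem2 <- stage_membership(un2)
  expect_equal(mem2$group[mem2$node == "p"], "early+middle")
})

test_that("annotation over-representation reuses the exact hypergeometric", {
  bg <- sprintf("bg%02d", 1:20)
  edges <- tibble::tibble(node_a = bg[c(1, 2, 3, 4, 6)],
                          node_b = bg[c(2, 3, 4, 5, 5)], confidence = 0.99)
  tissue <- tibble::tibble(node = bg, score = 5)
  early <- build_stage_network(bg[1:6], edges, tissue, "early")
  un <- merge_stage_networks(early, polyqnet:::empty_stage_network("middle"),
                             polyqnet:::empty_stage_network("late"))
  # network has 6 nodes, 5 of which are flagged: same 15/38760 configuration
  res <- annotation_overrepresentation(un, bg[1:5], bg)
  expect_equal(res$k, 5)
  expect_equal(res$p_value, 15 / 38760, tolerance = 1e-14)
  expect_error(annotation_overrepresentation(un, c("zz"), bg), "subset")
})
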