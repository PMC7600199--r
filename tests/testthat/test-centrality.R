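graph_of <- function(edges) {
  polyqnet:::graph_from_edges(
    tibble::tibble(node_a = edges[, 1], node_b = edges[, 2], confidence = 1))
}

test_that("worked path and star examples reproduce exactly", {
  p4 <- graph_of(cbind(c("a", "b", "c"), c("b", "c", "d")))
  cent <- centralities(p4)
  expect_equal(cent$dc[match(c("a", "b", "c", "d"), cent$node)], c(1, 2, 2, 1))
  expect_equal(cent$bc[cent$node == "b"], 2)          # pairs {a,c}, {a,d}
  expect_equal(cent$farness[cent$node == "a"], 6)     # 1 + 2 + 3
  expect_equal(cent$cc[cent$node == "a"], 0.5)        # 3 / 6

  star <- graph_of(cbind("hub", c("l1", "l2", "l3")))
  cent_s <- centralities(star)
  expect_equal(cent_s$dc[cent_s$node == "hub"], 3)
  expect_equal(cent_s$bc[cent_s$node == "hub"], 3)
  expect_equal(cent_s$cc[cent_s$node == "hub"], 1)
  expect_true(all(cent_s$bc[cent_s$node != "hub"] == 0))

  edge <- graph_of(cbind("x", "y"))
  cent_e <- centralities(edge)
  expect_equal(cent_e$dc, c(1, 1))
  expect_equal(cent_e$bc, c(0, 0))
  expect_equal(cent_e$cc, c(1, 1))
})

test_that("betweenness and closeness match the brute-force oracle", {
  set.seed(53)
  for (i in 1:100) {
    g <- random_named_graph(sample(4:8, 1), runif(1, 0.2, 0.8))
    cent <- centralities(g)
    ref <- oracle_centralities(g)
    idx <- match(ref$node, cent$node)
    expect_equal(cent$bc[idx], ref$bc, tolerance = 1e-9)
    expect_equal(cent$farness[idx], ref$farness, tolerance = 1e-9)
    expect_equal(cent$cc[idx], ref$cc, tolerance = 1e-9)
    # conservation: summed BC equals total intermediate incidences only when
    # every pair has a unique shortest path; in general it equals the summed
    # per-pair dependency, which the oracle accumulates identically
    expect_equal(sum(cent$bc), sum(ref$bc), tolerance = 1e-9)
  }
})

test_that("edge confidences never leak into the unweighted centralities", {
  edges <- tibble::tibble(node_a = c("a", "b", "a"), node_b = c("b", "c", "c"),
                          confidence = c(0.95, 0.99, 0.96))
  g <- polyqnet:::graph_from_edges(edges)
  cent <- centralities(g)
  expect_equal(cent$bc, c(0, 0, 0))   # triangle: no intermediates
  expect_equal(cent$cc, c(1, 1, 1))
})

test_that("min-max scaling maps constants to 0.5 per metric and stage", {
  tab <- tibble::tibble(node = c("a", "b", "c"), stage = "early",
                        dc = c(0, 5, 10), bc = c(2, 2, 2), cc = c(NA, 1, 2),
                        farness = 0)
  scaled <- scale_for_heatmap(tab)
  expect_equal(scaled$scaled_dc, c(0, 0.5, 1))
  expect_equal(scaled$scaled_bc, c(0.5, 0.5, 0.5))
  expect_equal(scaled$scaled_cc, c(NA, 0, 1))
  single <- scale_for_heatmap(tibble::tibble(node = "a", stage = "late",
                                             dc = 4, bc = 1, cc = 0.3,
                                             farness = 1))
  expect_equal(single$scaled_dc, 0.5)
})

test_that("top_nodes ranks by value with alphabetical tie-breaks", {
  tab <- scale_for_heatmap(tibble::tibble(
    node = c("zed", "abe", "mid"), stage = "early",
    dc = c(5, 5, 1), bc = 0, cc = 1, farness = 1))
  top <- top_nodes(tab, "dc", "early", k = 2)
  expect_equal(top$node, c("abe", "zed"))
  all_of_them <- top_nodes(tab, "dc", "early", k = 10)
  expect_equal(nrow(all_of_them), 3)
  expect_error(top_nodes(tab, "dc", "early", k = 0), "k")
})

test_that("trajectories classify by the late-minus-early scaled change", {
  tab <- tibble::tibble(
    node = rep(c("up", "down", "flat", "partial"), each = 3),
    stage = rep(c("early", "middle", "late"), 4),
    dc = c(1, 5, 9,  9, 5, 1,  5, 5.2, 4.8,  0, 6, 3),
    bc = 0, cc = 0.5, farness = 1
  )[-12, ]   # drop "partial" at late
  scaled <- scale_for_heatmap(tab)
  calls <- classify_trajectories(scaled, tolerance = 0.1)
  dc_calls <- calls[calls$metric == "dc", ]
  expect_equal(dc_calls$classification[dc_calls$node == "up"], "increasing")
  expect_equal(dc_calls$classification[dc_calls$node == "down"], "decreasing")
  expect_equal(dc_calls$classification[dc_calls$node == "flat"], "stable")
  expect_equal(dc_calls$classification[dc_calls$node == "partial"],
               "absent-some-stages")
  expect_equal(dc_calls$trend[dc_calls$node == "partial"], "increasing")
})

test_that("planted dynamics are prioritized into the right categories", {
  nets <- planted_dynamics_networks()
  cent <- stage_centralities(nets$early, nets$middle, nets$late)
  calls <- classify_trajectories(cent, tolerance = 0.05)
  targets <- prioritize_targets(calls, cent, cc_quantile = 0.75)
  expect_true("H" %in% targets$node[targets$category == "inhibition"])
  expect_true("X" %in% targets$node[targets$category == "stimulation"])
  persistent <- targets$node[targets$category == "persistent-high-cc"]
  expect_true(all(c("k1", "k2", "k3") %in% persistent))
  # the fading broker never looks like an inhibition target
  expect_false("X" %in% targets$node[targets$category == "inhibition"])
})
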