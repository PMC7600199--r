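letters_bg <- function(N) sprintf("bg%02d", seq_len(N))

one_set_collection <- function(members, id = "S1") {
  tibble::tibble(set_id = id, name = id, genes = list(members))
}

test_that("hypergeometric p matches the hand-computed tail exactly", {
  # N = 20, K = 5, n = 6, k = 5: P(X >= 5) = 15 / 38760
  bg <- letters_bg(20)
  set <- bg[1:5]
  hits <- c(bg[1:5], bg[6])
  res <- enrich(hits, one_set_collection(set), bg)
  expect_equal(res$k, 5)
  expect_equal(res$K, 5)
  expect_equal(res$p_value, 15 / 38760, tolerance = 1e-14)

  # zero overlap is never significant; saturation gives p = 1
  expect_equal(enrich(bg[6:11], one_set_collection(bg[1:5]), bg)$p_value, 1)
  sat <- enrich(bg, one_set_collection(bg[1:5]), bg)
  expect_equal(sat$k, sat$K)
  expect_equal(sat$p_value, 1)
})

test_that("enrichment agrees with exhaustive list enumeration for N <= 12", {
  set.seed(31)
  for (i in 1:12) {
    N <- sample(5:12, 1)
    K <- sample(2:(N - 1), 1)
    n <- sample(2:(N - 1), 1)
    bg <- letters_bg(N)
    set <- bg[1:K]
    hits <- sample(bg, n)
    k <- length(intersect(hits, set))
    res <- enrich(hits, one_set_collection(set), bg)
    expect_equal(res$p_value, oracle_hyper_tail(N, K, n, k),
                 tolerance = 1e-12)
  }
})

test_that("p-values are monotonically non-increasing in the overlap", {
  bg <- letters_bg(30)
  set <- bg[1:10]
  ps <- vapply(0:8, function(k) {
    hits <- c(set[seq_len(k)], setdiff(bg, set)[seq_len(8 - k)])
    enrich(hits, one_set_collection(set), bg)$p_value
  }, numeric(1))
  expect_true(all(diff(ps) <= 1e-14))
})

test_that("pathway selection applies a strict alpha", {
  res <- tibble::tibble(set_id = c("A", "B", "C"), name = set_id,
                        k = 1, K = 1, n = 1, N = 2,
                        p_value = c(0.05, 0.049, 0.5))
  expect_equal(significant_pathways(res), "B")
  expect_equal(significant_pathways(res[0, ]), character())
})

test_that("common pathways intersect per matched stage and flag persistence", {
  mk_res <- function(df) {
    dplyr::mutate(df, name = set_id, k = 1, K = 1, n = 1, N = 2)
  }
  matching <- stage_matching(c("D2", "D5", "D10"), c("W5", "W12", "W28"))
  res_a <- mk_res(tidyr::expand_grid(
    time_point = c("D2", "D5", "D10"), set_id = c("P1", "P2", "P3"))) |>
    dplyr::mutate(p_value = dplyr::case_when(
      set_id == "P1" ~ 0.001,                      # significant everywhere
      set_id == "P2" & time_point == "D5" ~ 0.01,  # middle only
      TRUE ~ 0.9))
  res_b <- mk_res(tidyr::expand_grid(
    time_point = c("W5", "W12", "W28"), set_id = c("P1", "P2", "P3"))) |>
    dplyr::mutate(p_value = dplyr::case_when(
      set_id == "P1" ~ 0.002,
      set_id == "P2" & time_point == "W12" ~ 0.04,
      set_id == "P3" ~ 0.01,                       # significant in B only
      TRUE ~ 0.9))
  common <- common_pathways(res_a, res_b, matching)
  expect_setequal(common$set_id[common$stage == "early"], "P1")
  expect_setequal(common$set_id[common$stage == "middle"], c("P1", "P2"))
  expect_false("P3" %in% common$set_id)
  expect_true(all(common$persistent[common$set_id == "P1"]))
  expect_false(any(common$persistent[common$set_id == "P2"]))

  # disjoint significant sets: empty intersection at every stage
  res_b2 <- dplyr::mutate(res_b, p_value = ifelse(set_id == "P3", 0.01, 0.9))
  res_a2 <- dplyr::mutate(res_a, p_value = ifelse(set_id == "P1", 0.01, 0.9))
  expect_equal(nrow(common_pathways(res_a2, res_b2, matching)), 0)
})

test_that("direction concordance reproduces exact binomial sign tests", {
  mk_deg <- function(genes, l2fc) {
    tibble::tibble(gene = genes, time_point = "T1", log2fc = l2fc,
                   p_value = 0.001, is_deg = TRUE)
  }
  genes <- sprintf("g%02d", 1:10)
  a <- mk_deg(genes, rep(1, 10))
  b <- mk_deg(genes, c(rep(1, 9), -1))        # 9 of 10 concordant
  res <- direction_concordance(a, b)
  expect_equal(res$n_shared, 10)
  expect_equal(res$n_discordant, 1)
  expect_equal(res$p_value, 22 / 1024, tolerance = 1e-12)

  a2 <- mk_deg(c("x", "y"), c(1, 1))
  res2 <- direction_concordance(a2, a2)
  expect_equal(res2$n_up_both, 2)
  expect_equal(res2$p_value, 0.5, tolerance = 1e-12)

  none <- direction_concordance(mk_deg("x", 1), mk_deg("z", 1))
  expect_equal(none$n_shared, 0)
  expect_true(is.na(none$p_value))
})

test_that("a gene's model direction comes from its strongest DEG call", {
  a <- tibble::tibble(gene = "g", time_point = c("T1", "T2"),
                      log2fc = c(0.8, -2.5), p_value = 0.001, is_deg = TRUE)
  b <- tibble::tibble(gene = "g", time_point = "T1",
                      log2fc = -1, p_value = 0.001, is_deg = TRUE)
  res <- direction_concordance(a, b)
  expect_equal(res$n_down_both, 1)   # |−2.5| dominates the +0.8 call
})
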