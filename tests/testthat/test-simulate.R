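small_config <- function(...) {
  simulation_config(n_genes = 60, n_pathways = 3, genes_per_pathway = c(5, 8),
                    seed = 9, ...)
}

test_that("generators are bit-reproducible under a fixed seed", {
  cfg <- small_config()
  expect_identical(simulate_study_pair(cfg), simulate_study_pair(cfg))
  sets <- simulate_study_pair(cfg)$gene_sets
  expect_identical(simulate_interactome(cfg, sets),
                   simulate_interactome(cfg, sets))
  expect_identical(simulate_drug_tables(cfg, c("G0001", "G0002")),
                   simulate_drug_tables(cfg, c("G0001", "G0002")))
})

test_that("zero planted pathways means zero true signal everywhere", {
  cfg <- small_config(planted_pathways = tibble::tibble(
    pathway = character(), onset = character(), effect = numeric(),
    direction = character(), shared = logical()))
  sim <- simulate_study_pair(cfg)
  expect_true(all(sim$truth$true_log2fc$log2fc == 0))
})

test_that("a shared early-onset pathway is perturbed at all later stages in both models", {
  cfg <- small_config(planted_pathways = tibble::tibble(
    pathway = "P01", onset = "early", effect = 1,
    direction = "up", shared = TRUE))
  sim <- simulate_study_pair(cfg)
  members <- sim$gene_sets$genes[[1]]
  fc <- sim$truth$true_log2fc
  for (model in c("cells", "mice")) {
    for (stage in c("early", "middle", "late")) {
      vals <- fc$log2fc[fc$model == model & fc$stage == stage &
                          fc$gene %in% members]
      expect_true(all(vals == 1))
    }
  }
  # everything outside the planted pathway stays flat
  expect_true(all(fc$log2fc[!fc$gene %in% members] == 0))
})

test_that("planted effects are recovered without bias at vanishing noise", {
  cfg <- simulation_config(n_genes = 30, n_pathways = 2,
                           genes_per_pathway = c(4, 6), noise_sd = 0.02,
                           planted_pathways = tibble::tibble(
                             pathway = "P01", onset = "early", effect = 1,
                             direction = "up", shared = TRUE),
                           seed = 1)
  reps <- 200
  means <- vapply(seq_len(reps), function(i) {
    cfg$seed <- i
    sim <- simulate_study_pair(cfg)
    members <- sim$gene_sets$genes[[1]]
    fc <- compute_fold_change(sim$cells, "D2", "D0", pseudocount = 0)
    mean(fc$log2fc[fc$gene %in% members])
  }, numeric(1))
  se <- sd(means) / sqrt(reps)
  expect_lt(abs(mean(means) - 1), 3 * se + 1e-3)
})

test_that("drawn effect signs follow frac_downregulated", {
  cfg <- simulation_config(n_genes = 400, n_pathways = 2,
                           genes_per_pathway = c(150, 180),
                           frac_downregulated = 0.7,
                           planted_pathways = tibble::tibble(
                             pathway = c("P01", "P02"), onset = "early",
                             effect = 1, direction = NA_character_,
                             shared = TRUE),
                           seed = 77)
  signs <- simulate_study_pair(cfg)$truth$effect_signs$sign
  n <- length(signs)
  phat <- mean(signs < 0)
  expect_lt(abs(phat - 0.7), 3 * sqrt(0.7 * 0.3 / n))
})

test_that("interactome respects edge probabilities and round-trips", {
  sets <- tibble::tibble(set_id = "P1", name = "p",
                         genes = list(c("G0001", "G0002", "G0003", "G0004")))
  none <- simulate_interactome(
    small_config(ppi_within_pathway_prob = 0, ppi_background_prob = 0), sets)
  expect_equal(nrow(none$edges), 0)

  full <- simulate_interactome(
    small_config(ppi_within_pathway_prob = 1, ppi_background_prob = 0), sets)
  expect_equal(nrow(full$edges), 6)   # all pairs of a 4-gene pathway

  path <- withr::local_tempfile(fileext = ".tsv")
  readr::write_tsv(full$edges, path)
  expect_equal(read_ppi_edges(path), full$edges)
  expect_error(simulate_interactome(small_config(), sets[0, ]), "empty")
})

test_that("interactome enriches confidence within pathways over background", {
  cfg <- simulation_config(n_genes = 120, n_pathways = 4,
                           genes_per_pathway = c(15, 20),
                           ppi_background_prob = 0.05, seed = 3)
  sim <- simulate_study_pair(cfg)
  inter <- simulate_interactome(cfg, sim$gene_sets,
                                genes = sim$cells$fpkm$gene)
  keys <- polyqnet:::pair_key(inter$edges$node_a, inter$edges$node_b)
  within <- keys %in% inter$truth$within_pathway_edges
  expect_gt(mean(inter$edges$confidence[within]),
            mean(inter$edges$confidence[!within]))
  expect_true(all(inter$tissue_scores$score >= 3 &
                    inter$tissue_scores$score <= 5))
})

test_that("drug generator honours planted BBB structure and empty requests", {
  cfg <- small_config(n_drugs = 12)
  sim <- simulate_drug_tables(cfg, targets = c("G0001", "G0002", "G0003"))
  counts <- dplyr::count(sim$bbb_calls, drug)
  expect_true(all(counts$n == 8))
  pos <- dplyr::count(dplyr::filter(sim$bbb_calls, call == "BBB+"), drug)
  full_pos <- pos$drug[pos$n == 8]
  expect_setequal(full_pos, sim$truth$permeable_drugs)

  nothing <- simulate_drug_tables(small_config(n_drugs = 0), character())
  expect_equal(nrow(nothing$drug_targets), 0)
  expect_equal(nrow(nothing$bbb_calls), 0)
})

test_that("configs validate their domains", {
  expect_error(simulation_config(n_genes = 0), "n_genes")
  expect_error(simulation_config(frac_downregulated = 1.2),
               "frac_downregulated")
  expect_error(small_config(planted_pathways = tibble::tibble(
    pathway = "P01", onset = "sometime", effect = 1,
    direction = NA_character_, shared = TRUE)), "onset")
  expect_error(small_config(planted_pathways = tibble::tibble(
    pathway = "P01", onset = "early", effect = Inf,
    direction = NA_character_, shared = TRUE)), "finite")
  expect_error(simulation_config(n_genes = 50, n_pathways = 10,
                                 genes_per_pathway = c(10, 20)), "Disjoint")
})
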