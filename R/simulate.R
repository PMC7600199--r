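#' Configuration for the synthetic two-model aggregation study
#'
#' Defines every parameter of the synthetic data emulating a matched pair of
#' polyQ-aggregation models: an in vitro cell model sampled at a single
#' baseline (`D0`) plus three aggregation time-points (`D2`, `D5`, `D10`)
#' and an in vivo mouse model sampled at three ages (`W5`, `W12`, `W28`),
#' each with its own age-matched control group. Pathway-level perturbations
#' are planted with a stage of onset and persist at all later stages, in
#' both models when `shared`. Per-gene effect signs are drawn once and reused
#' across models and stages; the majority are downregulated by default.
#'
#' @param n_genes Number of genes per model (default 600).
#' @param n_pathways Number of gene sets in the collection (default 10).
#' @param genes_per_pathway Integer range `c(min, max)` of set sizes
#'   (default `c(15, 25)`).
#' @param n_replicates Replicates per condition (default 3).
#' @param time_points Named cell-model time-points
#'   (`control`, `early`, `middle`, `late`).
#' @param mice_time_points Named mouse ages (`early`, `middle`, `late`).
#' @param planted_pathways Tibble with columns `pathway`, `onset`
#'   (`early`/`middle`/`late`), `effect` (|log2FC|, finite), `direction`
#'   (`"up"`, `"down"` or `NA` to draw per-gene signs), `shared` (logical:
#'   perturbed in both models). Default: three shared pathways with onsets
#'   early/middle/late and effect 1.
#' @param baseline_log_mean,baseline_log_sd Log2-scale mean and sd of the
#'   log-normal baseline FPKM distribution (defaults 3 and 1.5).
#' @param noise_sd Replicate noise sd on the log2 scale (default 0.2).
#' @param frac_downregulated Probability a drawn effect sign is negative
#'   (default 0.7 — most DEGs downregulated).
#' @param overlap_pathways Draw pathway memberships with replacement across
#'   pathways (default `FALSE`: disjoint modules, so planted signal is
#'   identifiable set by set).
#' @param ppi_within_pathway_prob,ppi_background_prob Edge probabilities for
#'   within-pathway and background protein pairs (defaults 0.35, 0.01).
#' @param confidence_within,confidence_background Uniform ranges for
#'   interaction confidence of within-pathway and background edges.
#' @param tissue_score_range Range of per-node tissue-expression scores.
#' @param frac_tissue_pass Fraction of nodes scoring at or above the 4.8
#'   nervous-system filter (default 0.9).
#' @param frac_one_to_one Fraction of genes with a unique ortholog mapping;
#'   the rest additionally map to a second target at low rank (default 0.9).
#' @param n_drugs Number of drugs in the drug-target table (default 16).
#' @param frac_bbb_positive Probability a drug is planted fully
#'   BBB-positive (default 0.25).
#' @param seed Integer seed; all generators are bit-reproducible under it.
#' @return A validated `simulation_config` list.
#' @export
simulation_config <- function(n_genes = 600,
                              n_pathways = 10,
                              genes_per_pathway = c(15, 25),
                              n_replicates = 3,
                              time_points = c(control = "D0", early = "D2",
                                              middle = "D5", late = "D10"),
                              mice_time_points = c(early = "W5",
                                                   middle = "W12",
                                                   late = "W28"),
                              planted_pathways = NULL,
                              baseline_log_mean = 3,
                              baseline_log_sd = 1.5,
                              noise_sd = 0.2,
                              frac_downregulated = 0.7,
                              overlap_pathways = FALSE,
                              ppi_within_pathway_prob = 0.35,
                              ppi_background_prob = 0.01,
                              confidence_within = c(0.95, 1),
                              confidence_background = c(0.5, 0.97),
                              tissue_score_range = c(3, 5),
                              frac_tissue_pass = 0.9,
                              frac_one_to_one = 0.9,
                              n_drugs = 16,
                              frac_bbb_positive = 0.25,
                              seed = 1L) {
  n_genes <- check_count(n_genes, "n_genes")
  n_pathways <- check_count(n_pathways, "n_pathways")
  n_replicates <- check_count(n_replicates, "n_replicates", min = 2L)
  n_drugs <- check_count(n_drugs, "n_drugs", min = 0L)
  if (length(genes_per_pathway) != 2L || genes_per_pathway[1] < 2 ||
      genes_per_pathway[2] < genes_per_pathway[1]) {
    abort("`genes_per_pathway` must be c(min, max) with 2 <= min <= max.")
  }
  if (!overlap_pathways && n_pathways * genes_per_pathway[2] > n_genes) {
    abort("Disjoint pathways need n_pathways * max(genes_per_pathway) <= n_genes.")
  }
  for (nm in c("noise_sd", "baseline_log_sd")) {
    check_scalar_number(get(nm), nm, min = 0)
  }
  for (nm in c("frac_downregulated", "ppi_within_pathway_prob",
               "ppi_background_prob", "frac_tissue_pass", "frac_one_to_one",
               "frac_bbb_positive")) {
    check_probability(get(nm), nm)
  }
  if (is.null(planted_pathways)) {
    k <- min(3L, n_pathways)
    planted_pathways <- tibble(
      pathway = sprintf("P%02d", seq_len(k)),
      onset = stage_levels()[seq_len(k)],
      effect = 1,
      direction = NA_character_,
      shared = TRUE
    )
  }
  planted_pathways <- as_tibble(planted_pathways)
  if (nrow(planted_pathways)) {
    if (!all(planted_pathways$onset %in% stage_levels())) {
      abort("Planted onset stages must be early, middle or late.")
    }
    if (any(!is.finite(planted_pathways$effect))) {
      abort("Planted effect sizes must be finite.")
    }
    if (!"direction" %in% names(planted_pathways)) {
      planted_pathways$direction <- NA_character_
    }
    if (!"shared" %in% names(planted_pathways)) {
      planted_pathways$shared <- TRUE
    }
  }
  structure(
    list(n_genes = n_genes, n_pathways = n_pathways,
         genes_per_pathway = as.integer(genes_per_pathway),
         n_replicates = n_replicates, time_points = time_points,
         mice_time_points = mice_time_points,
         planted_pathways = planted_pathways,
         baseline_log_mean = baseline_log_mean,
         baseline_log_sd = baseline_log_sd, noise_sd = noise_sd,
         frac_downregulated = frac_downregulated,
         overlap_pathways = overlap_pathways,
         ppi_within_pathway_prob = ppi_within_pathway_prob,
         ppi_background_prob = ppi_background_prob,
         confidence_within = confidence_within,
         confidence_background = confidence_background,
         tissue_score_range = tissue_score_range,
         frac_tissue_pass = frac_tissue_pass,
         frac_one_to_one = frac_one_to_one,
         n_drugs = n_drugs, frac_bbb_positive = frac_bbb_positive,
         seed = as.integer(seed)),
    class = "simulation_config"
  )
}

human_gene_ids <- function(n) sprintf("G%04d", seq_len(n))
mouse_gene_ids <- function(n) sprintf("g%04d", seq_len(n))

#' Simulate the matched cell-model / mouse-model study pair
#'
#' Generates the two FPKM expression studies, the gene-set collection, the
#' rank-scored ortholog map linking the mouse namespace to the human one, and
#' a ground-truth manifest. Baseline abundance is log-normal per gene (drawn
#' independently per model), replicate noise is additive Gaussian on the log2
#' scale, and every planted pathway perturbs its member genes from its onset
#' stage onward — in both models when `shared` — so unperturbed genes have
#' expected log2FC of exactly 0.
#'
#' @param config A [simulation_config()].
#' @return A `polyq_simulation` list: `cells` and `mice`
#'   ([expression_study()]s), `gene_sets`, `ortholog_map`, and `truth`
#'   (manifest with `true_log2fc`, `perturbed_pathways`, `effect_signs`).
#' @export
simulate_study_pair <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  with_seed(config$seed, {
    genes <- human_gene_ids(config$n_genes)
    m_genes <- mouse_gene_ids(config$n_genes)
    gene_sets <- draw_pathways(config, genes)
    plan <- config$planted_pathways
    bad <- setdiff(plan$pathway, gene_sets$set_id)
    if (length(bad)) {
      abort(sprintf("Planted pathway '%s' does not exist in the collection.",
                    bad[1]))
    }
    # one sign per perturbed gene, reused across models and stages
    effect_signs <- bind_rows(pmap(plan, function(pathway, onset, effect,
                                                  direction, shared, ...) {
      members <- gene_sets$genes[[match(pathway, gene_sets$set_id)]]
      s <- if (is.na(direction)) {
        ifelse(runif(length(members)) < config$frac_downregulated, -1, 1)
      } else if (direction == "down") {
        rep(-1, length(members))
      } else {
        rep(1, length(members))
      }
      tibble(pathway = pathway, gene = members, sign = s,
             effect = effect, onset = onset, shared = shared)
    }))
    truth_fc <- true_log2fc_table(config, genes, effect_signs)
    cells <- simulate_cells(config, genes, truth_fc)
    mice_truth <- filter(truth_fc, .data$model == "mice")
    mice <- simulate_mice(config, m_genes, genes, mice_truth)
    ortholog_map <- draw_ortholog_map(config, m_genes, genes)
    truth <- list(
      true_log2fc = truth_fc,
      perturbed_pathways = plan,
      effect_signs = effect_signs,
      planted_hubs = character()
    )
    structure(
      list(cells = cells, mice = mice, gene_sets = gene_sets,
           ortholog_map = ortholog_map, truth = truth, config = config),
      class = "polyq_simulation"
    )
  })
}

# Expected log2FC for every (model, gene, stage): planted effect from the
# onset stage onward, 0 elsewhere.
true_log2fc_table <- function(config, genes, effect_signs) {
  stages <- stage_levels()
  grids <- list(
    cells = tibble(model = "cells", stage = rep(stages, each = length(genes)),
                   gene = rep(genes, 3),
                   time_point = rep(unname(config$time_points[stages]),
                                    each = length(genes))),
    mice = tibble(model = "mice", stage = rep(stages, each = length(genes)),
                  gene = rep(genes, 3),
                  time_point = rep(unname(config$mice_time_points[stages]),
                                   each = length(genes)))
  )
  out <- bind_rows(grids)
  out$log2fc <- 0
  if (nrow(effect_signs)) {
    stage_idx <- setNames(1:3, stages)
    for (r in seq_len(nrow(effect_signs))) {
      active <- stages[stage_idx >= stage_idx[[effect_signs$onset[r]]]]
      models <- if (isTRUE(effect_signs$shared[r])) c("cells", "mice") else "cells"
      hit <- out$gene == effect_signs$gene[r] & out$stage %in% active &
        out$model %in% models
      out$log2fc[hit] <- out$log2fc[hit] +
        effect_signs$sign[r] * effect_signs$effect[r]
    }
  }
  out
}

draw_pathways <- function(config, genes) {
  sizes <- sample(seq(config$genes_per_pathway[1], config$genes_per_pathway[2]),
                  config$n_pathways, replace = TRUE)
  ids <- sprintf("P%02d", seq_len(config$n_pathways))
  if (config$overlap_pathways) {
    members <- map(sizes, function(s) sort(sample(genes, s)))
  } else {
    pool <- sample(genes, sum(sizes))
    stops <- cumsum(sizes)
    starts <- c(1, head(stops, -1) + 1)
    members <- map2(starts, stops, function(a, b) sort(pool[a:b]))
  }
  tibble(set_id = ids, name = paste("synthetic pathway", ids), genes = members)
}

simulate_cells <- function(config, genes, truth_fc) {
  stages <- stage_levels()
  tps <- config$time_points
  baseline <- rnorm(length(genes), config$baseline_log_mean,
                    config$baseline_log_sd)
  fc <- filter(truth_fc, .data$model == "cells")
  fc_mat <- matrix(0, nrow = length(genes), ncol = 3,
                   dimnames = list(genes, stages))
  for (s in stages) {
    v <- filter(fc, .data$stage == s)
    fc_mat[v$gene, s] <- v$log2fc
  }
  conds <- c(unname(tps["control"]), unname(tps[stages]))
  shift <- cbind(0, fc_mat)
  colnames(shift) <- conds
  build_fpkm_study(genes, baseline, shift, conds, config,
                   roles = c("control", rep("case", 3)),
                   tp_of = setNames(conds, conds),
                   contrasts = tibble(
                     stage = stages,
                     time_point = unname(tps[stages]),
                     case_condition = unname(tps[stages]),
                     control_condition = unname(tps["control"])),
                   model = "cells")
}

simulate_mice <- function(config, m_genes, genes, mice_truth) {
  stages <- stage_levels()
  tps <- config$mice_time_points
  baseline <- rnorm(length(m_genes), config$baseline_log_mean,
                    config$baseline_log_sd)
  fc_mat <- matrix(0, nrow = length(genes), ncol = 3,
                   dimnames = list(genes, stages))
  for (s in stages) {
    v <- filter(mice_truth, .data$stage == s)
    fc_mat[v$gene, s] <- v$log2fc
  }
  case_conds <- paste0(unname(tps[stages]), ".SCA1")
  ctrl_conds <- paste0(unname(tps[stages]), ".FVB")
  conds <- as.vector(rbind(case_conds, ctrl_conds))
  shift <- matrix(0, nrow = length(m_genes), ncol = length(conds),
                  dimnames = list(m_genes, conds))
  shift[, case_conds] <- fc_mat
  tp_of <- setNames(rep(unname(tps[stages]), each = 2), conds)
  build_fpkm_study(m_genes, baseline, shift, conds, config,
                   roles = rep(c("case", "control"), 3),
                   tp_of = tp_of,
                   contrasts = tibble(
                     stage = stages,
                     time_point = unname(tps[stages]),
                     case_condition = case_conds,
                     control_condition = ctrl_conds),
                   model = "mice")
}

build_fpkm_study <- function(genes, baseline, shift, conds, config, roles,
                             tp_of, contrasts, model) {
  n_rep <- config$n_replicates
  cols <- list(gene = genes)
  design <- list()
  for (j in seq_along(conds)) {
    for (r in seq_len(n_rep)) {
      sample_id <- sprintf("%s_%s_r%d", model, conds[j], r)
      noise <- rnorm(length(genes), 0, config$noise_sd)
      cols[[sample_id]] <- unname(2^(baseline + shift[, j] + noise))
      design[[sample_id]] <- tibble(sample = sample_id,
                                    condition = conds[j],
                                    time_point = unname(tp_of[conds[j]]),
                                    role = roles[j], replicate = r)
    }
  }
  expression_study(as_tibble(cols), bind_rows(design), contrasts,
                   model = model)
}

draw_ortholog_map <- function(config, m_genes, genes) {
  n <- length(genes)
  base <- tibble(source_id = m_genes, target_id = genes, rank_score = 3L)
  multi <- which(runif(n) >= config$frac_one_to_one)
  extra <- if (length(multi)) {
    tibble(
      source_id = m_genes[multi],
      target_id = genes[vapply(multi, function(i) {
        sample(setdiff(seq_len(n), i), 1)
      }, integer(1))],
      rank_score = 1L
    )
  } else {
    tibble(source_id = character(), target_id = character(),
           rank_score = integer())
  }
  arrange(bind_rows(base, extra), .data$source_id, .data$target_id)
}

#' Simulate the weighted interactome and tissue-expression scores
#'
#' Generates an undirected weighted PPI edge table over the gene universe:
#' pairs within a pathway interact with probability
#' `ppi_within_pathway_prob` and carry high confidence; background pairs
#' interact with probability `ppi_background_prob` at broadly lower
#' confidence. Every node receives a tissue-expression score, a fraction
#' `frac_tissue_pass` of them at or above the 4.8 nervous-system filter.
#'
#' @param config A [simulation_config()].
#' @param pathway_memberships Gene-set tibble (as from
#'   [simulate_study_pair()]'s `gene_sets`).
#' @param genes Gene universe; defaults to the union of pathway members.
#' @return List with `edges` (tibble `node_a`, `node_b`, `confidence`),
#'   `tissue_scores` (tibble `node`, `score`) and `truth` (per-edge
#'   within-pathway flags).
#' @export
simulate_interactome <- function(config, pathway_memberships, genes = NULL) {
  stopifnot(inherits(config, "simulation_config"))
  genes <- genes %||% sort(unique(unlist(pathway_memberships$genes)))
  if (!length(genes)) abort("Gene universe for the interactome is empty.")
  with_seed(config$seed + 1L, {
    idx <- seq_along(genes)
    within_keys <- character()
    edges_within <- map(pathway_memberships$genes, function(members) {
      members <- intersect(members, genes)
      if (length(members) < 2) return(NULL)
      pairs <- utils::combn(sort(members), 2)
      keep <- runif(ncol(pairs)) < config$ppi_within_pathway_prob
      if (!any(keep)) return(NULL)
      tibble(node_a = pairs[1, keep], node_b = pairs[2, keep])
    })
    ew <- bind_rows(edges_within)
    if (nrow(ew)) {
      ew <- distinct(ew, .data$node_a, .data$node_b)
      ew$confidence <- runif(nrow(ew), config$confidence_within[1],
                             config$confidence_within[2])
      within_keys <- pair_key(ew$node_a, ew$node_b)
    }
    # background pairs: everything not already drawn as a within-pathway edge
    n <- length(genes)
    eb <- tibble(node_a = character(), node_b = character(),
                 confidence = numeric())
    if (config$ppi_background_prob > 0 && n >= 2) {
      n_pairs <- n * (n - 1) / 2
      n_bg <- rbinom(1, n_pairs, config$ppi_background_prob)
      if (n_bg > 0) {
        picked <- sample(n_pairs, n_bg)
        ab <- pair_from_index(picked, n)
        eb <- tibble(node_a = genes[ab[, 1]], node_b = genes[ab[, 2]])
        eb <- filter(eb, !pair_key(.data$node_a, .data$node_b) %in% within_keys)
        eb$confidence <- runif(nrow(eb), config$confidence_background[1],
                               config$confidence_background[2])
      }
    }
    edges <- bind_rows(ew, eb) |>
      mutate(a = pmin(.data$node_a, .data$node_b),
             b = pmax(.data$node_a, .data$node_b)) |>
      select(node_a = "a", node_b = "b", "confidence") |>
      arrange(.data$node_a, .data$node_b)
    pass <- runif(n) < config$frac_tissue_pass
    score <- ifelse(pass,
                    runif(n, 4.8, config$tissue_score_range[2]),
                    runif(n, config$tissue_score_range[1], 4.8))
    list(
      edges = validate_ppi_edges(edges),
      tissue_scores = tibble(node = genes, score = score),
      truth = list(within_pathway_edges = within_keys)
    )
  })
}

# Map linear indices 1..n*(n-1)/2 to (i, j) pairs with i < j, row-major over i.
pair_from_index <- function(k, n) {
  i <- n - 1 - floor((sqrt(4 * n * (n - 1) - 8 * k + 1) - 1) / 2)
  base <- (i - 1) * n - i * (i - 1) / 2
  j <- i + (k - base)
  cbind(as.integer(i), as.integer(j))
}

#' Simulate the drug-target table and the BBB predictor call table
#'
#' Each drug interacts with one to three of the candidate target proteins at
#' a uniform interaction score, and receives exactly eight blood-brain-
#' barrier calls (2 algorithms x 4 fingerprints). Drugs planted as fully
#' BBB-positive get 8/8 `BBB+`; every other drug gets at least one `BBB-`.
#'
#' @param config A [simulation_config()].
#' @param targets Non-empty character vector of candidate target proteins.
#' @return List with `drug_targets` (tibble `drug`, `target`, `score`,
#'   `status`), `bbb_calls` (tibble `drug`, `algorithm`, `fingerprint`,
#'   `call`) and `truth` (the planted fully-positive drugs).
#' @export
simulate_drug_tables <- function(config, targets) {
  stopifnot(inherits(config, "simulation_config"))
  if (config$n_drugs > 0 && !length(targets)) {
    abort("Candidate target list is empty.")
  }
  with_seed(config$seed + 2L, {
    n <- config$n_drugs
    if (n == 0) {
      return(list(
        drug_targets = tibble(drug = character(), target = character(),
                              score = numeric(), status = character()),
        bbb_calls = tibble(drug = character(), algorithm = character(),
                           fingerprint = character(), call = character()),
        truth = list(permeable_drugs = character())
      ))
    }
    drugs <- sprintf("DRUG%02d", seq_len(n))
    dt <- bind_rows(map(drugs, function(d) {
      k <- sample(seq_len(min(3, length(targets))), 1)
      tibble(drug = d, target = sort(sample(targets, k)),
             score = runif(k, 0.3, 1),
             status = sample(c("approved", "investigational"), k,
                             replace = TRUE))
    }))
    permeable <- drugs[runif(n) < config$frac_bbb_positive]
    combos <- tidyr::expand_grid(algorithm = bbb_algorithms(),
                                 fingerprint = bbb_fingerprints())
    calls <- bind_rows(map(drugs, function(d) {
      call <- rep("BBB+", 8)
      if (!d %in% permeable) {
        n_neg <- sample(1:8, 1)
        call[sample(8, n_neg)] <- "BBB-"
      }
      mutate(combos, drug = d, call = call, .before = 1)
    }))
    list(drug_targets = dt, bbb_calls = calls,
         truth = list(permeable_drugs = permeable))
  })
}

#' Simulate every pipeline input at once
#'
#' Convenience wrapper running [simulate_study_pair()],
#' [simulate_interactome()] (over the full gene universe) and
#' [simulate_drug_tables()] (with the planted pathway genes as candidate
#' targets), merging their ground truths into one manifest.
#'
#' @param config A [simulation_config()].
#' @return A `polyq_simulation` list with all inputs and `truth`.
#' @export
simulate_all <- function(config) {
  sim <- simulate_study_pair(config)
  inter <- simulate_interactome(config, sim$gene_sets,
                                genes = sim$cells$fpkm$gene)
  candidates <- unique(sim$truth$effect_signs$gene)
  if (!length(candidates)) candidates <- sim$gene_sets$genes[[1]]
  drugs <- simulate_drug_tables(config, candidates)
  sim$ppi_edges <- inter$edges
  sim$tissue_scores <- inter$tissue_scores
  sim$drug_targets <- drugs$drug_targets
  sim$bbb_calls <- drugs$bbb_calls
  sim$truth$within_pathway_edges <- inter$truth$within_pathway_edges
  sim$truth$permeable_drugs <- drugs$truth$permeable_drugs
  sim
}

#' Write all simulated inputs to a directory of plain-text files
#'
#' Writes the expression matrices and designs, the GMT collection, the PPI
#' edge and tissue-score tables, the ortholog map, the drug tables and a
#' JSON ground-truth manifest.
#'
#' @param sim A `polyq_simulation` from [simulate_all()].
#' @param dir Output directory.
#' @return The directory, invisibly.
#' @export
write_simulation_inputs <- function(sim, dir) {
  stopifnot(inherits(sim, "polyq_simulation"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  write_expression(sim$cells, dir, "cells")
  write_expression(sim$mice, dir, "mice")
  write_gmt(sim$gene_sets, file.path(dir, "gene_sets.gmt"))
  readr::write_tsv(sim$ortholog_map, file.path(dir, "ortholog_map.tsv"))
  if (!is.null(sim$ppi_edges)) {
    readr::write_tsv(sim$ppi_edges, file.path(dir, "ppi_edges.tsv"))
    readr::write_tsv(sim$tissue_scores, file.path(dir, "tissue_scores.tsv"))
  }
  if (!is.null(sim$drug_targets)) {
    readr::write_tsv(sim$drug_targets, file.path(dir, "drug_targets.tsv"))
    readr::write_tsv(sim$bbb_calls, file.path(dir, "bbb_calls.tsv"))
  }
  manifest <- list(
    perturbed_pathways = sim$truth$perturbed_pathways,
    n_perturbed_genes = length(unique(sim$truth$effect_signs$gene)),
    permeable_drugs = sim$truth$permeable_drugs %||% character()
  )
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}
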