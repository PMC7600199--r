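#' Configuration of a full pipeline run
#'
#' Bundles a [simulation_config()] (or a directory of input files written in
#' the same layout as [write_simulation_inputs()]) with every analysis
#' threshold of the workflow.
#'
#' @param simulation A [simulation_config()], or `NULL` when `input_dir` is
#'   given.
#' @param input_dir Directory of input files (alternative to simulating).
#' @param fc_threshold,p_threshold DEG thresholds (strict; defaults 0.5, 0.05).
#' @param pseudocount Fold-change pseudocount (default 0.25).
#' @param test `"welch"` or `"student"`.
#' @param min_rank Minimum ortholog rank score (default 3).
#' @param alpha Pathway-selection level (strict; default 0.05).
#' @param edge_threshold,tissue_threshold Network filters (inclusive;
#'   defaults 0.950 and 4.8).
#' @param ensemble_size,swaps_per_edge Motif null-model settings (defaults
#'   1000 and 10).
#' @param tolerance Trajectory dead band on the scaled axis (default 0.05).
#' @param cc_quantile Persistent-high-CC quantile (default 0.9).
#' @param score_threshold Drug-interaction score threshold (default 0.5,
#'   inclusive).
#' @param seed Integer master seed for the run.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(simulation = simulation_config(),
                            input_dir = NULL,
                            fc_threshold = 0.5, p_threshold = 0.05,
                            pseudocount = 0.25,
                            test = c("welch", "student"),
                            min_rank = 3, alpha = 0.05,
                            edge_threshold = 0.950, tissue_threshold = 4.8,
                            ensemble_size = 1000, swaps_per_edge = 10,
                            tolerance = 0.05, cc_quantile = 0.9,
                            score_threshold = 0.5, seed = 1L) {
  test <- match.arg(test)
  if (is.null(simulation) && is.null(input_dir)) {
    abort("Provide either a simulation config or an input directory.")
  }
  check_probability(p_threshold, "p_threshold")
  check_probability(alpha, "alpha")
  check_probability(score_threshold, "score_threshold")
  check_scalar_number(edge_threshold, "edge_threshold", min = 0, max = 1)
  check_scalar_number(tissue_threshold, "tissue_threshold", min = 0)
  structure(
    list(simulation = simulation, input_dir = input_dir,
         fc_threshold = fc_threshold, p_threshold = p_threshold,
         pseudocount = pseudocount, test = test, min_rank = min_rank,
         alpha = alpha, edge_threshold = edge_threshold,
         tissue_threshold = tissue_threshold,
         ensemble_size = as.integer(ensemble_size),
         swaps_per_edge = swaps_per_edge, tolerance = tolerance,
         cc_quantile = cc_quantile, score_threshold = score_threshold,
         seed = as.integer(seed)),
    class = "pipeline_config"
  )
}

#' Load a pipeline configuration from a YAML file
#'
#' Top-level keys mirror the arguments of [pipeline_config()]; a `simulation`
#' block mirrors [simulation_config()].
#'
#' @param path YAML file.
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  raw <- yaml::read_yaml(path)
  sim <- NULL
  if (!is.null(raw$simulation)) {
    sim <- do.call(simulation_config, raw$simulation)
  }
  raw$simulation <- NULL
  do.call(pipeline_config, c(list(simulation = sim), raw))
}

#' Run the complete cross-model aggregation analysis
#'
#' Executes the whole workflow: obtain inputs (simulate or read), call DEGs
#' per stage in both models, map the mouse table into the human namespace,
#' run per-time-point pathway over-representation in both models, intersect
#' significant pathways at matched stages, build the three filtered stage
#' networks and their union, score 4-node motifs against the degree-
#' preserving null, compute centrality dynamics, classify trajectories and
#' prioritize targets, overlay drugs on the prioritized targets and apply
#' the 8/8 BBB consensus. With `out_dir` set, every intermediate table,
#' network and the JSON run report are written to disk. Identical config and
#' seed give byte-identical reports.
#'
#' @param config A [pipeline_config()].
#' @param out_dir Optional output directory.
#' @return A `polyq_report` list with every intermediate result and a
#'   `summary` block of headline counts.
#' @export
run_pipeline <- function(config, out_dir = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  step <- function(name, code) {
    tryCatch(force(code), error = function(e) {
      abort(sprintf("Pipeline stage '%s' failed: %s", name,
                    conditionMessage(e)))
    })
  }

  sim <- step("inputs", {
    if (!is.null(config$input_dir)) {
      read_pipeline_inputs(config$input_dir)
    } else {
      cfg <- config$simulation
      cfg$seed <- config$seed
      simulate_all(cfg)
    }
  })
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    if (inherits(sim, "polyq_simulation")) {
      write_simulation_inputs(sim, file.path(out_dir, "inputs"))
    }
  }

  deg_cells <- step("deg_cells", deg_table(
    sim$cells, fc_threshold = config$fc_threshold,
    p_threshold = config$p_threshold, pseudocount = config$pseudocount,
    test = config$test))
  deg_mice_raw <- step("deg_mice", deg_table(
    sim$mice, fc_threshold = config$fc_threshold,
    p_threshold = config$p_threshold, pseudocount = config$pseudocount,
    test = config$test))
  deg_mice <- step("ortholog_mapping", suppressMessages(
    map_to_target_namespace(deg_mice_raw, sim$ortholog_map,
                            min_rank = config$min_rank)))

  matching <- stage_matching(sim$cells$contrasts$time_point,
                             sim$mice$contrasts$time_point)

  enrich_model <- function(deg, genes) {
    background <- intersect(genes, unique(unlist(sim$gene_sets$genes)))
    bind_rows(map(unique(deg$time_point), function(tp) {
      ids <- deg$gene[deg$time_point == tp & deg$is_deg]
      suppressMessages(enrich(ids, sim$gene_sets, background)) |>
        mutate(time_point = tp, .before = 1)
    }))
  }
  enr_cells <- step("enrichment_cells",
                    enrich_model(deg_cells, sim$cells$fpkm$gene))
  enr_mice <- step("enrichment_mice",
                   enrich_model(deg_mice, unique(deg_mice$gene)))
  common <- step("common_pathways",
                 common_pathways(enr_cells, enr_mice, matching,
                                 alpha = config$alpha))
  concordance <- step("direction_concordance",
                      direction_concordance(deg_cells, deg_mice))

  networks <- step("stage_networks", {
    lapply(setNames(stage_levels(), stage_levels()), function(s) {
      ids <- common$set_id[common$stage == s]
      members <- unique(unlist(
        sim$gene_sets$genes[sim$gene_sets$set_id %in% ids]))
      if (!length(members)) {
        empty_stage_network(s, config$edge_threshold, config$tissue_threshold)
      } else {
        build_stage_network(members, sim$ppi_edges, sim$tissue_scores,
                            stage = s,
                            edge_threshold = config$edge_threshold,
                            tissue_threshold = config$tissue_threshold)
      }
    })
  })
  union_net <- step("union_network",
                    merge_stage_networks(networks$early, networks$middle,
                                         networks$late))

  motif_seed <- config$seed + 100L
  motifs <- step("motifs", {
    graphs <- c(lapply(networks, as_igraph), list(union = union_net$graph))
    imap(graphs, function(g, nm) {
      if (igraph::ecount(g) < 2L) {
        return(NULL)
      }
      motif_zscores(g, ensemble_size = config$ensemble_size,
                    n_swaps = config$swaps_per_edge * igraph::ecount(g),
                    seed = motif_seed + match(nm, c(stage_levels(), "union")))
    })
  })

  cent <- step("centralities",
               stage_centralities(networks$early, networks$middle,
                                  networks$late))
  calls <- step("trajectories",
                classify_trajectories(cent, tolerance = config$tolerance))
  targets <- step("prioritization",
                  prioritize_targets(calls, cent,
                                     cc_quantile = config$cc_quantile))

  overlay <- NULL
  verdicts <- tibble(drug = character(), n_calls = integer(),
                     n_positive = integer(), verdict = character())
  if (nrow(targets) && !is.null(sim$drug_targets) &&
      nrow(sim$drug_targets)) {
    overlay <- step("drug_overlay",
                    build_overlay(unique(targets$node), sim$drug_targets,
                                  score_threshold = config$score_threshold))
    if (length(overlay$drugs)) {
      verdicts <- step("bbb_consensus",
                       bbb_consensus(overlay, sim$bbb_calls))
    }
  }

  summary <- list(
    version = as.character(utils::packageVersion("polyqnet")),
    seed = config$seed,
    deg_counts = list(
      cells = setNames(as.list(
        vapply(stage_levels(), function(s) {
          sum(deg_cells$is_deg[deg_cells$stage == s])
        }, numeric(1))), stage_levels()),
      mice = setNames(as.list(
        vapply(stage_levels(), function(s) {
          sum(deg_mice$is_deg[deg_mice$stage == s])
        }, numeric(1))), stage_levels())
    ),
    common_pathways = lapply(setNames(stage_levels(), stage_levels()),
                             function(s) common$set_id[common$stage == s]),
    persistent_pathways = sort(unique(common$set_id[common$persistent])),
    concordance = as.list(concordance),
    network_sizes = lapply(networks, function(nw) {
      list(nodes = igraph::vcount(nw$graph), edges = igraph::ecount(nw$graph))
    }),
    union_size = list(nodes = igraph::vcount(union_net$graph),
                      edges = igraph::ecount(union_net$graph)),
    union_groups = as.list(table(union_net$membership$group)),
    motif_aggregate_z = lapply(motifs, function(m) {
      if (is.null(m)) NA else attr(m, "aggregate_z")
    }),
    prioritized = lapply(split(targets$node, targets$category), sort),
    n_permeable = sum(verdicts$verdict == "permeable"),
    permeable_drugs = sort(verdicts$drug[verdicts$verdict == "permeable"])
  )

  report <- structure(
    list(config = config, truth = sim$truth,
         deg_cells = deg_cells, deg_mice = deg_mice,
         enrichment = list(cells = enr_cells, mice = enr_mice),
         matching = matching, common_pathways = common,
         concordance = concordance, networks = networks,
         union_network = union_net, motifs = motifs,
         centralities = cent, trajectories = calls, targets = targets,
         drug_overlay = overlay, bbb_verdicts = verdicts,
         summary = summary),
    class = "polyq_report"
  )

  if (!is.null(out_dir)) write_report(report, out_dir)
  report
}

# Read a full input bundle from a directory laid out like
# write_simulation_inputs(); ground truth is unavailable in this mode.
read_pipeline_inputs <- function(dir) {
  sim <- list(
    cells = read_expression(dir, "cells"),
    mice = read_expression(dir, "mice"),
    gene_sets = read_gmt(file.path(dir, "gene_sets.gmt")),
    ortholog_map = read_ortholog_map(file.path(dir, "ortholog_map.tsv")),
    ppi_edges = read_ppi_edges(file.path(dir, "ppi_edges.tsv")),
    tissue_scores = read_tissue_scores(file.path(dir, "tissue_scores.tsv")),
    truth = NULL
  )
  dt_path <- file.path(dir, "drug_targets.tsv")
  if (file.exists(dt_path)) {
    sim$drug_targets <- readr::read_tsv(dt_path, show_col_types = FALSE)
    sim$bbb_calls <- readr::read_tsv(file.path(dir, "bbb_calls.tsv"),
                                     show_col_types = FALSE)
  }
  sim
}

write_report <- function(report, out_dir) {
  write_deg_table(report$deg_cells, file.path(out_dir, "deg_cells.tsv"))
  write_deg_table(report$deg_mice, file.path(out_dir, "deg_mice.tsv"))
  for (m in c("cells", "mice")) {
    readr::write_tsv(
      report$enrichment[[m]] |>
        mutate(overlap = map_chr(.data$overlap, paste, collapse = ",")),
      file.path(out_dir, sprintf("enrichment_%s.tsv", m)))
  }
  readr::write_tsv(report$common_pathways,
                   file.path(out_dir, "common_pathways.tsv"))
  for (s in stage_levels()) {
    write_network(report$networks[[s]],
                  file.path(out_dir, sprintf("network_%s.tsv", s)),
                  format = "edgelist")
  }
  write_network(report$union_network,
                file.path(out_dir, "union_network.graphml"),
                format = "graphml")
  readr::write_tsv(stage_membership(report$union_network),
                   file.path(out_dir, "stage_membership.tsv"))
  readr::write_tsv(as_tibble(report$centralities),
                   file.path(out_dir, "centralities.tsv"))
  readr::write_tsv(report$trajectories,
                   file.path(out_dir, "trajectories.tsv"))
  readr::write_tsv(as_tibble(report$targets),
                   file.path(out_dir, "targets.tsv"))
  if (!is.null(report$drug_overlay)) {
    readr::write_tsv(report$drug_overlay$edges,
                     file.path(out_dir, "drug_overlay.tsv"))
  }
  write_bbb_verdicts(report$bbb_verdicts,
                     file.path(out_dir, "bbb_verdicts.tsv"))
  jsonlite::write_json(report$summary, file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(out_dir)
}

#' @export
print.polyq_report <- function(x, ...) {
  s <- x$summary
  cat("<polyq_report>\n")
  cat(sprintf("  DEGs (cells): %s | DEGs (mice): %s\n",
              paste(unlist(s$deg_counts$cells), collapse = "/"),
              paste(unlist(s$deg_counts$mice), collapse = "/")))
  cat(sprintf("  common pathways per stage: %s\n",
              paste(lengths(s$common_pathways), collapse = "/")))
  cat(sprintf("  union network: %d nodes, %d edges\n",
              s$union_size$nodes, s$union_size$edges))
  cat(sprintf("  permeable drugs: %d\n", s$n_permeable))
  invisible(x)
}

#' @exportS3Method generics::glance
glance.polyq_report <- function(x, ...) {
  s <- x$summary
  tibble(
    n_deg_cells = sum(unlist(s$deg_counts$cells)),
    n_deg_mice = sum(unlist(s$deg_counts$mice)),
    n_shared_genes = s$concordance$n_shared,
    n_common_pathways = length(unique(unlist(s$common_pathways))),
    n_persistent_pathways = length(s$persistent_pathways),
    union_nodes = s$union_size$nodes,
    union_edges = s$union_size$edges,
    n_inhibition = length(s$prioritized[["inhibition"]]),
    n_stimulation = length(s$prioritized[["stimulation"]]),
    n_permeable_drugs = s$n_permeable
  )
}
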