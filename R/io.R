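#' Build an expression study from an FPKM table and a sample design
#'
#' An expression study bundles a gene-by-sample FPKM matrix (as a tibble whose
#' first column is `gene`), a sample design table, and the case-versus-control
#' contrasts that define the aggregation stages for one experimental model.
#'
#' @param fpkm Tibble or data frame. First column `gene` (unique character
#'   ids), remaining columns one per sample with non-negative FPKM values.
#' @param samples Tibble with columns `sample`, `condition`, `time_point`,
#'   `role` (`"case"` or `"control"`) and `replicate`. Every FPKM column must
#'   appear here and vice versa.
#' @param contrasts Tibble with columns `stage` (`early`/`middle`/`late`),
#'   `time_point`, `case_condition`, `control_condition`, ordered by stage.
#' @param model Character label for the model (e.g. `"cells"`, `"mice"`).
#'
#' @return An object of class `expression_study`.
#' @export
expression_study <- function(fpkm, samples, contrasts, model = "model") {
  fpkm <- as_tibble(fpkm)
  samples <- as_tibble(samples)
  contrasts <- as_tibble(contrasts)
  if (names(fpkm)[1] != "gene") {
    abort("First column of `fpkm` must be named 'gene'.")
  }
  if (anyDuplicated(fpkm$gene)) {
    dup <- fpkm$gene[duplicated(fpkm$gene)][1]
    abort(sprintf("Duplicate gene id in expression matrix: '%s'.", dup))
  }
  need <- c("sample", "condition", "time_point", "role", "replicate")
  missing_cols <- setdiff(need, names(samples))
  if (length(missing_cols)) {
    abort(paste0("Sample design lacks column(s): ",
                 paste(missing_cols, collapse = ", "), "."))
  }
  mat_samples <- names(fpkm)[-1]
  extra <- setdiff(mat_samples, samples$sample)
  if (length(extra)) {
    abort(sprintf("Matrix sample '%s' is absent from the sample design.", extra[1]))
  }
  orphan <- setdiff(samples$sample, mat_samples)
  if (length(orphan)) {
    abort(sprintf("Design sample '%s' is missing from the matrix.", orphan[1]))
  }
  for (s in mat_samples) {
    v <- fpkm[[s]]
    if (!is.numeric(v)) {
      abort(sprintf("FPKM column '%s' is not numeric.", s))
    }
    bad <- which(!is.finite(v) | v < 0)
    if (length(bad)) {
      abort(sprintf("Negative or non-finite FPKM for gene '%s' in sample '%s'.",
                    fpkm$gene[bad[1]], s))
    }
  }
  need_c <- c("stage", "time_point", "case_condition", "control_condition")
  if (!all(need_c %in% names(contrasts))) {
    abort("`contrasts` needs columns stage, time_point, case_condition, control_condition.")
  }
  known <- unique(samples$condition)
  bad_cond <- setdiff(c(contrasts$case_condition, contrasts$control_condition), known)
  if (length(bad_cond)) {
    abort(sprintf("Contrast condition '%s' is absent from the sample design.", bad_cond[1]))
  }
  structure(
    list(fpkm = fpkm, samples = samples, contrasts = contrasts,
         model = as.character(model)),
    class = "expression_study"
  )
}

#' @export
print.expression_study <- function(x, ...) {
  cat(sprintf("<expression_study '%s'>: %d genes x %d samples, %d contrasts\n",
              x$model, nrow(x$fpkm), ncol(x$fpkm) - 1L, nrow(x$contrasts)))
  invisible(x)
}

#' Write / read an expression study as three TSV files
#'
#' `write_expression()` writes `<prefix>_fpkm.tsv`, `<prefix>_samples.tsv`
#' and `<prefix>_contrasts.tsv` into `dir`; `read_expression()` reconstructs
#' the study, re-running all validation. The pair is a round-trip identity.
#'
#' @param study An `expression_study`.
#' @param dir Directory (created if needed).
#' @param prefix File-name prefix; defaults to the study's model label.
#' @return `write_expression()` returns the paths invisibly;
#'   `read_expression()` returns an `expression_study`.
#' @export
write_expression <- function(study, dir, prefix = study$model) {
  stopifnot(inherits(study, "expression_study"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- file.path(dir, paste0(prefix, c("_fpkm.tsv", "_samples.tsv", "_contrasts.tsv")))
  readr::write_tsv(study$fpkm, paths[1])
  readr::write_tsv(study$samples, paths[2])
  readr::write_tsv(study$contrasts, paths[3])
  invisible(paths)
}

#' @rdname write_expression
#' @param model Model label for the reconstructed study.
#' @export
read_expression <- function(dir, prefix, model = prefix) {
  paths <- file.path(dir, paste0(prefix, c("_fpkm.tsv", "_samples.tsv", "_contrasts.tsv")))
  for (p in paths) {
    if (!file.exists(p)) abort(sprintf("Expected file '%s' not found.", p))
  }
  fpkm <- readr::read_tsv(paths[1], show_col_types = FALSE,
                          col_types = readr::cols(gene = "c", .default = "d"))
  samples <- readr::read_tsv(paths[2], show_col_types = FALSE,
                             col_types = readr::cols(replicate = "i", .default = "c"))
  contrasts <- readr::read_tsv(paths[3], show_col_types = FALSE,
                               col_types = readr::cols(.default = "c"))
  expression_study(fpkm, samples, contrasts, model = model)
}

#' Read and write gene-set collections in GMT format
#'
#' GMT is the conventional tab-separated gene-set exchange format: one set per
#' line as `set_id<TAB>description<TAB>member1<TAB>member2...`. Members
#' duplicated within a line are dropped with a warning.
#'
#' @param path File path.
#' @return A tibble with columns `set_id`, `name` and a list-column `genes`.
#' @export
read_gmt <- function(path) {
  if (!file.exists(path)) abort(sprintf("GMT file '%s' not found.", path))
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) {
    warn("GMT file is empty; returning an empty collection.")
    return(tibble(set_id = character(), name = character(), genes = list()))
  }
  parsed <- map(lines, function(l) strsplit(l, "\t", fixed = TRUE)[[1]])
  short <- which(lengths(parsed) < 3L)
  if (length(short)) {
    abort(sprintf("GMT line %d has fewer than 3 fields.", short[1]))
  }
  sets <- map(parsed, function(f) {
    members <- f[-(1:2)]
    members <- members[nzchar(members)]
    if (anyDuplicated(members)) {
      warn(sprintf("Duplicated member(s) in set '%s'; deduplicated.", f[1]))
      members <- unique(members)
    }
    if (!length(members)) abort(sprintf("Gene set '%s' has no members.", f[1]))
    list(set_id = f[1], name = f[2], genes = members)
  })
  tibble(
    set_id = map_chr(sets, "set_id"),
    name = map_chr(sets, "name"),
    genes = map(sets, "genes")
  )
}

#' @rdname read_gmt
#' @param collection A gene-set tibble as returned by [read_gmt()].
#' @export
write_gmt <- function(collection, path) {
  lines <- pmap(collection[c("set_id", "name", "genes")], function(set_id, name, genes) {
    paste(c(set_id, name, genes), collapse = "\t")
  })
  writeLines(unlist(lines), path)
  invisible(path)
}

#' Read a PPI edge table or a per-node tissue-expression score table
#'
#' The edge table is TSV with columns `node_a`, `node_b`, `confidence`
#' (confidence in `[0, 1]`, no self-loops, unordered pairs unique); the tissue
#' table is TSV with columns `node`, `score` (non-negative).
#'
#' @param path File path.
#' @return A validated tibble.
#' @export
read_ppi_edges <- function(path) {
  edges <- readr::read_tsv(path, show_col_types = FALSE,
                           col_types = readr::cols(node_a = "c", node_b = "c",
                                                   confidence = "d"))
  validate_ppi_edges(edges)
}

#' @rdname read_ppi_edges
#' @export
read_tissue_scores <- function(path) {
  ts <- readr::read_tsv(path, show_col_types = FALSE,
                        col_types = readr::cols(node = "c", score = "d"))
  if (any(!is.finite(ts$score) | ts$score < 0)) {
    abort("Tissue scores must be non-negative and finite.")
  }
  if (anyDuplicated(ts$node)) abort("Duplicate node in tissue-score table.")
  ts
}

validate_ppi_edges <- function(edges) {
  edges <- as_tibble(edges)
  need <- c("node_a", "node_b", "confidence")
  if (!all(need %in% names(edges))) {
    abort("PPI edge table needs columns node_a, node_b, confidence.")
  }
  if (any(edges$node_a == edges$node_b)) {
    abort("PPI edge table contains a self-loop.")
  }
  if (any(edges$confidence < 0 | edges$confidence > 1 | !is.finite(edges$confidence))) {
    abort("Edge confidence must lie in [0, 1].")
  }
  if (anyDuplicated(pair_key(edges$node_a, edges$node_b))) {
    abort("Duplicate unordered node pair in PPI edge table.")
  }
  edges
}

#' Serialize a network to edge-list TSV, GraphML or SIF
#'
#' Accepts an igraph, a `stage_network` or a `union_network`; node attributes
#' present on the graph (stage membership, group, centralities) are carried
#' into GraphML. The edge-list TSV has columns `node_a`, `node_b`,
#' `confidence`; SIF uses the `pp` interaction type.
#'
#' @param graph Graph to write.
#' @param path Output file.
#' @param format One of `"edgelist"`, `"graphml"`, `"sif"`.
#' @return `path`, invisibly.
#' @export
write_network <- function(graph, path, format = c("edgelist", "graphml", "sif")) {
  format <- match.arg(format)
  g <- as_igraph(graph)
  if (format == "graphml") {
    igraph::write_graph(g, path, format = "graphml")
    return(invisible(path))
  }
  el <- igraph::as_edgelist(g)
  conf <- igraph::edge_attr(g, "confidence") %||% rep(NA_real_, nrow(el))
  if (format == "edgelist") {
    readr::write_tsv(
      tibble(node_a = el[, 1], node_b = el[, 2], confidence = conf),
      path
    )
  } else {
    lines <- if (nrow(el)) paste(el[, 1], "pp", el[, 2], sep = "\t") else character()
    # SIF also lists orphan nodes (a bare name per line), so empty graphs and
    # isolated vertices stay representable
    lonely <- setdiff(igraph::V(g)$name, c(el[, 1], el[, 2]))
    writeLines(c(lines, lonely), path)
  }
  invisible(path)
}

#' @rdname write_network
#' @export
read_network_edgelist <- function(path) {
  edges <- readr::read_tsv(path, show_col_types = FALSE,
                           col_types = readr::cols(node_a = "c", node_b = "c",
                                                   confidence = "d"))
  graph_from_edges(edges)
}

# Coerce the package's graph wrappers down to a plain igraph.
as_igraph <- function(x) {
  if (igraph::is_igraph(x)) return(x)
  if (inherits(x, "stage_network") || inherits(x, "union_network")) return(x$graph)
  abort("Cannot interpret object as a graph.")
}

# Build an undirected simple igraph from a node_a/node_b/confidence tibble,
# with deterministic (sorted) vertex ordering.
graph_from_edges <- function(edges, nodes = NULL) {
  nodes <- sort(unique(c(nodes, edges$node_a, edges$node_b)))
  g <- igraph::make_empty_graph(n = length(nodes), directed = FALSE)
  g <- igraph::set_vertex_attr(g, "name", value = nodes)
  if (nrow(edges)) {
    idx <- rbind(match(edges$node_a, nodes), match(edges$node_b, nodes))
    g <- igraph::add_edges(g, as.vector(idx))
    g <- igraph::set_edge_attr(g, "confidence", value = edges$confidence)
  }
  g
}
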