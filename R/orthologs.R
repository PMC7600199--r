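#' Map a DEG table into an ortholog target namespace
#'
#' Translates gene identifiers of a DEG table (e.g. mouse symbols) into a
#' target namespace (e.g. human symbols) through a rank-scored ortholog table,
#' keeping only mappings at or above a minimum rank. Resolution is fully
#' deterministic:
#'
#' * a source gene with several admissible targets keeps the highest-rank
#'   mapping, ties broken by lexicographically smallest target id;
#' * several source genes landing on one target at the same time-point are
#'   collapsed to the source with the higher mapping rank, ties broken by
#'   lexicographically smallest source id; losers are counted and reported;
#' * genes with no admissible mapping are dropped and counted.
#'
#' @param deg A [deg_table()] (or any tibble with a `gene` column).
#' @param map Tibble with columns `source_id`, `target_id`, `rank_score`
#'   (integer >= 0, no duplicated source/target pairs).
#' @param min_rank Minimum accepted rank score (default 3, the top rank class
#'   of the generated maps).
#' @return The input table with `gene` rewritten to target ids and an added
#'   `source_gene` column; mapping statistics are attached as attribute
#'   `mapping_stats`.
#' @export
map_to_target_namespace <- function(deg, map, min_rank = 3) {
  map <- as_tibble(map)
  need <- c("source_id", "target_id", "rank_score")
  if (!all(need %in% names(map))) {
    abort("Ortholog map needs columns source_id, target_id, rank_score.")
  }
  if (!nrow(map)) abort("Ortholog map is empty.")
  if (anyDuplicated(map[, c("source_id", "target_id")])) {
    abort("Ortholog map contains a duplicated (source, target) pair.")
  }
  if (any(map$rank_score < 0)) abort("Rank scores must be non-negative.")

  admissible <- filter(map, .data$rank_score >= min_rank)
  # best target per source: highest rank, then lexicographic target id
  best <- admissible |>
    arrange(.data$source_id, desc(.data$rank_score), .data$target_id) |>
    distinct(.data$source_id, .keep_all = TRUE)

  tab <- as_tibble(deg)
  # re-mapping an already-mapped table overwrites its provenance column
  tab$source_gene <- NULL
  has_tp <- "time_point" %in% names(tab)
  n_in <- length(unique(tab$gene))
  mapped <- inner_join(tab, best, by = c(gene = "source_id"))
  n_unmapped <- n_in - length(unique(mapped$gene))
  if (n_unmapped > 0) {
    inform(sprintf("Dropped %d gene(s) with no ortholog at rank >= %s.",
                   n_unmapped, format(min_rank)))
  }
  mapped <- mapped |>
    rename(source_gene = "gene", gene = "target_id") |>
    select("gene", dplyr::everything())

  # collapse collisions on the target id (per time-point when present)
  keys <- if (has_tp) c("gene", "time_point") else "gene"
  resolved <- mapped |>
    arrange(across(dplyr::all_of(keys)), desc(.data$rank_score),
            .data$source_gene) |>
    distinct(across(dplyr::all_of(keys)), .keep_all = TRUE)
  n_collided <- nrow(mapped) - nrow(resolved)
  if (n_collided > 0) {
    inform(sprintf("Resolved %d many-to-one ortholog collision(s) by rank.",
                   n_collided))
  }
  resolved <- select(resolved, -"rank_score")
  out <- if (inherits(deg, "deg_table")) {
    new_deg_table(resolved, model = attr(deg, "model"),
                  fc_threshold = attr(deg, "fc_threshold"),
                  p_threshold = attr(deg, "p_threshold"),
                  pseudocount = attr(deg, "pseudocount"),
                  test = attr(deg, "test"))
  } else {
    resolved
  }
  attr(out, "mapping_stats") <- list(
    n_input_genes = n_in,
    n_unmapped = n_unmapped,
    n_collisions = n_collided
  )
  out
}

#' @rdname map_to_target_namespace
#' @param path TSV path with columns `source_id`, `target_id`, `rank_score`.
#' @export
read_ortholog_map <- function(path) {
  map <- readr::read_tsv(path, show_col_types = FALSE,
                         col_types = readr::cols(source_id = "c",
                                                 target_id = "c",
                                                 rank_score = "i"))
  if (anyDuplicated(map[, c("source_id", "target_id")])) {
    abort("Ortholog map contains a duplicated (source, target) pair.")
  }
  map
}
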