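#' Hypergeometric gene-set over-representation
#'
#' One-sided over-representation test of a gene list against each set of a
#' collection, relative to a background universe. With `N` background genes,
#' `K` of them in the set, a list of `n` and an overlap of `k`, the p-value is
#' the exact hypergeometric upper tail
#' `P(X >= k) = sum_{i=k}^{min(K, n)} C(K, i) C(N-K, n-i) / C(N, n)`,
#' the test behind the usual pathway over-representation tools. Listed genes
#' outside the background are ignored (their count is reported); set sizes
#' `K` are background-restricted.
#'
#' @param gene_ids Character vector, the gene list (e.g. DEGs at one
#'   time-point).
#' @param collection Gene-set tibble from [read_gmt()] (columns `set_id`,
#'   `name`, list-column `genes`).
#' @param background_ids Character vector, the background universe.
#' @return Tibble with columns `set_id`, `name`, `k`, `K`, `n`, `N`,
#'   `p_value` and list-column `overlap`, sorted by ascending p-value then
#'   set id.
#' @export
enrich <- function(gene_ids, collection, background_ids) {
  background_ids <- unique(background_ids)
  if (!length(background_ids)) abort("Background universe is empty.")
  gene_ids <- unique(gene_ids)
  outside <- setdiff(gene_ids, background_ids)
  if (length(outside)) {
    inform(sprintf("Ignoring %d listed gene(s) outside the background.",
                   length(outside)))
  }
  lst <- intersect(gene_ids, background_ids)
  N <- length(background_ids)
  n <- length(lst)
  if (n > N) abort("Gene list is larger than the background.")
  res <- pmap(collection[c("set_id", "name", "genes")],
              function(set_id, name, genes) {
    members <- intersect(unique(genes), background_ids)
    K <- length(members)
    overlap <- intersect(members, lst)
    k <- length(overlap)
    # upper tail P(X >= k); k = 0 gives p = 1
    p <- phyper(k - 1, K, N - K, n, lower.tail = FALSE)
    tibble(set_id = set_id, name = name, k = k, K = K, n = n, N = N,
           p_value = p, overlap = list(sort(overlap)))
  })
  bind_rows(res) |>
    arrange(.data$p_value, .data$set_id)
}

#' Select significant pathways from enrichment results
#'
#' Keeps set ids with `p_value` strictly below `alpha`, ordered by ascending
#' p-value with ties broken by set id.
#'
#' @param results Tibble from [enrich()].
#' @param alpha Significance level (strict inequality; default 0.05).
#' @return Character vector of set ids.
#' @export
significant_pathways <- function(results, alpha = 0.05) {
  check_probability(alpha, "alpha")
  if (!nrow(results)) return(character())
  results |>
    filter(.data$p_value < alpha) |>
    arrange(.data$p_value, .data$set_id) |>
    pull("set_id")
}

#' Stage matching between two models' time-points
#'
#' Pairs the in vitro time-points with the in vivo ages that correspond to
#' the same aggregation stage (early/middle/late).
#'
#' @param time_points_a,time_points_b Character vectors of equal length,
#'   ordered by stage.
#' @param stages Stage labels (default early/middle/late).
#' @return Tibble with columns `stage`, `time_point_a`, `time_point_b`.
#' @export
stage_matching <- function(time_points_a, time_points_b,
                           stages = stage_levels()) {
  if (length(time_points_a) != length(stages) ||
      length(time_points_b) != length(stages)) {
    abort("Stage matching must pair exactly one time-point per stage in each model.")
  }
  if (anyDuplicated(time_points_a) || anyDuplicated(time_points_b)) {
    abort("Stage matching must be one-to-one.")
  }
  tibble(stage = stages, time_point_a = time_points_a,
         time_point_b = time_points_b)
}

#' Pathways dysregulated in both models at matched stages
#'
#' Enriches each model per time-point result set, intersects the significant
#' pathways of the two models at each matched stage, and flags pathways that
#' are common at every stage ("persistent" dysregulation).
#'
#' @param res_a,res_b Per-time-point enrichment results: tibbles as from
#'   [enrich()] with an added `time_point` column, one model each, computed on
#'   the same collection.
#' @param matching A [stage_matching()] table.
#' @param alpha Significance level passed to [significant_pathways()].
#' @return Tibble with columns `stage`, `set_id`, `p_a`, `p_b`, `persistent`.
#' @export
common_pathways <- function(res_a, res_b, matching, alpha = 0.05) {
  if (!setequal(unique(res_a$set_id), unique(res_b$set_id))) {
    abort("The two models were enriched on different collections.")
  }
  per_stage <- pmap(matching, function(stage, time_point_a, time_point_b) {
    ra <- filter(res_a, .data$time_point == time_point_a)
    rb <- filter(res_b, .data$time_point == time_point_b)
    common <- intersect(significant_pathways(ra, alpha),
                        significant_pathways(rb, alpha))
    if (!length(common)) {
      return(tibble(stage = character(), set_id = character(),
                    p_a = numeric(), p_b = numeric()))
    }
    tibble(stage = stage, set_id = sort(common)) |>
      left_join(select(ra, "set_id", p_a = "p_value"), by = "set_id") |>
      left_join(select(rb, "set_id", p_b = "p_value"), by = "set_id")
  })
  out <- bind_rows(per_stage)
  n_stages <- nrow(matching)
  persistent_ids <- out |>
    dplyr::count(.data$set_id) |>
    filter(.data$n == n_stages) |>
    pull("set_id")
  mutate(out, persistent = .data$set_id %in% persistent_ids)
}

#' Direction concordance of DEGs shared by two models
#'
#' A gene is "shared" when it is called a DEG at one or more time-points in
#' both models. Each model assigns the gene a direction: the sign of the
#' log2 fold change of its largest-magnitude DEG call. Concordance (up in
#' both plus down in both) is tested against chance (0.5) with an exact
#' two-sided binomial sign test.
#'
#' @param deg_a,deg_b [deg_table()]s in a common gene namespace.
#' @return One-row tibble: `n_shared`, `n_up_both`, `n_down_both`,
#'   `n_discordant`, `p_value` (`NA` when no genes are shared).
#' @export
direction_concordance <- function(deg_a, deg_b) {
  dir_a <- model_directions(deg_a)
  dir_b <- model_directions(deg_b)
  shared <- inner_join(dir_a, dir_b, by = "gene", suffix = c("_a", "_b"))
  n <- nrow(shared)
  up_both <- sum(shared$direction_a > 0 & shared$direction_b > 0)
  down_both <- sum(shared$direction_a < 0 & shared$direction_b < 0)
  concordant <- up_both + down_both
  p <- if (n == 0) NA_real_ else binom.test(concordant, n, p = 0.5)$p.value
  tibble(n_shared = n, n_up_both = up_both, n_down_both = down_both,
         n_discordant = n - concordant, p_value = p)
}

# Per-gene model-level direction: sign of the largest-|log2fc| DEG call.
model_directions <- function(deg) {
  as_tibble(deg) |>
    filter(.data$is_deg) |>
    arrange(.data$gene, desc(abs(.data$log2fc))) |>
    distinct(.data$gene, .keep_all = TRUE) |>
    mutate(direction = sign(.data$log2fc)) |>
    select("gene", "direction")
}
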