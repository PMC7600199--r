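#' Per-gene fold change between two conditions
#'
#' Mean FPKM is taken over the replicates of each condition and the fold
#' change is the ratio of means, `FC = (mean_case + pc) / (mean_control + pc)`
#' with a shared pseudocount `pc` guarding against division by zero; `log2fc`
#' is its base-2 logarithm.
#'
#' @param study An [expression_study()].
#' @param case_condition,control_condition Condition labels from the study's
#'   sample design.
#' @param pseudocount Non-negative value added to both means before the
#'   ratio (default 0.25).
#' @return Tibble with columns `gene`, `mean_case`, `mean_control`, `fc`,
#'   `log2fc`.
#' @export
compute_fold_change <- function(study, case_condition, control_condition,
                                pseudocount = 0.25) {
  stopifnot(inherits(study, "expression_study"))
  check_scalar_number(pseudocount, "pseudocount", min = 0)
  mc <- condition_matrix(study, case_condition)
  mk <- condition_matrix(study, control_condition)
  mean_case <- rowMeans(mc)
  mean_control <- rowMeans(mk)
  fc <- (mean_case + pseudocount) / (mean_control + pseudocount)
  tibble(
    gene = study$fpkm$gene,
    mean_case = mean_case,
    mean_control = mean_control,
    fc = fc,
    log2fc = log2(fc)
  )
}

#' Per-gene two-sided t-test between two conditions
#'
#' Compares FPKM replicate values of the case condition against its control,
#' gene by gene. The default is Welch's unequal-variance t-test; a pooled
#' Student's t is available. The statistic is computed in closed form across
#' all genes at once; genes with zero variance in both groups return p = 1
#' when the means are equal and p = 0 otherwise.
#'
#' @inheritParams compute_fold_change
#' @param test `"welch"` (default) or `"student"`.
#' @return Tibble with columns `gene`, `p_value`.
#' @export
deg_test <- function(study, case_condition, control_condition,
                     test = c("welch", "student")) {
  stopifnot(inherits(study, "expression_study"))
  test <- match.arg(test)
  x <- condition_matrix(study, case_condition)
  y <- condition_matrix(study, control_condition)
  if (ncol(x) < 2L || ncol(y) < 2L) {
    abort("Each condition needs at least 2 replicates for the t-test.")
  }
  tibble(gene = study$fpkm$gene,
         p_value = row_t_p(x, y, test = test))
}

# Vectorised two-sample two-sided t-test over the rows of two matrices.
row_t_p <- function(x, y, test = "welch") {
  nx <- ncol(x); ny <- ncol(y)
  mx <- rowMeans(x); my <- rowMeans(y)
  vx <- rowSums((x - mx)^2) / (nx - 1)
  vy <- rowSums((y - my)^2) / (ny - 1)
  if (test == "welch") {
    se2 <- vx / nx + vy / ny
    df <- se2^2 / ((vx / nx)^2 / (nx - 1) + (vy / ny)^2 / (ny - 1))
  } else {
    sp2 <- ((nx - 1) * vx + (ny - 1) * vy) / (nx + ny - 2)
    se2 <- sp2 * (1 / nx + 1 / ny)
    df <- rep(nx + ny - 2, length(mx))
  }
  tstat <- (mx - my) / sqrt(se2)
  p <- 2 * pt(-abs(tstat), df)
  degenerate <- se2 == 0
  if (any(degenerate)) {
    p[degenerate] <- ifelse(mx[degenerate] == my[degenerate], 1, 0)
  }
  unname(p)
}

#' Call differentially expressed genes from fold changes and p-values
#'
#' A gene is a DEG when `|log2fc| > fc_threshold` and `p_value < p_threshold`,
#' both strict, mirroring the usual FPKM workflow cutoffs (default 0.5 on the
#' log2 scale and 0.05).
#'
#' @param fold_changes Output of [compute_fold_change()].
#' @param p_values Output of [deg_test()] on the same gene universe.
#' @param fc_threshold,p_threshold DEG thresholds (strict inequalities).
#' @return Tibble joining the inputs with a logical `is_deg` column.
#' @export
call_degs <- function(fold_changes, p_values, fc_threshold = 0.5,
                      p_threshold = 0.05) {
  check_scalar_number(fc_threshold, "fc_threshold", min = 0)
  check_probability(p_threshold, "p_threshold")
  if (!setequal(fold_changes$gene, p_values$gene)) {
    abort("Fold-change and p-value tables cover different gene universes.")
  }
  out <- inner_join(fold_changes, p_values, by = "gene")
  mutate(out, is_deg = abs(.data$log2fc) > fc_threshold &
           .data$p_value < p_threshold)
}

#' Full DEG table for every stage contrast of a study
#'
#' Runs [compute_fold_change()], [deg_test()] and [call_degs()] for each row
#' of the study's contrast table (each aggregation stage against its matched
#' control) and stacks the results.
#'
#' @inheritParams compute_fold_change
#' @inheritParams deg_test
#' @inheritParams call_degs
#' @return A `deg_table`: tibble with columns `gene`, `stage`, `time_point`,
#'   `mean_case`, `mean_control`, `fc`, `log2fc`, `p_value`, `is_deg`, with
#'   the thresholds and model id stored as attributes.
#' @export
deg_table <- function(study, fc_threshold = 0.5, p_threshold = 0.05,
                      pseudocount = 0.25, test = c("welch", "student")) {
  stopifnot(inherits(study, "expression_study"))
  test <- match.arg(test)
  rows <- pmap(study$contrasts, function(stage, time_point, case_condition,
                                         control_condition, ...) {
    fc <- compute_fold_change(study, case_condition, control_condition,
                              pseudocount = pseudocount)
    pv <- deg_test(study, case_condition, control_condition, test = test)
    out <- call_degs(fc, pv, fc_threshold = fc_threshold,
                     p_threshold = p_threshold)
    mutate(out, stage = stage, time_point = time_point, .after = "gene")
  })
  out <- bind_rows(rows)
  new_deg_table(out, model = study$model, fc_threshold = fc_threshold,
                p_threshold = p_threshold, pseudocount = pseudocount,
                test = test)
}

new_deg_table <- function(x, model, fc_threshold, p_threshold,
                          pseudocount = NA_real_, test = NA_character_) {
  structure(
    as_tibble(x),
    model = model,
    fc_threshold = fc_threshold,
    p_threshold = p_threshold,
    pseudocount = pseudocount,
    test = test,
    class = c("deg_table", class(tibble()))
  )
}

#' @rdname deg_table
#' @param path Output TSV path.
#' @param x A `deg_table`.
#' @export
write_deg_table <- function(x, path) {
  stopifnot(inherits(x, "deg_table"))
  readr::write_tsv(as_tibble(x), path)
  invisible(path)
}

#' @exportS3Method generics::glance
glance.deg_table <- function(x, ...) {
  as_tibble(x) |>
    group_by(.data$stage, .data$time_point) |>
    summarise(n_genes = n(), n_deg = sum(.data$is_deg),
              n_down = sum(.data$is_deg & .data$log2fc < 0),
              .groups = "drop") |>
    mutate(model = attr(x, "model"), .before = 1)
}

# Matrix of FPKM values (genes x replicates) for one condition label.
condition_matrix <- function(study, condition) {
  samples <- study$samples$sample[study$samples$condition == condition]
  if (!length(samples)) {
    abort(sprintf("Condition '%s' is absent from the sample design.", condition))
  }
  as.matrix(study$fpkm[, samples, drop = FALSE])
}
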