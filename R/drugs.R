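#' Build a drug-target overlay for prioritized proteins
#'
#' Restricts a drug-target interaction table to the prioritized target
#' proteins, keeping interactions whose score reaches `score_threshold`
#' (inclusive). Drugs left without a surviving interaction are absent from
#' the overlay; per-target drug counts are reported for every listed target
#' (zero allowed).
#'
#' @param targets Non-empty character vector of target protein ids.
#' @param table Tibble with columns `drug`, `target`, `score` (in `[0, 1]`)
#'   and optionally `status` (approval status label).
#' @param score_threshold Minimum interaction score (default 0.5, inclusive).
#' @return A `drug_overlay`: list with `edges` (tibble `drug`, `target`,
#'   `score`, `status`), `drugs`, `targets`, `target_degree` (tibble
#'   `target`, `n_drugs`), and the threshold used.
#' @export
build_overlay <- function(targets, table, score_threshold = 0.5) {
  if (!length(targets)) abort("Target list is empty.")
  table <- as_tibble(table)
  need <- c("drug", "target", "score")
  if (!all(need %in% names(table))) {
    abort("Drug-target table needs columns drug, target, score.")
  }
  if (anyDuplicated(table[, c("drug", "target")])) {
    abort("Duplicate (drug, target) pair in interaction table.")
  }
  if (any(table$score < 0 | table$score > 1)) {
    abort("Interaction scores must lie in [0, 1].")
  }
  check_probability(score_threshold, "score_threshold")
  if (!"status" %in% names(table)) table$status <- NA_character_
  targets <- unique(targets)
  edges <- table |>
    filter(.data$target %in% targets, .data$score >= score_threshold) |>
    arrange(.data$drug, .data$target)
  target_degree <- tibble(target = sort(targets)) |>
    left_join(dplyr::count(edges, .data$target, name = "n_drugs"),
              by = "target") |>
    mutate(n_drugs = dplyr::coalesce(.data$n_drugs, 0L))
  structure(
    list(edges = edges, drugs = sort(unique(edges$drug)), targets = targets,
         target_degree = target_degree, score_threshold = score_threshold),
    class = "drug_overlay"
  )
}

#' @export
print.drug_overlay <- function(x, ...) {
  cat(sprintf("<drug_overlay>: %d drugs x %d targets, %d interactions (score >= %.2f)\n",
              length(x$drugs), length(x$targets), nrow(x$edges),
              x$score_threshold))
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.drug_overlay <- function(x, ...) x$edges

#' @exportS3Method generics::glance
glance.drug_overlay <- function(x, ...) {
  tibble(n_drugs = length(x$drugs), n_targets = length(x$targets),
         n_interactions = nrow(x$edges), score_threshold = x$score_threshold)
}

bbb_algorithms <- function() c("ADABoost", "SVM")
bbb_fingerprints <- function() c("MACCS", "Openbabel", "Molprint", "PubChem")

#' Blood-brain-barrier consensus verdicts
#'
#' Applies the strict 8/8 consensus rule to per-drug predictor calls: a drug
#' is `permeable` only when all eight (algorithm, fingerprint) combinations —
#' 2 algorithms x 4 chemical fingerprints — call `BBB+`; a single `BBB-`
#' makes it `not-permeable`; a missing or partial call set yields
#' `incomplete`, never a silent pass. The rule is monotone: flipping any call
#' to `BBB-` can only remove permeability.
#'
#' @param overlay A `drug_overlay`, or a character vector of drug ids.
#' @param calls Tibble with columns `drug`, `algorithm` (`ADABoost`/`SVM`),
#'   `fingerprint` (`MACCS`/`Openbabel`/`Molprint`/`PubChem`), `call`
#'   (`BBB+`/`BBB-`). Duplicated (drug, algorithm, fingerprint) rows are an
#'   error.
#' @return Tibble with columns `drug`, `n_calls`, `n_positive`, `verdict`.
#' @export
bbb_consensus <- function(overlay, calls) {
  drugs <- if (inherits(overlay, "drug_overlay")) overlay$drugs
           else unique(as.character(overlay))
  calls <- as_tibble(calls)
  need <- c("drug", "algorithm", "fingerprint", "call")
  if (!all(need %in% names(calls))) {
    abort("BBB call table needs columns drug, algorithm, fingerprint, call.")
  }
  if (anyDuplicated(calls[, c("drug", "algorithm", "fingerprint")])) {
    abort("Duplicate (drug, algorithm, fingerprint) row in BBB call table.")
  }
  bad_alg <- setdiff(unique(calls$algorithm), bbb_algorithms())
  bad_fp <- setdiff(unique(calls$fingerprint), bbb_fingerprints())
  if (length(bad_alg) || length(bad_fp)) {
    abort(sprintf("Unknown algorithm/fingerprint label(s): %s.",
                  paste(c(bad_alg, bad_fp), collapse = ", ")))
  }
  if (!all(calls$call %in% c("BBB+", "BBB-"))) {
    abort("BBB calls must be 'BBB+' or 'BBB-'.")
  }
  rows <- map(drugs, function(d) {
    dc <- filter(calls, .data$drug == d)
    n_calls <- nrow(dc)
    n_pos <- sum(dc$call == "BBB+")
    verdict <- if (n_calls < 8L) "incomplete"
               else if (n_pos == 8L) "permeable"
               else "not-permeable"
    tibble(drug = d, n_calls = n_calls, n_positive = n_pos, verdict = verdict)
  })
  bind_rows(rows) |> arrange(.data$drug)
}

#' @rdname bbb_consensus
#' @param path Output TSV path.
#' @param verdicts Result of `bbb_consensus()`.
#' @export
write_bbb_verdicts <- function(verdicts, path) {
  readr::write_tsv(verdicts, path)
  invisible(path)
}
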