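#' Run the de novo gene screen over a batch of candidates
#'
#' Applies [classify_candidate()] to every trio, joins the per-gene filter
#' ledgers into stage-level counts (mirroring a screening funnel: each
#' stage's entrants are the previous stage's passers), and returns a
#' deterministic, gene-id-ordered report.
#'
#' @param trios A list of [trio_alignment()] objects, or a data frame with a
#'   `gene_id` column and an `alignment` list-column of trio alignments.
#' @param evidence An evidence table covering every gene (see
#'   [read_evidence()] / [evidence_record()]).
#' @param thresholds A [screen_thresholds()] object (or named list).
#' @return An object of class `"screen_report"`: list with `verdicts` (one
#'   row per gene: `gene_id`, `verdict`, `failed_stage`, `n_enabling`,
#'   `fixation_note`), `ledgers` (long per-gene stage table),
#'   `stage_counts` (per-stage `entered`, `passed`, `failed`), `details`
#'   (the `candidate_verdict` objects, named by gene), and `thresholds`.
#' @export
run_candidate_screen <- function(trios, evidence, thresholds = NULL) {
  th <- as_thresholds(thresholds)
  if (is.data.frame(trios)) {
    stopifnot(all(c("gene_id", "alignment") %in% names(trios)))
    trio_list <- stats::setNames(trios$alignment, trios$gene_id)
  } else {
    trio_list <- trios
    names(trio_list) <- vapply(trio_list, function(x) x$gene_id, character(1))
  }
  ev <- validate_evidence(evidence)
  missing_ev <- setdiff(names(trio_list), ev$gene_id)
  missing_trio <- setdiff(ev$gene_id, names(trio_list))
  if (length(missing_ev) > 0 || length(missing_trio) > 0) {
    stop("trio/evidence key mismatch:\n",
         if (length(missing_ev) > 0)
           paste0("  no evidence for: ", paste(missing_ev, collapse = ", "), "\n"),
         if (length(missing_trio) > 0)
           paste0("  no trio for: ", paste(missing_trio, collapse = ", "), "\n"),
         call. = FALSE)
  }
  trio_list <- trio_list[order(names(trio_list))]
  details <- purrr::map(trio_list, classify_candidate, evidence = ev,
                        thresholds = th)
  empty_verdicts <- tibble::tibble(
    gene_id = character(), verdict = character(), failed_stage = integer(),
    n_enabling = integer(), fixation_note = character())
  verdicts <- dplyr::bind_rows(empty_verdicts, purrr::map_dfr(details, function(v) {
    tibble::tibble(
      gene_id = v$gene_id, verdict = v$verdict,
      failed_stage = first_failed_stage(v),
      n_enabling = nrow(v$enabling), fixation_note = v$fixation_note)
  }))
  empty_ledger <- tibble::tibble(
    gene_id = character(), stage = integer(), name = character(),
    status = character(), reason = character())
  ledgers <- dplyr::bind_rows(empty_ledger, purrr::map_dfr(details, function(v) {
    dplyr::mutate(v$ledger, gene_id = v$gene_id, .before = 1)
  }))
  stage_counts <- ledgers |>
    dplyr::filter(.data$status != "skip") |>
    dplyr::group_by(.data$stage, .data$name) |>
    dplyr::summarise(
      entered = dplyr::n(),
      passed = sum(.data$status == "pass"),
      failed = sum(.data$status == "fail"),
      .groups = "drop"
    ) |>
    dplyr::right_join(
      tibble::tibble(stage = seq_along(SCREEN_STAGES), name = SCREEN_STAGES),
      by = c("stage", "name")) |>
    dplyr::mutate(dplyr::across(c("entered", "passed", "failed"),
                                ~ dplyr::coalesce(.x, 0L))) |>
    dplyr::arrange(.data$stage)
  structure(
    list(verdicts = verdicts, ledgers = ledgers, stage_counts = stage_counts,
         details = details, thresholds = th),
    class = "screen_report"
  )
}

#' @export
print.screen_report <- function(x, ...) {
  n <- nrow(x$verdicts)
  n_pos <- sum(x$verdicts$verdict == "de_novo")
  cat("<screen_report> ", n, " candidates screened, ", n_pos,
      " called de novo\n", sep = "")
  print(x$stage_counts)
  invisible(x)
}

#' Tidy a screen report into its per-gene ledger
#'
#' @param x A `screen_report`.
#' @param ... Unused.
#' @return The long ledger tibble (`gene_id`, `stage`, `name`, `status`,
#'   `reason`).
#' @method tidy screen_report
#' @export
tidy.screen_report <- function(x, ...) x$ledgers

#' One-row summary of a screen report
#'
#' @param x A `screen_report`.
#' @param ... Unused.
#' @return Tibble with `n_candidates`, `n_de_novo`, `n_rejected`.
#' @method glance screen_report
#' @export
glance.screen_report <- function(x, ...) {
  tibble::tibble(
    n_candidates = nrow(x$verdicts),
    n_de_novo = sum(x$verdicts$verdict == "de_novo"),
    n_rejected = sum(x$verdicts$verdict == "rejected")
  )
}

#' Write a screen report to JSON and TSV
#'
#' Serialization is byte-stable for identical inputs: genes are ordered by
#' id and no timestamps are embedded. The JSON carries one object per gene
#' (verdict, ledger, enabling mutations); the TSV is the flat verdict
#' summary.
#'
#' @param report A `screen_report`.
#' @param json_path,tsv_path Output paths (either may be `NULL` to skip).
#' @return Invisibly, the report.
#' @export
write_screen_report <- function(report, json_path = NULL, tsv_path = NULL) {
  if (!is.null(json_path)) {
    per_gene <- purrr::map(report$details, function(v) {
      list(gene_id = v$gene_id, verdict = v$verdict,
           ledger = v$ledger, enabling = v$enabling,
           fixation_note = v$fixation_note)
    })
    jsonlite::write_json(
      list(genes = per_gene, stage_counts = report$stage_counts,
           thresholds = unclass(report$thresholds)),
      json_path, auto_unbox = TRUE, digits = NA, na = "null", pretty = TRUE)
  }
  if (!is.null(tsv_path)) {
    readr::write_tsv(report$verdicts, tsv_path)
  }
  invisible(report)
}

signif_or_zero <- function(x, digits) ifelse(x == 0, 0, signif(x, digits))

#' De novo gene birth-rate arithmetic
#'
#' Converts a count of fixed de novo genes and a divergence-time window into
#' a per-lineage origination rate (genes per million years, reported to 3
#' significant figures) and, when a genome-wide gene count is supplied, a
#' per-gene rate (per gene per million years, 2 significant figures). The
#' lower rate uses the older divergence bound and vice versa.
#'
#' @param n_fixed_genes Number of fixed de novo genes.
#' @param t_low,t_high Divergence-time bounds in millions of years
#'   (defaults 5 and 6).
#' @param n_genome_genes Optional total number of protein-coding genes in
#'   the genome.
#' @return A one-row tibble: `rate_low`, `rate_high` (genes/Myr), and, when
#'   `n_genome_genes` is given, `per_gene_low`, `per_gene_high`.
#' @examples
#' compute_birth_rate(59, 5, 6, n_genome_genes = 30000)
#' @export
compute_birth_rate <- function(n_fixed_genes, t_low = 5, t_high = 6,
                               n_genome_genes = NULL) {
  if (n_fixed_genes < 0) stop("n_fixed_genes must be nonnegative", call. = FALSE)
  if (t_low <= 0 || t_high <= 0) stop("divergence times must be positive", call. = FALSE)
  if (t_low > t_high) stop("t_low must not exceed t_high", call. = FALSE)
  out <- tibble::tibble(
    rate_low = signif_or_zero(n_fixed_genes / t_high, 3),
    rate_high = signif_or_zero(n_fixed_genes / t_low, 3)
  )
  if (!is.null(n_genome_genes)) {
    out$per_gene_low <- signif_or_zero(n_fixed_genes / t_high / n_genome_genes, 2)
    out$per_gene_high <- signif_or_zero(n_fixed_genes / t_low / n_genome_genes, 2)
  }
  out
}
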