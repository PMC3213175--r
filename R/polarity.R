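#' Find human-specific ORF-enabling mutations
#'
#' The guard against parallel loss: a candidate is only accepted as a de novo
#' gene if at least one human-specific change is singly sufficient for the
#' completed reading frame. For every alignment column (and every contiguous
#' gap run) where chimpanzee and orangutan share a state that differs from
#' human, the human row is counterfactually reverted to that ancestral state
#' and re-assessed with the same anchored-then-rescue translation logic the
#' outgroups receive. If the reverted human ORF is disrupted (incomplete, or
#' below the intact fraction of the real human protein), the change is an
#' enabling mutation. Columns where the outgroups disagree, or where either
#' carries `N`, are unpolarizable and skipped; partially overlapping outgroup
#' gap runs are likewise skipped.
#'
#' @param trio A [trio_alignment()] whose anchored human ORF is complete.
#' @param thresholds A [screen_thresholds()] object (or named list).
#' @return A tibble with one row per enabling mutation: `column` and
#'   `end_column` (0-based, inclusive), `human_state`, `ancestral_state`
#'   (`-` denotes a gap), and `effect` — `start_creation` when the reversion
#'   destroys the start codon, `frame_completion` when it shifts the reading
#'   frame, `stop_removal` otherwise (an ancestral in-frame stop).
#' @export
find_enabling_mutations <- function(trio, thresholds = NULL) {
  th <- as_thresholds(thresholds)
  hrow <- trio$rows[["human"]]
  hseq <- degap(hrow)
  anchor <- column_to_position(hrow, trio$start_col)
  href <- scan_orf(hseq, anchor = anchor, policy = "anchored")
  if (!href$complete) stop("human ORF not complete", call. = FALSE)
  ref_len <- nchar(href$protein)

  h <- alignment_chars(hrow)
  c_ <- alignment_chars(trio$rows[["chimp"]])
  o <- alignment_chars(trio$rows[["orang"]])
  n <- length(h)

  candidates <- list()
  add <- function(from, to, human_state, ancestral_state, is_indel) {
    candidates[[length(candidates) + 1L]] <<- list(
      from = from, to = to, human_state = human_state,
      ancestral_state = ancestral_state, is_indel = is_indel)
  }

  # Point substitutions: all three rows have a base, outgroups agree.
  pt <- which(h != "-" & c_ != "-" & o != "-" & c_ == o & c_ != h &
                c_ != "N" & h != "N")
  for (i in pt) add(i - 1L, i - 1L, h[[i]], c_[[i]], FALSE)

  run_bounds <- function(mask) {
    r <- rle(mask)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    cbind(starts[r$values], ends[r$values])
  }

  # Human insertions: bases in human over a gap shared by both outgroups.
  # The outgroup gap runs must coincide exactly with the run (no partial
  # overlap with a wider outgroup gap).
  ins <- run_bounds(h != "-" & c_ == "-" & o == "-")
  if (length(ins) > 0) for (k in seq_len(nrow(ins))) {
    a <- ins[k, 1]; b <- ins[k, 2]
    left_ok <- a == 1L || (c_[[a - 1L]] != "-" && o[[a - 1L]] != "-")
    right_ok <- b == n || (c_[[b + 1L]] != "-" && o[[b + 1L]] != "-")
    if (left_ok && right_ok) {
      add(a - 1L, b - 1L, paste(h[a:b], collapse = ""), "-", TRUE)
    }
  }

  # Human deletions: a human gap run over identical outgroup bases. The
  # human gap run must not extend past the region where the outgroups agree.
  del <- run_bounds(h == "-" & c_ != "-" & o != "-" & c_ == o & c_ != "N")
  if (length(del) > 0) for (k in seq_len(nrow(del))) {
    a <- del[k, 1]; b <- del[k, 2]
    left_ok <- a == 1L || h[[a - 1L]] != "-"
    right_ok <- b == n || h[[b + 1L]] != "-"
    if (left_ok && right_ok) {
      add(a - 1L, b - 1L, "-", paste(c_[a:b], collapse = ""), TRUE)
    }
  }

  out <- list()
  for (cand in candidates) {
    cf <- h
    idx <- (cand$from:cand$to) + 1L
    cf[idx] <- alignment_chars(
      if (cand$ancestral_state == "-") {
        strrep("-", length(idx))
      } else {
        cand$ancestral_state
      })
    cf_row <- paste(cf, collapse = "")
    cf_seq <- degap(cf_row)
    cf_anchor <- column_to_position(cf_row, trio$start_col)
    start_lost <- is.na(cf_anchor) || cf_anchor + 3L > nchar(cf_seq) ||
      substr(cf_seq, cf_anchor + 1L, cf_anchor + 3L) != "ATG"
    rep <- scan_orf(cf_seq, anchor = cf_anchor, policy = "anchored",
                    human_protein_len = ref_len)
    if (!rep$complete && is.na(rep$start_pos)) {
      rep <- scan_orf(cf_seq, policy = "rescue", human_protein_len = ref_len)
    }
    disrupted <- !rep$complete || rep$length_fraction < th$intact_fraction
    if (!disrupted) next
    indel_len <- cand$to - cand$from + 1L
    effect <- if (start_lost) {
      "start_creation"
    } else if (cand$is_indel && indel_len %% 3L != 0L) {
      "frame_completion"
    } else {
      "stop_removal"
    }
    out[[length(out) + 1L]] <- tibble::tibble(
      column = cand$from, end_column = cand$to,
      human_state = cand$human_state, ancestral_state = cand$ancestral_state,
      effect = effect)
  }
  if (length(out) == 0L) {
    tibble::tibble(column = integer(), end_column = integer(),
                   human_state = character(), ancestral_state = character(),
                   effect = character())
  } else {
    dplyr::bind_rows(out)
  }
}

SCREEN_STAGES <- c(
  "human_orf_complete", "min_protein_length", "single_copy",
  "outgroups_disrupted", "enabling_mutation", "transcription_evidence",
  "translation_evidence"
)

#' Classify one candidate gene through the full screen
#'
#' Applies the screen's seven stages in fixed order: (1) the anchored human
#' ORF is complete with start and stop; (2) the human protein reaches the
#' minimum length; (3) the gene is single-copy in human and the outgroups;
#' (4) both outgroup orthologs are disrupted; (5) at least one polarizable
#' human-specific enabling mutation exists; (6) transcription evidence (mRNA
#' or EST hit); (7) translation evidence (peptide hit). Stages after the
#' first failure are recorded as skipped. A known ORF-disrupting SNP does not
#' reject the gene but is recorded as a fixation note (the gene may not be
#' fixed in the population).
#'
#' @param trio A [trio_alignment()].
#' @param evidence A one-row evidence tibble (see [evidence_record()]), or a
#'   multi-row table containing this gene's `gene_id`.
#' @param thresholds A [screen_thresholds()] object (or named list).
#' @return A `candidate_verdict`: list with `gene_id`, `verdict`
#'   (`"de_novo"` or `"rejected"`), `ledger` (7-row tibble of stage, status,
#'   reason), `enabling` (tibble of enabling mutations), `statuses` (list of
#'   the two `ortholog_status` objects), and `fixation_note`.
#' @export
classify_candidate <- function(trio, evidence, thresholds = NULL) {
  th <- as_thresholds(thresholds)
  ev <- validate_evidence(evidence)
  if (nrow(ev) > 1L) ev <- ev[ev$gene_id == trio$gene_id, , drop = FALSE]
  if (nrow(ev) != 1L) {
    stop("no evidence record for gene ", trio$gene_id, call. = FALSE)
  }

  status <- character(0)
  reason <- character(0)
  failed <- FALSE
  note <- function(ok, why_fail) {
    if (failed) {
      status <<- c(status, "skip"); reason <<- c(reason, "not evaluated")
    } else if (ok) {
      status <<- c(status, "pass"); reason <<- c(reason, "")
    } else {
      status <<- c(status, "fail"); reason <<- c(reason, why_fail)
      failed <<- TRUE
    }
  }

  # Stage 1: complete anchored human ORF.
  hrow <- trio$rows[["human"]]
  hseq <- degap(hrow)
  anchor <- column_to_position(hrow, trio$start_col)
  href <- tryCatch(
    scan_orf(hseq, anchor = anchor, policy = "anchored"),
    error = function(e) empty_orf_report())
  note(href$complete, "human ORF lacks a start or in-frame stop")

  # Stage 2: minimum protein length.
  plen <- nchar(href$protein)
  note(!failed && plen >= th$min_protein_aa,
       sprintf("human protein %d aa < %d aa minimum", plen, th$min_protein_aa))

  # Stage 3: single copy in human and outgroups.
  note(ev$single_copy_human && ev$single_copy_outgroups,
       "gene has close paralogs (not single-copy)")

  # Stage 4: both outgroup orthologs disrupted.
  statuses <- NULL
  if (!failed) {
    statuses <- tryCatch(
      list(chimp = assess_ortholog(trio, "chimp", th),
           orang = assess_ortholog(trio, "orang", th)),
      error = function(e) conditionMessage(e))
  }
  if (is.character(statuses)) {
    note(FALSE, statuses)
    statuses <- NULL
  } else {
    both <- !is.null(statuses) &&
      statuses$chimp$status == "disrupted" && statuses$orang$status == "disrupted"
    why <- if (!is.null(statuses)) {
      intact <- names(statuses)[vapply(statuses, function(s) s$status != "disrupted",
                                       logical(1))]
      paste0("ortholog not disrupted in: ", paste(intact, collapse = ", "))
    } else "not evaluated"
    note(both, why)
  }

  # Stage 5: at least one polarizable enabling mutation.
  enabling <- NULL
  if (!failed) enabling <- find_enabling_mutations(trio, th)
  note(!is.null(enabling) && nrow(enabling) > 0L,
       "no polarizable enabling mutation")

  # Stages 6-7: expression and translation evidence.
  note(ev$has_mrna || ev$has_est, "no mRNA or EST evidence of transcription")
  note(ev$has_peptide, "no peptide evidence of translation")

  ledger <- tibble::tibble(
    stage = seq_along(SCREEN_STAGES), name = SCREEN_STAGES,
    status = status, reason = reason)
  structure(
    list(
      gene_id = trio$gene_id,
      verdict = if (all(ledger$status == "pass")) "de_novo" else "rejected",
      ledger = ledger,
      enabling = if (is.null(enabling)) {
        find_enabling_mutations_empty()
      } else enabling,
      statuses = statuses,
      fixation_note = if (ev$disrupting_snp) {
        "segregating ORF-disrupting SNP: reported, but may not be fixed in the population"
      } else NA_character_
    ),
    class = "candidate_verdict"
  )
}

find_enabling_mutations_empty <- function() {
  tibble::tibble(column = integer(), end_column = integer(),
                 human_state = character(), ancestral_state = character(),
                 effect = character())
}

#' @export
print.candidate_verdict <- function(x, ...) {
  cat("<candidate_verdict> ", x$gene_id, ": ", x$verdict, "\n", sep = "")
  for (i in seq_len(nrow(x$ledger))) {
    cat(sprintf("  %d. %-24s %-5s %s\n", x$ledger$stage[[i]],
                x$ledger$name[[i]], x$ledger$status[[i]], x$ledger$reason[[i]]))
  }
  if (nrow(x$enabling) > 0) {
    cat("  enabling mutations: ",
        paste(sprintf("%s@%d", x$enabling$effect, x$enabling$column),
              collapse = ", "), "\n", sep = "")
  }
  if (!is.na(x$fixation_note)) cat("  note: ", x$fixation_note, "\n", sep = "")
  invisible(x)
}

first_failed_stage <- function(verdict) {
  i <- which(verdict$ledger$status == "fail")
  if (length(i) == 0L) NA_integer_ else verdict$ledger$stage[[i[[1L]]]]
}
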