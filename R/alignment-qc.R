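#' Global pairwise alignment with affine gaps
#'
#' A desk-scale stand-in for a full multiple-alignment program when only two
#' ortholog sequences need aligning. Needleman-Wunsch global alignment with
#' affine gap costs, delegated to [Biostrings::pairwiseAlignment()]; a gap
#' run of length L costs `gap_open + L * gap_extend`.
#'
#' @param a,b Nucleotide strings (nonempty).
#' @param match,mismatch,gap_open,gap_extend Scoring scheme; defaults
#'   +1/-1/4/1 (gap penalties given as positive costs).
#' @return A list with `a_aln`, `b_aln` (aligned strings of equal length)
#'   and `score`.
#' @examples
#' align_pair("ACGT", "AGT")
#' @export
align_pair <- function(a, b, match = 1, mismatch = -1, gap_open = 4,
                       gap_extend = 1) {
  if (nchar(a) == 0L || nchar(b) == 0L) {
    stop("align_pair requires nonempty sequences", call. = FALSE)
  }
  mat <- Biostrings::nucleotideSubstitutionMatrix(
    match = match, mismatch = mismatch, baseOnly = FALSE)
  aln <- Biostrings::pairwiseAlignment(
    a, b, type = "global", substitutionMatrix = mat,
    gapOpening = gap_open, gapExtension = gap_extend)
  list(
    a_aln = as.character(Biostrings::alignedPattern(aln)),
    b_aln = as.character(Biostrings::alignedSubject(aln)),
    score = Biostrings::score(aln)
  )
}

qc_result <- function(passed, failing_window = NA_integer_, reason = NA_character_) {
  tibble::tibble(passed = passed, failing_window = as.integer(failing_window),
                 reason = reason)
}

#' Sliding-window alignment quality filter
#'
#' Scans an aligned protein pair with a window of `qc_window_aa` aligned
#' columns (default 5), stepping one column at a time, and computes the
#' fraction of identically matching residues in each window (a gap against
#' anything counts as non-identical). If any window's identity is at or
#' below `qc_max_similarity` (default 20%), the ortholog pair is discarded
#' as a likely misalignment or non-orthologous region; the first failing
#' window is reported.
#'
#' @param pa,pb Aligned amino-acid strings of equal length (gaps as `-`).
#' @param thresholds A [screen_thresholds()] object (or named list).
#' @return A one-row tibble: `passed`, `failing_window` (0-based window
#'   start, `NA` if passed), `reason`. The per-window identities are
#'   attached as attribute `"similarities"`.
#' @export
window_similarity_filter <- function(pa, pb, thresholds = NULL) {
  th <- as_thresholds(thresholds)
  if (nchar(pa) != nchar(pb)) {
    stop("aligned protein strings must have equal length", call. = FALSE)
  }
  w <- th$qc_window_aa
  n <- nchar(pa)
  if (n < w) {
    stop("aligned length ", n, " shorter than the ", w, "-aa window", call. = FALSE)
  }
  ca <- alignment_chars(pa)
  cb <- alignment_chars(pb)
  ident <- as.integer(ca == cb & ca != "-")
  csum <- c(0L, cumsum(ident))
  starts <- seq_len(n - w + 1L)
  sims <- (csum[starts + w] - csum[starts]) / w
  bad <- which(sims <= th$qc_max_similarity)
  res <- if (length(bad) > 0L) {
    qc_result(FALSE, bad[[1L]] - 1L,
              sprintf("window identity %.0f%% <= %.0f%% at aligned position %d",
                      100 * sims[bad[[1L]]], 100 * th$qc_max_similarity,
                      bad[[1L]] - 1L))
  } else {
    qc_result(TRUE)
  }
  attr(res, "similarities") <- sims
  res
}

#' Prefilter ortholog protein records
#'
#' Per-record screens applied before rate estimation: records whose protein
#' contains an ambiguous `X` residue are dropped; among a gene's remaining
#' isoforms only the longest alignment is kept (others are superseded); a
#' kept alignment shorter than 100 aligned amino acids is dropped.
#'
#' @param records A data frame with columns `gene_id`, `isoform`, `protein`
#'   (amino-acid string), and `aln_length` (aligned length in aa).
#' @param thresholds A [screen_thresholds()] object (or named list). The
#'   100-aa floor reuses `min_protein_aa`.
#' @return `records` with added columns `passed` and `reason`
#'   (`"ambiguous residue"`, `"superseded by longer isoform"`,
#'   `"alignment <100 aa"`, or `NA` when kept).
#' @export
prefilter_ortholog_pair <- function(records, thresholds = NULL) {
  th <- as_thresholds(thresholds)
  records <- tibble::as_tibble(records)
  stopifnot(all(c("gene_id", "isoform", "protein", "aln_length") %in% names(records)))
  records |>
    dplyr::mutate(
      .has_x = stringr::str_detect(.data$protein, stringr::fixed("X"))) |>
    dplyr::group_by(.data$gene_id) |>
    dplyr::mutate(
      .best_idx = {
        ok <- which(!.data$.has_x)
        if (length(ok) == 0L) NA_integer_ else ok[[which.max(.data$aln_length[ok])]]
      },
      .best = !is.na(.data$.best_idx) & dplyr::row_number() == .data$.best_idx
    ) |>
    dplyr::ungroup() |>
    dplyr::mutate(
      reason = dplyr::case_when(
        .data$.has_x ~ "ambiguous residue",
        !.data$.best ~ "superseded by longer isoform",
        .data$aln_length < th$min_protein_aa ~
          sprintf("alignment <%d aa", th$min_protein_aa),
        TRUE ~ NA_character_
      ),
      passed = is.na(.data$reason)
    ) |>
    dplyr::select(-".has_x", -".best", -".best_idx")
}
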