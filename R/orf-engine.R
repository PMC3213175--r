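#' @importFrom rlang .data
NULL

# Standard nuclear genetic code, with any codon containing N (or an
# unexpected character) translating to 'X'. 'X' is never a start or a stop.
codon_table <- local({
  tab <- NULL
  function() {
    if (is.null(tab)) tab <<- as.list(Biostrings::GENETIC_CODE)
    tab
  }
})

translate_codon <- function(codon) {
  aa <- codon_table()[[codon]]
  if (is.null(aa)) "X" else aa
}

is_stop_codon <- function(codon) codon %in% STOP_CODONS

#' Translate an ungapped sequence from a fixed start
#'
#' Reads codons from `start` until the first stop codon or the end of the
#' sequence. A codon containing `N` translates to `X` and never terminates
#' translation. This is the primitive every disruption verdict reduces to:
#' an ortholog is non-translatable exactly when no acceptable start yields a
#' completed, long-enough protein.
#'
#' @param seq Ungapped nucleotide string.
#' @param start 0-based position of the first base of the first codon.
#' @param human_protein_len Optional reference protein length (aa) against
#'   which `length_fraction` is computed.
#' @return An `orf_report`: a list with `start_pos`, `stop_pos` (0-based
#'   position of the stop codon's first base, `NA` if translation ran off the
#'   end), `protein`, `complete`, and `length_fraction`.
#' @examples
#' translate_from("ATGAAATAA", 0)
#' @export
translate_from <- function(seq, start, human_protein_len = NA_integer_) {
  n <- nchar(seq)
  if (start < 0 || start >= n) {
    stop("start position ", start, " outside sequence of length ", n, call. = FALSE)
  }
  starts <- seq.int(start + 1L, n, by = 3L)
  starts <- starts[starts + 2L <= n]
  if (length(starts) == 0L) {
    return(orf_report(start, NA_integer_, "", FALSE, human_protein_len))
  }
  codons <- substring(seq, starts, starts + 2L)
  stop_idx <- which(codons %in% STOP_CODONS)
  if (length(stop_idx) > 0L) {
    k <- stop_idx[[1L]]
    protein <- paste(vapply(codons[seq_len(k - 1L)], translate_codon,
                            character(1), USE.NAMES = FALSE), collapse = "")
    orf_report(start, starts[[k]] - 1L, protein, TRUE, human_protein_len)
  } else {
    protein <- paste(vapply(codons, translate_codon, character(1),
                            USE.NAMES = FALSE), collapse = "")
    orf_report(start, NA_integer_, protein, FALSE, human_protein_len)
  }
}

orf_report <- function(start_pos, stop_pos, protein, complete,
                       human_protein_len = NA_integer_) {
  lf <- if (is.na(human_protein_len)) NA_real_ else nchar(protein) / human_protein_len
  structure(
    list(start_pos = as.integer(start_pos), stop_pos = as.integer(stop_pos),
         protein = protein, complete = isTRUE(complete), length_fraction = lf),
    class = "orf_report"
  )
}

empty_orf_report <- function(human_protein_len = NA_integer_) {
  rep <- orf_report(NA_integer_, NA_integer_, "", FALSE, human_protein_len)
  rep$start_pos <- NA_integer_
  rep$length_fraction <- if (is.na(human_protein_len)) NA_real_ else 0
  rep
}

#' @export
print.orf_report <- function(x, ...) {
  cat("<orf_report> ",
      if (x$complete) "complete" else "incomplete",
      ", start=", x$start_pos, ", stop=", x$stop_pos,
      ", protein ", nchar(x$protein), " aa",
      if (!is.na(x$length_fraction))
        paste0(" (", signif(x$length_fraction, 3), " of reference)"),
      "\n", sep = "")
  invisible(x)
}

atg_positions <- function(seq) {
  m <- gregexpr("(?=ATG)", seq, perl = TRUE)[[1L]]
  if (m[[1L]] == -1L) integer(0) else as.integer(m) - 1L
}

#' Scan a sequence for an open reading frame
#'
#' Two policies reflect the two ways the screen reads an ortholog. Under
#' `"anchored"` the only acceptable start is the position homologous to the
#' human ATG; translation happens there if and only if the sequence spells
#' ATG at the anchor. Under `"rescue"` (the alternative-start search) every
#' ATG in the provided region, in any frame, is tried, and the report with
#' the longest protein wins; ties go to the 5'-most start.
#'
#' @param seq Ungapped nucleotide string.
#' @param anchor 0-based preferred start position (required for
#'   `policy = "anchored"`).
#' @param policy `"anchored"` or `"rescue"`.
#' @param human_protein_len Reference protein length (aa) for
#'   `length_fraction`.
#' @return An `orf_report`; when no acceptable ATG exists, a report with an
#'   absent start and `complete = FALSE`.
#' @examples
#' scan_orf("CCCATGAAATAA", policy = "rescue", human_protein_len = 2)
#' @export
scan_orf <- function(seq, anchor = NULL, policy = c("anchored", "rescue"),
                     human_protein_len = NA_integer_) {
  policy <- match.arg(policy)
  if (policy == "anchored") {
    if (is.null(anchor)) stop("`anchor` is required for policy = \"anchored\"", call. = FALSE)
    if (anchor < 0 || anchor + 3L > nchar(seq) ||
        substr(seq, anchor + 1L, anchor + 3L) != "ATG") {
      return(empty_orf_report(human_protein_len))
    }
    return(translate_from(seq, anchor, human_protein_len))
  }
  starts <- atg_positions(seq)
  if (length(starts) == 0L) return(empty_orf_report(human_protein_len))
  best <- NULL
  for (s in starts) {
    rep <- translate_from(seq, s, human_protein_len)
    if (is.null(best) || nchar(rep$protein) > nchar(best$protein)) best <- rep
  }
  best
}

disruption_event <- function(kind, column, detail) {
  tibble::tibble(kind = kind, column = as.integer(column), detail = detail)
}

no_events <- function() {
  tibble::tibble(kind = character(), column = integer(), detail = character())
}

# Explanatory annotations: how the taxon row differs from the human row in
# the human codon frame. The translation verdict, not this list, decides the
# final status.
collect_disruption_events <- function(trio, taxon) {
  h <- alignment_chars(trio$rows[["human"]])
  t <- alignment_chars(trio$rows[[taxon]])
  cds_cols <- human_cds_columns(trio)
  span <- trio$start_col:cds_cols[[length(cds_cols)]]
  ev <- no_events()

  start_codon <- paste(t[trio$start_col + 1:3], collapse = "")
  if (start_codon != "ATG") {
    ev <- dplyr::bind_rows(ev, disruption_event(
      "missing_start", trio$start_col,
      paste0("taxon spells ", start_codon, " at the human start")))
  }

  # Indel runs inside the CDS span, relative to the human row.
  in_span <- seq(min(span) + 1L, max(span) + 1L)
  del <- t[in_span] == "-" & h[in_span] != "-"
  ins <- t[in_span] != "-" & h[in_span] == "-"
  for (kind in c("del", "ins")) {
    r <- rle(if (kind == "del") del else ins)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    for (i in which(r$values)) {
      len <- r$lengths[[i]]
      if (len %% 3L != 0L) {
        ev <- dplyr::bind_rows(ev, disruption_event(
          "frameshift_indel", min(span) + starts[[i]] - 1L,
          sprintf("%s of %d nt (not a multiple of 3)",
                  if (kind == "del") "deletion" else "insertion", len)))
      }
    }
  }

  # Premature stops read in the human codon frame (terminal codon excluded).
  n_codons <- length(cds_cols) %/% 3L
  for (ci in seq_len(n_codons - 1L)) {
    cols <- cds_cols[(3L * ci - 2L):(3L * ci)]
    codon <- paste(t[cols + 1L], collapse = "")
    if (is_stop_codon(codon) && ci > 1L) {
      ev <- dplyr::bind_rows(ev, disruption_event(
        "premature_stop", cols[[1L]],
        sprintf("%s at human codon %d", codon, ci - 1L)))
    }
  }
  ev
}

#' Assess whether an ortholog's reading frame is disrupted
#'
#' Implements the screen's core criterion: the candidate must be
#' non-translatable in the outgroup. The taxon row is degapped and first
#' translated from the position homologous to the human ATG; if no ATG sits
#' there, the whole provided region is searched for alternative starts
#' ([scan_orf()] with `policy = "rescue"`). The ortholog is `disrupted` when
#' no complete ORF is found or the predicted protein is shorter than
#' `intact_fraction` (default 80%) of the human protein; a complete ORF at or
#' above that fraction is `intact_enough` (the gene is then discarded as a
#' candidate) or `intact` when the row shows no disruption events at all.
#'
#' @param trio A [trio_alignment()].
#' @param taxon `"chimp"` or `"orang"`.
#' @param thresholds A [screen_thresholds()] object (or named list).
#' @return An `ortholog_status`: list with `taxon`, `status`, `events`
#'   (tibble of explanatory disruption events), and `orf` (the decisive
#'   `orf_report`).
#' @export
assess_ortholog <- function(trio, taxon = c("chimp", "orang"), thresholds = NULL) {
  taxon <- match.arg(taxon)
  th <- as_thresholds(thresholds)
  row <- trio$rows[[taxon]]
  cds_cols <- human_cds_columns(trio)
  tchars <- alignment_chars(row)
  if (all(tchars[cds_cols + 1L] == "-")) {
    stop("ortholog region absent: ", taxon, " row entirely gapped within the ",
         "human CDS span of gene ", trio$gene_id, call. = FALSE)
  }
  hlen <- human_protein_length(trio)
  seq <- degap(row)
  anchor <- column_to_position(row, trio$start_col)
  orf <- scan_orf(seq, anchor = anchor, policy = "anchored",
                  human_protein_len = hlen)
  if (!orf$complete && is.na(orf$start_pos)) {
    orf <- scan_orf(seq, policy = "rescue", human_protein_len = hlen)
  }
  events <- collect_disruption_events(trio, taxon)
  if (!orf$complete && !is.na(orf$start_pos)) {
    events <- dplyr::bind_rows(events, disruption_event(
      "no_stop", NA_integer_, "translation runs off the provided region"))
  }
  status <- if (!orf$complete || orf$length_fraction < th$intact_fraction) {
    "disrupted"
  } else if (nrow(events) == 0L) {
    "intact"
  } else {
    "intact_enough"
  }
  structure(list(taxon = taxon, status = status, events = events, orf = orf),
            class = "ortholog_status")
}

#' @export
print.ortholog_status <- function(x, ...) {
  cat("<ortholog_status> ", x$taxon, ": ", x$status, sep = "")
  if (nrow(x$events) > 0) {
    cat("  [", paste(x$events$kind, collapse = ", "), "]", sep = "")
  }
  cat("\n")
  print(x$orf)
  invisible(x)
}
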