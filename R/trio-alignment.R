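#' Gapped coding-region trio alignment
#'
#' The central data record of the screen: one candidate coding region aligned
#' across human, chimpanzee, and orangutan, with the human start and stop
#' codons anchored to alignment columns. All coordinates are 0-based and
#' columns are the primary frame; sequences must already be on the coding
#' strand.
#'
#' @param gene_id Gene identifier.
#' @param human,chimp,orang Aligned nucleotide strings over `A C G T N -`,
#'   all of identical length.
#' @param start_col 0-based alignment column of the first base of the
#'   annotated human ATG.
#' @param stop_col 0-based alignment column of the first base of the human
#'   stop codon.
#' @param validate If `TRUE` (default) enforce all invariants: equal row
#'   lengths of at least 6, an ungapped ATG at the start columns, and a human
#'   coding subsequence of length divisible by three ending in a stop codon.
#'   `validate = FALSE` builds the record unchecked, which is useful for
#'   exercising the screen's own rejection stages.
#'
#' @return An object of class `"trio_alignment"`.
#' @examples
#' trio_alignment("g1", "ATGAAATAA", "ATGAAATAA", "ATGAAATAA", 0, 6)
#' @export
trio_alignment <- function(gene_id, human, chimp, orang, start_col, stop_col,
                           validate = TRUE) {
  rows <- c(human = toupper(human), chimp = toupper(chimp), orang = toupper(orang))
  x <- structure(
    list(gene_id = as.character(gene_id), rows = rows,
         start_col = as.integer(start_col), stop_col = as.integer(stop_col)),
    class = "trio_alignment"
  )
  if (validate) validate_trio(x)
  x
}

validate_trio <- function(x) {
  lens <- nchar(x$rows)
  if (length(unique(lens)) != 1L) {
    stop("unequal alignment lengths in gene ", x$gene_id, ": ",
         paste(names(x$rows), lens, sep = "=", collapse = ", "), call. = FALSE)
  }
  if (lens[[1]] < 6L) {
    stop("alignment for gene ", x$gene_id, " is shorter than 6 columns", call. = FALSE)
  }
  for (tx in names(x$rows)) {
    bad <- stringr::str_locate(x$rows[[tx]], "[^ACGTN-]")[1, "start"]
    if (!is.na(bad)) {
      stop("non-nucleotide character in record ", tx, " of gene ", x$gene_id,
           " at column ", bad - 1L, call. = FALSE)
    }
  }
  if (x$start_col < 0L || x$stop_col + 2L >= lens[[1]]) {
    stop("start/stop columns outside the alignment for gene ", x$gene_id, call. = FALSE)
  }
  start_codon <- substr(x$rows[["human"]], x$start_col + 1L, x$start_col + 3L)
  if (grepl("-", start_codon, fixed = TRUE)) {
    stop("human start columns are gapped in gene ", x$gene_id, call. = FALSE)
  }
  if (start_codon != "ATG") {
    stop("human start is not ATG in gene ", x$gene_id,
         " (found ", start_codon, ")", call. = FALSE)
  }
  cds <- human_cds_columns(x)
  if (length(cds) %% 3L != 0L) {
    stop("human coding subsequence length not divisible by 3 in gene ",
         x$gene_id, call. = FALSE)
  }
  hchars <- alignment_chars(x$rows[["human"]])
  last_codon <- paste(hchars[cds[(length(cds) - 2L):length(cds)] + 1L], collapse = "")
  if (!last_codon %in% STOP_CODONS) {
    stop("human coding subsequence does not end in a stop codon in gene ",
         x$gene_id, " (found ", last_codon, ")", call. = FALSE)
  }
  invisible(x)
}

#' @export
print.trio_alignment <- function(x, ...) {
  cat("<trio_alignment> ", x$gene_id,
      "  (", nchar(x$rows[[1]]), " columns, start_col=", x$start_col,
      ", stop_col=", x$stop_col, ")\n", sep = "")
  w <- min(60L, nchar(x$rows[[1]]))
  for (tx in names(x$rows)) {
    cat(sprintf("  %-6s %s%s\n", tx, substr(x$rows[[tx]], 1, w),
                if (nchar(x$rows[[tx]]) > w) "..." else ""))
  }
  invisible(x)
}

alignment_chars <- function(row) strsplit(row, "", fixed = TRUE)[[1]]

#' Map alignment columns to ungapped positions
#'
#' For one aligned row, returns the bidirectional correspondence between
#' 0-based alignment columns and 0-based positions in the degapped sequence.
#' The map covers exactly the non-gap columns.
#'
#' @param row An aligned sequence string (may contain `-`).
#' @return A tibble with columns `column` and `position`, one row per
#'   non-gap character, both 0-based.
#' @examples
#' ungapped_map("A-CG")
#' @export
ungapped_map <- function(row) {
  stopifnot(nchar(row) > 0L)
  ch <- alignment_chars(row)
  cols <- which(ch != "-") - 1L
  tibble::tibble(column = cols, position = seq_along(cols) - 1L)
}

# 0-based ungapped position of the character at (or, for a gapped column, the
# next non-gap character after) `col` in `row`; NA when the row is gapped at
# `col` and gap_ok is FALSE.
column_to_position <- function(row, col, gap_ok = TRUE) {
  ch <- alignment_chars(row)
  if (col >= length(ch)) return(NA_integer_)
  before <- sum(ch[seq_len(col)] != "-")
  if (ch[[col + 1L]] == "-" && !gap_ok) return(NA_integer_)
  before
}

degap <- function(row) gsub("-", "", row, fixed = TRUE)

# Non-gap human columns (0-based) from the start codon through the final base
# of the annotated stop codon.
human_cds_columns <- function(trio) {
  ch <- alignment_chars(trio$rows[["human"]])
  nongap <- which(ch != "-") - 1L
  from <- nongap[nongap >= trio$start_col]
  i <- match(trio$stop_col, from)
  if (is.na(i)) {
    stop("human stop column is gapped or precedes the start in gene ",
         trio$gene_id, call. = FALSE)
  }
  if (i + 2L > length(from)) {
    stop("human stop codon truncated by the alignment in gene ",
         trio$gene_id, call. = FALSE)
  }
  from[seq_len(i + 2L)]
}

# Human protein length in amino acids (stop codon excluded).
human_protein_length <- function(trio) {
  length(human_cds_columns(trio)) %/% 3L - 1L
}

TAXON_ALIASES <- list(
  human = c("human", "hsapiens", "homo_sapiens", "hg"),
  chimp = c("chimp", "chimpanzee", "ptroglodytes", "pan_troglodytes", "pt"),
  orang = c("orang", "orangutan", "pabelii", "pongo", "po")
)

match_taxon <- function(label) {
  lab <- tolower(label)
  for (tx in names(TAXON_ALIASES)) {
    if (any(vapply(TAXON_ALIASES[[tx]], grepl, logical(1), x = lab, fixed = TRUE))) {
      return(tx)
    }
  }
  NA_character_
}

#' Read a trio alignment from gapped multi-FASTA
#'
#' Expects exactly three records whose headers identify the gene and taxon as
#' `gene_id|taxon`, with the human start/stop anchor columns supplied either
#' as `start_col=` / `stop_col=` key=value tokens on the human header or
#' through `anchors`, a data frame with columns `gene_id`, `start_col`,
#' `stop_col` (the sidecar-TSV form).
#'
#' @param path Path to a gapped multi-FASTA file.
#' @param anchors Optional data frame of anchor columns per gene.
#' @param validate Passed through to [trio_alignment()].
#' @return A [trio_alignment()] object.
#' @export
read_trio_alignment <- function(path, anchors = NULL, validate = TRUE) {
  seqs <- Biostrings::readBStringSet(path)
  if (length(seqs) != 3L) {
    stop("expected exactly 3 FASTA records, found ", length(seqs), call. = FALSE)
  }
  headers <- names(seqs)
  fields <- strsplit(headers, "[| ]+")
  gene_id <- fields[[1]][1]
  taxa <- vapply(headers, match_taxon, character(1), USE.NAMES = FALSE)
  if (anyNA(taxa)) {
    stop("missing taxon: could not recognize taxon in header(s) ",
         paste(shQuote(headers[is.na(taxa)]), collapse = ", "), call. = FALSE)
  }
  if (!setequal(taxa, c("human", "chimp", "orang"))) {
    stop("missing taxon: need one each of human, chimp, orang; found ",
         paste(taxa, collapse = ", "), call. = FALSE)
  }
  rows <- stats::setNames(as.character(seqs), taxa)

  token <- function(hdr, key) {
    m <- stringr::str_match(hdr, paste0(key, "=(\\d+)"))[, 2]
    if (is.na(m)) NA_integer_ else as.integer(m)
  }
  hhdr <- headers[taxa == "human"]
  start_col <- token(hhdr, "start_col")
  stop_col <- token(hhdr, "stop_col")
  if ((is.na(start_col) || is.na(stop_col)) && !is.null(anchors)) {
    row <- anchors[anchors$gene_id == gene_id, , drop = FALSE]
    if (nrow(row) == 1L) {
      start_col <- as.integer(row$start_col)
      stop_col <- as.integer(row$stop_col)
    }
  }
  if (is.na(start_col) || is.na(stop_col)) {
    stop("no start/stop anchors found for gene ", gene_id,
         " (neither header tokens nor sidecar anchors)", call. = FALSE)
  }
  trio_alignment(gene_id, rows[["human"]], rows[["chimp"]], rows[["orang"]],
                 start_col, stop_col, validate = validate)
}

#' Write a trio alignment as gapped multi-FASTA
#'
#' The inverse of [read_trio_alignment()]: headers carry `gene_id|taxon` plus
#' `start_col=`/`stop_col=` tokens on the human record, so a write/read
#' round trip reproduces the object exactly.
#'
#' @param trio A [trio_alignment()] object.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_trio_alignment <- function(trio, path) {
  hdr <- vapply(names(trio$rows), function(tx) {
    if (tx == "human") {
      sprintf("%s|%s start_col=%d stop_col=%d", trio$gene_id, tx,
              trio$start_col, trio$stop_col)
    } else {
      sprintf("%s|%s", trio$gene_id, tx)
    }
  }, character(1))
  lines <- as.vector(rbind(paste0(">", hdr), unname(trio$rows)))
  writeLines(lines, path)
  invisible(path)
}

EVIDENCE_COLUMNS <- c("gene_id", "has_mrna", "has_est", "has_peptide",
                      "single_copy_human", "single_copy_outgroups",
                      "disrupting_snp")

#' Read a per-gene evidence table
#'
#' The evidence table stands in for external-database lookups: mRNA and EST
#' hits (transcription), proteomics peptide hits (translation), single-copy
#' flags in human and the outgroups, and a known ORF-disrupting polymorphism.
#'
#' @param path TSV file with header exactly
#'   `gene_id, has_mrna, has_est, has_peptide, single_copy_human,
#'   single_copy_outgroups, disrupting_snp` and 0/1 values.
#' @return A tibble with `gene_id` and six logical flag columns.
#' @export
read_evidence <- function(path) {
  ev <- readr::read_tsv(path, show_col_types = FALSE)
  if (!identical(names(ev), EVIDENCE_COLUMNS)) {
    stop("evidence table header must be exactly: ",
         paste(EVIDENCE_COLUMNS, collapse = ", "), call. = FALSE)
  }
  validate_evidence(dplyr::mutate(
    ev, dplyr::across(-"gene_id", ~ as.logical(as.integer(.x)))
  ))
}

validate_evidence <- function(ev) {
  ev <- tibble::as_tibble(ev)
  missing <- setdiff(EVIDENCE_COLUMNS, names(ev))
  if (length(missing) > 0) {
    stop("evidence table lacks column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  ev <- ev[EVIDENCE_COLUMNS]
  if (anyDuplicated(ev$gene_id)) {
    stop("evidence table has duplicated gene_id(s)", call. = FALSE)
  }
  flags <- ev[setdiff(EVIDENCE_COLUMNS, "gene_id")]
  if (!all(vapply(flags, is.logical, logical(1))) || anyNA(flags)) {
    stop("evidence flags must be strictly boolean (0/1, no missing values)",
         call. = FALSE)
  }
  ev
}

#' Construct an evidence record
#'
#' @param gene_id Gene identifier.
#' @param has_mrna,has_est,has_peptide,single_copy_human,single_copy_outgroups,disrupting_snp
#'   Logical flags; defaults describe a fully supported single-copy gene with
#'   no disrupting polymorphism.
#' @return A one-row tibble in evidence-table layout.
#' @export
evidence_record <- function(gene_id, has_mrna = TRUE, has_est = TRUE,
                            has_peptide = TRUE, single_copy_human = TRUE,
                            single_copy_outgroups = TRUE,
                            disrupting_snp = FALSE) {
  validate_evidence(tibble::tibble(
    gene_id = as.character(gene_id), has_mrna = has_mrna, has_est = has_est,
    has_peptide = has_peptide, single_copy_human = single_copy_human,
    single_copy_outgroups = single_copy_outgroups,
    disrupting_snp = disrupting_snp
  ))
}
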