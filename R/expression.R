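#' Count unique-mapping reads overlapping a coding region
#'
#' Only reads that map to a single genomic location are counted; a placement
#' contributes if it overlaps the coding interval by at least one
#' nucleotide. Intervals are 0-based, half-open.
#'
#' @param reads A data frame of placements with columns `chrom`, `start`,
#'   `end`, and `unique` (logical or 0/1); extra BED columns (`name`,
#'   `score`, `strand`) are ignored.
#' @param chrom Chromosome of the coding region.
#' @param cds_start,cds_end 0-based half-open bounds of the coding region.
#' @return Integer count.
#' @export
count_unique_reads <- function(reads, chrom, cds_start, cds_end) {
  if (cds_end <= cds_start) {
    stop("malformed interval: end (", cds_end, ") <= start (", cds_start, ")",
         call. = FALSE)
  }
  reads <- tibble::as_tibble(reads)
  stopifnot(all(c("chrom", "start", "end", "unique") %in% names(reads)))
  if (any(reads$end <= reads$start)) {
    stop("malformed read interval(s): end <= start", call. = FALSE)
  }
  sum(as.logical(reads$unique) & reads$chrom == chrom &
        reads$start < cds_end & reads$end > cds_start)
}

#' Assemble a gene-by-tissue expression matrix
#'
#' Collects unique-read counts over coding regions together with the per-gene
#' coding lengths and per-tissue total valid read counts needed for the two
#' expression levels used throughout: the raw read density `U/L`
#' (reads per coding nucleotide) and the normalized level `(U/L)/V`
#' (additionally divided by the tissue's library size, conventionally
#' displayed on a 1e-8 scale).
#'
#' @param counts Long data frame with columns `gene_id`, `tissue`,
#'   `unique_reads` (nonnegative integers). Missing gene-tissue pairs are
#'   treated as zero.
#' @param lengths Data frame with columns `gene_id`, `coding_length` (nt).
#' @param libsizes Data frame with columns `tissue`, `valid_reads`.
#' @return An object of class `"expression_matrix"`: a list with the
#'   completed long `counts` tibble (including `raw_level` and `norm_level`
#'   columns), `lengths`, and `libsizes`. Tissue order follows `libsizes`.
#' @export
build_expression_matrix <- function(counts, lengths, libsizes) {
  counts <- tibble::as_tibble(counts)
  lengths <- tibble::as_tibble(lengths)
  libsizes <- tibble::as_tibble(libsizes)
  stopifnot(all(c("gene_id", "tissue", "unique_reads") %in% names(counts)),
            all(c("gene_id", "coding_length") %in% names(lengths)),
            all(c("tissue", "valid_reads") %in% names(libsizes)))
  if (any(counts$unique_reads < 0) || any(counts$unique_reads != round(counts$unique_reads))) {
    stop("unique_reads must be nonnegative integers", call. = FALSE)
  }
  if (any(lengths$coding_length <= 0)) stop("coding lengths must be positive", call. = FALSE)
  if (any(libsizes$valid_reads <= 0)) stop("library sizes must be positive", call. = FALSE)
  missing_lib <- setdiff(unique(counts$tissue), libsizes$tissue)
  if (length(missing_lib) > 0) {
    stop("missing library size for tissue(s): ",
         paste(missing_lib, collapse = ", "), call. = FALSE)
  }
  missing_len <- setdiff(unique(counts$gene_id), lengths$gene_id)
  if (length(missing_len) > 0) {
    stop("missing coding length for gene(s): ",
         paste(missing_len, collapse = ", "), call. = FALSE)
  }
  genes <- unique(lengths$gene_id)
  full <- tidyr::expand_grid(gene_id = genes, tissue = libsizes$tissue) |>
    dplyr::left_join(counts, by = c("gene_id", "tissue")) |>
    dplyr::mutate(unique_reads = dplyr::coalesce(.data$unique_reads, 0L)) |>
    dplyr::left_join(lengths, by = "gene_id") |>
    dplyr::left_join(libsizes, by = "tissue") |>
    dplyr::mutate(
      raw_level = .data$unique_reads / .data$coding_length,
      norm_level = .data$raw_level / .data$valid_reads
    )
  structure(list(counts = full, lengths = lengths, libsizes = libsizes),
            class = "expression_matrix")
}

#' @export
print.expression_matrix <- function(x, ...) {
  cat("<expression_matrix> ", nrow(x$lengths), " genes x ",
      nrow(x$libsizes), " tissues\n", sep = "")
  print(utils::head(x$counts, 6))
  invisible(x)
}

#' Per-tissue expression summary
#'
#' Computes, for each tissue: the pooled read density (all unique reads over
#' all coding nucleotides, `sum(U)/sum(L)`), its library-size-normalized form
#' `(sum(U)/sum(L))/V` (also given on the conventional 1e-8 display scale),
#' the mean of per-gene densities, the proportion of genes with any mapped
#' read, and the proportion of expressed genes whose highest normalized
#' level falls in the tissue (ties broken by the fixed alphabetical tissue
#' order; genes with no reads anywhere are excluded from this denominator
#' but retained in `proportion_expressed`). When a genome-wide background
#' matrix is supplied, each statistic is also reported as a ratio to its
#' background counterpart.
#'
#' @param m An [build_expression_matrix()] object for the gene set.
#' @param background Optional `expression_matrix` over the same tissues
#'   (e.g. genome-wide genes) for background normalization.
#' @param thresholds A [screen_thresholds()] object; `norm_scale` sets the
#'   display multiplier.
#' @return A tibble of class `"tissue_summary"`, one row per tissue, with a
#'   per-gene tissue-rank table (which tissue holds each expressed gene's
#'   1st, 2nd, ... highest normalized level) in attribute `"ranks"`.
#' @export
summarize_tissues <- function(m, background = NULL, thresholds = NULL) {
  th <- as_thresholds(thresholds)
  stopifnot(inherits(m, "expression_matrix"))
  if (nrow(m$lengths) < 1L || nrow(m$libsizes) < 1L) {
    stop("need at least one gene and one tissue", call. = FALSE)
  }
  smry <- tissue_stats(m, th)
  if (!is.null(background)) {
    stopifnot(inherits(background, "expression_matrix"))
    if (!setequal(background$libsizes$tissue, m$libsizes$tissue)) {
      stop("background tissue set does not match", call. = FALSE)
    }
    bg <- tissue_stats(background, th)
    ratio_cols <- c("pooled_mean", "pooled_norm", "mean_density",
                    "proportion_expressed", "proportion_highest")
    bgr <- bg |>
      dplyr::select("tissue", dplyr::all_of(ratio_cols)) |>
      dplyr::rename_with(~ paste0("bg_", .x), -"tissue")
    smry <- dplyr::left_join(smry, bgr, by = "tissue")
    for (col in ratio_cols) {
      smry[[paste0("ratio_", col)]] <- smry[[col]] / smry[[paste0("bg_", col)]]
    }
  }
  attr(smry, "ranks") <- gene_tissue_ranks(m)
  class(smry) <- c("tissue_summary", class(smry))
  smry
}

tissue_stats <- function(m, th) {
  total_len <- sum(m$lengths$coding_length)
  n_genes <- nrow(m$lengths)
  expressed_anywhere <- m$counts |>
    dplyr::group_by(.data$gene_id) |>
    dplyr::summarise(any_expr = sum(.data$unique_reads) > 0) |>
    dplyr::filter(.data$any_expr)
  n_expressed <- nrow(expressed_anywhere)
  ranks <- gene_tissue_ranks(m)
  top <- ranks |> dplyr::filter(.data$rank == 1L) |> dplyr::count(.data$tissue)
  m$counts |>
    dplyr::group_by(.data$tissue) |>
    dplyr::summarise(
      valid_reads = .data$valid_reads[[1L]],
      total_unique_reads = sum(.data$unique_reads),
      pooled_mean = sum(.data$unique_reads) / total_len,
      mean_density = mean(.data$raw_level),
      proportion_expressed = sum(.data$unique_reads > 0) / n_genes
    ) |>
    dplyr::mutate(
      pooled_norm = .data$pooled_mean / .data$valid_reads,
      pooled_norm_scaled = .data$pooled_norm * th$norm_scale
    ) |>
    dplyr::left_join(top, by = "tissue") |>
    dplyr::mutate(
      proportion_highest = if (n_expressed > 0) {
        dplyr::coalesce(.data$n, 0L) / n_expressed
      } else {
        NA_real_
      }
    ) |>
    dplyr::select(-"n") |>
    dplyr::arrange(match(.data$tissue, m$libsizes$tissue))
}

# For each gene with any mapped read, order tissues by normalized level
# (highest first); ties broken by alphabetical tissue name.
gene_tissue_ranks <- function(m) {
  m$counts |>
    dplyr::group_by(.data$gene_id) |>
    dplyr::filter(sum(.data$unique_reads) > 0) |>
    dplyr::arrange(dplyr::desc(.data$norm_level), .data$tissue,
                   .by_group = TRUE) |>
    dplyr::mutate(rank = dplyr::row_number()) |>
    dplyr::ungroup() |>
    dplyr::select("gene_id", "tissue", "norm_level", "rank")
}

#' Proportion of genes with k-th highest expression per tissue
#'
#' From a [summarize_tissues()] result, the fraction of expressed genes
#' whose k-th highest normalized level falls in each tissue.
#'
#' @param smry A `tissue_summary`.
#' @param k Rank (1 = highest).
#' @return A tibble: `tissue`, `proportion`.
#' @export
proportion_kth_highest <- function(smry, k = 1L) {
  ranks <- attr(smry, "ranks")
  n_expressed <- dplyr::n_distinct(ranks$gene_id)
  tibble::tibble(tissue = smry$tissue) |>
    dplyr::left_join(
      ranks |> dplyr::filter(.data$rank == k) |> dplyr::count(.data$tissue),
      by = "tissue") |>
    dplyr::mutate(proportion = dplyr::coalesce(.data$n, 0L) / n_expressed) |>
    dplyr::select("tissue", "proportion")
}

#' Read a 6-column BED of read placements
#'
#' Uniqueness is taken from a 7th column (`unique`, 0/1) when present,
#' otherwise from a `|unique` / `|multi` suffix on the name field.
#'
#' @param path BED file path.
#' @return Tibble with `chrom`, `start`, `end`, `name`, `score`, `strand`,
#'   `unique`.
#' @export
read_bed_reads <- function(path) {
  bed <- readr::read_tsv(path, col_names = FALSE, show_col_types = FALSE)
  if (ncol(bed) < 6L) stop("expected at least 6 BED columns", call. = FALSE)
  names(bed)[1:6] <- c("chrom", "start", "end", "name", "score", "strand")
  bed$unique <- if (ncol(bed) >= 7L) {
    as.logical(as.integer(bed[[7L]]))
  } else {
    !grepl("\\|multi$", bed$name)
  }
  tibble::as_tibble(bed[c("chrom", "start", "end", "name", "score", "strand", "unique")])
}
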