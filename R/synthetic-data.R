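SCENARIO_KINDS <- c(
  "de_novo_stop_removal", "de_novo_start_creation", "de_novo_frame_completion",
  "parallel_loss", "ancestrally_intact", "alt_start_rescue",
  "intact_enough_85pct", "shared_human_chimp_gain"
)

# The 11-tissue RNA-seq panel used as the default fixture tissue list.
DEFAULT_TISSUES <- c(
  "adipose", "whole_brain", "cerebral_cortex", "breast", "colon", "heart",
  "liver", "lymph_node", "skeletal_muscle", "lung", "testes"
)

# Run expr under a private RNG stream seeded with `seed`, restoring any
# pre-existing global RNG state afterwards: generators are pure functions of
# their seed and never perturb the caller's stream.
with_rng <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv(), inherits = FALSE)
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}

NONSTOP_CODONS <- local({
  all64 <- as.vector(outer(outer(BASES, BASES, paste0), BASES, paste0))
  setdiff(all64, STOP_CODONS)
})

# Random coding sequence: ATG, n_codons-2 non-stop codons, one stop codon.
# With avoid_internal_atg, every ATG occurrence beyond position 0 (in any
# frame) is destroyed by a T->C substitution; substituting C can create
# neither a stop codon nor a new ATG.
random_cds <- function(n_codons, avoid_internal_atg = FALSE) {
  body <- paste(sample(NONSTOP_CODONS, n_codons - 2L, replace = TRUE),
                collapse = "")
  seq <- paste0("ATG", body, sample(STOP_CODONS, 1L))
  if (avoid_internal_atg) {
    # Any internal ATG necessarily starts inside the body (it cannot begin
    # within the ATG start or the terminal stop), so mutating its leading A
    # to C stays clear of the anchors and can create neither a new ATG nor a
    # stop codon.
    repeat {
      pos <- atg_positions(seq)
      pos <- pos[pos > 0L]
      if (length(pos) == 0L) break
      substr(seq, pos[[1L]] + 1L, pos[[1L]] + 1L) <- "C"
    }
  }
  seq
}

set_codon <- function(seq, codon_index, value) {
  # codon_index is 0-based (0 = start codon)
  substr(seq, 3L * codon_index + 1L, 3L * codon_index + 3L) <- value
  seq
}

get_codon <- function(seq, codon_index) {
  substr(seq, 3L * codon_index + 1L, 3L * codon_index + 3L)
}

#' Generate a labeled trio-alignment scenario
#'
#' Constructs a human/chimp/orang alignment that plants one of eight
#' screening situations with known ground truth, together with an evidence
#' record and the expected verdict. Positive kinds plant a single
#' human-specific enabling change (an ancestral in-frame stop reverted, a
#' start codon created, or a frame-restoring 1-nt insertion) whose reversion
#' demonstrably disrupts the ORF; negative kinds realize the screen's
#' designed rejections (parallel loss with unpolarizable states, intact
#' ancestors, alternative-start rescue in the outgroups, a premature stop
#' that still leaves at least 80% of the protein, and a gain shared with
#' chimpanzee that predates the split). Every emitted scenario is
#' self-checked through [classify_candidate()]; generation fails rather than
#' return a mislabeled case.
#'
#' @param kind One of `r paste0('"', SCENARIO_KINDS, '"', collapse = ", ")`.
#' @param n_codons Human CDS length in codons, stop included (default 150;
#'   at least 20).
#' @param seed Integer seed; the generator is a pure function of
#'   `(kind, n_codons, seed)`.
#' @param thresholds Thresholds used for the self-check classification.
#' @return A list with `trio` ([trio_alignment()]), `evidence` (one-row
#'   tibble), and `label` (list: `kind`, `expected_verdict`,
#'   `expected_stage` — the 1-based stage at which rejection is expected, or
#'   `NA` for a de novo verdict).
#' @export
generate_trio_scenario <- function(kind = SCENARIO_KINDS, n_codons = 150L,
                                   seed = 1L, thresholds = NULL) {
  kind <- match.arg(kind)
  th <- as_thresholds(thresholds)
  if (n_codons < 20L) stop("n_codons must be at least 20", call. = FALSE)
  for (attempt in seq_len(50L)) {
    sub_seed <- as.integer((abs(as.numeric(seed)) * 1009 + attempt) %% 2147483647)
    out <- with_rng(sub_seed, build_scenario(kind, n_codons, th))
    v <- classify_candidate(out$trio, out$evidence, th)
    ok <- identical(v$verdict, out$label$expected_verdict) &&
      (is.na(out$label$expected_stage) ||
         identical(first_failed_stage(v), out$label$expected_stage))
    if (ok) return(out)
  }
  stop("could not construct a self-consistent '", kind, "' scenario at ",
       n_codons, " codons (seed ", seed, ")", call. = FALSE)
}

build_scenario <- function(kind, n_codons, th) {
  n_aa <- n_codons - 1L  # human protein length
  de_novo_ok <- n_aa >= th$min_protein_aa
  gene_id <- sprintf("sim_%s_s", kind)
  label_de_novo <- list(
    kind = kind,
    expected_verdict = if (de_novo_ok) "de_novo" else "rejected",
    expected_stage = if (de_novo_ok) NA_integer_ else 2L)
  label_rejected <- function(stage) {
    # Below the protein-length floor every kind is rejected at stage 2
    # before its planted defect is ever reached.
    list(kind = kind, expected_verdict = "rejected",
         expected_stage = if (de_novo_ok) stage else 2L)
  }
  stop_pos_early <- max(2L, floor(0.4 * n_aa))      # fraction < 0.8
  stop_pos_late <- min(n_aa - 1L, ceiling(0.85 * n_aa))  # fraction >= 0.8

  human <- random_cds(n_codons, avoid_internal_atg = TRUE)
  chimp <- human
  orang <- human
  label <- NULL

  if (kind == "de_novo_stop_removal") {
    human <- set_codon(human, stop_pos_early, "TGG")
    chimp <- set_codon(chimp, stop_pos_early, "TGA")
    orang <- set_codon(orang, stop_pos_early, "TGA")
    label <- label_de_novo
  } else if (kind == "de_novo_start_creation") {
    chimp <- paste0("ATA", substr(chimp, 4L, nchar(chimp)))
    orang <- paste0("ATA", substr(orang, 4L, nchar(orang)))
    label <- label_de_novo
  } else if (kind == "de_novo_frame_completion") {
    # Human carries a 1-nt insertion absent in both outgroups; without it
    # the frame shifts and the ancestral ORF truncates or loses its stop.
    ins_at <- 3L * stop_pos_early  # column just before this codon's base
    chimp <- paste0(substr(chimp, 1L, ins_at), "-",
                    substr(chimp, ins_at + 2L, nchar(chimp)))
    orang <- chimp
    label <- label_de_novo
  } else if (kind == "parallel_loss") {
    j1 <- stop_pos_early
    j2 <- max(2L, floor(0.6 * n_aa))
    if (j2 == j1) j2 <- j1 + 1L
    human <- set_codon(human, j1, "TGG")
    human <- set_codon(human, j2, "TGG")
    chimp <- set_codon(set_codon(chimp, j1, "TGA"), j2, "TGG")
    orang <- set_codon(set_codon(orang, j1, "TGG"), j2, "TGA")
    label <- label_rejected(5L)
  } else if (kind == "ancestrally_intact") {
    label <- label_rejected(4L)
  } else if (kind == "alt_start_rescue") {
    j <- max(1L, floor(0.15 * n_aa))
    human <- set_codon(human, j, "ATG")
    chimp <- set_codon(chimp, j, "ATG")
    orang <- set_codon(orang, j, "ATG")
    chimp <- paste0("ATA", substr(chimp, 4L, nchar(chimp)))
    orang <- paste0("ATA", substr(orang, 4L, nchar(orang)))
    label <- label_rejected(4L)
  } else if (kind == "intact_enough_85pct") {
    chimp <- set_codon(chimp, stop_pos_late, "TAA")
    orang <- set_codon(orang, stop_pos_late, "TAA")
    label <- label_rejected(4L)
  } else if (kind == "shared_human_chimp_gain") {
    human <- set_codon(human, stop_pos_early, "TGG")
    chimp <- human
    orang <- set_codon(orang, stop_pos_early, "TGA")
    label <- label_rejected(4L)
  }

  # The frame-completion case needs a gapped outgroup row of equal aligned
  # length; all other cases are ungapped and already equal.
  if (kind == "de_novo_frame_completion") {
    n_align <- nchar(human)
    stopifnot(nchar(chimp) == n_align, nchar(orang) == n_align)
  }
  trio <- trio_alignment(gene_id, human, chimp, orang,
                         start_col = 0L, stop_col = nchar(human) - 3L)
  list(trio = trio, evidence = evidence_record(gene_id), label = label)
}

#' Generate a batch of labeled scenarios
#'
#' Convenience wrapper cycling over all scenario kinds with per-scenario
#' sub-seeds; gene ids are made unique.
#'
#' @param n Total number of scenarios.
#' @param kinds Scenario kinds to cycle through (default all eight).
#' @param n_codons Human CDS length in codons.
#' @param seed Master seed.
#' @param thresholds Thresholds for generator self-checks.
#' @return A tibble with columns `gene_id`, `kind`, `expected_verdict`,
#'   `expected_stage`, and list-columns `alignment`, `evidence`.
#' @export
generate_scenario_batch <- function(n, kinds = SCENARIO_KINDS,
                                    n_codons = 150L, seed = 1L,
                                    thresholds = NULL) {
  purrr::map_dfr(seq_len(n), function(i) {
    kind <- kinds[[(i - 1L) %% length(kinds) + 1L]]
    sc <- generate_trio_scenario(
      kind, n_codons = n_codons,
      seed = as.integer((abs(as.numeric(seed)) * 7919 + i) %% 2147483647),
      thresholds = thresholds)
    gene_id <- sprintf("%s_%03d", kind, i)
    sc$trio$gene_id <- gene_id
    sc$evidence$gene_id <- gene_id
    tibble::tibble(
      gene_id = gene_id, kind = kind,
      expected_verdict = sc$label$expected_verdict,
      expected_stage = sc$label$expected_stage,
      alignment = list(sc$trio), evidence = list(sc$evidence))
  })
}

#' Simulate trio sequences under HKY85
#'
#' Evolves an ancestral sequence independently along the three terminal
#' branches of the star tree using exact HKY85 transition probabilities
#' (matrix exponential per branch), optionally placing indels whose true
#' alignment is retained by construction.
#'
#' @param t_human,t_chimp,t_orang Branch lengths in substitutions/site.
#' @param kappa Transition/transversion rate ratio.
#' @param base_freqs Equilibrium base frequencies (A, C, G, T).
#' @param length_nt Ancestral sequence length (at least 300).
#' @param seed Integer seed.
#' @param indel_rate Expected indel events per site per branch (default 0;
#'   rate-fitting fixtures are gap-free since gapped columns are dropped
#'   before fitting anyway).
#' @param indel_len_p Geometric length parameter for indels (mean length
#'   `1/indel_len_p`).
#' @return A list with `rows` (named aligned strings `human`, `chimp`,
#'   `orang`) and `truth` (the simulation parameters).
#' @export
simulate_hky85 <- function(t_human = 0.02, t_chimp = 0.03, t_orang = 0.05,
                           kappa = 4, base_freqs = rep(0.25, 4),
                           length_nt = 1000L, seed = 1L, indel_rate = 0,
                           indel_len_p = 0.5) {
  if (length_nt < 300L) stop("length_nt must be at least 300", call. = FALSE)
  if (any(base_freqs <= 0)) stop("degenerate base frequencies", call. = FALSE)
  base_freqs <- base_freqs / sum(base_freqs)
  with_rng(seed, {
    anc <- sample.int(4L, length_nt, replace = TRUE, prob = base_freqs)
    evolve <- function(t) {
      P <- hky_transition_probs(t, kappa, base_freqs)
      child <- integer(length_nt)
      for (b in 1:4) {
        idx <- which(anc == b)
        if (length(idx) > 0) {
          child[idx] <- sample.int(4L, length(idx), replace = TRUE, prob = P[b, ])
        }
      }
      child
    }
    taxa <- list(human = evolve(t_human), chimp = evolve(t_chimp),
                 orang = evolve(t_orang))

    if (indel_rate > 0) {
      # Per taxon: deleted ancestral positions, and strings inserted after
      # each ancestral position. The true alignment is rebuilt column-wise.
      dels <- list(human = integer(0), chimp = integer(0), orang = integer(0))
      inss <- list(human = list(), chimp = list(), orang = list())
      for (tx in names(taxa)) {
        n_ev <- stats::rpois(1L, indel_rate * length_nt)
        for (k in seq_len(n_ev)) {
          len <- stats::rgeom(1L, indel_len_p) + 1L
          pos <- sample.int(length_nt, 1L)
          if (stats::runif(1L) < 0.5) {
            dels[[tx]] <- union(dels[[tx]], pos:min(pos + len - 1L, length_nt))
          } else {
            ins_seq <- paste(BASES[sample.int(4L, len, replace = TRUE,
                                              prob = base_freqs)], collapse = "")
            inss[[tx]][[as.character(pos)]] <-
              paste0(ins_seq, inss[[tx]][[as.character(pos)]] %||% "")
          }
        }
      }
      cols <- character(0)
      rows <- list(human = character(0), chimp = character(0), orang = character(0))
      push <- function(h, c_, o) {
        rows$human <<- c(rows$human, h)
        rows$chimp <<- c(rows$chimp, c_)
        rows$orang <<- c(rows$orang, o)
      }
      for (i in seq_len(length_nt)) {
        push(
          if (i %in% dels$human) "-" else BASES[taxa$human[[i]]],
          if (i %in% dels$chimp) "-" else BASES[taxa$chimp[[i]]],
          if (i %in% dels$orang) "-" else BASES[taxa$orang[[i]]]
        )
        for (tx in names(inss)) {
          ins <- inss[[tx]][[as.character(i)]]
          if (!is.null(ins)) {
            for (ch in alignment_chars(ins)) {
              push(if (tx == "human") ch else "-",
                   if (tx == "chimp") ch else "-",
                   if (tx == "orang") ch else "-")
            }
          }
        }
      }
      rows <- vapply(rows, paste, character(1), collapse = "")
    } else {
      rows <- vapply(taxa, function(v) paste(BASES[v], collapse = ""), character(1))
    }
    list(
      rows = rows,
      truth = list(t_human = t_human, t_chimp = t_chimp, t_orang = t_orang,
                   kappa = kappa, base_freqs = base_freqs,
                   length_nt = length_nt, seed = seed)
    )
  })
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Simulate unique-read counts over coding regions
#'
#' Draws gene-by-tissue unique-read counts from a Poisson law at the given
#' expected counts, returning the inputs an expression analysis needs plus
#' the generating truth. Defaults emulate the study conditions the
#' expression statistics were designed for: 53 genes over the 11-tissue
#' panel, short single-exon coding regions, tens of millions of valid reads
#' per library, and a mean structure in which most genes are weakly
#' expressed with testes and cerebral cortex elevated.
#'
#' @param n_genes Number of genes (default 53).
#' @param tissues Tissue names (default: the 11-tissue panel).
#' @param mean_matrix Optional matrix (`n_genes` x tissues) of expected
#'   counts; when omitted, means are drawn as
#'   gene-baseline x tissue-multiplier (gamma baselines, testes x3 and
#'   cerebral cortex x2).
#' @param libsizes Optional numeric vector of per-tissue valid read totals
#'   (default drawn uniformly between 8e6 and 1.2e7).
#' @param coding_lengths Optional per-gene coding lengths in nt (default
#'   uniform 300-1200, multiples of 3).
#' @param seed Integer seed.
#' @param emit_reads Also emit a BED-like tibble of read placements (unique
#'   reads inside each gene's coding interval on a synthetic contig, plus
#'   multi-mapped decoys that must not be counted).
#' @return A list with `counts` (long tibble `gene_id`, `tissue`,
#'   `unique_reads`), `lengths`, `libsizes`, `truth` (the mean matrix), and
#'   optionally `reads` and `gene_intervals`.
#' @export
simulate_expression <- function(n_genes = 53L, tissues = DEFAULT_TISSUES,
                                mean_matrix = NULL, libsizes = NULL,
                                coding_lengths = NULL, seed = 1L,
                                emit_reads = FALSE) {
  with_rng(seed, {
    gene_ids <- sprintf("gene_%03d", seq_len(n_genes))
    if (is.null(coding_lengths)) {
      coding_lengths <- 3L * sample(100:400, n_genes, replace = TRUE)
    }
    if (is.null(libsizes)) {
      libsizes <- round(stats::runif(length(tissues), 8e6, 1.2e7))
    }
    if (length(libsizes) != length(tissues)) {
      stop("tissue/libsize mismatch: ", length(tissues), " tissues vs ",
           length(libsizes), " library sizes", call. = FALSE)
    }
    if (is.null(mean_matrix)) {
      baseline <- stats::rgamma(n_genes, shape = 0.6, scale = 8)
      mult <- stats::setNames(rep(1, length(tissues)), tissues)
      if ("testes" %in% tissues) mult[["testes"]] <- 3
      if ("cerebral_cortex" %in% tissues) mult[["cerebral_cortex"]] <- 2
      mean_matrix <- outer(baseline, mult)
    }
    if (any(mean_matrix < 0)) stop("expected counts must be >= 0", call. = FALSE)
    dimnames(mean_matrix) <- list(gene_ids, tissues)
    counts <- tidyr::expand_grid(gene_id = gene_ids, tissue = tissues) |>
      dplyr::mutate(
        unique_reads = stats::rpois(
          dplyr::n(), mean_matrix[cbind(.data$gene_id, .data$tissue)]))
    lengths <- tibble::tibble(gene_id = gene_ids, coding_length = coding_lengths)
    libs <- tibble::tibble(tissue = tissues, valid_reads = libsizes)
    out <- list(counts = counts, lengths = lengths, libsizes = libs,
                truth = mean_matrix)
    if (emit_reads) {
      starts <- 1000L + cumsum(c(0L, utils::head(coding_lengths + 1000L, -1L)))
      intervals <- tibble::tibble(
        gene_id = gene_ids, chrom = "chrSim", cds_start = starts,
        cds_end = starts + coding_lengths)
      read_len <- 35L
      reads <- counts |>
        dplyr::left_join(intervals, by = "gene_id") |>
        dplyr::rowwise() |>
        dplyr::mutate(placements = list({
          k <- .data$unique_reads
          if (k > 0) {
            s <- sample(seq.int(.data$cds_start - read_len + 1L,
                                .data$cds_end - 1L), k, replace = TRUE)
            tibble::tibble(start = s, end = s + read_len, unique = TRUE)
          } else {
            tibble::tibble(start = integer(0), end = integer(0),
                           unique = logical(0))
          }
        })) |>
        dplyr::ungroup() |>
        tidyr::unnest("placements") |>
        dplyr::transmute(
          chrom = .data$chrom, start = .data$start, end = .data$end,
          name = paste0(.data$gene_id, "_r"), score = 0L, strand = "+",
          unique = .data$unique, tissue = .data$tissue)
      n_decoy <- max(10L, nrow(reads) %/% 20L)
      decoys <- tibble::tibble(
        chrom = "chrSim",
        start = sample.int(max(intervals$cds_end), n_decoy, replace = TRUE),
        tissue = sample(tissues, n_decoy, replace = TRUE)
      ) |>
        dplyr::mutate(end = .data$start + read_len, name = "decoy|multi",
                      score = 0L, strand = "+", unique = FALSE) |>
        dplyr::select("chrom", "start", "end", "name", "score", "strand",
                      "unique", "tissue")
      out$reads <- dplyr::bind_rows(reads, decoys)
      out$gene_intervals <- intervals
    }
    out
  })
}
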