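# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths: plain loops, direct formulas, and brute-force
# enumeration.

GENETIC_CODE_TAB <- as.list(Biostrings::GENETIC_CODE)

oracle_translate <- function(seq, start0) {
  # start0 is 0-based; returns list(protein_len, complete, stop_pos)
  n <- nchar(seq)
  i <- start0 + 1L
  len <- 0L
  while (i + 2L <= n) {
    codon <- substr(seq, i, i + 2L)
    if (codon %in% c("TAA", "TAG", "TGA")) {
      return(list(protein_len = len, complete = TRUE, stop_pos = i - 1L))
    }
    len <- len + 1L
    i <- i + 3L
  }
  list(protein_len = len, complete = FALSE, stop_pos = NA_integer_)
}

# Exhaustive alternative-start search: try every ATG, keep the longest
# protein, ties to the smallest start.
oracle_best_orf <- function(seq) {
  best <- NULL
  n <- nchar(seq)
  for (s in seq_len(max(n - 2L, 0L))) {
    if (substr(seq, s, s + 2L) == "ATG") {
      r <- oracle_translate(seq, s - 1L)
      if (is.null(best) || r$protein_len > best$protein_len) {
        best <- c(r, list(start0 = s - 1L))
      }
    }
  }
  best
}

random_dna <- function(n) paste(sample(c("A", "C", "G", "T"), n, replace = TRUE),
                                collapse = "")

# Gotoh three-state affine DP, written independently of Biostrings: a gap
# run of length L costs gap_open + L * gap_extend.
oracle_affine_score <- function(a, b, match = 1, mismatch = -1,
                                gap_open = 4, gap_extend = 1) {
  ca <- strsplit(a, "")[[1]]
  cb <- strsplit(b, "")[[1]]
  n <- length(ca); m <- length(cb)
  NEG <- -1e9
  M <- matrix(NEG, n + 1, m + 1)  # ends in match/mismatch
  X <- matrix(NEG, n + 1, m + 1)  # ends in gap in b (a consumed)
  Y <- matrix(NEG, n + 1, m + 1)  # ends in gap in a (b consumed)
  M[1, 1] <- 0
  for (i in seq_len(n)) X[i + 1, 1] <- -(gap_open + i * gap_extend)
  for (j in seq_len(m)) Y[1, j + 1] <- -(gap_open + j * gap_extend)
  for (i in seq_len(n)) {
    for (j in seq_len(m)) {
      s <- if (ca[i] == cb[j]) match else mismatch
      M[i + 1, j + 1] <- max(M[i, j], X[i, j], Y[i, j]) + s
      X[i + 1, j + 1] <- max(M[i, j + 1] - gap_open - gap_extend,
                             X[i, j + 1] - gap_extend)
      Y[i + 1, j + 1] <- max(M[i + 1, j] - gap_open - gap_extend,
                             Y[i + 1, j] - gap_extend)
    }
  }
  max(M[n + 1, m + 1], X[n + 1, m + 1], Y[n + 1, m + 1])
}

# Direct per-window identity recount.
oracle_window_fail <- function(pa, pb, w = 5L, thr = 0.20) {
  ca <- strsplit(pa, "")[[1]]
  cb <- strsplit(pb, "")[[1]]
  for (s in seq_len(length(ca) - w + 1L)) {
    idx <- s:(s + w - 1L)
    sim <- sum(ca[idx] == cb[idx] & ca[idx] != "-") / w
    if (sim <= thr) return(s - 1L)  # 0-based failing window
  }
  NA_integer_
}

# A 150-codon trio where all three rows share the human CDS (everything
# intact), built without the package's generator.
identity_trio <- function(gene_id = "idt", n_codons = 150L, seed = 42L) {
  set.seed(seed)
  nonstop <- setdiff(
    as.vector(outer(outer(c("A", "C", "G", "T"), c("A", "C", "G", "T"), paste0),
                    c("A", "C", "G", "T"), paste0)),
    c("TAA", "TAG", "TGA"))
  nonstop <- nonstop[!grepl("ATG", nonstop)]
  cds <- paste0("ATG", paste(sample(nonstop, n_codons - 2L, replace = TRUE),
                             collapse = ""), "TAA")
  trio_alignment(gene_id, cds, cds, cds, 0L, nchar(cds) - 3L)
}

mutate_at_col <- function(row, col0, value) {
  substr(row, col0 + 1L, col0 + nchar(value)) <- value
  row
}
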