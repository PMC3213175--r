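test_that("unique-read counting respects the uniqueness flag and >=1 nt overlap", {
  reads <- tibble::tibble(
    chrom = "chr1",
    start = c(100L, 150L, 395L, 400L, 50L, 120L),
    end = c(135L, 185L, 430L, 435L, 85L, 155L),
    unique = c(TRUE, TRUE, TRUE, TRUE, TRUE, FALSE)
  )
  # CDS [100, 400): reads 1-3 overlap, read 4 starts exactly at the end,
  # read 5 ends exactly at the start, read 6 is multi-mapped
  expect_identical(count_unique_reads(reads, "chr1", 100L, 400L), 3L)
  expect_identical(count_unique_reads(reads, "chr2", 100L, 400L), 0L)
  expect_error(count_unique_reads(reads, "chr1", 400L, 100L), "malformed interval")
})

test_that("unique-read counting equals a brute-force overlap scan on random placements", {
  set.seed(81)
  reads <- tibble::tibble(
    chrom = sample(c("chr1", "chr2"), 1000, replace = TRUE),
    start = sample.int(5000L, 1000, replace = TRUE),
    unique = sample(c(TRUE, FALSE), 1000, replace = TRUE, prob = c(0.8, 0.2))
  )
  reads$end <- reads$start + sample(20:40, 1000, replace = TRUE)
  cds <- c(start = 2000L, end = 2600L)
  got <- count_unique_reads(reads, "chr1", cds[["start"]], cds[["end"]])
  want <- 0L
  for (i in seq_len(nrow(reads))) {
    if (reads$unique[[i]] && reads$chrom[[i]] == "chr1" &&
        reads$start[[i]] < cds[["end"]] && reads$end[[i]] > cds[["start"]]) {
      want <- want + 1L
    }
  }
  expect_identical(got, want)
})

test_that("raw and normalized levels follow U/L and (U/L)/V; scaling is invariant", {
  counts <- tibble::tibble(gene_id = "g", tissue = "t", unique_reads = 10L)
  lengths <- tibble::tibble(gene_id = "g", coding_length = 1000L)
  libs <- tibble::tibble(tissue = "t", valid_reads = 1e7)
  m <- build_expression_matrix(counts, lengths, libs)
  expect_equal(m$counts$raw_level, 0.01)
  expect_equal(m$counts$norm_level, 1e-9)
  # 1e-9 is 0.1 on the 1e-8 display scale
  expect_equal(m$counts$norm_level * screen_thresholds()$norm_scale, 0.1)

  # multiplying U and V of a tissue by 10 leaves normalized levels unchanged
  m10 <- build_expression_matrix(
    dplyr::mutate(counts, unique_reads = unique_reads * 10L), lengths,
    dplyr::mutate(libs, valid_reads = valid_reads * 10))
  expect_equal(m10$counts$norm_level, m$counts$norm_level)

  expect_error(
    build_expression_matrix(counts, lengths,
                            tibble::tibble(tissue = "other", valid_reads = 1)),
    "missing library size")
})

test_that("tissue summary statistics equal an independent recomputation", {
  se <- simulate_expression(n_genes = 53, seed = 82)
  m <- build_expression_matrix(se$counts, se$lengths, se$libsizes)
  smry <- summarize_tissues(m)

  # independent recount with base R from the raw inputs
  U <- stats::xtabs(unique_reads ~ gene_id + tissue, data = se$counts)
  L <- se$lengths$coding_length[match(rownames(U), se$lengths$gene_id)]
  V <- se$libsizes$valid_reads[match(colnames(U), se$libsizes$tissue)]
  norm <- sweep(sweep(U, 1, L, "/"), 2, V, "/")
  expressed <- rowSums(U) > 0

  for (j in seq_along(colnames(U))) {
    tis <- colnames(U)[[j]]
    row <- smry[smry$tissue == tis, ]
    expect_equal(row$pooled_mean, sum(U[, j]) / sum(L))
    expect_equal(row$pooled_norm, sum(U[, j]) / sum(L) / V[[j]])
    expect_equal(row$pooled_norm_scaled, row$pooled_norm * 1e8)
    expect_equal(row$mean_density, mean(U[, j] / L))
    expect_equal(row$proportion_expressed, mean(U[, j] > 0))
    # argmax tissue per expressed gene, ties to alphabetical order
    top <- apply(norm[expressed, , drop = FALSE], 1, function(x) {
      cand <- colnames(U)[x == max(x)]
      sort(cand)[[1]]
    })
    expect_equal(row$proportion_highest, mean(top == tis))
  }
  expect_equal(sum(smry$proportion_highest), 1)
})

test_that("pooled mean is sum(U)/sum(L), not the mean of per-gene ratios", {
  counts <- tibble::tibble(
    gene_id = c("a", "b"), tissue = "t", unique_reads = c(10L, 100L))
  lengths <- tibble::tibble(gene_id = c("a", "b"),
                            coding_length = c(100L, 10000L))
  libs <- tibble::tibble(tissue = "t", valid_reads = 1e6)
  smry <- summarize_tissues(build_expression_matrix(counts, lengths, libs))
  expect_equal(smry$pooled_mean, 110 / 10100)
  expect_equal(smry$mean_density, mean(c(10 / 100, 100 / 10000)))
})

test_that("proportion_highest excludes all-zero genes; ties break alphabetically", {
  counts <- tidyr::expand_grid(
    gene_id = c("g1", "g2", "g3", "g4"),
    tissue = c("cortex", "testes")) |>
    dplyr::mutate(unique_reads = c(5L, 0L, 3L, 3L, 0L, 2L, 0L, 0L))
  lengths <- tibble::tibble(gene_id = unique(counts$gene_id), coding_length = 300L)
  libs <- tibble::tibble(tissue = c("cortex", "testes"), valid_reads = 1e6)
  smry <- summarize_tissues(build_expression_matrix(counts, lengths, libs))
  # g4 is unexpressed: denominator 3; g1 -> cortex, g2 tie -> cortex, g3 -> testes
  expect_equal(smry$proportion_highest[smry$tissue == "cortex"], 2 / 3)
  expect_equal(smry$proportion_highest[smry$tissue == "testes"], 1 / 3)
  # but proportion_expressed still divides by all 4 genes
  expect_equal(smry$proportion_expressed[smry$tissue == "cortex"], 1 / 2)
})

test_that("a background identical to the set gives unit ratios", {
  se <- simulate_expression(n_genes = 20, seed = 83)
  m <- build_expression_matrix(se$counts, se$lengths, se$libsizes)
  smry <- summarize_tissues(m, background = m)
  expect_equal(smry$ratio_pooled_mean, rep(1, nrow(smry)))
  expect_equal(smry$ratio_proportion_expressed, rep(1, nrow(smry)))
})

test_that("per-gene rank lists cover ranks 1..k and kth-highest proportions sum to 1", {
  se <- simulate_expression(n_genes = 30, seed = 84)
  m <- build_expression_matrix(se$counts, se$lengths, se$libsizes)
  smry <- summarize_tissues(m)
  ranks <- attr(smry, "ranks")
  expect_true(all(ranks$rank >= 1L))
  for (k in 1:4) {
    pk <- proportion_kth_highest(smry, k)
    expect_equal(sum(pk$proportion), 1)
  }
})
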