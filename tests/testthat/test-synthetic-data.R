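test_that("scenario generation is a pure function of (kind, n_codons, seed)", {
  a <- generate_trio_scenario("de_novo_stop_removal", seed = 7)
  b <- generate_trio_scenario("de_novo_stop_removal", seed = 7)
  expect_identical(a$trio$rows, b$trio$rows)
  expect_identical(a$evidence, b$evidence)
  expect_identical(a$label, b$label)
  c <- generate_trio_scenario("de_novo_stop_removal", seed = 8)
  expect_false(identical(a$trio$rows, c$trio$rows))
})

test_that("generators do not disturb the caller's RNG stream", {
  set.seed(123)
  x1 <- stats::runif(1)
  set.seed(123)
  invisible(generate_trio_scenario("parallel_loss", seed = 5))
  invisible(simulate_hky85(length_nt = 500, seed = 5))
  x2 <- stats::runif(1)
  expect_identical(x1, x2)
})

test_that("every scenario kind self-checks against its planted label", {
  for (kind in denovoscreen:::SCENARIO_KINDS) {
    sc <- generate_trio_scenario(kind, seed = 11)
    v <- classify_candidate(sc$trio, sc$evidence)
    expect_identical(v$verdict, sc$label$expected_verdict, label = kind)
    if (!is.na(sc$label$expected_stage)) {
      expect_identical(denovoscreen:::first_failed_stage(v),
                       sc$label$expected_stage, label = kind)
    }
  }
})

test_that("below the protein-length floor every kind is rejected at stage 2", {
  sc <- generate_trio_scenario("de_novo_stop_removal", n_codons = 50, seed = 12)
  expect_identical(sc$label$expected_verdict, "rejected")
  expect_identical(sc$label$expected_stage, 2L)
  v <- classify_candidate(sc$trio, sc$evidence)
  expect_identical(denovoscreen:::first_failed_stage(v), 2L)
})

test_that("HKY85 simulation reproduces the closed-form mismatch fraction", {
  # at kappa = 1, equal frequencies: p = (3/4)(1 - exp(-4t/3)) between any
  # tip pair separated by path t
  t_pair <- 0.10
  sim <- simulate_hky85(t_pair / 2, t_pair / 2, 0.05, kappa = 1,
                        base_freqs = rep(0.25, 4), length_nt = 100000,
                        seed = 13)
  h <- strsplit(sim$rows[["human"]], "")[[1]]
  c_ <- strsplit(sim$rows[["chimp"]], "")[[1]]
  p_obs <- mean(h != c_)
  p_exp <- 0.75 * (1 - exp(-4 * t_pair / 3))
  se <- sqrt(p_exp * (1 - p_exp) / 100000)
  expect_lt(abs(p_obs - p_exp), 3 * se)
})

test_that("zero branch lengths give identical rows; fixed seeds reproduce", {
  sim <- simulate_hky85(0, 0, 0, length_nt = 500, seed = 14)
  expect_identical(sim$rows[["human"]], sim$rows[["chimp"]])
  expect_identical(sim$rows[["human"]], sim$rows[["orang"]])
  again <- simulate_hky85(0, 0, 0, length_nt = 500, seed = 14)
  expect_identical(sim$rows, again$rows)
  expect_error(simulate_hky85(length_nt = 100), "at least 300")
  expect_error(simulate_hky85(base_freqs = c(0.5, 0.5, 0, 0), length_nt = 500),
               "degenerate")
})

test_that("the observed transition:transversion ratio increases with kappa", {
  ratio_at <- function(kappa, seed) {
    sim <- simulate_hky85(0.05, 0.05, 0.05, kappa = kappa,
                          length_nt = 30000, seed = seed)
    h <- strsplit(sim$rows[["human"]], "")[[1]]
    c_ <- strsplit(sim$rows[["chimp"]], "")[[1]]
    diff <- h != c_
    pur <- c("A", "G")
    ts <- sum(diff & ((h %in% pur) == (c_ %in% pur)))
    tv <- sum(diff) - ts
    ts / tv
  }
  r <- vapply(c(1, 4, 16), ratio_at, numeric(1), seed = 15)
  expect_true(all(diff(r) > 0))
})

test_that("indels are placed with the true alignment retained", {
  sim <- simulate_hky85(0.02, 0.02, 0.05, length_nt = 2000, seed = 16,
                        indel_rate = 0.005)
  lens <- nchar(sim$rows)
  expect_identical(length(unique(lens)), 1L)
  expect_true(any(grepl("-", sim$rows)))
  # degapped rows have no alignment artifacts
  expect_false(any(grepl("-", gsub("-", "", sim$rows))))
  # fitting drops gapped columns and still recovers sane branch lengths
  fit <- fit_hky85_trio(sim$rows)
  expect_lt(fit$t_human, 0.2)
})

test_that("expression simulation matches its Poisson truth", {
  se <- simulate_expression(n_genes = 1000, tissues = c("t1", "t2"),
                            mean_matrix = matrix(100, 1000, 2),
                            libsizes = c(1e7, 1e7), seed = 17)
  emp <- mean(se$counts$unique_reads[se$counts$tissue == "t1"])
  se_mean <- sqrt(100 / 1000)
  expect_lt(abs(emp - 100), 3 * se_mean)

  zero <- simulate_expression(n_genes = 5, tissues = "t",
                              mean_matrix = matrix(0, 5, 1), libsizes = 1e6,
                              seed = 18)
  expect_true(all(zero$counts$unique_reads == 0))

  again <- simulate_expression(n_genes = 5, tissues = "t",
                               mean_matrix = matrix(0, 5, 1), libsizes = 1e6,
                               seed = 18)
  expect_identical(zero$counts, again$counts)

  expect_error(
    simulate_expression(n_genes = 2, tissues = c("a", "b"), libsizes = 1e6,
                        seed = 19),
    "tissue/libsize mismatch")
})

test_that("emitted read placements reproduce the drawn counts through counting", {
  se <- simulate_expression(n_genes = 8, seed = 20, emit_reads = TRUE)
  tissues <- denovoscreen:::DEFAULT_TISSUES
  for (g in se$lengths$gene_id[c(1, 4, 8)]) {
    iv <- se$gene_intervals[se$gene_intervals$gene_id == g, ]
    for (tis in tissues[c(3, 11)]) {
      reads_t <- se$reads[se$reads$tissue == tis, ]
      n <- count_unique_reads(reads_t, iv$chrom, iv$cds_start, iv$cds_end)
      truth <- se$counts$unique_reads[se$counts$gene_id == g &
                                        se$counts$tissue == tis]
      # genes are spaced beyond read length and decoys are multi-mapped,
      # so counting must reproduce the drawn counts exactly
      expect_identical(n, as.integer(truth))
    }
  }
})
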