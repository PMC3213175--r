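test_that("translate_from reads codons to the first stop and flags missing stops", {
  r <- translate_from("ATGAAATAA", 0)
  expect_identical(r$protein, "MK")
  expect_true(r$complete)
  expect_identical(r$stop_pos, 6L)

  expect_identical(translate_from("ATGTAA", 0)$protein, "M")
  r2 <- translate_from("ATGAAA", 0)
  expect_identical(r2$protein, "MK")
  expect_false(r2$complete)

  # N codons translate to X and never stop translation
  r3 <- translate_from("ATGTNAAAATAA", 0)
  expect_identical(r3$protein, "MXK")
  expect_true(r3$complete)

  expect_error(translate_from("ATG", 10), "outside sequence")
})

test_that("anchored scans require ATG at the anchor; rescue finds the best ATG", {
  r <- scan_orf("CCCATGAAATAA", policy = "rescue", human_protein_len = 2)
  expect_identical(r$start_pos, 3L)
  expect_identical(r$protein, "MK")
  expect_equal(r$length_fraction, 1.0)

  r2 <- scan_orf("CCCCCC", policy = "rescue")
  expect_true(is.na(r2$start_pos))
  expect_false(r2$complete)

  r3 <- scan_orf("CCCATGAAATAA", anchor = 0, policy = "anchored")
  expect_true(is.na(r3$start_pos))
  expect_false(r3$complete)
})

test_that("rescue equals exhaustive enumeration over every ATG on random sequences", {
  set.seed(101)
  for (i in 1:150) {
    seq <- random_dna(300)
    got <- scan_orf(seq, policy = "rescue")
    want <- oracle_best_orf(seq)
    if (is.null(want)) {
      expect_true(is.na(got$start_pos))
    } else {
      expect_identical(nchar(got$protein), want$protein_len)
      expect_identical(got$complete, want$complete)
      # ties break to the 5'-most start
      expect_lte(got$start_pos, want$start0)
    }
  }
})

test_that("an ortholog identical to the human row is intact with no events", {
  trio <- identity_trio(seed = 21)
  st <- assess_ortholog(trio, "chimp")
  expect_identical(st$status, "intact")
  expect_identical(nrow(st$events), 0L)
  expect_equal(st$orf$length_fraction, 1.0)
})

test_that("an early premature stop disrupts; the same stop at 85% is intact_enough", {
  trio <- identity_trio(seed = 22)  # 150 codons, protein 149 aa
  # TGA at 0-based codon 29: predicted protein 29 aa, fraction 29/149
  early <- trio
  early$rows[["chimp"]] <- mutate_at_col(early$rows[["chimp"]], 87L, "TGA")
  st <- assess_ortholog(early, "chimp")
  expect_identical(st$status, "disrupted")
  expect_true("premature_stop" %in% st$events$kind)
  expect_equal(st$orf$length_fraction, 29 / 149, tolerance = 1e-12)
  # oracle check on the mutated ungapped sequence
  ora <- oracle_translate(gsub("-", "", early$rows[["chimp"]]), 0L)
  expect_identical(nchar(st$orf$protein), ora$protein_len)

  # stop at codon 127: fraction 127/149 ~ 0.852 >= 0.80 -> intact_enough
  late <- trio
  late$rows[["chimp"]] <- mutate_at_col(late$rows[["chimp"]], 381L, "TGA")
  st2 <- assess_ortholog(late, "chimp")
  expect_identical(st2$status, "intact_enough")
  expect_gte(st2$orf$length_fraction, 0.80)
})

test_that("the 80% boundary itself counts as intact_enough (gene discarded)", {
  # 100-codon human protein: protein 99 aa; a stop leaving exactly 80 aa
  # would need 80/99; use 150 codons and fraction exactly >= 0.80 via codon 120
  trio <- identity_trio(n_codons = 151L, seed = 23)  # protein 150 aa
  # stop at codon 120 -> 119 aa? codon index 120 (0-based) -> protein 119... place
  # stop so predicted protein is exactly 120 aa = 0.80 * 150
  b <- trio
  b$rows[["chimp"]] <- mutate_at_col(b$rows[["chimp"]], 3L * 120L, "TGA")
  st <- assess_ortholog(b, "chimp")
  expect_equal(st$orf$length_fraction, 0.80, tolerance = 1e-12)
  expect_identical(st$status, "intact_enough")
})

test_that("missing start triggers rescue over the whole region", {
  trio <- identity_trio(seed = 24)
  n_aa <- nchar(trio$rows[["human"]]) / 3 - 1
  # outgroup loses the start; an in-frame ATG at codon 10 exists in all rows
  resc <- trio
  for (tx in c("human", "chimp", "orang")) {
    resc$rows[[tx]] <- mutate_at_col(resc$rows[[tx]], 30L, "ATG")
  }
  resc$rows[["chimp"]] <- mutate_at_col(resc$rows[["chimp"]], 0L, "ATA")
  st <- assess_ortholog(resc, "chimp")
  expect_true("missing_start" %in% st$events$kind)
  # rescued ORF: 149 - 10 = 139 aa, fraction 139/149 >= 0.8 -> not disrupted
  expect_identical(st$status, "intact_enough")
  expect_equal(nchar(st$orf$protein), n_aa - 10)
})

test_that("a lone 1-nt deletion disrupts by frameshift, matching the translate oracle", {
  trio <- identity_trio(seed = 25)
  shift <- trio
  shift$rows[["chimp"]] <- mutate_at_col(shift$rows[["chimp"]], 60L, "-")
  st <- assess_ortholog(shift, "chimp")
  expect_true("frameshift_indel" %in% st$events$kind)
  expect_identical(st$status, "disrupted")
  ora <- oracle_translate(gsub("-", "", shift$rows[["chimp"]]), 0L)
  expect_identical(nchar(st$orf$protein), ora$protein_len)
  expect_identical(st$orf$complete, ora$complete)
})

test_that("a compensated +1/-1 double indel restores the frame; status follows the fraction", {
  # chimp loses one base at column 60 and gains one at column 75 (a column
  # gapped in human and orang), so its degapped sequence keeps the human
  # length and the frame is shifted only between the two indels.
  found_complete <- FALSE
  for (seed in 1:10) {
    trio0 <- identity_trio(seed = seed)
    cds <- trio0$rows[["human"]]
    L <- nchar(cds)
    human_aln <- paste0(substr(cds, 1, 75), "-", substr(cds, 76, L))
    chimp_aln <- human_aln
    substr(chimp_aln, 61, 61) <- "-"
    substr(chimp_aln, 76, 76) <- "T"
    trio <- trio_alignment(paste0("comp", seed), human_aln, chimp_aln,
                           human_aln, 0L, L - 3L + 1L)
    st <- assess_ortholog(trio, "chimp")
    ora <- oracle_translate(gsub("-", "", chimp_aln), 0L)
    expect_identical(nchar(st$orf$protein), ora$protein_len)
    expect_identical(st$orf$complete, ora$complete)
    expect_identical(st$status == "disrupted",
                     !st$orf$complete || st$orf$length_fraction < 0.80)
    if (ora$complete && ora$protein_len == L / 3 - 1) {
      # no new stop in the out-of-frame window: full-length complete ORF,
      # so the event list (two frameshift indels) must NOT disrupt it
      expect_identical(st$status, "intact_enough")
      found_complete <- TRUE
    }
  }
  expect_true(found_complete)
})

test_that("inserting an earlier stop never increases the length fraction", {
  trio <- identity_trio(seed = 26)
  fractions <- vapply(c(120L, 80L, 40L, 10L), function(codon) {
    m <- trio
    m$rows[["chimp"]] <- mutate_at_col(m$rows[["chimp"]], 3L * codon, "TGA")
    assess_ortholog(m, "chimp")$orf$length_fraction
  }, numeric(1))
  expect_true(all(diff(fractions) < 0))
})

test_that("a fully gapped ortholog region raises the absence error", {
  trio <- identity_trio(seed = 27)
  gone <- trio
  gone$rows[["chimp"]] <- strrep("-", nchar(gone$rows[["chimp"]]))
  expect_error(assess_ortholog(gone, "chimp"), "ortholog region absent")
})
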