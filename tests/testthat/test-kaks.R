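test_that("identical CDS align gaplessly with Ka = Ks = 0 and no ratio", {
  withr::with_seed(151, {
    cds <- make_cds_fixture(60)
    aln <- align_codon_pair(cds, cds)
    expect_false(any(aln$codons$codon_a == "---"))
    res <- compute_kaks(aln)
    expect_identical(res$Ka, 0)
    expect_identical(res$Ks, 0)
    expect_true(is.na(res$ratio))
    expect_equal(res$N + res$S, 3 * res$n_codons, tolerance = 1e-9)
  })
})

test_that("an inserted codon back-threads as a single length-3 gap", {
  withr::with_seed(152, {
    cds <- make_cds_fixture(40)
    ins <- paste0(substr(cds, 1, 60), "GCT", substr(cds, 61, nchar(cds)))
    aln <- align_codon_pair(cds, ins)
    gaps_a <- sum(aln$codons$codon_a == "---")
    expect_identical(gaps_a, 1L)
    expect_false(any(aln$codons$codon_b == "---"))
    expect_false(grepl("[^-ACGT]", aln$aligned_a))
  })
})

test_that("internal stop codons are rejected by name", {
  withr::with_seed(153, {
    cds <- make_cds_fixture(30)
    bad <- paste0(substr(cds, 1, 30), "TAA", substr(cds, 34, nchar(cds)))
    expect_error(align_codon_pair(bad, cds, names = c("geneX", "geneY")),
                 "internal stop codon in geneX")
  })
})

test_that("a synonymous TTT->TTC change gives Ka = 0 and ratio 0", {
  base <- paste(rep("TTT", 100), collapse = "")
  mut <- paste0("TTC", substr(base, 4, 300))
  res <- compute_kaks(c(base, mut))
  expect_identical(res$Na, 0)
  expect_identical(res$Ka, 0)
  expect_gt(res$Ks, 0)
  expect_identical(res$ratio, 0)
  # NG86 site count for TTT: one synonymous change (TTC) out of nine
  expect_equal(res$S, 100 / 3, tolerance = 1e-9)
})

test_that("substitution counting matches exhaustive path enumeration", {
  codons <- names(Biostrings::GENETIC_CODE)
  sense <- codons[Biostrings::GENETIC_CODE != "*"]
  withr::with_seed(154, {
    pad <- paste(sample(sense, 15, replace = TRUE), collapse = "")
    pairs_checked <- 0
    while (pairs_checked < 120) {
      c1 <- sample(sense, 1)
      c2 <- sample(sense, 1)
      nd <- sum(strsplit(c1, "")[[1]] != strsplit(c2, "")[[1]])
      if (nd == 0) next
      mine <- bchrom:::ng86_path_counts(c1, c2)
      ora <- oracle_ng86_paths(c1, c2)
      expect_equal(mine[["syn"]], ora[["syn"]], tolerance = 1e-9)
      expect_equal(mine[["nonsyn"]], ora[["nonsyn"]], tolerance = 1e-9)
      # and through the full pipeline with padding codons
      res <- compute_kaks(c(paste0(pad, c1), paste0(pad, c2)))
      expect_equal(res$Na, unname(ora[["nonsyn"]]), tolerance = 1e-9)
      expect_equal(res$Ns, unname(ora[["syn"]]), tolerance = 1e-9)
      pairs_checked <- pairs_checked + 1
    }
  })
})

test_that("site counts always satisfy N + S = 3 x codons", {
  withr::with_seed(155, {
    for (rep in 1:10) {
      n_codons <- sample(12:40, 1)
      a <- make_cds_fixture(n_codons)
      b <- evolve_cds(a, 0.1, 1)
      res <- kaks_pair(a, b)
      expect_equal(res$N + res$S, 3 * res$n_codons, tolerance = 1e-9)
    }
  })
})

test_that("neutral evolution gives Ka/Ks near one on average", {
  withr::with_seed(156, {
    pairs <- make_neutral_pairs(30, n_codons = 300, sub_rate = 0.05,
                                seed = 157)
    ratios <- vapply(seq_len(nrow(pairs)), function(i) {
      kaks_pair(pairs$cds1[i], pairs$cds2[i])$ratio
    }, numeric(1))
    expect_gt(mean(ratios, na.rm = TRUE), 0.85)
    expect_lt(mean(ratios, na.rm = TRUE), 1.15)
  })
})

test_that("relaxed B copies elevate Ka/Ks against the outgroup contrast", {
  triples <- make_coding_triples(40, n_codons = 200, b_multiplier = 2.5,
                                 seed = 158)
  cmp <- selection_comparison(triples)
  expect_gt(cmp$medians[["b_a"]], cmp$medians[["a_out"]])
  expect_lt(cmp$wilcox$p, 0.05)
  null <- selection_comparison(make_coding_triples(30, n_codons = 200,
                                                   b_multiplier = 1,
                                                   seed = 159))
  expect_gt(null$wilcox$p, 0.05)
  expect_s3_class(generics::tidy(cmp), "tbl_df")
  expect_s3_class(ggplot2::autoplot(cmp), "ggplot")
})
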