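test_that("exact tandem copies are each recovered at 100% identity", {
  withr::with_seed(111, {
    mono <- random_dna_str(150)
    arr <- strrep(mono, 5)
    hits <- scan_monomers(arr, mono)
    expect_identical(nrow(hits), 5L)
    expect_true(all(hits$identity == 100))
    expect_true(all(hits$strand == "+"))
    # abutting, non-overlapping, covering the array
    h <- dplyr::arrange(hits, start)
    expect_identical(h$start, seq(0L, 600L, by = 150L))
    expect_identical(h$end - h$start, rep(150L, 5))
  })
})

test_that("identity counts substitutions against alignment columns", {
  withr::with_seed(112, {
    mono <- random_dna_str(150)
    copy <- mono
    for (p in c(30, 75, 120)) {
      substr(copy, p, p) <- setdiff(c("A", "C", "G", "T"),
                                    substr(copy, p, p))[1]
    }
    seq <- paste0(random_dna_str(60), copy, random_dna_str(60))
    hits <- scan_monomers(seq, mono)
    expect_identical(nrow(hits), 1L)
    expect_equal(hits$identity, 100 * 147 / 150, tolerance = 1e-6)
  })
})

test_that("reverse-complemented arrays yield the same hits on '-'", {
  withr::with_seed(113, {
    mono <- random_dna_str(120)
    arr <- strrep(mono, 4)
    fwd <- scan_monomers(arr, mono)
    rev <- scan_monomers(revcomp(arr), mono)
    expect_identical(nrow(rev), nrow(fwd))
    expect_true(all(rev$strand == "-"))
    expect_identical(sort(nchar(arr) - rev$end), sort(fwd$start))
  })
})

test_that("mutated arrays still recover the true copy number", {
  withr::with_seed(114, {
    mono <- random_dna_str(150)
    copies <- vapply(1:6, function(i) {
      x <- mono
      for (p in sample(150, 15)) {  # 10% divergence -> identity ~90%
        substr(x, p, p) <- sample(c("A", "C", "G", "T"), 1)
      }
      x
    }, "")
    arr <- paste(copies, collapse = "")
    hits <- scan_monomers(arr, mono, min_identity = 70)
    expect_identical(nrow(hits), 6L)
  })
})

test_that("read pairs merge at the exact overlap length", {
  withr::with_seed(115, {
    frag <- random_dna_str(150)
    pairs <- tibble::tibble(pair_id = "p1",
                            read1 = substr(frag, 1, 100),
                            read2 = revcomp(substr(frag, 51, 150)))
    m <- merge_read_pairs(pairs)
    expect_identical(nrow(m), 1L)
    expect_identical(m$overlap, 50L)
    expect_identical(m$seq, frag)
    expect_identical(attr(m, "n_unmerged"), 0L)
  })
})

test_that("non-overlapping mates are dropped and counted", {
  withr::with_seed(116, {
    pairs <- tibble::tibble(pair_id = "p1",
                            read1 = random_dna_str(80),
                            read2 = random_dna_str(80))
    m <- merge_read_pairs(pairs)
    expect_identical(nrow(m), 0L)
    expect_identical(attr(m, "n_unmerged"), 1L)
  })
})

test_that("merging tolerates one mismatch per 10 bp of overlap", {
  withr::with_seed(117, {
    frag <- random_dna_str(150)
    r2 <- substr(frag, 51, 150)
    substr(r2, 10, 10) <- setdiff(c("A", "C", "G", "T"),
                                  substr(r2, 10, 10))[1]
    substr(r2, 30, 30) <- setdiff(c("A", "C", "G", "T"),
                                  substr(r2, 30, 30))[1]
    pairs <- tibble::tibble(pair_id = "p1",
                            read1 = substr(frag, 1, 100),
                            read2 = revcomp(r2))
    m <- merge_read_pairs(pairs)
    expect_identical(nrow(m), 1L)
    expect_identical(m$overlap, 50L)
  })
})

test_that("midpoint offsets fold placements onto the monomer", {
  withr::with_seed(118, {
    mono <- random_dna_str(150)
    tri <- strrep(mono, 3)
    # a read at [10, 60) has midpoint 35
    reads <- tibble::tibble(seq = substr(tri, 11, 60))
    prof <- midpoint_profile(reads, mono, copies = 3)
    expect_identical(prof$chip[prof$offset == 35], 1L)
    expect_identical(sum(prof$chip), 1L)
    # placement on a later copy gives the same offset
    reads2 <- tibble::tibble(seq = substr(tri, 161, 210))
    prof2 <- midpoint_profile(reads2, mono, copies = 3)
    expect_identical(prof2$chip[prof2$offset == 35], 1L)
  })
})

test_that("profile mass equals the number of mapped merged reads", {
  sim <- simulate_midpoint_reads(tiny_world()$lib$monomers[["b_specific"]],
                                 array_copies = 10, dyad_positions = c(40, 110),
                                 n_pairs = 400, seed = 119)
  merged <- merge_read_pairs(sim$chip)
  prof <- midpoint_profile(merged, sim$params$monomer, copies = 3)
  expect_identical(sum(prof$chip), attr(prof, "n_mapped_chip"))
  expect_identical(attr(prof, "n_mapped_chip") +
                     attr(prof, "n_skipped_chip"), nrow(merged))
})

test_that("flat chip equal to input yields no peaks", {
  prof <- tibble::tibble(offset = 0:149, chip = 10L, input = 10L)
  class(prof) <- c("midpoint_profile", class(prof))
  peaks <- call_peaks(prof)
  expect_identical(nrow(peaks), 0L)
})

test_that("a single planted dyad yields one peak at the planted offset", {
  withr::with_seed(120, {
    mono <- random_dna_str(150)
    sim <- simulate_midpoint_reads(mono, array_copies = 12,
                                   dyad_positions = 60, n_pairs = 2000,
                                   sigma = 5, seed = 121)
    chip <- merge_read_pairs(sim$chip)
    inp <- merge_read_pairs(sim$input)
    prof <- midpoint_profile(chip, mono, copies = 3, input = inp)
    peaks <- call_peaks(prof)
    expect_identical(nrow(peaks), 1L)
    expect_lte(min(abs(c(peaks$offset - 60, peaks$offset - 60 + 150,
                         peaks$offset - 60 - 150))), 3)
  })
})

test_that("identity summaries and Welch tests behave at the boundaries", {
  s <- identity_stats(list(a = c(90, 90, 90), b = c(90, 90, 90)))
  expect_identical(s$tests$t, 0)
  expect_identical(s$tests$p, 1)
  expect_identical(s$tests$flag, "zero_variance")
  withr::with_seed(122, {
    s2 <- identity_stats(list(high = rnorm(200, 95, 1),
                              low = rnorm(200, 85, 1)))
    expect_lt(s2$tests$p, 0.001)
    expect_gt(s2$tests$t, 0)
    expect_gt(s2$summary$median[s2$summary$group == "high"],
              s2$summary$median[s2$summary$group == "low"])
  })
})
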