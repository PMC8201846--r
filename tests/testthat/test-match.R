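reads_tbl <- function(seqs) {
  tibble::tibble(read_id = sprintf("r%03d", seq_along(seqs)), seq = seqs)
}

test_that("3' N and poly-G tails are trimmed; internal runs kept", {
  rd <- reads_tbl(c(strrep("ACGTACGTAT", 3),                      # clean
                    paste0(strrep("ACGTACGTAT", 3), "GGGGGG"),    # poly-G
                    paste0(strrep("ACGTACGTAT", 3), "NNN"),       # Ns
                    paste0("ACGGGTA", strrep("ACGTACGTAT", 3))))  # internal
  out <- preprocess_reads(rd, min_keep = 10)
  expect_identical(out$seq[1], strrep("ACGTACGTAT", 3))
  expect_identical(out$seq[2], strrep("ACGTACGTAT", 3))
  expect_identical(out$seq[3], strrep("ACGTACGTAT", 3))
  expect_identical(out$seq[4], paste0("ACGGGTA", strrep("ACGTACGTAT", 3)))
  expect_identical(attr(out, "n_trimmed"), 2L)
})

test_that("reads shorter than min_keep after trimming are dropped", {
  rd <- reads_tbl(c(paste0("ACGTAC", strrep("G", 40)),
                    strrep("ACGTACGTAT", 4)))
  out <- preprocess_reads(rd, min_keep = 30)
  expect_identical(nrow(out), 1L)
  expect_identical(attr(out, "n_dropped"), 1L)
})

test_that("host subtraction removes unique hits and keeps multi/zero hits", {
  withr::with_seed(41, {
    locus <- random_dna_str(400)
    a <- c(A1 = paste0(random_dna_str(200), locus, random_dna_str(200)),
           A2 = paste0(random_dna_str(150), locus, random_dna_str(100)))
    uniq_read <- substr(a[["A1"]], 50, 124)        # unique A locus
    dup_read <- substr(locus, 100, 174)            # two identical A loci
    alien_read <- random_dna_str(75)               # absent from A
    near_read <- uniq_read
    substr(near_read, 10, 10) <- "A"               # may add 1 mismatch
  })
  rd <- reads_tbl(c(uniq_read, dup_read, alien_read))
  out <- subtract_host_reads(rd, a)
  expect_identical(out$read_id, c("r002", "r003"))
  expect_identical(attr(out, "n_removed"), 1L)
})

test_that("subtraction agrees with the brute-force Hamming oracle", {
  withr::with_seed(42, {
    for (rep in 1:10) {
      a <- c(A1 = random_dna_str(300), A2 = random_dna_str(250))
      seqs <- c(
        vapply(1:4, function(i) random_dna_str(60), ""),
        # near-copies of A loci with 0-3 substitutions
        vapply(1:6, function(i) {
          src <- if (runif(1) < 0.5) a[["A1"]] else a[["A2"]]
          s <- sample(nchar(src) - 59, 1)
          x <- substr(src, s, s + 59)
          nmut <- sample(0:3, 1)
          if (nmut > 0) {
            for (p in sample(60, nmut)) {
              substr(x, p, p) <- sample(c("A", "C", "G", "T"), 1)
            }
          }
          if (runif(1) < 0.5) x else revcomp(x)
        }, "")
      )
      rd <- reads_tbl(seqs)
      out <- subtract_host_reads(rd, a, max_mismatches = 2)
      oracle_removed <- vapply(seqs, function(s) {
        oracle_placement_count(s, as.list(a), 2) == 1
      }, logical(1))
      expect_identical(setdiff(rd$read_id, out$read_id),
                       rd$read_id[oracle_removed])
    }
  })
})

test_that("unique zero-mismatch mapping matches the exact-substring oracle", {
  withr::with_seed(43, {
    for (rep in 1:10) {
      scf <- c(s1 = random_dna_str(400), s2 = random_dna_str(300))
      dup <- substr(scf[["s1"]], 20, 79)
      scf[["s2"]] <- paste0(scf[["s2"]], dup)  # a shared 60-mer
      seqs <- c(
        vapply(1:5, function(i) {
          src <- sample(names(scf), 1)
          s <- sample(nchar(scf[[src]]) - 59, 1)
          x <- substr(scf[[src]], s, s + 59)
          if (runif(1) < 0.5) x else revcomp(x)
        }, ""),
        dup,                    # in both scaffolds -> no placement
        random_dna_str(60)      # nowhere -> no placement
      )
      rd <- reads_tbl(seqs)
      pl <- map_unique_reads(rd, scf)
      for (i in seq_along(seqs)) {
        op <- oracle_placements_one(seqs[i], as.list(scf), 0)
        mine <- pl[pl$read_id == rd$read_id[i], ]
        if (nrow(op) == 1) {
          expect_identical(nrow(mine), 1L)
          expect_identical(mine$scaffold, op$subject)
          expect_identical(mine$start, op$start - 1L)
          expect_identical(mine$strand, op$strand)
        } else {
          expect_identical(nrow(mine), 0L)
        }
      }
    }
  })
})

test_that("the generic placement engine enumerates all near matches", {
  withr::with_seed(44, {
    subj <- c(x = random_dna_str(500))
    read <- substr(subj[["x"]], 100, 174)
    substr(read, 40, 40) <- setdiff(c("A", "C", "G", "T"),
                                    substr(read, 40, 40))[1]
    pl <- match_placements(read, subj, max_mismatch = 2)
    op <- oracle_placements_one(read, as.list(subj), 2)
    expect_identical(nrow(pl), nrow(op))
    expect_setequal(paste(pl$subject, pl$strand, pl$start),
                    paste(op$subject, op$strand, op$start))
  })
})
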