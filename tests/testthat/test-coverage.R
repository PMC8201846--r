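test_that("empty placements give all-zero window counts", {
  scf <- tibble::tibble(scaffold = "s1", seq = NA_character_, length = 3500L)
  cw <- coverage_windows(
    tibble::tibble(read_id = character(0), scaffold = character(0),
                   start = integer(0), strand = character(0),
                   width = integer(0)),
    scf, window = 1000)
  expect_identical(nrow(cw), 4L)
  expect_true(all(cw$count == 0))
  expect_identical(cw$win_end[4], 3500L)
})

test_that("placements are counted in the window containing their start", {
  scf <- tibble::tibble(scaffold = "s1", length = 5000L)
  pl <- tibble::tibble(read_id = c("a", "b", "c"), scaffold = "s1",
                       start = c(0L, 999L, 1000L), strand = "+",
                       width = 75L)
  cw <- coverage_windows(pl, scf, window = 1000)
  expect_identical(cw$count[1:2], c(2L, 1L))
  expect_error(coverage_windows(dplyr::mutate(pl, start = 6000L), scf),
               "out of scaffold bounds")
})

test_that("windows mostly covered by the repeat mask are flagged", {
  scf <- tibble::tibble(scaffold = "s1", length = 3000L)
  mask <- tibble::tibble(chrom = "s1", start = c(0L, 1200L),
                         end = c(600L, 1500L))
  pl <- tibble::tibble(read_id = "a", scaffold = "s1", start = 10L,
                       strand = "+", width = 75L)
  cw <- coverage_windows(pl, scf, window = 1000, repeat_mask = mask)
  expect_identical(cw$repetitive, c(TRUE, FALSE, FALSE))
})

test_that("presence calls follow the covered-fraction thresholds", {
  mk_cov <- function(frac, line = "L", n = 20) {
    tibble::tibble(line = line, scaffold = "s1",
                   win_start = (0:(n - 1)) * 1000L,
                   win_end = (1:n) * 1000L,
                   count = c(rep(5L, round(frac * n)),
                             rep(0L, n - round(frac * n))),
                   repetitive = FALSE)
  }
  pm <- call_presence(dplyr::bind_rows(mk_cov(1, "full"), mk_cov(0, "none"),
                                       mk_cov(0.5, "half")))
  x <- tibble::as_tibble(pm)
  expect_identical(x$call[x$line == "full"], "present")
  expect_identical(x$call[x$line == "none"], "absent")
  expect_identical(x$call[x$line == "half"], "partial")
})

test_that("scaffolds with no informative window are uninformative", {
  cov <- tibble::tibble(line = "L", scaffold = "s1",
                        win_start = 0L, win_end = 1000L, count = 50L,
                        repetitive = TRUE)
  pm <- call_presence(cov)
  expect_identical(tibble::as_tibble(pm)$call, "uninformative")
})

test_that("covered fraction rises with the retained overlap fraction", {
  w <- tiny_world()
  g <- w$genome
  scf <- w$scaffolds[which.max(w$scaffolds$length), ]
  s_cat <- subject_catalog(scf)
  mask <- repeat_mask(scf, g$a_chromosomes, window = 500)
  fracs <- c(0.2, 0.5, 0.9)
  covered <- vapply(seq_along(fracs), function(i) {
    keep_end <- as.integer(scf$true_start +
                             round(fracs[i] * scf$length))
    line <- list(line = sprintf("f%d", i),
                 retained = tibble::tibble(start = scf$true_start,
                                           end = keep_end),
                 a_dosage = setNames(rep(0L, nrow(g$a_segments)),
                                     g$a_segments$segment),
                 b_copies = 1L)
    rd <- simulate_reads(g, line, coverage = 6, error_rate = 0,
                         tail_frac = 0, seed = 70 + i)
    pl <- map_unique_reads(rd, s_cat)
    pl <- filter_masked_placements(pl, mask$positions, scf)
    cw <- dplyr::mutate(coverage_windows(pl, scf, window = 500,
                                         repeat_mask = mask$windows),
                        line = line$line)
    tibble::as_tibble(call_presence(cw, min_count = 2))$covered_fraction
  }, numeric(1))
  expect_true(all(diff(covered) > 0))
})
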