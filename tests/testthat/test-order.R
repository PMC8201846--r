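# hand-built presence matrices for the ordering logic
pm_from_calls <- function(calls) {
  # calls: named list scaffold -> named vector line -> call
  rows <- list()
  for (scf in names(calls)) {
    for (ln in names(calls[[scf]])) {
      cf <- c(present = 1, partial = 0.5, absent = 0,
              uninformative = NA_real_)[[calls[[scf]][[ln]]]]
      rows[[length(rows) + 1]] <- tibble::tibble(
        scaffold = scf, line = ln, covered_fraction = cf,
        call = calls[[scf]][[ln]])
    }
  }
  bchrom:::new_presence_matrix(dplyr::bind_rows(rows))
}

toy_panel <- function(lines) {
  p <- tibble::tibble(
    line = c("control", lines),
    type = c("control", rep("terminal", length(lines))),
    retained = replicate(length(lines) + 1,
                         tibble::tibble(start = 0L, end = 1L),
                         simplify = FALSE),
    a_dosage = replicate(length(lines) + 1, c(A1_L = 2L), simplify = FALSE),
    b_copies = 1L)
  class(p) <- c("line_panel", class(p))
  p
}

test_that("two nested deletions order three scaffolds uniquely", {
  # lines retaining [0,30k) and [0,60k); scaffolds at [5k,15k), [35k,45k),
  # [65k,75k) -> signatures (P,P), (A,P), (A,A) -> s1 < s2 < s3
  pm <- pm_from_calls(list(
    s1 = c(control = "present", L30 = "present", L60 = "present"),
    s2 = c(control = "present", L30 = "absent", L60 = "present"),
    s3 = c(control = "present", L30 = "absent", L60 = "absent")))
  lay <- order_scaffolds(pm, toy_panel(c("L30", "L60")))
  ord <- lay$bins$scaffold[order(lay$bins$bin)]
  expect_identical(ord, c("s1", "s2", "s3"))
  expect_identical(lay$line_order, c("L30", "L60"))
  expect_false(any(lay$bins$unresolved))
})

test_that("identical signatures share a bin and are flagged unresolved", {
  pm <- pm_from_calls(list(
    s1 = c(control = "present", L1 = "present", L2 = "present"),
    s2 = c(control = "present", L1 = "present", L2 = "present"),
    s3 = c(control = "present", L1 = "absent", L2 = "present")))
  lay <- order_scaffolds(pm, toy_panel(c("L1", "L2")))
  b <- lay$bins
  expect_identical(b$bin[b$scaffold == "s1"], b$bin[b$scaffold == "s2"])
  expect_true(all(b$unresolved[b$scaffold %in% c("s1", "s2")]))
  expect_false(b$unresolved[b$scaffold == "s3"])
})

test_that("partial scaffolds anchor boundaries between bins", {
  pm <- pm_from_calls(list(
    s1 = c(control = "present", L1 = "present", L2 = "present"),
    sx = c(control = "present", L1 = "partial", L2 = "present"),
    s2 = c(control = "present", L1 = "absent", L2 = "present")))
  lay <- order_scaffolds(pm, toy_panel(c("L1", "L2")))
  b <- lay$bins
  expect_lt(b$bin[b$scaffold == "s1"], b$bin[b$scaffold == "sx"])
  expect_lt(b$bin[b$scaffold == "sx"], b$bin[b$scaffold == "s2"])
})

test_that("chain-inconsistent signatures raise a conflict unless forced", {
  # anchor scaffolds fix the chain direction; "bad" contradicts it
  pm <- pm_from_calls(list(
    s1 = c(control = "present", L1 = "present", L2 = "present"),
    s2 = c(control = "present", L1 = "absent", L2 = "present"),
    s3 = c(control = "present", L1 = "absent", L2 = "present"),
    bad = c(control = "present", L1 = "present", L2 = "absent")))
  expect_error(order_scaffolds(pm, toy_panel(c("L1", "L2"))),
               class = "bchrom_chain_conflict")
  lay <- order_scaffolds(pm, toy_panel(c("L1", "L2")), force = TRUE)
  expect_gt(nrow(lay$conflicts), 0)
  expect_identical(unique(lay$conflicts$scaffold), "bad")
})

test_that("uninformative scaffolds are excluded and reported", {
  pm <- pm_from_calls(list(
    s1 = c(control = "present", L1 = "present", L2 = "present"),
    rep1 = c(control = "uninformative", L1 = "uninformative",
             L2 = "uninformative")))
  lay <- order_scaffolds(pm, toy_panel(c("L1", "L2")))
  expect_identical(lay$unplaced$scaffold, "rep1")
  expect_false("rep1" %in% lay$bins$scaffold)
})

test_that("two 1-kb scaffolds joined with a 100-N gap give 2,100 bp", {
  withr::with_seed(81, {
    seqs <- c(sA = random_dna_str(1000), sB = random_dna_str(1000))
    pm <- pm_from_calls(list(
      sA = c(control = "present", L1 = "present", L2 = "present"),
      sB = c(control = "present", L1 = "absent", L2 = "present")))
    lay <- order_scaffolds(pm, toy_panel(c("L1", "L2")))
    scf <- tibble::tibble(scaffold = names(seqs), seq = unname(seqs),
                          length = 1000L)
    cov <- tibble::tibble(line = "L1", scaffold = "sA", win_start = 0L,
                          win_end = 1000L, count = 10L, repetitive = FALSE)
    build <- orient_and_build(lay, scf, cov, pm, gap_len = 100)
    expect_identical(nchar(build$seq), 2100L)
    expect_identical(substr(build$seq, 1001, 1100), strrep("N", 100))
    expect_identical(substr(build$seq, 1, 1000), seqs[["sA"]])
    # AGP round-trip
    path <- withr::local_tempfile(fileext = ".agp")
    write_agp(build$agp, path)
    expect_identical(as.data.frame(read_agp(path)),
                     as.data.frame(build$agp))
  })
})

test_that("half-coverage orientation picks the covered, proximal-facing side", {
  withr::with_seed(82, {
    seqs <- c(sp = random_dna_str(4000))
    pm <- pm_from_calls(list(
      sp = c(control = "present", L1 = "partial", L2 = "present")))
    lay <- order_scaffolds(pm, toy_panel(c("L1", "L2")))
    scf <- tibble::tibble(scaffold = "sp", seq = unname(seqs), length = 4000L)
    cov_first_half <- tibble::tibble(
      line = "L1", scaffold = "sp", win_start = c(0L, 1000L, 2000L, 3000L),
      win_end = c(1000L, 2000L, 3000L, 4000L),
      count = c(40L, 38L, 0L, 0L), repetitive = FALSE)
    b1 <- orient_and_build(lay, scf, cov_first_half, pm)
    expect_identical(b1$bins$orientation, "+")
    cov_second_half <- dplyr::mutate(cov_first_half, count = rev(count))
    b2 <- orient_and_build(lay, scf, cov_second_half, pm)
    expect_identical(b2$bins$orientation, "-")
    # ambiguous halves stay unknown with a warning
    cov_even <- dplyr::mutate(cov_first_half, count = 20L)
    expect_warning(b3 <- orient_and_build(lay, scf, cov_even, pm),
                   "ambiguous")
    expect_identical(b3$bins$orientation, "unknown")
  })
})
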