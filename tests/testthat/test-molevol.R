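test_that("JC69 and K2P corrections match their closed forms and ape", {
  expect_equal(jc69_distance(0.10), -(3 / 4) * log(1 - 4 * 0.10 / 3),
               tolerance = 1e-12)
  expect_equal(jc69_distance(0.10), 0.10732, tolerance = 1e-4)
  expect_true(is.na(jc69_distance(0.75)))
  # forward-model consistency: p(d) = 3/4 (1 - exp(-4d/3)) inverts back
  d <- jc69_distance(0.2)
  p_back <- 0.75 * (1 - exp(-4 * d / 3))
  expect_equal(p_back, 0.2, tolerance = 1e-9)
  skip_if_not_installed("ape")
  withr::with_seed(141, {
    a <- random_dna_str(600)
    b <- a
    for (p in sample(600, 60)) {
      substr(b, p, p) <- sample(c("A", "C", "G", "T"), 1)
    }
    m <- rbind(strsplit(tolower(a), "")[[1]], strsplit(tolower(b), "")[[1]])
    bin <- ape::as.DNAbin(m)
    est <- estimate_insertion_age(
      tibble::tibble(element_id = "e1", ltr5 = a, ltr3 = b))
    expect_equal(est$d, as.numeric(ape::dist.dna(bin, model = "JC69")),
                 tolerance = 1e-9)
    est_k <- estimate_insertion_age(
      tibble::tibble(element_id = "e1", ltr5 = a, ltr3 = b), model = "K2P")
    expect_equal(est_k$d, as.numeric(ape::dist.dna(bin, model = "K80")),
                 tolerance = 1e-9)
  })
})

test_that("identical LTRs date to age zero; T = d / (2r) in My", {
  withr::with_seed(142, {
    s <- random_dna_str(500)
    est <- estimate_insertion_age(
      tibble::tibble(element_id = "e", ltr5 = s, ltr3 = s))
    expect_identical(est$age_my, 0)
    # p = 0.10 at r = 1.3e-8 -> ~4.13 My
    b <- s
    pos <- sample(500, 50)
    for (p in pos) {
      substr(b, p, p) <- setdiff(c("A", "C", "G", "T"), substr(b, p, p))[1]
    }
    est2 <- estimate_insertion_age(
      tibble::tibble(element_id = "e", ltr5 = s, ltr3 = b))
    expect_equal(est2$p_distance, 0.1, tolerance = 1e-9)
    expect_equal(est2$age_my, 0.10732 / (2 * 1.3e-8) / 1e6, tolerance = 1e-3)
  })
})

test_that("cohort age estimation recovers the planted exponential median", {
  lib <- make_repeat_library(seed = 143, ltr_len = 3000)
  cohort <- make_ltr_cohort(200, lib, median_age = 0.46, seed = 144)
  est <- estimate_insertion_age(cohort)
  expect_lt(abs(median(est$age_my) - median(cohort$true_age)) /
              median(cohort$true_age), 0.10)
})

test_that("family clustering equals brute-force connected components", {
  withr::with_seed(145, {
    for (rep in 1:6) {
      n_templates <- sample(2:3, 1)
      templates <- vapply(seq_len(n_templates), function(i) random_dna_str(150),
                          "")
      n <- sample(8:14, 1)
      ltr5 <- vapply(seq_len(n), function(i) {
        t <- templates[sample(n_templates, 1)]
        for (p in sample(150, 8)) {
          substr(t, p, p) <- sample(c("A", "C", "G", "T"), 1)
        }
        t
      }, "")
      elements <- tibble::tibble(element_id = sprintf("e%02d", seq_len(n)),
                                 ltr5 = ltr5,
                                 class = sample(c("A", "B"), n, replace = TRUE))
      cl <- cluster_ltr_families(elements, identity_threshold = 80,
                                 min_members = 2)
      ora <- oracle_families(ltr5, 80)
      # same partition: equal label co-membership matrices
      mine <- outer(cl$members$family, cl$members$family, "==")
      theirs <- outer(ora, ora, "==")
      expect_identical(mine, theirs)
      # per-family class counts sum correctly
      expect_identical(sum(cl$families$n), n)
      expect_identical(sum(cl$families$n_A) + sum(cl$families$n_B), n)
    }
  })
})

test_that("single-template cohorts form one family; min_members filters", {
  lib <- make_repeat_library(seed = 146, n_te_templates = 1)
  cohort <- make_ltr_cohort(12, lib, median_age = 0.2, seed = 147)
  cl <- cluster_ltr_families(cohort)
  expect_identical(nrow(cl$families), 1L)
  expect_true(cl$families$included[1])
  cl2 <- cluster_ltr_families(cohort, min_members = 20)
  expect_false(cl2$families$included[1])
})

test_that("age summaries apply the percentile display cut", {
  ages <- tibble::tibble(
    element_id = sprintf("e%03d", 1:200),
    family = "LTRfam01",
    class = rep(c("A", "B"), 100),
    age_my = c(rep(0.5, 199), 50))
  s <- summarize_ages(ages, percentile_cut = 99)
  expect_lt(s$cut_age, 50)
  expect_identical(sum(s$per_family$n), 199L)
  expect_equal(s$comparison$delta, 0, tolerance = 1e-12)
})

test_that("A and B cohorts drawn from one distribution have close medians", {
  lib <- make_repeat_library(seed = 148, n_te_templates = 2, ltr_len = 600)
  cohort <- make_ltr_cohort(150, lib, median_age = 0.46, seed = 149)
  est <- estimate_insertion_age(cohort)
  s <- summarize_ages(est)
  big <- dplyr::filter(s$per_family, n >= 10)
  iqr <- dplyr::summarise(
    dplyr::group_by(dplyr::semi_join(est, big, by = "family"), family),
    iqr = stats::IQR(age_my))
  cmp <- dplyr::inner_join(s$comparison, iqr, by = "family")
  expect_true(all(cmp$delta < cmp$iqr))
})
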