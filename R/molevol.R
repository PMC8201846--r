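#' Cluster LTR retrotransposons into families by 5' LTR similarity
#'
#' Single-linkage clustering on pairwise global identity of the 5' LTRs:
#' elements are in the same family when connected by a chain of pairwise
#' identities at or above `identity_threshold`. Families with fewer than
#' `min_members` members are reported but excluded from summaries; per-family
#' A/B member counts give the abundance comparison.
#'
#' @param elements Tibble with `element_id`, `ltr5` and optionally `class`
#'   (A/B), e.g. from [make_ltr_cohort()].
#' @param identity_threshold Percent identity for linkage (default 80).
#' @param min_members Minimum family size for inclusion (default 10).
#' @return A list: `members` (tibble: `element_id`, `family`, `class`),
#'   `families` (tibble: `family`, `n`, `n_A`, `n_B`, `included`).
#' @export
cluster_ltr_families <- function(elements, identity_threshold = 80,
                                 min_members = 10) {
  n <- nrow(elements)
  check_that(n >= 1, "need at least one element")
  parent <- seq_len(n)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  if (n > 1) {
    for (i in 1:(n - 1)) {
      for (j in (i + 1):n) {
        if (find(i) == find(j)) next
        if (align_identity(elements$ltr5[i], elements$ltr5[j]) >=
            identity_threshold) {
          parent[find(j)] <- find(i)
        }
      }
    }
  }
  root <- vapply(seq_len(n), find, integer(1))
  fam_id <- match(root, unique(root[order(-tabulate(root, n))]))
  members <- tibble(
    element_id = elements$element_id,
    family = sprintf("LTRfam%02d", fam_id),
    class = if ("class" %in% names(elements)) elements$class else
      rep(NA_character_, n)
  )
  families <- members |>
    group_by(.data$family) |>
    summarise(n = n(),
              n_A = sum(.data$class == "A", na.rm = TRUE),
              n_B = sum(.data$class == "B", na.rm = TRUE),
              .groups = "drop") |>
    mutate(included = .data$n >= min_members) |>
    arrange(desc(.data$n))
  list(members = members, families = families)
}

# aligned ungapped column comparison of two sequences; returns p-distance and
# transition/transversion proportions
ltr_divergence <- function(a, b) {
  aln <- Biostrings::pairwiseAlignment(
    Biostrings::DNAString(a), Biostrings::DNAString(b), type = "global",
    substitutionMatrix = Biostrings::nucleotideSubstitutionMatrix(
      match = 1, mismatch = -1),
    gapOpening = 4, gapExtension = 1)
  pa <- strsplit(as.character(Biostrings::alignedPattern(aln)), "")[[1]]
  sa <- strsplit(as.character(Biostrings::alignedSubject(aln)), "")[[1]]
  ok <- pa != "-" & sa != "-"
  pa <- pa[ok]
  sa <- sa[ok]
  nsite <- length(pa)
  diff <- pa != sa
  purine <- c("A", "G")
  is_ts <- diff & ((pa %in% purine) == (sa %in% purine))
  list(p = sum(diff) / nsite, P = sum(is_ts) / nsite,
       Q = sum(diff & !is_ts) / nsite, n_sites = nsite)
}

#' Estimate LTR retrotransposon insertion ages
#'
#' For each element, globally aligns its 5' and 3' LTRs, computes the
#' p-distance over ungapped columns, corrects it for multiple hits (JC69 by
#' default, or K2P) and converts to an age `T = d / (2r)`: the two LTRs were
#' identical at insertion and each accumulates substitutions at rate `r`.
#' Saturated pairs (JC69 undefined at `p >= 0.74`) are flagged with `NA`
#' distance and age.
#'
#' @param pairs Tibble with `element_id`, `ltr5`, `ltr3` (extra columns are
#'   carried through), e.g. from [make_ltr_cohort()].
#' @param rate Substitution rate in substitutions/site/year (default
#'   `1.3e-8`, a standard plant LTR clock; not derived from any one dataset).
#' @param model Distance correction: `"JC69"` (default) or `"K2P"`.
#' @return The input tibble with added `p_distance`, `d`, `age_my`,
#'   `saturated`.
#' @export
estimate_insertion_age <- function(pairs, rate = 1.3e-8,
                                   model = c("JC69", "K2P")) {
  model <- match.arg(model)
  check_that(rate > 0, "rate must be > 0")
  res <- purrr::map_dfr(seq_len(nrow(pairs)), function(i) {
    dv <- ltr_divergence(pairs$ltr5[i], pairs$ltr3[i])
    d <- switch(model,
      JC69 = jc69_distance(dv$p),
      K2P = k2p_distance(dv$P, dv$Q)
    )
    tibble(p_distance = dv$p, d = d,
           age_my = d / (2 * rate) / 1e6,
           saturated = is.na(d))
  })
  bind_cols(pairs, res)
}

#' Jukes-Cantor and Kimura two-parameter distance corrections
#'
#' `jc69_distance()` returns `-(3/4) log(1 - 4p/3)`; `k2p_distance()` returns
#' `(1/2) log(1 / (1 - 2P - Q)) + (1/4) log(1 / (1 - 2Q))` for transition and
#' transversion proportions `P` and `Q`. Saturated inputs give `NA`.
#'
#' @param p Proportion of differing sites.
#' @param P,Q Transition and transversion proportions.
#' @return Corrected distance in substitutions/site.
#' @export
jc69_distance <- function(p) {
  ifelse(p >= 0.74, NA_real_, -0.75 * log(1 - 4 * p / 3))
}

#' @rdname jc69_distance
#' @export
k2p_distance <- function(P, Q) {
  w1 <- 1 - 2 * P - Q
  w2 <- 1 - 2 * Q
  ifelse(w1 <= 0 | w2 <= 0, NA_real_, 0.5 * log(1 / w1) + 0.25 * log(1 / w2))
}

#' Summarise insertion ages per family with a display percentile cut
#'
#' Excludes elements above the `percentile_cut` age percentile (computed over
#' the whole cohort; default 99) and reports per-family medians and quartiles
#' for A- and B-class members side by side.
#'
#' @param ages Tibble from [estimate_insertion_age()] with `family` and
#'   `class` columns.
#' @param percentile_cut Percentile above which elements are excluded.
#' @return A list: `per_family` (tibble: `family`, `class`, `n`, `median_age`,
#'   `q25`, `q75`), `comparison` (tibble: `family`, `median_A`, `median_B`,
#'   `delta`), `cut_age`.
#' @export
summarize_ages <- function(ages, percentile_cut = 99) {
  check_that(nrow(ages) >= 1, "need at least one estimate")
  usable <- ages |> filter(!is.na(.data$age_my))
  cut_age <- quantile(usable$age_my, percentile_cut / 100, names = FALSE)
  kept <- usable |> filter(.data$age_my <= cut_age)
  per_family <- kept |>
    group_by(.data$family, .data$class) |>
    summarise(n = n(), median_age = median(.data$age_my),
              q25 = quantile(.data$age_my, 0.25, names = FALSE),
              q75 = quantile(.data$age_my, 0.75, names = FALSE),
              .groups = "drop")
  comparison <- per_family |>
    select("family", "class", "median_age") |>
    tidyr::pivot_wider(names_from = "class", values_from = "median_age",
                       names_prefix = "median_")
  comparison$delta <- if (all(c("median_A", "median_B") %in% names(comparison))) {
    abs(comparison$median_A - comparison$median_B)
  } else {
    NA_real_
  }
  list(per_family = per_family, comparison = comparison, cut_age = cut_age)
}
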