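#' Protein-guided codon alignment of two coding sequences
#'
#' Trims any trailing length remainder and trailing stop codons, translates
#' both sequences, aligns the proteins globally (BLOSUM62, affine gaps) and
#' back-threads the nucleotides, so every gap has length a multiple of 3 and
#' codon columns stay in frame. Internal stop codons are an error naming the
#' offending sequence.
#'
#' @param cds_a,cds_b Coding sequences.
#' @param names Length-2 character vector used in error messages.
#' @return A `codon_alignment` list: `codons` (tibble: `codon_a`, `codon_b`,
#'   `"---"` for gaps), `aligned_a`, `aligned_b`.
#' @export
align_codon_pair <- function(cds_a, cds_b, names = c("cds_a", "cds_b")) {
  a <- trim_cds(cds_a, names[1])
  b <- trim_cds(cds_b, names[2])
  pa <- as.character(Biostrings::translate(Biostrings::DNAString(a)))
  pb <- as.character(Biostrings::translate(Biostrings::DNAString(b)))
  aln <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(pa), Biostrings::AAString(pb), type = "global",
    substitutionMatrix = "BLOSUM62", gapOpening = 10, gapExtension = 0.5)
  ap <- strsplit(as.character(Biostrings::alignedPattern(aln)), "")[[1]]
  as_ <- strsplit(as.character(Biostrings::alignedSubject(aln)), "")[[1]]
  ca <- codon_split(a)
  cb <- codon_split(b)
  ia <- 0L
  ib <- 0L
  codon_a <- character(length(ap))
  codon_b <- character(length(ap))
  for (i in seq_along(ap)) {
    if (ap[i] == "-") {
      codon_a[i] <- "---"
    } else {
      ia <- ia + 1L
      codon_a[i] <- ca[ia]
    }
    if (as_[i] == "-") {
      codon_b[i] <- "---"
    } else {
      ib <- ib + 1L
      codon_b[i] <- cb[ib]
    }
  }
  structure(list(
    codons = tibble(codon_a = codon_a, codon_b = codon_b),
    aligned_a = paste(codon_a, collapse = ""),
    aligned_b = paste(codon_b, collapse = "")
  ), class = "codon_alignment")
}

trim_cds <- function(cds, name) {
  cds <- substr(cds, 1, (nchar(cds) %/% 3) * 3)
  codons <- codon_split(cds)
  stops <- c("TAA", "TAG", "TGA")
  while (length(codons) && tail(codons, 1) %in% stops) {
    codons <- head(codons, -1)
  }
  check_that(length(codons) > 0, sprintf("%s is empty after trimming", name))
  internal_stop <- codons %in% stops
  if (any(internal_stop)) {
    abort(sprintf("internal stop codon in %s at codon %d", name,
                  which(internal_stop)[1]))
  }
  paste(codons, collapse = "")
}

codon_split <- function(cds) {
  n <- nchar(cds) %/% 3
  substring(cds, 3 * (seq_len(n) - 1) + 1, 3 * seq_len(n))
}

# ---- NG86 machinery ---------------------------------------------------------
# Synonymous site fraction per codon: for each position, the fraction of the
# three possible changes that preserve the amino acid. Changes to stop codons
# count as nonsynonymous, so N + S = 3 * codons exactly.
ng86_site_table <- local({
  tbl <- NULL
  function() {
    if (!is.null(tbl)) return(tbl)
    codons <- names(Biostrings::GENETIC_CODE)
    stops <- codons[Biostrings::GENETIC_CODE == "*"]
    sense <- setdiff(codons, stops)
    syn <- vapply(sense, function(cd) {
      chars <- strsplit(cd, "")[[1]]
      s <- 0
      for (pos in 1:3) {
        for (nb in setdiff(DNA_BASES, chars[pos])) {
          alt <- chars
          alt[pos] <- nb
          alt_cd <- paste(alt, collapse = "")
          if (Biostrings::GENETIC_CODE[[alt_cd]] ==
              Biostrings::GENETIC_CODE[[cd]] && !alt_cd %in% stops) {
            s <- s + 1 / 3
          }
        }
      }
      s
    }, numeric(1))
    tbl <<- syn
    tbl
  }
})

# Average synonymous/nonsynonymous substitution counts between two codons over
# all shortest mutational paths (equal weights); paths through stop codons are
# excluded unless every path is blocked.
ng86_path_counts <- function(cd1, cd2) {
  diff_pos <- which(strsplit(cd1, "")[[1]] != strsplit(cd2, "")[[1]])
  nd <- length(diff_pos)
  if (nd == 0) return(c(syn = 0, nonsyn = 0))
  stops <- c("TAA", "TAG", "TGA")
  perms <- all_permutations(diff_pos)
  path_counts <- list()
  for (ord in perms) {
    cur <- strsplit(cd1, "")[[1]]
    tgt <- strsplit(cd2, "")[[1]]
    s <- 0
    ns <- 0
    blocked <- FALSE
    for (p in ord) {
      prev_cd <- paste(cur, collapse = "")
      cur[p] <- tgt[p]
      new_cd <- paste(cur, collapse = "")
      if (new_cd %in% stops && !identical(new_cd, cd2)) blocked <- TRUE
      if (prev_cd %in% stops || new_cd %in% stops) {
        # step through/into a stop: classified nonsynonymous if kept
        ns <- ns + 1
      } else if (Biostrings::GENETIC_CODE[[prev_cd]] ==
                 Biostrings::GENETIC_CODE[[new_cd]]) {
        s <- s + 1
      } else {
        ns <- ns + 1
      }
    }
    path_counts[[length(path_counts) + 1]] <-
      list(syn = s, nonsyn = ns, blocked = blocked)
  }
  ok <- !vapply(path_counts, `[[`, logical(1), "blocked")
  use <- if (any(ok)) path_counts[ok] else path_counts
  c(syn = mean(vapply(use, `[[`, numeric(1), "syn")),
    nonsyn = mean(vapply(use, `[[`, numeric(1), "nonsyn")))
}

all_permutations <- function(x) {
  if (length(x) == 1) return(list(x))
  out <- list()
  for (i in seq_along(x)) {
    for (rest in all_permutations(x[-i])) {
      out[[length(out) + 1]] <- c(x[i], rest)
    }
  }
  out
}

#' NG86 Ka/Ks from a codon alignment
#'
#' Nei-Gojobori (1986) counting: per-codon synonymous site fractions averaged
#' over the two sequences; substitutions classified by averaging over all
#' shortest mutational paths between differing codons (ties equally
#' weighted, stop-traversing paths excluded when avoidable); Jukes-Cantor
#' correction applied to the proportions. Codons containing gaps or ambiguous
#' bases are dropped. The ratio is undefined (`NA`) when Ks = 0; saturated
#' proportions (>= 0.74) are flagged and left uncorrected as `NA` distances
#' with the raw proportions still reported.
#'
#' @param alignment A `codon_alignment` from [align_codon_pair()], or a
#'   two-element character vector of equal-length in-frame CDS (aligned
#'   gaplessly).
#' @param min_codons Minimum aligned codons (default 10).
#' @return A `kaks_result` one-row tibble: `n_codons`, `N`, `S`, `Na`, `Ns`,
#'   `pN`, `pS`, `Ka`, `Ks`, `ratio`, `saturated`.
#' @export
compute_kaks <- function(alignment, min_codons = 10) {
  if (is.character(alignment)) {
    check_that(length(alignment) == 2 &&
                 nchar(alignment[1]) == nchar(alignment[2]),
               "character input must be two equal-length sequences")
    codons <- tibble(codon_a = codon_split(alignment[1]),
                     codon_b = codon_split(alignment[2]))
  } else {
    codons <- alignment$codons
  }
  ok <- !grepl("[^ACGT]", codons$codon_a) & !grepl("[^ACGT]", codons$codon_b)
  codons <- codons[ok, ]
  check_that(nrow(codons) >= min_codons,
             sprintf("fewer than %d aligned codons", min_codons))
  site <- ng86_site_table()
  s_a <- sum(site[codons$codon_a])
  s_b <- sum(site[codons$codon_b])
  S <- (s_a + s_b) / 2
  N <- 3 * nrow(codons) - S
  diffs <- which(codons$codon_a != codons$codon_b)
  Na <- 0
  Ns <- 0
  for (i in diffs) {
    cnt <- ng86_path_counts(codons$codon_a[i], codons$codon_b[i])
    Ns <- Ns + cnt[["syn"]]
    Na <- Na + cnt[["nonsyn"]]
  }
  pN <- Na / N
  pS <- Ns / S
  Ka <- jc69_distance(pN)
  Ks <- jc69_distance(pS)
  saturated <- is.na(Ka) || is.na(Ks)
  ratio <- if (saturated || Ks == 0) NA_real_ else Ka / Ks
  out <- tibble(n_codons = nrow(codons), N = N, S = S, Na = Na, Ns = Ns,
                pN = pN, pS = pS, Ka = Ka, Ks = Ks, ratio = ratio,
                saturated = saturated)
  class(out) <- c("kaks_result", class(out))
  out
}

#' Ka/Ks of a CDS pair (align + compute)
#'
#' Convenience wrapper: [align_codon_pair()] then [compute_kaks()].
#'
#' @param cds_a,cds_b Coding sequences.
#' @param ... Passed to [compute_kaks()].
#' @return A `kaks_result` tibble row.
#' @export
kaks_pair <- function(cds_a, cds_b, ...) {
  compute_kaks(align_codon_pair(cds_a, cds_b), ...)
}

#' Three-way relaxed-selection comparison
#'
#' For each (B, A, outgroup) gene triple, computes NG86 Ka/Ks for the B-A,
#' B-outgroup and A-outgroup pairs, then tests for a global elevation of
#' Ka/Ks in the comparisons that involve the B copy: a one-sided Wilcoxon
#' signed-rank test of paired Ka/Ks(B,A) vs Ka/Ks(A,outgroup). Triples with
#' an undefined ratio in either member of the tested pair are dropped from
#' the test (and counted).
#'
#' @param triples Tibble with `pair_id`, `cds_b`, `cds_a`, `cds_out`, e.g.
#'   from [make_coding_triples()].
#' @return A `selection_comparison` list: `ratios` (tibble: `pair_id`,
#'   `kaks_b_a`, `kaks_b_out`, `kaks_a_out`), `medians`, `wilcox` (statistic,
#'   `p`), `n_dropped`.
#' @export
selection_comparison <- function(triples) {
  ratios <- purrr::map_dfr(seq_len(nrow(triples)), function(i) {
    tibble(
      pair_id = triples$pair_id[i],
      kaks_b_a = kaks_pair(triples$cds_b[i], triples$cds_a[i])$ratio,
      kaks_b_out = kaks_pair(triples$cds_b[i], triples$cds_out[i])$ratio,
      kaks_a_out = kaks_pair(triples$cds_a[i], triples$cds_out[i])$ratio
    )
  })
  paired <- ratios |>
    filter(!is.na(.data$kaks_b_a), !is.na(.data$kaks_a_out))
  n_dropped <- nrow(ratios) - nrow(paired)
  wt <- stats::wilcox.test(paired$kaks_b_a, paired$kaks_a_out,
                           paired = TRUE, alternative = "greater",
                           exact = FALSE)
  structure(list(
    ratios = ratios,
    medians = c(b_a = median(ratios$kaks_b_a, na.rm = TRUE),
                b_out = median(ratios$kaks_b_out, na.rm = TRUE),
                a_out = median(ratios$kaks_a_out, na.rm = TRUE)),
    wilcox = list(statistic = unname(wt$statistic), p = wt$p.value),
    n_dropped = n_dropped
  ), class = "selection_comparison")
}

#' @export
print.selection_comparison <- function(x, ...) {
  cat("<selection_comparison>\n")
  cat(sprintf("  median Ka/Ks: B-A %.3f, B-out %.3f, A-out %.3f\n",
              x$medians[["b_a"]], x$medians[["b_out"]], x$medians[["a_out"]]))
  cat(sprintf("  one-sided Wilcoxon (B-A > A-out): p = %.3g (%d dropped)\n",
              x$wilcox$p, x$n_dropped))
  invisible(x)
}
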