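#' Default B-chromosome blueprint
#'
#' Segment layout of the synthetic acrocentric B chromosome, in fixed order:
#' short arm (BS), centromere (BC), proximal heterochromatin (PH), proximal
#' euchromatin (PE), four distal heterochromatin blocks (DH1-DH4), and distal
#' euchromatin (DE). Each segment carries a transposable-element occupancy, a
#' tandem-array composition (B-specific, knob, centromeric-satellite weights)
#' and a gene density. The per-segment TE fractions are scaled so that TE
#' features cover `te_fraction` of the whole chromosome (default 0.60,
#' matching the TE occupancy the chromosome is modelled on). The short arm is
#' almost pure B-specific repeat; the centromere mixes B-specific arrays with
#' centromeric satellite plus a minor unique/genic component; knob arrays sit
#' in the heterochromatin blocks and are shared with the A chromosomes.
#'
#' @param total_length Total B length in bp (> 20 kb).
#' @param te_fraction Genome-wide fraction of the B covered by TE features.
#' @return A `b_blueprint` tibble with one row per segment: `segment`,
#'   `length`, `te_frac`, `arr_b`, `arr_knob`, `arr_centc`, `gene_per_mb`.
#' @export
default_blueprint <- function(total_length = 4e5, te_fraction = 0.60) {
  check_that(total_length > 2e4, "total_length must exceed 20 kb")
  bp <- tibble(
    segment = c("BS", "BC", "PH", "PE", "DH1", "DH2", "DH3", "DH4", "DE"),
    frac = c(0.04, 0.06, 0.10, 0.22, 0.09, 0.09, 0.09, 0.09, 0.22),
    te_frac = c(0.05, 0.15, 0.45, 0.75, 0.60, 0.60, 0.60, 0.60, 0.75),
    arr_b = c(0.80, 0.45, 0.10, 0, 0, 0, 0, 0, 0),
    arr_knob = c(0.05, 0, 0.30, 0, 0.25, 0.25, 0.25, 0.25, 0),
    arr_centc = c(0, 0.25, 0, 0, 0, 0, 0, 0, 0),
    gene_per_mb = c(0, 25, 5, 40, 5, 5, 5, 5, 40)
  )
  # rescale TE occupancy so the genome-wide weighted fraction hits te_fraction
  bp$te_frac <- bp$te_frac * te_fraction / sum(bp$te_frac * bp$frac)
  check_that(all(bp$te_frac + bp$arr_b + bp$arr_knob + bp$arr_centc < 0.97),
             "te_fraction too high: segment composition exceeds capacity")
  bp$length <- diff(round(cumsum(c(0, bp$frac)) * total_length))
  structure(bp[, c("segment", "length", "te_frac", "arr_b", "arr_knob",
                   "arr_centc", "gene_per_mb")],
            class = c("b_blueprint", class(bp)))
}

# ---- low-level builders (use current RNG state) -----------------------------

sample_age_my <- function(n, median_age) rexp(n, log(2) / median_age)

# One LTR retrotransposon copy: both LTRs derive from the family template and
# are mutated independently with expected per-site divergence age * rate each,
# so the expected pairwise 5'-3' divergence is 2 * age * rate.
make_te_element <- function(library, family, age_my, rate = 1.3e-8) {
  tmpl <- library$te_templates[library$te_templates$family == family, ]
  per_site <- age_my * 1e6 * rate
  ltr5 <- mutate_seq_rate(tmpl$ltr, per_site)
  ltr3 <- mutate_seq_rate(tmpl$ltr, per_site)
  internal <- mutate_seq_rate(tmpl$internal, per_site)
  list(seq = paste0(ltr5, internal, ltr3), family = family, age = age_my,
       ltr5 = ltr5, ltr3 = ltr3, internal = internal)
}

#' Generate a cohort of dated LTR insertion events
#'
#' Draws `n` LTR retrotransposon insertions with ages from an exponential
#' distribution (configurable median; default 0.46 My, used as a simulation
#' default). Each element's 5' and 3' LTRs are mutated independently from the
#' family template so their expected pairwise divergence is `2 * age * rate`.
#' True ages are retained for parameter-recovery testing.
#'
#' @param n Number of elements.
#' @param library A [make_repeat_library()] object.
#' @param median_age Median insertion age in million years.
#' @param rate Substitution rate in substitutions/site/year.
#' @param p_b Probability an element is assigned to the B chromosome class
#'   (ages are drawn from the same distribution for both classes by default).
#' @param seed Integer seed.
#' @return Tibble: `element_id`, `family`, `class` (A/B), `true_age` (My),
#'   `ltr5`, `ltr3`, `internal`.
#' @export
make_ltr_cohort <- function(n, library, median_age = 0.46, rate = 1.3e-8,
                            p_b = 0.5, seed = 1) {
  check_that(n >= 1, "n must be >= 1")
  withr::with_seed(seed, {
    fams <- sample(library$te_templates$family, n, replace = TRUE)
    ages <- sample_age_my(n, median_age)
    cls <- ifelse(runif(n) < p_b, "B", "A")
    els <- lapply(seq_len(n), function(i) {
      make_te_element(library, fams[i], ages[i], rate)
    })
    tibble(
      element_id = sprintf("el%04d", seq_len(n)),
      family = fams, class = cls, true_age = ages,
      ltr5 = vapply(els, `[[`, "", "ltr5"),
      ltr3 = vapply(els, `[[`, "", "ltr3"),
      internal = vapply(els, `[[`, "", "internal")
    )
  })
}

# Random CDS: ATG + (n_codons - 2) random non-stop codons + TAA.
make_cds <- function(n_codons) {
  stops <- c("TAA", "TAG", "TGA")
  codons <- character(n_codons)
  codons[1] <- "ATG"
  body <- replicate(n_codons - 2, {
    repeat {
      cd <- paste(sample(DNA_BASES, 3, replace = TRUE), collapse = "")
      if (!cd %in% stops) break
    }
    cd
  })
  codons[2:(n_codons - 1)] <- body
  codons[n_codons] <- "TAA"
  paste(codons, collapse = "")
}

GENETIC_CODE_V <- Biostrings::GENETIC_CODE

translate_codon <- function(codon) unname(GENETIC_CODE_V[codon])

#' Evolve a coding sequence under configurable selective constraint
#'
#' Proposes random single-base substitutions at `sub_rate` per site;
#' synonymous proposals are always accepted, nonsynonymous proposals with
#' probability `nonsyn_accept`, and proposals creating an internal stop are
#' rejected. `nonsyn_accept = 1` gives neutral evolution; values below 1 give
#' purifying selection; raising it emulates relaxed constraint (as for genes
#' transposed onto a dispensable chromosome).
#'
#' @param cds Coding sequence (length a multiple of 3, no internal stops).
#' @param sub_rate Expected proposed substitutions per site.
#' @param nonsyn_accept Acceptance probability for nonsynonymous proposals.
#' @return The evolved CDS string.
#' @export
evolve_cds <- function(cds, sub_rate, nonsyn_accept = 0.2) {
  len <- nchar(cds)
  check_that(len %% 3 == 0, "cds length must be a multiple of 3")
  chars <- strsplit(cds, "", fixed = TRUE)[[1]]
  stops <- c("TAA", "TAG", "TGA")
  n_prop <- rpois(1, len * sub_rate)
  if (n_prop == 0) return(cds)
  pos <- sample.int(len, n_prop, replace = TRUE)
  n_codon <- len / 3
  for (p in pos) {
    ci <- (p - 1) %/% 3
    old_codon <- paste(chars[(ci * 3 + 1):(ci * 3 + 3)], collapse = "")
    new_base <- sample(setdiff(DNA_BASES, chars[p]), 1)
    new_chars <- chars[(ci * 3 + 1):(ci * 3 + 3)]
    new_chars[p - ci * 3] <- new_base
    new_codon <- paste(new_chars, collapse = "")
    if (new_codon %in% stops && ci < n_codon - 1) next
    syn <- identical(translate_codon(old_codon), translate_codon(new_codon))
    if (syn || runif(1) < nonsyn_accept) chars[p] <- new_base
  }
  paste(chars, collapse = "")
}

#' Simulate gene triples with relaxed selection on the B copy
#'
#' For each triple an ancestral CDS is evolved along an outgroup branch and an
#' A-chromosome branch under the same purifying constraint; the B copy is then
#' derived from the A copy (a transposition event) with its nonsynonymous
#' acceptance multiplied by `b_multiplier`, emulating relaxed purifying
#' selection on a dispensable chromosome. With `b_multiplier = 1` all three
#' copies evolve under identical constraint (the null case).
#'
#' @param n Number of triples.
#' @param n_codons Codons per CDS.
#' @param out_rate,a_rate,b_rate Proposed substitutions/site on the outgroup,
#'   A, and B branches.
#' @param nonsyn_accept Baseline nonsynonymous acceptance probability.
#' @param b_multiplier Multiplier on the B-branch nonsynonymous acceptance.
#' @param seed Integer seed.
#' @return Tibble: `pair_id`, `cds_b`, `cds_a`, `cds_out`.
#' @export
make_coding_triples <- function(n = 100, n_codons = 300, out_rate = 0.08,
                                a_rate = 0.03, b_rate = 0.05,
                                nonsyn_accept = 0.2, b_multiplier = 2,
                                seed = 1) {
  withr::with_seed(seed, {
    purrr::map_dfr(seq_len(n), function(i) {
      anc <- make_cds(n_codons)
      tibble(
        pair_id = sprintf("g%04d", i),
        cds_out = evolve_cds(anc, out_rate, nonsyn_accept),
        cds_a = evolve_cds(anc, a_rate, nonsyn_accept),
      ) |>
        mutate(cds_b = evolve_cds(.data$cds_a, b_rate,
                                  min(1, nonsyn_accept * b_multiplier))) |>
        select("pair_id", "cds_b", "cds_a", "cds_out")
    })
  })
}

#' Simulate neutrally evolving coding pairs
#'
#' Both copies descend from a common ancestor with every proposed substitution
#' accepted (`nonsyn_accept = 1`), so the expected Ka/Ks is 1.
#'
#' @param n Number of pairs.
#' @param n_codons Codons per CDS.
#' @param sub_rate Proposed substitutions/site on each branch.
#' @param seed Integer seed.
#' @return Tibble: `pair_id`, `cds1`, `cds2`.
#' @export
make_neutral_pairs <- function(n = 100, n_codons = 300, sub_rate = 0.05,
                               seed = 1) {
  withr::with_seed(seed, {
    purrr::map_dfr(seq_len(n), function(i) {
      anc <- make_cds(n_codons)
      tibble(pair_id = sprintf("p%04d", i),
             cds1 = evolve_cds(anc, sub_rate, 1),
             cds2 = evolve_cds(anc, sub_rate, 1))
    })
  })
}

# ---- region assembly --------------------------------------------------------

# Assemble one region from typed blocks. Quotas are in bp; blocks are created
# per class, shuffled, and concatenated. Returns seq + 0-based feature table.
build_region <- function(len, library, te_bp, array_bp, genes, median_age,
                         rate, monomer_divergence = 0.02) {
  blocks <- list()
  add <- function(seq, type, source_id, age = NA_real_, strand = "+",
                  intact = NA) {
    blocks[[length(blocks) + 1]] <<- list(seq = seq, type = type,
                                          source_id = source_id, age = age,
                                          strand = strand, intact = intact)
  }
  # TE copies (truncate the last to fit the quota; truncated copies are real
  # features but are not usable for LTR dating)
  remaining <- te_bp
  fams <- library$te_templates$family
  while (remaining > 0) {
    el <- make_te_element(library, sample(fams, 1),
                          sample_age_my(1, median_age), rate)
    s <- el$seq
    intact <- TRUE
    if (nchar(s) > remaining) {
      s <- substr(s, 1, remaining)
      intact <- FALSE
    }
    add(s, "te", el$family, age = el$age, intact = intact)
    remaining <- remaining - nchar(s)
  }
  # tandem arrays: runs of lightly diverged monomer copies
  for (cls in names(array_bp)) {
    quota <- array_bp[[cls]]
    monomer <- library$monomers[[cls]]
    ml <- nchar(monomer)
    while (quota > 0) {
      copies <- sample(8:40, 1)
      units <- vapply(seq_len(copies), function(i) {
        mutate_seq(monomer, rpois(1, ml * monomer_divergence))
      }, character(1))
      s <- paste(units, collapse = "")
      if (nchar(s) > quota) s <- substr(s, 1, quota)
      add(s, "repeat", cls)
      quota <- quota - nchar(s)
    }
  }
  # genes: tibble(gene_id, cds, donor)
  if (!is.null(genes) && nrow(genes) > 0) {
    for (i in seq_len(nrow(genes))) {
      strand <- sample(c("+", "-"), 1)
      s <- if (strand == "+") genes$cds[i] else revcomp(genes$cds[i])
      add(s, "gene", genes$gene_id[i], strand = strand)
    }
  }
  used <- sum(vapply(blocks, function(b) nchar(b$seq), numeric(1)))
  check_that(used <= len, "region composition exceeds region length")
  # unique filler in chunks, shuffled in between everything else
  remaining <- len - used
  while (remaining > 0) {
    chunk <- min(remaining, sample(1000:4000, 1))
    add(random_dna(chunk), "unique", NA_character_)
    remaining <- remaining - chunk
  }
  blocks <- blocks[sample.int(length(blocks))]
  seqs <- vapply(blocks, `[[`, "", "seq")
  widths <- nchar(seqs)
  starts <- cumsum(c(0, widths[-length(widths)]))
  feats <- tibble(
    type = vapply(blocks, `[[`, "", "type"),
    start = as.integer(starts),
    end = as.integer(starts + widths),
    strand = vapply(blocks, `[[`, "", "strand"),
    source_id = vapply(blocks, `[[`, "", "source_id"),
    age = vapply(blocks, function(b) b$age, numeric(1)),
    intact = vapply(blocks, function(b) b$intact, logical(1))
  )
  list(seq = paste(seqs, collapse = ""),
       features = feats[feats$type != "unique", ])
}

#' Generate a synthetic genome model
#'
#' Builds a small A-chromosome complement plus one acrocentric B chromosome
#' following the segment blueprint, with a complete ground-truth feature
#' table. B-specific tandem arrays occur only on the B; knob arrays occur on
#' both A and B; TEs are drawn from a shared template/age distribution on both
#' complements; each transposed B gene is a mutated copy of a randomly chosen
#' A gene with elevated nonsynonymous acceptance (relaxed purifying
#' selection), and the donor is recorded.
#'
#' @param blueprint A [default_blueprint()] tibble.
#' @param library A [make_repeat_library()] object.
#' @param n_a_chromosomes Number of A chromosomes.
#' @param a_length Length of each A chromosome (bp).
#' @param n_transposed_genes Number of genes transposed from A onto the B.
#' @param seed Integer seed.
#' @param median_age Median TE insertion age (My) for both complements.
#' @param rate LTR substitution rate (subs/site/year).
#' @param gene_len_codons Codons per synthetic gene.
#' @param a_gene_per_mb A-chromosome gene density.
#' @param b_nonsyn_multiplier Multiplier on nonsynonymous acceptance for
#'   transposed B gene copies (default 2, making relaxed selection
#'   recoverable by construction).
#' @param b_median_age Optional separate median TE age for the B (defaults to
#'   `median_age`; a different value gives a divergent-age negative control).
#' @return A `genome_model` list: `a_chromosomes` (named character),
#'   `b_chromosome` (character), `truth` (B feature tibble, 0-based
#'   half-open), `a_truth`, `a_genes`, `b_genes`, `a_segments`, plus the
#'   library, blueprint and parameters.
#' @export
make_genome <- function(blueprint = default_blueprint(),
                        library = make_repeat_library(),
                        n_a_chromosomes = 2,
                        a_length = 150000,
                        n_transposed_genes = 20,
                        seed = 1,
                        median_age = 0.46,
                        rate = 1.3e-8,
                        gene_len_codons = 300,
                        a_gene_per_mb = 100,
                        b_nonsyn_multiplier = 2,
                        b_median_age = NULL) {
  check_that(inherits(blueprint, "b_blueprint"), "blueprint must be a b_blueprint")
  check_that(n_a_chromosomes >= 1, "need at least one A chromosome")
  b_median_age <- b_median_age %||% median_age
  withr::with_seed(seed, {
    # --- A complement: TE background, shared knob arrays, a satellite
    # centromere, and genes at a_gene_per_mb
    a_seqs <- character(n_a_chromosomes)
    names(a_seqs) <- paste0("A", seq_len(n_a_chromosomes))
    a_truth <- list()
    a_genes <- list()
    gidx <- 0
    for (ci in seq_len(n_a_chromosomes)) {
      n_genes <- max(2, round(a_gene_per_mb * a_length / 1e6))
      genes <- tibble(
        gene_id = sprintf("%s_g%03d", names(a_seqs)[ci], seq_len(n_genes) + gidx),
        cds = vapply(seq_len(n_genes), function(i) make_cds(gene_len_codons),
                     character(1))
      )
      gidx <- gidx + n_genes
      reg <- build_region(
        a_length, library,
        te_bp = round(0.55 * a_length),
        array_bp = c(knob = round(0.05 * a_length),
                     centromeric_satellite = round(0.02 * a_length)),
        genes = genes, median_age = median_age, rate = rate
      )
      a_seqs[ci] <- reg$seq
      a_truth[[ci]] <- reg$features |> mutate(chrom = names(a_seqs)[ci])
      pos <- reg$features |> filter(.data$type == "gene")
      a_genes[[ci]] <- genes |>
        left_join(pos |> select(gene_id = "source_id", "start", "end", "strand"),
                  by = "gene_id") |>
        mutate(chrom = names(a_seqs)[ci])
    }
    a_truth <- bind_rows(a_truth)
    a_genes <- bind_rows(a_genes)
    check_that(n_transposed_genes <= nrow(a_genes),
               "n_transposed_genes exceeds the number of A genes")

    # --- transposed gene copies for the B
    b_gene_tbl <- if (n_transposed_genes > 0) {
      donors <- a_genes[sample.int(nrow(a_genes), n_transposed_genes), ]
      tibble(
        gene_id = sprintf("Bg%03d", seq_len(n_transposed_genes)),
        donor = donors$gene_id,
        cds = vapply(donors$cds, function(cd) {
          evolve_cds(cd, sub_rate = 0.03,
                     nonsyn_accept = min(1, 0.2 * b_nonsyn_multiplier))
        }, character(1), USE.NAMES = FALSE)
      )
    } else {
      tibble(gene_id = character(0), donor = character(0), cds = character(0))
    }

    # --- B chromosome, segment by segment
    seg_gene_w <- blueprint$gene_per_mb * blueprint$length
    n_per_seg <- if (n_transposed_genes > 0 && sum(seg_gene_w) > 0) {
      alloc_proportional(n_transposed_genes, seg_gene_w)
    } else {
      rep(0L, nrow(blueprint))
    }
    b_parts <- list()
    b_feats <- list()
    offset <- 0L
    g_used <- 0
    for (si in seq_len(nrow(blueprint))) {
      row <- blueprint[si, ]
      genes <- NULL
      if (n_per_seg[si] > 0) {
        genes <- b_gene_tbl[(g_used + 1):(g_used + n_per_seg[si]), ]
        g_used <- g_used + n_per_seg[si]
      }
      arrays <- c(
        b_specific = round(row$arr_b * row$length),
        knob = round(row$arr_knob * row$length),
        centromeric_satellite = round(row$arr_centc * row$length)
      )
      arrays <- arrays[arrays > 0]
      reg <- build_region(
        row$length, library,
        te_bp = round(row$te_frac * row$length),
        array_bp = as.list(arrays),
        genes = genes, median_age = b_median_age, rate = rate
      )
      b_parts[[si]] <- reg$seq
      feats <- reg$features |>
        mutate(start = .data$start + offset, end = .data$end + offset)
      seg_row <- tibble(type = "segment", start = offset,
                        end = offset + as.integer(row$length), strand = "+",
                        source_id = row$segment, age = NA_real_, intact = NA)
      b_feats[[si]] <- bind_rows(seg_row, feats)
      offset <- offset + as.integer(row$length)
    }
    truth <- bind_rows(b_feats) |>
      left_join(b_gene_tbl |> select("gene_id", "donor"),
                by = c(source_id = "gene_id")) |>
      as_tibble()

    structure(list(
      a_chromosomes = a_seqs,
      b_chromosome = paste(unlist(b_parts), collapse = ""),
      truth = truth,
      a_truth = a_truth,
      a_genes = a_genes,
      b_genes = b_gene_tbl,
      a_segments = make_a_segments(a_seqs),
      library = library,
      blueprint = blueprint,
      params = list(seed = seed, median_age = median_age, rate = rate,
                    n_transposed_genes = n_transposed_genes)
    ), class = "genome_model")
  })
}

# integer allocation of n across weights, largest remainders
alloc_proportional <- function(n, w) {
  raw <- n * w / sum(w)
  base <- floor(raw)
  rem <- n - sum(base)
  if (rem > 0) {
    ord <- order(raw - base, decreasing = TRUE)
    base[ord[seq_len(rem)]] <- base[ord[seq_len(rem)]] + 1
  }
  as.integer(base)
}

# Each A chromosome split into three equal segments used as dosage units; an
# odd segment count per chromosome keeps the copy-neutral baseline robust
# when one segment carries a planted CNV.
make_a_segments <- function(a_seqs) {
  purrr::map_dfr(names(a_seqs), function(nm) {
    len <- nchar(a_seqs[[nm]])
    cuts <- as.integer(round(seq(0, len, length.out = 4)))
    tibble(segment = paste0(nm, c("_L", "_M", "_R")), chrom = nm,
           start = cuts[1:3], end = cuts[2:4])
  })
}

#' @export
print.genome_model <- function(x, ...) {
  cat("<genome_model>\n")
  cat(sprintf("  A complement: %d chromosome(s), %s bp total\n",
              length(x$a_chromosomes),
              format(sum(nchar(x$a_chromosomes)), big.mark = ",")))
  cat(sprintf("  B chromosome: %s bp, %d truth features\n",
              format(nchar(x$b_chromosome), big.mark = ","),
              nrow(x$truth)))
  te <- x$truth |> filter(.data$type == "te")
  cat(sprintf("  TE occupancy on B: %.1f%%\n",
              100 * sum(te$end - te$start) / nchar(x$b_chromosome)))
  invisible(x)
}
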