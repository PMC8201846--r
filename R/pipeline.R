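#' Run the deficiency-mapping pipeline end to end
#'
#' Simulates reads for every mapping line of a panel (control, terminal and
#' mini lines), then runs the full inference chain: 3' trimming, host-read
#' subtraction against the A complement, unique no-mismatch placement on the
#' scaffolds, 1-kb window counts over a k-mer-derived repeat mask, presence
#' calls, consecutive-ones ordering, and oriented pseudomolecule
#' construction. Everything downstream of read simulation sees only the
#' observable data -- never the hidden truth columns.
#'
#' @param genome A [make_genome()] model.
#' @param scaffolds A [fragment_scaffolds()] set.
#' @param panel A [make_line_panel()] panel.
#' @param coverage,read_len,error_rate,tail_frac Read simulation parameters.
#' @param window Window size (bp).
#' @param k K-mer size for the repeat mask.
#' @param gap_len Pseudomolecule gap length (Ns).
#' @param seed Integer seed (per-line read seeds are derived from it).
#' @param verify Also run [verify_profile()] on the result.
#' @return A list: `reads` (named list), `coverage` (stacked windows),
#'   `presence` (`presence_matrix`), `layout` (`pseudo_layout`), `build`
#'   (`pseudomolecule`), `mask`, and optionally `verification`.
#' @export
run_deficiency_pipeline <- function(genome, scaffolds, panel, coverage = 6,
                                    read_len = 75, error_rate = 0,
                                    tail_frac = 0.02, window = 1000, k = 49,
                                    gap_len = 100, seed = 1, verify = FALSE) {
  mapping_types <- c("control", "terminal", "mini")
  lines <- panel |> filter(.data$type %in% mapping_types)
  mask <- repeat_mask(scaffolds, a_sequences = genome$a_chromosomes,
                      k = k, window = window)
  a_cat <- subject_catalog(genome$a_chromosomes)
  scf_cat <- subject_catalog(scaffolds)
  reads <- list()
  cov <- list()
  for (i in seq_len(nrow(lines))) {
    ln <- lines$line[i]
    rd <- simulate_reads(genome, lines[i, ], coverage = coverage,
                         read_len = read_len, error_rate = error_rate,
                         tail_frac = tail_frac,
                         seed = seed * 1000L + i)
    reads[[ln]] <- rd
    rd <- preprocess_reads(rd)
    rd <- subtract_host_reads(rd, a_cat)
    pl <- map_unique_reads(rd, scf_cat)
    pl <- filter_masked_placements(pl, mask$positions, scaffolds, k = k)
    cov[[ln]] <- coverage_windows(pl, scaffolds, window = window,
                                  repeat_mask = mask$windows)
  }
  cov_all <- bind_rows(cov, .id = "line")
  # covered-window threshold scaled to expected per-window depth (10% of
  # expectation): sparse cross-mapping noise -- multi-copy host reads and
  # error-flipped near-copy reads -- stays well below it, while genuine
  # coverage saturates far above it even when sequencing errors cost half
  # the exactly-mappable reads
  min_count <- max(2, round(0.10 * coverage * window / read_len))
  pm <- call_presence(cov_all, min_count = min_count)
  layout <- order_scaffolds(pm, panel, scaffolds = scaffolds)
  build <- orient_and_build(layout, scaffolds, cov_all, pm,
                            gap_len = gap_len, min_count = min_count)
  out <- list(reads = reads, coverage = cov_all, presence = pm,
              layout = layout, build = build, mask = mask)
  if (verify) {
    out$verification <- verify_profile(build, reads, genome$a_chromosomes,
                                       window = window, k = k)
  }
  out
}

#' Compare a recovered layout with the hidden truth
#'
#' Test/validation helper: checks that the recovered bin order is consistent
#' with the true scaffold coordinates (every scaffold in an earlier bin
#' precedes every scaffold in a later bin) and that every breakpoint-spanning
#' scaffold's recovered orientation equals its true strand.
#'
#' @param build A `pseudomolecule` from [orient_and_build()].
#' @param scaffolds The `scaffold_set` with truth columns.
#' @return A list: `order_ok`, `orientation_ok`, `n_placed`, `n_oriented`,
#'   and the per-scaffold comparison tibble.
#' @export
compare_with_truth <- function(build, scaffolds) {
  cmp <- build$bins |>
    left_join(scaffolds |>
                select("scaffold", "true_start", "true_strand"),
              by = "scaffold")
  by_bin <- cmp |>
    group_by(.data$bin) |>
    summarise(lo = min(.data$true_start), hi = max(.data$true_start),
              .groups = "drop") |>
    arrange(.data$bin)
  order_ok <- nrow(by_bin) <= 1 ||
    all(head(by_bin$hi, -1) < tail(by_bin$lo, -1))
  oriented <- cmp |> filter(.data$orientation %in% c("+", "-"))
  orientation_ok <- nrow(oriented) == 0 ||
    all(oriented$orientation == oriented$true_strand)
  list(order_ok = order_ok, orientation_ok = orientation_ok,
       n_placed = nrow(cmp), n_oriented = nrow(oriented), comparison = cmp)
}
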