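#' Chromosome-arm dosage (copy-number) test from gene-region read counts
#'
#' Counts uniquely placed reads in gene regions of the A complement for each
#' library, normalises by library size (fraction of placed reads), forms
#' per-region ratios against a haploid control, and re-centres the ratios by
#' their cohort median so that copy-neutral regions sit at 1 (the extra or
#' missing segment copy otherwise shifts every ratio through the library
#' size). The per-segment estimate is the median of its member regions;
#' segments are classified `gain` (ratio >= `gain_at`), `loss`
#' (<= `loss_at`) or `neutral`. A segment present at two copies against a
#' haploid control recovers a ratio near 2; one copy in a disomic background
#' recovers near 0.5.
#'
#' @param libraries Named list of read tibbles; must include `control`.
#' @param a_genome A-complement sequences (named character, tibble or
#'   `DNAStringSet`).
#' @param gene_regions Tibble of gene regions: `chrom`, `start`, `end`,
#'   `region_id` (e.g. from a genome model's `a_genes`).
#' @param segments Tibble assigning regions to segments: `segment`, `chrom`,
#'   `start`, `end` (e.g. a genome model's `a_segments`).
#' @param control Name of the haploid control library.
#' @param gain_at,loss_at Classification thresholds on the segment ratio.
#' @return A `dosage_profile` list: `regions` (tibble: `region_id`, `segment`,
#'   per-library counts, `ratio` per test library) and `segments` (tibble:
#'   `segment`, `library`, `ratio`, `n_regions`, `class`).
#' @export
dosage_profile <- function(libraries, a_genome, gene_regions, segments,
                           control, gain_at = 1.5, loss_at = 0.66) {
  check_that(control %in% names(libraries), "control library not found")
  regions <- gene_regions |>
    left_join(assign_segments(gene_regions, segments), by = "region_id")
  counts <- purrr::imap(libraries, function(reads, nm) {
    pl <- map_unique_reads(reads, a_genome)
    cnt <- count_in_regions(pl, regions)
    tibble(region_id = regions$region_id, library = nm, count = cnt,
           total = nrow(pl))
  }) |> bind_rows()
  norm <- counts |> mutate(nfrac = .data$count / .data$total)
  ctrl <- norm |> filter(.data$library == control) |>
    select("region_id", ctrl_count = "count", ctrl_nfrac = "nfrac")
  skipped <- ctrl |> filter(.data$ctrl_count == 0)
  if (nrow(skipped) > 0) {
    warn(sprintf("%d region(s) with zero control counts skipped",
                 nrow(skipped)))
  }
  ratios <- norm |>
    filter(.data$library != control) |>
    left_join(ctrl, by = "region_id") |>
    filter(.data$ctrl_count > 0) |>
    mutate(raw_ratio = .data$nfrac / .data$ctrl_nfrac) |>
    left_join(regions |> select("region_id", "segment"), by = "region_id")
  # baseline = median of per-segment medians, so a CNV segment cannot drag
  # the copy-neutral baseline however many regions it holds
  centre <- ratios |>
    group_by(.data$library, .data$segment) |>
    summarise(seg_raw = median(.data$raw_ratio), .groups = "drop_last") |>
    summarise(centre = median(.data$seg_raw), .groups = "drop")
  ratios <- ratios |>
    left_join(centre, by = "library") |>
    mutate(ratio = .data$raw_ratio / .data$centre) |>
    select(-"centre")
  seg <- ratios |>
    group_by(.data$segment, .data$library) |>
    summarise(ratio = median(.data$ratio), n_regions = n(),
              .groups = "drop") |>
    mutate(class = dplyr::case_when(
      .data$ratio >= gain_at ~ "gain",
      .data$ratio <= loss_at ~ "loss",
      TRUE ~ "neutral"
    ))
  structure(list(
    regions = ratios |>
      select("region_id", "segment", "library", "count", "ratio"),
    segments = seg,
    control = control
  ), class = "dosage_profile")
}

# region_id -> segment by region midpoint
assign_segments <- function(gene_regions, segments) {
  mid <- (gene_regions$start + gene_regions$end) / 2
  seg <- vapply(seq_len(nrow(gene_regions)), function(i) {
    hit <- segments$segment[segments$chrom == gene_regions$chrom[i] &
                              segments$start <= mid[i] &
                              segments$end > mid[i]]
    if (length(hit)) hit[1] else NA_character_
  }, character(1))
  tibble(region_id = gene_regions$region_id, segment = seg)
}

count_in_regions <- function(placements, regions) {
  vapply(seq_len(nrow(regions)), function(i) {
    sum(placements$scaffold == regions$chrom[i] &
          placements$start >= regions$start[i] &
          placements$start < regions$end[i])
  }, integer(1))
}

#' @export
print.dosage_profile <- function(x, ...) {
  cat("<dosage_profile> segment ratios vs", x$control, "\n")
  print(as.data.frame(x$segments), right = FALSE)
  invisible(x)
}
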