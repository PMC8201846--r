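#' Order scaffolds into breakpoint-defined bins
#'
#' Consecutive-ones ordering along a containment chain of terminal-deletion
#' lines. Terminal lines are sorted by inferred retention (column sums of
#' covered fraction; the chain is verified from the calls themselves, never
#' from hidden truth). Scaffolds with identical presence signatures share a
#' bin; bins are ordered so that scaffolds present in smaller retentions
#' (centromere-proximal) come first; breakpoint-spanning (partial) scaffolds
#' anchor bin boundaries. Within-bin order is unresolved and flagged; for
#' determinism it falls back to descending scaffold length. Signatures
#' inconsistent with any chain order (present in a smaller retention but
#' absent in a larger one) are conflicts: the operation fails unless
#' `force = TRUE`, and the offending scaffold-by-line cells are reported
#' either way. Mini-chromosome (interstitial) lines are not used for
#' ordering; they confirm centromere-proximal bins via the `mini_support`
#' flag.
#'
#' @param pm A `presence_matrix` from [call_presence()].
#' @param panel The `line_panel` (for line types).
#' @param scaffolds Optional `scaffold_set` (or tibble with `scaffold` and
#'   `length`) used for the deterministic within-bin fallback order.
#' @param force Proceed despite chain conflicts.
#' @return A `pseudo_layout` list: `bins` (tibble: `scaffold`, `bin`, `key`,
#'   `signature`, `n_partial`, `unresolved`, `mini_support`), `line_order`,
#'   `conflicts`, `unplaced`.
#' @export
order_scaffolds <- function(pm, panel, scaffolds = NULL,
                            force = FALSE) {
  terminals <- panel$line[panel$type == "terminal"]
  control <- panel$line[panel$type == "control"]
  check_that(length(control) >= 1, "panel must contain a control line")
  check_that(length(terminals) >= 2, "need >= 2 terminal lines")
  x <- as_tibble(pm)
  ctrl <- x |> filter(.data$line == control[1])
  unplaced <- ctrl |>
    filter(.data$call == "uninformative") |>
    mutate(reason = "uninformative") |>
    select("scaffold", "reason")
  bad_ctrl <- ctrl |>
    filter(!.data$call %in% c("present", "uninformative"))
  check_that(nrow(bad_ctrl) == 0,
             "control line must be all-present over informative scaffolds")
  keep <- setdiff(unique(x$scaffold), unplaced$scaffold)
  # chain: terminal lines by inferred retention, ascending
  chain <- x |>
    filter(.data$line %in% terminals, .data$scaffold %in% keep) |>
    group_by(.data$line) |>
    summarise(score = sum(.data$covered_fraction), .groups = "drop") |>
    arrange(.data$score) |>
    pull("line")
  val <- c(absent = 0, partial = 0.5, present = 1)
  sig <- x |>
    filter(.data$line %in% chain, .data$scaffold %in% keep) |>
    mutate(line = factor(.data$line, levels = chain)) |>
    arrange(.data$scaffold, .data$line)
  conflicts <- sig |>
    group_by(.data$scaffold) |>
    filter({
      v <- val[.data$call]
      c(FALSE, diff(v) < 0)
    }) |>
    ungroup() |>
    select("scaffold", "line", "call")
  if (nrow(conflicts) > 0 && !force) {
    msg <- paste0("presence signatures conflict with a chain order for: ",
                  paste(unique(conflicts$scaffold), collapse = ", "),
                  " (use force = TRUE to order anyway)")
    cond <- rlang::error_cnd("bchrom_chain_conflict", message = msg,
                             conflicts = conflicts)
    stop(cond)
  }
  minis <- panel$line[panel$type == "mini"]
  mini_sup <- x |>
    filter(.data$line %in% minis) |>
    group_by(.data$scaffold) |>
    summarise(mini_support = any(.data$call %in% c("present", "partial")),
              .groups = "drop")
  bins <- sig |>
    group_by(.data$scaffold) |>
    summarise(
      key = sum(val[.data$call]),
      signature = paste(c(absent = "A", partial = "p",
                          present = "P")[.data$call], collapse = ""),
      n_partial = sum(.data$call == "partial"),
      .groups = "drop"
    ) |>
    arrange(desc(.data$key))
  bins$bin <- match(bins$key, sort(unique(bins$key), decreasing = TRUE))
  if (!is.null(scaffolds)) {
    lens <- scaffold_lengths(scaffolds)
    bins$length <- as.integer(lens[bins$scaffold])
  } else {
    bins$length <- NA_integer_
  }
  bins <- bins |>
    group_by(.data$bin) |>
    mutate(unresolved = n() > 1) |>
    ungroup() |>
    arrange(.data$bin, desc(.data$length), .data$scaffold) |>
    left_join(mini_sup, by = "scaffold") |>
    select("scaffold", "bin", "key", "signature", "n_partial", "length",
           "unresolved", "mini_support")
  structure(list(bins = bins, line_order = chain, conflicts = conflicts,
                 unplaced = unplaced),
            class = "pseudo_layout")
}

#' @export
print.pseudo_layout <- function(x, ...) {
  cat(sprintf("<pseudo_layout> %d scaffolds in %d bins; %d unplaced; %d conflict cells\n",
              nrow(x$bins), length(unique(x$bins$bin)), nrow(x$unplaced),
              nrow(x$conflicts)))
  print(as.data.frame(x$bins), right = FALSE)
  invisible(x)
}

#' Orient scaffolds and build the pseudomolecule
#'
#' Orients each breakpoint-spanning scaffold by comparing per-window coverage
#' of its two halves in the terminal line that defines the breakpoint: the
#' covered half must face the retained, centromere-proximal side. Halves
#' within `tie_margin` (relative) are left `unknown` with a warning, as are
#' scaffolds that span no breakpoint; unknowns are emitted as '+'. Scaffolds
#' are joined in bin order with `gap_len` Ns, starting from the
#' centromere-proximal bin, and the layout is serialised as AGP 2.1.
#'
#' @param layout A `pseudo_layout` from [order_scaffolds()].
#' @param scaffolds The `scaffold_set` (sequences).
#' @param cov Stacked per-line window coverage (as passed to
#'   [call_presence()]).
#' @param pm The `presence_matrix` (to locate each spanning scaffold's
#'   defining line).
#' @param gap_len Gap length in Ns between consecutive scaffolds.
#' @param tie_margin Relative half-coverage difference under which
#'   orientation is ambiguous.
#' @param min_count Depth at which a window counts as covered (matches the
#'   threshold used for the presence calls).
#' @return A `pseudomolecule` list: `seq`, `agp` (9-column tibble), `bins`
#'   (layout with `orientation` and 0-based `offset`), `gap_len`.
#' @export
orient_and_build <- function(layout, scaffolds, cov, pm, gap_len = 100,
                             tie_margin = 0.1, min_count = 1) {
  bins <- layout$bins
  seqs <- setNames(scaffolds$seq, scaffolds$scaffold)
  lens <- setNames(as.integer(nchar(seqs)), names(seqs))
  orientation <- rep("unknown", nrow(bins))
  x <- as_tibble(pm)
  for (i in which(bins$n_partial > 0)) {
    scf <- bins$scaffold[i]
    sig_calls <- x |>
      filter(.data$scaffold == scf,
             .data$line %in% layout$line_order) |>
      mutate(line = factor(.data$line, levels = layout$line_order)) |>
      arrange(.data$line)
    def_line <- as.character(sig_calls$line[match("partial", sig_calls$call)])
    w <- cov |>
      filter(.data$line == def_line, .data$scaffold == scf,
             !.data$repetitive)
    half <- lens[scf] / 2
    f1 <- covered_fraction_of(w$count[w$win_start < half], min_count)
    f2 <- covered_fraction_of(w$count[w$win_start >= half], min_count)
    if (is.nan(f1) || is.nan(f2) ||
        abs(f1 - f2) <= tie_margin * max(f1, f2, 1e-9)) {
      warn(sprintf("orientation ambiguous for %s (halves %.2f vs %.2f)",
                   scf, f1, f2))
    } else {
      orientation[i] <- if (f1 > f2) "+" else "-"
    }
  }
  bins$orientation <- orientation
  emitted <- ifelse(bins$orientation == "-", revcomp(seqs[bins$scaffold]),
                    seqs[bins$scaffold])
  n <- nrow(bins)
  starts <- cumsum(c(0, head(lens[bins$scaffold], -1) + gap_len))
  bins$offset <- as.integer(starts)
  pseudo <- paste(emitted, collapse = strrep("N", gap_len))
  agp <- build_agp(bins, lens, gap_len)
  structure(list(seq = pseudo, agp = agp, bins = bins, gap_len = gap_len),
            class = "pseudomolecule")
}

build_agp <- function(bins, lens, gap_len) {
  rows <- list()
  part <- 0L
  gap_len <- as.integer(gap_len)
  pos <- 0L  # 1-based running end
  obj <- "chrB_pseudo"
  for (i in seq_len(nrow(bins))) {
    scf <- bins$scaffold[i]
    if (i > 1 && gap_len > 0) {
      part <- part + 1L
      rows[[length(rows) + 1]] <- tibble(
        object = obj, object_beg = pos + 1L, object_end = pos + gap_len,
        part_number = part, component_type = "N",
        col6 = as.character(gap_len), col7 = "scaffold", col8 = "yes",
        col9 = "map")
      pos <- pos + gap_len
    }
    part <- part + 1L
    ori <- bins$orientation[i]
    rows[[length(rows) + 1]] <- tibble(
      object = obj, object_beg = pos + 1L, object_end = pos + lens[[scf]],
      part_number = part, component_type = "W",
      col6 = scf, col7 = "1", col8 = as.character(lens[[scf]]),
      col9 = if (ori %in% c("+", "-")) ori else "?")
    pos <- pos + lens[[scf]]
  }
  bind_rows(rows)
}

#' @export
print.pseudomolecule <- function(x, ...) {
  cat(sprintf("<pseudomolecule> %s bp, %d scaffolds, gap %d N\n",
              format(nchar(x$seq), big.mark = ","), nrow(x$bins), x$gap_len))
  invisible(x)
}

#' Verify a pseudomolecule against per-line reads
#'
#' Re-runs the read pipeline (trimming, host subtraction, unique no-mismatch
#' placement, windows) against the pseudomolecule itself and checks that each
#' line's covered region forms a single contiguous block over informative
#' (nonrepetitive) windows -- a prefix block for terminal-deletion lines. A
#' shuffled layout breaks contiguity.
#'
#' @param build A `pseudomolecule` from [orient_and_build()] (or a character
#'   sequence).
#' @param reads_by_line Named list of read tibbles.
#' @param a_genome A-complement sequences for host subtraction.
#' @param window Window size (bp).
#' @param gap_tol Tolerated fraction of uncovered informative windows inside
#'   the covered span.
#' @param k K-mer size for the self repeat mask.
#' @return Tibble: `line`, `n_informative`, `n_covered`, `first`, `last`,
#'   `gap_frac`, `contiguous`, `prefix`, `pass`.
#' @export
verify_profile <- function(build, reads_by_line, a_genome, window = 1000,
                           gap_tol = 0.05, k = 49) {
  seq <- if (inherits(build, "pseudomolecule")) build$seq else build
  ps <- tibble(scaffold = "pseudomolecule", seq = seq,
               length = nchar(seq))
  mask <- repeat_mask(ps, a_sequences = a_genome, k = k, window = window)
  a_cat <- subject_catalog(a_genome)
  ps_cat <- subject_catalog(ps)
  purrr::map_dfr(names(reads_by_line), function(ln) {
    reads <- preprocess_reads(reads_by_line[[ln]])
    reads <- subtract_host_reads(reads, a_cat)
    pl <- map_unique_reads(reads, ps_cat)
    pl <- filter_masked_placements(pl, mask$positions, ps, k = k)
    cw <- coverage_windows(pl, ps, window = window,
                           repeat_mask = mask$windows)
    inf <- cw |> filter(!.data$repetitive)
    v <- inf$count >= 1
    if (!any(v)) {
      return(tibble(line = ln, n_informative = nrow(inf), n_covered = 0L,
                    first = NA_integer_, last = NA_integer_,
                    gap_frac = NA_real_, contiguous = TRUE, prefix = FALSE,
                    pass = TRUE))
    }
    first <- which(v)[1]
    last <- tail(which(v), 1)
    gap_frac <- mean(!v[first:last])
    tibble(line = ln, n_informative = nrow(inf), n_covered = sum(v),
           first = first, last = last, gap_frac = gap_frac,
           contiguous = gap_frac <= gap_tol, prefix = first <= 3,
           pass = gap_frac <= gap_tol)
  })
}
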