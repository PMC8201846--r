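#' Count unique-read placements in fixed windows
#'
#' Counts placements in consecutive windows (default 1 kb) along each
#' scaffold; each placement increments the window containing its start. A
#' window is flagged repetitive when at least half of it overlaps the repeat
#' mask; the last window of a scaffold may be short.
#'
#' @param placements Placement tibble from [map_unique_reads()].
#' @param scaffolds `scaffold_set` or tibble with `scaffold` and `length`
#'   (or `seq`) columns.
#' @param window Window size in bp (>= 100).
#' @param repeat_mask Optional BED-like tibble (`chrom`, `start`, `end`) of
#'   repetitive intervals, e.g. from [repeat_mask_windows()].
#' @param mask_frac Overlap fraction at or above which a window is flagged.
#' @return Tibble: `scaffold`, `win_start`, `win_end`, `count`, `repetitive`.
#' @export
coverage_windows <- function(placements, scaffolds, window = 1000,
                             repeat_mask = NULL, mask_frac = 0.5) {
  check_that(window >= 100, "window must be >= 100")
  lens <- scaffold_lengths(scaffolds)
  if (nrow(placements) > 0) {
    bad <- !placements$scaffold %in% names(lens) |
      placements$start < 0 |
      placements$start >= lens[placements$scaffold]
    check_that(!any(bad), "placement out of scaffold bounds (corrupt input)")
  }
  grid <- purrr::map_dfr(names(lens), function(nm) {
    n_win <- ceiling(lens[[nm]] / window)
    tibble(scaffold = nm,
           win_start = as.integer((seq_len(n_win) - 1) * window),
           win_end = as.integer(pmin(seq_len(n_win) * window, lens[[nm]])))
  })
  cnt <- if (nrow(placements) > 0) {
    placements |>
      mutate(win_start = as.integer((.data$start %/% window) * window)) |>
      count(.data$scaffold, .data$win_start, name = "count")
  } else {
    tibble(scaffold = character(0), win_start = integer(0), count = integer(0))
  }
  out <- grid |>
    left_join(cnt, by = c("scaffold", "win_start")) |>
    mutate(count = ifelse(is.na(.data$count), 0L, .data$count))
  out$repetitive <- window_mask_flags(out, repeat_mask, mask_frac)
  # a short trailing window offers few (or no) positions where a placement
  # can start and still fit inside the scaffold, so its counts are
  # structurally unreliable: flag it out of the presence denominator
  if (nrow(placements) > 0) {
    rl <- max(placements$width)
    scf_end <- unname(lens[out$scaffold])
    valid_starts <- scf_end - rl - out$win_start + 1
    out$repetitive <- out$repetitive |
      (out$win_end == scf_end & valid_starts < 0.5 * window)
  }
  out
}

scaffold_lengths <- function(scaffolds) {
  if (is.data.frame(scaffolds)) {
    lens <- scaffolds$length %||% nchar(scaffolds$seq)
    return(setNames(as.integer(lens), scaffolds$scaffold))
  }
  x <- subjects_as_dss(scaffolds)
  setNames(Biostrings::width(x), names(x))
}

window_mask_flags <- function(grid, repeat_mask, mask_frac) {
  if (is.null(repeat_mask) || nrow(repeat_mask) == 0) {
    return(rep(FALSE, nrow(grid)))
  }
  flags <- rep(FALSE, nrow(grid))
  for (nm in unique(grid$scaffold)) {
    gi <- which(grid$scaffold == nm)
    mk <- repeat_mask |> filter(.data$chrom == nm)
    if (nrow(mk) == 0) next
    win <- IRanges::IRanges(grid$win_start[gi] + 1L, grid$win_end[gi])
    msk <- IRanges::reduce(IRanges::IRanges(mk$start + 1L, mk$end))
    ov <- IRanges::findOverlaps(win, msk)
    if (!length(ov)) next
    inter <- IRanges::pintersect(win[S4Vectors::queryHits(ov)],
                                 msk[S4Vectors::subjectHits(ov)])
    cov_bp <- tapply(IRanges::width(inter), S4Vectors::queryHits(ov), sum)
    qi <- as.integer(names(cov_bp))
    flags[gi[qi]] <- cov_bp / IRanges::width(win)[qi] >= mask_frac
  }
  flags
}

#' Call per-line presence of each scaffold
#'
#' Computes, per scaffold and line, the fraction of nonrepetitive windows with
#' at least `min_count` placements, and calls `present` (>= `present_frac`),
#' `absent` (<= `absent_frac`) or `partial`. Scaffolds with no nonrepetitive
#' window are called `uninformative` and excluded from ordering.
#'
#' @param cov Window coverage tibble with a `line` column (stack the output
#'   of [coverage_windows()] per line, e.g. with `bind_rows(.id = "line")`).
#' @param present_frac Covered fraction at or above which a scaffold is
#'   present (default 0.9).
#' @param absent_frac Covered fraction at or below which it is absent
#'   (default 0.1).
#' @param min_count Minimum window count that marks a window covered.
#' @return A `presence_matrix` tibble: `scaffold`, `line`, `covered_fraction`,
#'   `call`.
#' @export
call_presence <- function(cov, present_frac = 0.9, absent_frac = 0.1,
                          min_count = 1) {
  check_that("line" %in% names(cov), "cov must carry a line column")
  check_that(absent_frac < present_frac, "absent_frac must be < present_frac")
  pm <- cov |>
    group_by(.data$line, .data$scaffold) |>
    summarise(
      n_informative = sum(!.data$repetitive),
      covered_fraction = if (sum(!.data$repetitive) == 0) NA_real_ else
        covered_fraction_of(.data$count[!.data$repetitive], min_count),
      .groups = "drop"
    ) |>
    mutate(call = dplyr::case_when(
      is.na(.data$covered_fraction) ~ "uninformative",
      .data$covered_fraction >= present_frac ~ "present",
      .data$covered_fraction <= absent_frac ~ "absent",
      TRUE ~ "partial"
    )) |>
    select("scaffold", "line", "covered_fraction", "call")
  new_presence_matrix(pm)
}

# Fraction of windows covered at depth >= min_count. With min_count > 1,
# windows caught between empty and covered (0 < count < min_count) are
# ambiguous -- boundary windows of a genuine block, or sparse cross-mapping
# noise -- and abstain from the denominator; when nothing reaches the
# threshold the fraction is 0. With min_count = 1 this reduces to the plain
# fraction of windows with any placement.
covered_fraction_of <- function(counts, min_count) {
  if (!length(counts)) return(NaN)
  covered <- counts >= min_count
  decided <- covered | counts == 0
  if (any(decided)) sum(covered) / sum(decided) else 0
}

new_presence_matrix <- function(x) {
  class(x) <- unique(c("presence_matrix", class(x)))
  x
}

#' @export
print.presence_matrix <- function(x, ...) {
  wide <- as_tibble(x) |>
    mutate(sym = dplyr::case_when(
      .data$call == "present" ~ "P", .data$call == "absent" ~ ".",
      .data$call == "partial" ~ "p", TRUE ~ "?")) |>
    select("scaffold", "line", "sym") |>
    tidyr::pivot_wider(names_from = "line", values_from = "sym")
  cat(sprintf("<presence_matrix> %d scaffolds x %d lines (P present, . absent, p partial, ? uninformative)\n",
              nrow(wide), ncol(wide) - 1))
  print(as.data.frame(wide), right = FALSE)
  invisible(x)
}
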