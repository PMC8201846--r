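#' Generate a panel of B-deficiency lines
#'
#' Emulates a panel of lines each carrying only a portion of the B chromosome
#' (translocation, misdivision and breakage derivatives): a nested family of
#' terminal lines retaining `[0, bp_i)` with strictly increasing breakpoints
#' (every retained segment includes the centromere), mini-chromosome lines
#' retaining an interval that fully contains the centromere segment, a control
#' line with the full B, a line with no B, and two dosage lines for the
#' copy-number test (one A segment at two copies in an otherwise haploid
#' background; one A segment at one copy in an otherwise disomic background).
#'
#' @param genome A [make_genome()] model.
#' @param n_terminal Number of terminal-deletion lines (>= 2).
#' @param n_mini Number of mini-chromosome lines.
#' @param seed Integer seed.
#' @return A `line_panel` tibble: `line`, `type`, `retained` (list of
#'   `start`/`end` tibbles, 0-based half-open), `a_dosage` (list of named
#'   integer vectors over A segments), `b_copies`. Attributes
#'   `disomy_segment` and `monosomy_segment` name the planted CNV segments.
#' @export
make_line_panel <- function(genome, n_terminal = 8, n_mini = 2, seed = 1) {
  check_that(n_terminal >= 2, "n_terminal must be >= 2")
  b_len <- nchar(genome$b_chromosome)
  segs <- genome$truth |> filter(.data$type == "segment")
  bc <- segs |> filter(.data$source_id == "BC")
  check_that(nrow(bc) == 1, "genome truth lacks a BC segment")
  seg_names <- genome$a_segments$segment
  base_dosage <- function(copies) setNames(rep(as.integer(copies),
                                               length(seg_names)), seg_names)
  withr::with_seed(seed, {
    margin <- round(0.02 * b_len)
    lo <- bc$end + margin
    hi <- b_len - margin
    # jittered even spacing keeps breakpoints distinct and well separated
    for (attempt in 1:20) {
      q <- lo + (hi - lo) * (seq_len(n_terminal) - 0.5) / n_terminal
      bps <- sort(round(q + runif(n_terminal, -0.3, 0.3) * (hi - lo) / n_terminal))
      if (!anyDuplicated(bps)) break
    }
    check_that(!anyDuplicated(bps), "could not draw distinct breakpoints")
    rows <- list()
    add_line <- function(line, type, retained, a_dosage, b_copies) {
      rows[[length(rows) + 1]] <<- tibble(
        line = line, type = type, retained = list(retained),
        a_dosage = list(a_dosage), b_copies = as.integer(b_copies)
      )
    }
    add_line("control", "control",
             tibble(start = 0L, end = as.integer(b_len)), base_dosage(2), 1)
    for (i in seq_len(n_terminal)) {
      add_line(sprintf("T%02d", i), "terminal",
               tibble(start = 0L, end = as.integer(bps[i])), base_dosage(2), 1)
    }
    bc_len <- bc$end - bc$start
    for (i in seq_len(n_mini)) {
      s <- max(0L, as.integer(bc$start - round(bc_len * runif(1, 0.5, 1.5))))
      e <- min(b_len, as.integer(bc$end + round(bc_len * runif(1, 0.5, 1.5))))
      add_line(sprintf("M%02d", i), "mini",
               tibble(start = s, end = as.integer(e)), base_dosage(2), 1)
    }
    add_line("zeroB", "zero_b", tibble(start = integer(0), end = integer(0)),
             base_dosage(2), 0)
    # dosage variants (disomy: +1 copy of one segment in a haploid background;
    # monosomy: -1 copy of one segment in a disomic background)
    disomy_seg <- seg_names[min(2, length(seg_names))]
    monosomy_seg <- seg_names[min(3, length(seg_names))]
    if (monosomy_seg == disomy_seg) monosomy_seg <- seg_names[1]
    d1 <- base_dosage(1); d1[disomy_seg] <- 2L
    add_line("disomy", "dosage_disomy",
             tibble(start = 0L, end = as.integer(round(b_len / 2))), d1, 1)
    d2 <- base_dosage(2); d2[monosomy_seg] <- 1L
    add_line("monosomy", "dosage_monosomy",
             tibble(start = as.integer(round(0.9 * b_len)),
                    end = as.integer(b_len)), d2, 1)
    add_line("haploid", "dosage_control",
             tibble(start = integer(0), end = integer(0)), base_dosage(1), 0)
    out <- bind_rows(rows)
    validate_panel(out, b_len)
    attr(out, "disomy_segment") <- disomy_seg
    attr(out, "monosomy_segment") <- monosomy_seg
    class(out) <- c("line_panel", class(out))
    out
  })
}

validate_panel <- function(panel, b_len) {
  for (i in seq_len(nrow(panel))) {
    iv <- panel$retained[[i]]
    if (nrow(iv) == 0) next
    check_that(all(iv$start >= 0 & iv$end <= b_len & iv$start < iv$end),
               "retained interval out of bounds")
    check_that(!is.unsorted(iv$start, strictly = TRUE) || nrow(iv) == 1,
               "retained intervals must be sorted")
  }
  check_that(any(vapply(panel$retained, function(iv) {
    nrow(iv) == 1 && iv$start == 0 && iv$end == b_len
  }, logical(1))), "panel must contain a full-B control line")
  invisible(panel)
}
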