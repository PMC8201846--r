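#' Fragment the B chromosome into scaffolds
#'
#' Partitions the synthetic B chromosome into `n_scaffolds` pieces of at least
#' `min_len` bp (emulating the scaffold stage of an assembly, with the >= 10 kb
#' selection as the default), optionally separated by small gaps whose
#' sequence is recorded. Each scaffold's strand is flipped with probability
#' 0.5 and its true coordinates are retained as hidden truth columns
#' (`true_start`, `true_end`, `true_strand`) used only for validation --
#' inference functions never read them.
#'
#' @param genome A [make_genome()] model.
#' @param n_scaffolds Number of scaffolds (>= 2, or 1 for the degenerate case).
#' @param min_len Minimum scaffold length (bp, >= 1000).
#' @param seed Integer seed.
#' @param gap_len Inter-scaffold gap length (bp, default 0 so that the
#'   partition is exact).
#' @return A `scaffold_set` tibble: `scaffold`, `seq`, `length`, `true_start`,
#'   `true_end`, `true_strand`, `gap_after`, `gap_seq`.
#' @export
fragment_scaffolds <- function(genome, n_scaffolds = 20, min_len = 10000,
                               seed = 1, gap_len = 0) {
  check_that(n_scaffolds >= 1, "n_scaffolds must be >= 1")
  check_that(min_len >= 1000, "min_len must be >= 1000")
  b <- genome$b_chromosome
  b_len <- nchar(b)
  total_gap <- gap_len * (n_scaffolds - 1)
  check_that(n_scaffolds * min_len + total_gap <= b_len,
             "infeasible partition: scaffolds + gaps exceed B length")
  withr::with_seed(seed, {
    lens <- random_partition(b_len - total_gap, n_scaffolds, min_len)
    starts <- cumsum(c(0, head(lens, -1) + gap_len))
    ends <- starts + lens
    seqs <- substring(b, starts + 1, ends)
    strands <- sample(c("+", "-"), n_scaffolds, replace = TRUE)
    seqs[strands == "-"] <- revcomp(seqs[strands == "-"])
    gap_seq <- if (n_scaffolds > 1) {
      c(substring(b, ends[-n_scaffolds] + 1, ends[-n_scaffolds] + gap_len),
        "")
    } else {
      ""
    }
    out <- tibble(
      scaffold = sprintf("scf%03d", sample.int(n_scaffolds)),
      seq = seqs, length = as.integer(lens),
      true_start = as.integer(starts), true_end = as.integer(ends),
      true_strand = strands,
      gap_after = c(rep(as.integer(gap_len), n_scaffolds - 1), 0L),
      gap_seq = gap_seq
    )
    class(out) <- c("scaffold_set", class(out))
    out
  })
}

#' Reconstruct the B chromosome from a scaffold set
#'
#' Inverse of [fragment_scaffolds()]: re-orients every scaffold to '+' using
#' the recorded truth, orders by true coordinate and re-inserts the recorded
#' gap sequences, yielding the original B sequence exactly.
#'
#' @param scaffolds A `scaffold_set`.
#' @return The reconstructed B chromosome as a character string.
#' @export
reconstruct_b <- function(scaffolds) {
  x <- scaffolds |> arrange(.data$true_start)
  seqs <- ifelse(x$true_strand == "-", revcomp(x$seq), x$seq)
  paste(paste0(seqs, x$gap_seq), collapse = "")
}
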