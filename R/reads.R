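#' Simulate low-pass sequencing reads for one line
#'
#' Draws fixed-length single-end reads uniformly from a line's genome: every A
#' segment at its stated dosage plus the retained B intervals at the line's B
#' copy number. Coverage is per-copy mean depth. Substitution errors are
#' i.i.d. at `error_rate` (no indels -- the package's matchers are
#' substitution-only); a configurable fraction of reads gets its 3' end
#' overwritten with a poly-G or poly-N tail to exercise trimming. Hidden truth
#' (source, 0-based start, strand) is retained per read.
#'
#' @param genome A [make_genome()] model.
#' @param line One row of a [make_line_panel()] tibble (or a list with
#'   elements `line`, `retained`, `a_dosage`, `b_copies`).
#' @param coverage Mean per-copy depth (default 6, the low-pass design).
#' @param read_len Read length in bp (default 75).
#' @param error_rate Per-base substitution error rate (`0 <= e < 0.1`).
#' @param tail_frac Fraction of reads receiving an artificial 3' tail.
#' @param seed Integer seed.
#' @return A tibble of reads: `read_id`, `seq`, `true_source`, `true_start`,
#'   `true_strand`.
#' @export
simulate_reads <- function(genome, line, coverage = 6, read_len = 75,
                           error_rate = 0, tail_frac = 0.02, seed = 1) {
  check_that(coverage > 0, "coverage must be > 0")
  check_that(read_len >= 20, "read_len must be >= 20")
  check_that(error_rate >= 0 && error_rate < 0.1,
             "error_rate must be in [0, 0.1)")
  if (is.data.frame(line)) {
    check_that(nrow(line) == 1, "line must be a single panel row")
    line <- list(line = line$line, retained = line$retained[[1]],
                 a_dosage = line$a_dosage[[1]], b_copies = line$b_copies)
  }
  comp <- line_components(genome, line)
  check_that(nrow(comp) > 0 && sum(comp$copies * comp$len) > 0,
             "line genome is empty")
  comp <- comp |> filter(.data$len >= read_len)
  check_that(nrow(comp) > 0, "no component long enough for read_len")
  withr::with_seed(seed, {
    n_reads <- round(coverage * sum(comp$copies * comp$len) / read_len)
    w <- comp$copies * (comp$len - read_len + 1)
    ci <- sample.int(nrow(comp), n_reads, replace = TRUE, prob = w)
    pos <- floor(runif(n_reads) * (comp$len[ci] - read_len + 1)) + 1
    seqs <- unname(substring(comp$seq[ci], pos, pos + read_len - 1))
    strand <- sample(c("+", "-"), n_reads, replace = TRUE)
    neg <- strand == "-"
    if (any(neg)) seqs[neg] <- revcomp(seqs[neg])
    if (error_rate > 0) seqs <- inject_errors(seqs, read_len, error_rate)
    if (tail_frac > 0) {
      tailed <- which(runif(n_reads) < tail_frac)
      if (length(tailed)) {
        tl <- sample(3:12, length(tailed), replace = TRUE)
        ch <- sample(c("G", "N"), length(tailed), replace = TRUE,
                     prob = c(0.7, 0.3))
        seqs[tailed] <- paste0(
          substr(seqs[tailed], 1, read_len - tl), strrep(ch, tl)
        )
      }
    }
    tibble(
      read_id = sprintf("%s_r%06d", line$line, seq_len(n_reads)),
      seq = seqs,
      true_source = comp$source[ci],
      true_start = as.integer(comp$offset[ci] + pos - 1),
      true_strand = strand
    )
  })
}

# components of a line's genome: (source, offset, seq, len, copies)
line_components <- function(genome, line) {
  segs <- genome$a_segments
  dosage <- line$a_dosage[segs$segment]
  a_comp <- tibble(
    source = segs$chrom, offset = segs$start,
    seq = substring(genome$a_chromosomes[segs$chrom], segs$start + 1, segs$end),
    copies = as.integer(dosage)
  )
  iv <- line$retained
  b_comp <- if (nrow(iv) > 0 && line$b_copies > 0) {
    tibble(source = "B", offset = iv$start,
           seq = substring(genome$b_chromosome, iv$start + 1, iv$end),
           copies = as.integer(line$b_copies))
  } else {
    tibble(source = character(0), offset = integer(0), seq = character(0),
           copies = integer(0))
  }
  bind_rows(a_comp, b_comp) |>
    mutate(len = nchar(.data$seq)) |>
    filter(.data$copies > 0)
}

# vectorised i.i.d. substitution errors; every error changes the base
inject_errors <- function(seqs, read_len, error_rate) {
  n_err <- rbinom(length(seqs), read_len, error_rate)
  hit <- which(n_err > 0)
  if (!length(hit)) return(seqs)
  read_idx <- rep(hit, n_err[hit])
  pos <- floor(runif(length(read_idx)) * read_len) + 1
  k <- sequence(n_err[hit])
  others <- rbind(c("C", "G", "T"), c("A", "G", "T"),
                  c("A", "C", "T"), c("A", "C", "G"))
  rownames(others) <- DNA_BASES
  for (round_k in seq_len(max(k))) {
    sel <- k == round_k
    idx <- read_idx[sel]
    p <- pos[sel]
    orig <- substring(seqs[idx], p, p)
    pick <- others[cbind(match(orig, DNA_BASES),
                         sample.int(3, length(idx), replace = TRUE))]
    substr(seqs[idx], p, p) <- pick
  }
  seqs
}
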