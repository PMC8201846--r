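#' Build a canonical k-mer occurrence index
#'
#' Counts every length-`k` window of the input sequences after
#' canonicalisation (the lexicographic minimum of the k-mer and its reverse
#' complement, so reads are treated as unstranded). Windows containing
#' non-ACGT characters are dropped. The default `k = 49` follows the
#' tallymer-style profiling procedure the classifier reproduces.
#'
#' @param sequences Character vector of sequences, a tibble with a `seq`
#'   column (e.g. a read set), or a `DNAStringSet`.
#' @param k K-mer size (>= 2; all sequences shorter than `k` are ignored, but
#'   at least one must reach `k`).
#' @param min_count Discard k-mers seen fewer than `min_count` times
#'   (default 1, i.e. keep everything).
#' @param source Free-text label for the index.
#' @return A `kmer_index` list: `k`, `kmer` (character vector of canonical
#'   k-mers), `count` (integer), `source`.
#' @export
build_kmer_index <- function(sequences, k = 49, min_count = 1, source = "") {
  check_that(k >= 2, "k must be >= 2")
  seqs <- sequences_as_character(sequences)
  seqs <- seqs[nchar(seqs) >= k]
  check_that(length(seqs) > 0, "no input sequence of length >= k")
  tab <- kmer_count_table(unname(seqs), as.integer(k))
  keep <- tab$count >= min_count
  structure(list(k = k,
                 kmer = tab$kmer[keep],
                 count = tab$count[keep],
                 source = source),
            class = "kmer_index")
}

sequences_as_character <- function(x) {
  if (is.data.frame(x)) return(x$seq)
  if (methods::is(x, "DNAStringSet")) return(as.character(x))
  x  # already character; keep any names
}

# canonical k-mers of one sequence, in position order; NA where the window
# contains a non-ACGT character
canonical_kmers <- function(seq, k) {
  n <- nchar(seq)
  if (n < k) return(character(0))
  fwd <- substring(seq, 1:(n - k + 1), k:n)
  rc <- revcomp_windows(seq, k)
  can <- pmin(fwd, rc)
  can[grepl("[^ACGT]", fwd)] <- NA_character_
  can
}

# reverse complements of all k-windows, aligned with forward window order:
# window i of seq corresponds to window (n-k+2-i) of revcomp(seq)
revcomp_windows <- function(seq, k) {
  n <- nchar(seq)
  rcs <- revcomp(gsub("[^ACGT]", "A", seq))  # placeholder; masked later
  w <- substring(rcs, 1:(n - k + 1), k:n)
  rev(w)
}

#' @export
print.kmer_index <- function(x, ...) {
  cat(sprintf("<kmer_index> k=%d, %d distinct k-mers, %s total occurrences",
              x$k, length(x$kmer), format(sum(x$count), big.mark = ","))
      , if (nzchar(x$source)) sprintf(" [%s]", x$source) else "", "\n", sep = "")
  invisible(x)
}

# occurrence counts of query canonical k-mers in an index (0 when absent)
kmer_lookup <- function(index, kmers) {
  m <- match(kmers, index$kmer)
  out <- ifelse(is.na(m), 0L, index$count[m])
  out[is.na(kmers)] <- NA_integer_
  out
}

#' Per-position k-mer profile of a scaffold
#'
#' For each k-mer start position of a scaffold, reports the occurrence count
#' of the (canonical) k-mer in the A-genome index and whether it is present in
#' the B-enriched read index. Positions whose A-index count reaches
#' `repeat_threshold` form the repetitive mask.
#'
#' @param scaffold A single DNA string.
#' @param a_index,b_index `kmer_index` objects with identical `k`.
#' @param repeat_threshold A-count at or above which a position is masked
#'   repetitive (default 4).
#' @return A tibble: `pos` (0-based), `a_count`, `b_covered`, `repetitive`.
#' @export
profile_scaffold <- function(scaffold, a_index, b_index,
                             repeat_threshold = 4) {
  check_that(a_index$k == b_index$k, "index k mismatch between a_index and b_index")
  k <- a_index$k
  check_that(nchar(scaffold) >= k, "scaffold shorter than k")
  a_count <- kmer_count_lookup(scaffold, as.integer(k), a_index$kmer,
                               a_index$count)
  b_count <- kmer_count_lookup(scaffold, as.integer(k), b_index$kmer,
                               b_index$count)
  b_cov <- b_count > 0
  tibble(pos = seq_along(a_count) - 1L,
         a_count = a_count,
         b_covered = b_cov,
         repetitive = !is.na(a_count) & a_count >= repeat_threshold)
}

#' Classify scaffolds as A-derived, B-derived or ambiguous
#'
#' Applies the k-mer decision rule over nonrepetitive positions: a scaffold is
#' labelled `A` when at least `a_align_frac` of its nonrepetitive positions
#' hit the A index, else `B` when at least `min_b_covered_frac` of them are
#' covered by the B-enriched read index, else `ambiguous`. Scaffolds shorter
#' than `min_len` (default 10 kb) are excluded and reported as `short`;
#' scaffolds with no nonrepetitive positions are reported as `repeat_only`
#' (the analog of satellite-only scaffolds that k-mer evidence cannot place).
#'
#' @param scaffolds A `scaffold_set`, tibble with `scaffold`/`seq` columns,
#'   or named character vector.
#' @param a_index,b_index `kmer_index` objects with identical `k`.
#' @param min_len Minimum scaffold length for classification.
#' @param min_b_covered_frac B-coverage fraction required for a `B` label.
#' @param a_align_frac A-hit fraction at or above which the label is `A`.
#' @param repeat_threshold Passed to [profile_scaffold()].
#' @return A tibble: `scaffold`, `length`, `frac_a_hit`, `frac_b_covered`,
#'   `n_nonrepetitive`, `label`.
#' @export
classify_scaffolds <- function(scaffolds, a_index, b_index, min_len = 10000,
                               min_b_covered_frac = 0.8, a_align_frac = 0.5,
                               repeat_threshold = 4) {
  seqs <- if (is.data.frame(scaffolds)) {
    setNames(scaffolds$seq, scaffolds$scaffold %||% scaffolds$name)
  } else {
    x <- sequences_as_character(scaffolds)
    if (is.null(names(x))) names(x) <- paste0("scf", seq_along(x))
    x
  }
  check_that(length(seqs) > 0, "no scaffolds to classify")
  purrr::map_dfr(names(seqs), function(nm) {
    len <- nchar(seqs[[nm]])
    if (len < min_len) {
      return(tibble(scaffold = nm, length = len, frac_a_hit = NA_real_,
                    frac_b_covered = NA_real_, n_nonrepetitive = NA_integer_,
                    label = "short"))
    }
    prof <- profile_scaffold(seqs[[nm]], a_index, b_index, repeat_threshold)
    nonrep <- prof |> filter(!.data$repetitive, !is.na(.data$a_count))
    if (nrow(nonrep) == 0) {
      return(tibble(scaffold = nm, length = len, frac_a_hit = NA_real_,
                    frac_b_covered = NA_real_, n_nonrepetitive = 0L,
                    label = "repeat_only"))
    }
    fa <- mean(nonrep$a_count >= 1)
    fb <- mean(nonrep$b_covered)
    label <- if (fa >= a_align_frac) "A"
      else if (fb >= min_b_covered_frac) "B"
      else "ambiguous"
    tibble(scaffold = nm, length = len, frac_a_hit = fa, frac_b_covered = fb,
           n_nonrepetitive = nrow(nonrep), label = label)
  })
}

#' Repetitive-position mask from k-mer self-multiplicity
#'
#' Marks scaffold windows as repetitive where the scaffold set's own k-mers
#' recur. A position is repetitive when its canonical k-mer occurs at least
#' `self_threshold` times within the scaffold set (tandem arrays and young TE
#' copies recur many times; unique sequence once); a window is masked when at
#' least `min_masked_frac` of its k-mer positions are repetitive. This is the
#' mask [coverage_windows()] consumes: it flags exactly the regions where
#' unique-placement read mapping is uninformative.
#'
#' @param scaffolds A `scaffold_set` or tibble with `scaffold`/`seq`.
#' @param a_sequences Optional A-complement sequences (named character,
#'   tibble or `DNAStringSet`); positions whose k-mer occurs at least
#'   `a_threshold` times in the A complement are also masked, so regions the
#'   host complement can explain -- and host reads can cross-map into -- are
#'   excluded from coverage calls.
#' @param k K-mer size.
#' @param self_threshold Occurrence count at or above which a k-mer is
#'   repetitive within the scaffold set (default 2).
#' @param a_threshold Occurrence count in the A complement at or above which
#'   a position is masked (default 1: any host-shared k-mer).
#' @param window Window size in bp for the output window mask.
#' @param min_masked_frac Fraction of repetitive positions that masks a window.
#' @return A list: `positions` (BED-like tibble of merged repetitive
#'   k-mer-start intervals per scaffold) and `windows` (BED-like tibble of
#'   masked windows).
#' @export
repeat_mask <- function(scaffolds, a_sequences = NULL, k = 49,
                        self_threshold = 2, a_threshold = 1,
                        window = 1000, min_masked_frac = 0.5) {
  seqs <- setNames(scaffolds$seq, scaffolds$scaffold)
  idx <- kmer_hash_build(unname(seqs), as.integer(k))
  a_idx <- if (!is.null(a_sequences)) {
    kmer_hash_build(unname(subjects_as_character(a_sequences)),
                    as.integer(k))
  }
  pos_l <- list()
  win_l <- list()
  for (nm in names(seqs)) {
    self_n <- kmer_hash_lookup(idx, seqs[[nm]], as.integer(k))
    rep_pos <- self_n >= self_threshold
    if (!is.null(a_idx)) {
      a_n <- kmer_hash_lookup(a_idx, seqs[[nm]], as.integer(k))
      rep_pos <- rep_pos | a_n >= a_threshold
    }
    rep_pos[is.na(rep_pos)] <- TRUE
    len <- nchar(seqs[[nm]])
    r <- rle(rep_pos)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths
    if (any(r$values)) {
      pos_l[[nm]] <- tibble(chrom = nm,
                            start = as.integer(starts[r$values]),
                            end = as.integer(ends[r$values]))
    }
    n_win <- ceiling(len / window)
    win_id <- (seq_along(rep_pos) - 1L) %/% window
    frac <- tapply(rep_pos, factor(win_id, levels = 0:(n_win - 1)), mean)
    frac[is.na(frac)] <- 1  # trailing windows with no full k-mer
    masked <- which(frac >= min_masked_frac) - 1L
    if (length(masked)) {
      win_l[[nm]] <- tibble(chrom = nm, start = as.integer(masked * window),
                            end = as.integer(pmin((masked + 1) * window, len)))
    }
  }
  empty <- tibble(chrom = character(0), start = integer(0), end = integer(0))
  list(positions = if (length(pos_l)) bind_rows(pos_l) else empty,
       windows = if (length(win_l)) bind_rows(win_l) else empty)
}

#' @rdname repeat_mask
#' @param ... Passed to [repeat_mask()].
#' @export
repeat_mask_windows <- function(scaffolds, a_sequences = NULL, ...) {
  repeat_mask(scaffolds, a_sequences = a_sequences, ...)$windows
}

#' Drop read placements lying mostly in masked positions
#'
#' Removes placements for which more than `max_masked_frac` of the
#' k-mer-start positions spanned by the read are masked: such a placement
#' sits in sequence the host complement or another internal copy can
#' explain, carries no deletion-mapping information, and is the signature of
#' a cross-mapped multi-copy (or sequencing-error cross-matched) read.
#' Genuine placements in informative sequence overlap mostly unmasked
#' positions and are untouched.
#'
#' @param placements Placement tibble from [map_unique_reads()].
#' @param mask_positions The `positions` element of [repeat_mask()].
#' @param scaffolds The scaffold set (for lengths; positions past the last
#'   k-mer start are clamped).
#' @param k K-mer size used to build the mask.
#' @param max_masked_frac Masked fraction of the spanned positions above
#'   which a placement is dropped (default 0.5).
#' @return The filtered placement tibble.
#' @export
filter_masked_placements <- function(placements, mask_positions,
                                     scaffolds = NULL, k = 49,
                                     max_masked_frac = 0.5) {
  if (nrow(placements) == 0 || nrow(mask_positions) == 0) return(placements)
  lens <- if (!is.null(scaffolds)) scaffold_lengths(scaffolds)
  keep <- rep(TRUE, nrow(placements))
  for (nm in unique(placements$scaffold)) {
    rows <- which(placements$scaffold == nm)
    mk <- mask_positions |> filter(.data$chrom == nm)
    if (nrow(mk) == 0) next
    top <- if (!is.null(lens) && nm %in% names(lens)) {
      max(1L, lens[[nm]] - k + 1L)
    } else {
      max(placements$start[rows] + placements$width[rows])
    }
    # cumulative masked-position count over k-mer starts [0, top)
    delta <- integer(top + 1L)
    s <- pmin(mk$start, top)
    e <- pmin(mk$end, top)
    delta[s + 1L] <- delta[s + 1L] + 1L
    delta[e + 1L] <- delta[e + 1L] - 1L
    cum <- c(0L, cumsum(cumsum(delta))[seq_len(top)])
    p0 <- pmin(placements$start[rows], top - 1L)
    p1 <- pmin(placements$start[rows] + placements$width[rows] - k + 1L, top)
    p1 <- pmax(p1, p0 + 1L)
    masked_frac <- (cum[p1 + 1L] - cum[p0 + 1L]) / (p1 - p0)
    keep[rows] <- masked_frac <= max_masked_frac
  }
  placements[keep, ]
}
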