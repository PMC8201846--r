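#' Trim artificial 3' tails from reads
#'
#' Removes the maximal 3' run of ambiguous bases (N) and/or artificial poly-G
#' when it is at least `trim_min` long, then drops reads shorter than
#' `min_keep`. Internal runs are untouched.
#'
#' @param reads Tibble with a `seq` column.
#' @param trim_min Minimum 3' run length to trim (default 3).
#' @param min_keep Minimum retained read length (default 30).
#' @return The trimmed read tibble; attributes `n_trimmed` and `n_dropped`
#'   record what happened.
#' @export
preprocess_reads <- function(reads, trim_min = 3, min_keep = 30) {
  check_that(nrow(reads) > 0, "reads must be nonempty")
  pattern <- sprintf("[NG]{%d,}$", trim_min)
  trimmed <- sub(pattern, "", reads$seq)
  n_trimmed <- sum(trimmed != reads$seq)
  out <- reads
  out$seq <- trimmed
  keep <- nchar(out$seq) >= min_keep
  n_dropped <- sum(!keep)
  out <- out[keep, ]
  if (nrow(out) == 0) warn("all reads dropped by preprocessing")
  attr(out, "n_trimmed") <- n_trimmed
  attr(out, "n_dropped") <- n_dropped
  out
}

# ---- matching engine --------------------------------------------------------
# Exact and near-exact (Hamming) placement of short reads on subject
# sequences. Subjects are concatenated with short N separators so each strand
# is scanned once; any placement touching a separator is discarded, which
# keeps the semantics identical to per-subject scanning (N matches nothing
# and separators exceed the mismatch budget, so placements cannot bridge
# subjects).
#
# Near-exact search is seed-and-verify with pigeonhole anchoring: three
# disjoint 19-bp seeds at fixed offsets are matched exactly (one PDict, one
# Aho-Corasick pass per strand); any placement with <= 2 substitutions leaves
# at least one seed intact, so the union of seed hits contains every
# placement, and candidates are then verified by vectorised Hamming
# comparison. Exact search uses full-read dictionaries for the common read
# lengths and a shared-prefix dictionary (verified by string equality) for
# the rest. Substitution-only throughout, by design.

subjects_as_character <- function(subjects) {
  if (is.data.frame(subjects)) {
    nm_col <- intersect(c("scaffold", "name"), names(subjects))[1]
    return(setNames(subjects$seq,
                    if (!is.na(nm_col)) subjects[[nm_col]] else
                      paste0("seq", seq_len(nrow(subjects)))))
  }
  x <- if (methods::is(subjects, "DNAStringSet")) {
    as.character(subjects)  # keeps names for XStringSet
  } else {
    subjects
  }
  if (is.null(names(x))) names(x) <- paste0("seq", seq_along(x))
  x
}

#' Build a reusable subject catalog for read placement
#'
#' Concatenates subject sequences (with N separators) and caches both strands
#' so repeated placement queries against the same subjects skip the setup.
#'
#' @param subjects Named character vector, tibble (`scaffold`/`name` + `seq`)
#'   or `DNAStringSet`.
#' @param sep_len Separator length (must exceed any mismatch budget used).
#' @return A `subject_catalog` object.
#' @export
subject_catalog <- function(subjects, sep_len = 16) {
  seqs <- subjects_as_character(subjects)
  widths <- nchar(seqs)
  starts <- as.integer(cumsum(c(1, head(widths, -1) + sep_len)))
  big_char <- paste(seqs, collapse = strrep("N", sep_len))
  big <- Biostrings::DNAString(big_char)
  big_rc <- Biostrings::reverseComplement(big)
  structure(list(big = big, big_rc = big_rc,
                 big_char = big_char, big_rc_char = as.character(big_rc),
                 starts = starts, ends = as.integer(starts + widths - 1L),
                 names = names(seqs), total = nchar(big_char),
                 cache = new.env(parent = emptyenv())),
            class = "subject_catalog")
}

as_catalog <- function(subjects) {
  if (inherits(subjects, "subject_catalog")) subjects else
    subject_catalog(subjects)
}

# lazily built subject-side seed index (shared across queries on a catalog)
get_seed_index <- function(cat_) {
  if (is.null(cat_$cache$seed_ix)) {
    cat_$cache$seed_ix <- seed_index_build(cat_$big_char, SEED_W)
  }
  cat_$cache$seed_ix
}

# harvest matchPDict hits into (pattern original index, start) pairs
harvest_hits <- function(m, grp) {
  sl <- Biostrings::startIndex(m)
  nh <- lengths(sl)
  if (sum(nh) == 0) {
    return(list(idx = integer(0), start = integer(0)))
  }
  list(idx = rep(grp, nh), start = unlist(sl, use.names = FALSE))
}

# candidate (idx, strand, start-on-strand, verified) -> verified
# forward-strand placements within subject bounds; unverified candidates go
# through the compiled Hamming kernel against the strand they were found on
finalize_candidates <- function(cand, cat_, seqs, max_mm) {
  empty <- tibble(idx = integer(0), subject = character(0),
                  strand = character(0), start = integer(0))
  if (!nrow(cand)) return(empty)
  w_all <- nchar(seqs[cand$idx])
  neg <- cand$strand == "-"
  fwd <- cand$start
  fwd[neg] <- cat_$total - (cand$start[neg] + w_all[neg] - 1L) + 1L
  si <- findInterval(fwd, cat_$starts)
  inb <- si >= 1 & fwd >= cat_$starts[pmax(si, 1L)] &
    fwd + w_all - 1L <= cat_$ends[pmax(si, 1L)]
  cand <- cand[inb, ]
  if (!nrow(cand)) return(empty)
  fwd <- fwd[inb]
  si <- si[inb]
  neg <- neg[inb]
  keep <- if ("verified" %in% names(cand)) cand$verified else
    logical(nrow(cand))
  for (s in c(FALSE, TRUE)) {
    rows <- which(!keep & neg == s)
    if (!length(rows)) next
    keep[rows] <- verify_candidates(
      if (s) cat_$big_rc_char else cat_$big_char,
      cand$start[rows], unname(seqs), cand$idx[rows], as.integer(max_mm))
  }
  tibble(idx = cand$idx[keep], subject = cat_$names[si[keep]],
         strand = cand$strand[keep],
         start = as.integer(fwd[keep] - cat_$starts[si[keep]] + 1L))
}

SEED_W <- 19L

#' All near-exact placements of reads on subject sequences
#'
#' Enumerates every placement of each read on every subject (both strands)
#' with at most `max_mismatch` substitutions (1-based forward-strand starts).
#' This is the engine behind [subtract_host_reads()] and
#' [map_unique_reads()].
#'
#' @param seqs Character vector of read sequences.
#' @param subjects Subjects (named character, tibble, `DNAStringSet`, or a
#'   prebuilt [subject_catalog()]).
#' @param max_mismatch Maximum substitutions per placement.
#' @param only_idx Optional subset of read indices to search.
#' @return Tibble: `idx` (read index), `subject`, `strand`, `start`.
#' @export
match_placements <- function(seqs, subjects, max_mismatch = 0,
                             only_idx = NULL) {
  cat_ <- as_catalog(subjects)
  empty <- tibble(idx = integer(0), subject = character(0),
                  strand = character(0), start = integer(0))
  idx_all <- only_idx %||% seq_along(seqs)
  idx_all <- idx_all[!grepl("[^ACGT]", seqs[idx_all])]
  if (!length(idx_all)) return(empty)
  widths <- nchar(seqs[idx_all])
  cand <- if (max_mismatch == 0) {
    exact_candidates(seqs, cat_, idx_all, widths)
  } else {
    seeded_candidates(seqs, cat_, idx_all, widths, max_mismatch)
  }
  out <- finalize_candidates(cand, cat_, seqs, max_mismatch)
  distinct(out)
}

# exact search: full-read PDict for common widths, shared-prefix dict +
# equality verification for the rest
exact_candidates <- function(seqs, cat_, idx_all, widths, min_bulk = 200) {
  frames <- list()
  scan_pdict <- function(pd, grp, verified) {
    for (strand in c("+", "-")) {
      target <- if (strand == "+") cat_$big else cat_$big_rc
      h <- harvest_hits(Biostrings::matchPDict(pd, target), grp)
      if (length(h$idx)) {
        frames[[length(frames) + 1]] <<- tibble(
          idx = h$idx, strand = strand, start = h$start,
          verified = verified)
      }
    }
  }
  tab <- table(widths)
  bulk_w <- as.integer(names(tab)[tab >= min_bulk])
  for (w in bulk_w) {
    grp <- idx_all[widths == w]
    pd <- Biostrings::PDict(Biostrings::DNAStringSet(unname(seqs[grp])))
    scan_pdict(pd, grp, verified = TRUE)  # full-read hits are exact already
  }
  rest <- idx_all[!widths %in% bulk_w]
  if (length(rest)) {
    p <- min(nchar(seqs[rest]))
    pd <- Biostrings::PDict(Biostrings::DNAStringSet(
      substr(unname(seqs[rest]), 1, p)))
    scan_pdict(pd, rest, verified = FALSE)  # prefix anchors need full check
  }
  if (!length(frames)) {
    return(tibble(idx = integer(0), strand = character(0),
                  start = integer(0), verified = logical(0)))
  }
  bind_rows(frames)  # one dictionary per read: hits already unique
}

# near-exact search: three disjoint fixed-offset seeds, pigeonhole over
# max_mismatch <= 2; short reads fall back to per-read matchPattern
seeded_candidates <- function(seqs, cat_, idx_all, widths, max_mismatch) {
  check_that(max_mismatch <= 2,
             "seeded search supports at most 2 mismatches")
  frames <- list()
  long <- idx_all[widths >= 3L * SEED_W]
  if (length(long)) {
    offs <- c(0L, SEED_W, 2L * SEED_W)
    pat <- unlist(lapply(offs, function(o) {
      substr(unname(seqs[long]), o + 1L, o + SEED_W)
    }))
    grp <- rep(long, times = 3)
    shift <- rep(offs, each = length(long))
    pd <- Biostrings::PDict(Biostrings::DNAStringSet(pat))
    for (strand in c("+", "-")) {
      target <- if (strand == "+") cat_$big else cat_$big_rc
      h <- harvest_hits(Biostrings::matchPDict(pd, target), seq_along(pat))
      if (!length(h$idx)) next
      frames[[length(frames) + 1]] <- tibble(
        idx = grp[h$idx], strand = strand,
        start = h$start - shift[h$idx], verified = FALSE)
    }
  }
  short <- setdiff(idx_all, long)
  for (i in short) {
    pat <- Biostrings::DNAString(seqs[i])
    for (strand in c("+", "-")) {
      target <- if (strand == "+") cat_$big else cat_$big_rc
      m <- Biostrings::matchPattern(pat, target,
                                    max.mismatch = max_mismatch)
      if (length(m)) {
        frames[[length(frames) + 1]] <- tibble(
          idx = i, strand = strand,
          start = as.integer(BiocGenerics::start(m)), verified = TRUE)
      }
    }
  }
  if (!length(frames)) {
    return(tibble(idx = integer(0), strand = character(0),
                  start = integer(0), verified = logical(0)))
  }
  out <- bind_rows(frames)
  out <- out[out$start >= 1L, ]
  distinct(out, .data$idx, .data$strand, .data$start, .keep_all = TRUE)
}

#' Subtract reads explained by the host (A) genome
#'
#' Removes a read if and only if it has exactly one placement on the A
#' complement with at most `max_mismatches` substitutions among at most
#' `max_hits` considered placements; reads with zero or multiple placements
#' are retained. The matcher is exact seed anchoring with Hamming
#' verification (substitution-only, both strands).
#'
#' @param reads Preprocessed read tibble (`seq` column).
#' @param a_genome A-complement sequences (named character, tibble,
#'   `DNAStringSet`, or a prebuilt [subject_catalog()]).
#' @param max_mismatches Maximum substitutions for a host placement
#'   (default 2).
#' @param max_hits Placement-count cap; any read reaching it is treated as
#'   multi-mapping and retained (default 10).
#' @return The retained reads; attribute `n_removed` counts subtractions.
#' @export
subtract_host_reads <- function(reads, a_genome, max_mismatches = 2,
                                max_hits = 10) {
  check_that(nrow(reads) > 0, "reads must be nonempty")
  check_that(min(nchar(reads$seq)) >= 3 * (max_mismatches + 1),
             "reads too short for banded anchoring")
  cat_ <- as_catalog(a_genome)
  q <- seed_index_query(get_seed_index(cat_), reads$seq, cat_$starts,
                        cat_$ends, as.integer(max_mismatches), 3L, 0L, 2L)
  nhit <- q$counts
  short <- which(is.na(nhit))
  if (length(short)) {  # reads too short for three seeds: generic engine
    pl <- match_placements(reads$seq, cat_, max_mismatch = max_mismatches,
                           only_idx = short)
    nhit[short] <- 0L
    if (nrow(pl)) {
      tab <- pl |> count(.data$idx)
      nhit[tab$idx] <- tab$n
    }
  }
  removed <- nhit == 1 & nhit <= max_hits
  out <- reads[!removed, ]
  attr(out, "n_removed") <- sum(removed)
  out
}

#' Uniquely place reads on scaffolds with no mismatches
#'
#' Keeps a read only when it matches exactly one location across all scaffolds
#' (both strands) with zero mismatches, and reports that placement.
#'
#' @param reads Read tibble (`read_id`, `seq`).
#' @param scaffolds `scaffold_set`, tibble (`scaffold`, `seq`), named
#'   character vector, or a prebuilt [subject_catalog()].
#' @return Placement tibble: `read_id`, `scaffold`, `start` (0-based, forward
#'   strand), `strand`, `width`.
#' @export
map_unique_reads <- function(reads, scaffolds) {
  empty <- tibble(read_id = character(0), scaffold = character(0),
                  start = integer(0), strand = character(0),
                  width = integer(0))
  if (nrow(reads) == 0) return(empty)
  cat_ <- as_catalog(scaffolds)
  q <- seed_index_query(get_seed_index(cat_), reads$seq, cat_$starts,
                        cat_$ends, 0L, 1L, 1L, 2L)
  keep <- !is.na(q$counts[q$idx]) & q$counts[q$idx] == 1
  out <- tibble(idx = q$idx[keep],
                strand = c("+", "-")[q$strand[keep] + 1L],
                big_start = q$start[keep])
  short <- which(is.na(q$counts))
  if (length(short)) {
    pl <- match_placements(reads$seq, cat_, max_mismatch = 0,
                           only_idx = short)
    uniq <- pl |> group_by(.data$idx) |> filter(n() == 1) |> ungroup()
    if (nrow(uniq)) {
      si <- match(uniq$subject, cat_$names)
      out <- bind_rows(out, tibble(
        idx = uniq$idx, strand = uniq$strand,
        big_start = uniq$start - 1L + cat_$starts[si] - 1L))
    }
  }
  if (nrow(out) == 0) return(empty)
  si <- findInterval(out$big_start + 1L, cat_$starts)
  tibble(read_id = reads$read_id[out$idx],
         scaffold = cat_$names[si],
         start = as.integer(out$big_start - (cat_$starts[si] - 1L)),
         strand = out$strand,
         width = nchar(reads$seq[out$idx]))
}
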