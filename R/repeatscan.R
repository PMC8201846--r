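#' Scan a sequence for tandem repeat monomer units
#'
#' Greedy non-overlapping detection of monomer copies against a consensus by
#' iterated best local alignment (both strands): the best-scoring hit is
#' recorded, then the flanking regions are scanned recursively. Hits are
#' retained when identity (matches / alignment columns) reaches
#' `min_identity` and the hit length is within `[0.5, 1.5]` monomer lengths.
#'
#' @param sequence DNA string to scan.
#' @param consensus Monomer consensus (>= 20 bp).
#' @param min_identity Minimum percent identity (default 70).
#' @return Tibble of hits: `start`, `end` (0-based half-open), `strand`,
#'   `identity`, sorted by position.
#' @export
scan_monomers <- function(sequence, consensus, min_identity = 70) {
  check_that(nchar(consensus) >= 20, "consensus must be >= 20 bp")
  L <- nchar(consensus)
  submat <- Biostrings::nucleotideSubstitutionMatrix(match = 2, mismatch = -3)
  cons <- list(`+` = Biostrings::DNAString(consensus),
               `-` = Biostrings::DNAString(revcomp(consensus)))
  hits <- list()
  scan_region <- function(from, to) {  # 0-based half-open region
    if (to - from < 0.5 * L) return(invisible())
    subj <- Biostrings::DNAString(substr(sequence, from + 1, to))
    best <- NULL
    for (strand in c("+", "-")) {
      aln <- Biostrings::pairwiseAlignment(
        cons[[strand]], subj, type = "local",
        substitutionMatrix = submat, gapOpening = 5, gapExtension = 2)
      if (is.null(best) || Biostrings::score(aln) > best$score) {
        best <- list(aln = aln, strand = strand,
                     score = Biostrings::score(aln))
      }
    }
    aln <- best$aln
    s <- BiocGenerics::start(Biostrings::subject(aln))
    e <- BiocGenerics::end(Biostrings::subject(aln))
    if (length(s) == 0 || e < s) return(invisible())
    cols <- nchar(as.character(Biostrings::alignedPattern(aln)))
    ident <- 100 * Biostrings::nmatch(aln) / cols
    width <- e - s + 1
    keep <- ident >= min_identity && width >= 0.5 * L && width <= 1.5 * L
    if (!keep) return(invisible())
    hits[[length(hits) + 1]] <<- tibble(
      start = from + s - 1L, end = from + e, strand = best$strand,
      identity = ident)
    scan_region(from, from + s - 1L)
    scan_region(from + e, to)
    invisible()
  }
  scan_region(0L, nchar(sequence))
  if (!length(hits)) {
    return(tibble(start = integer(0), end = integer(0),
                  strand = character(0), identity = numeric(0)))
  }
  bind_rows(hits) |> arrange(.data$start)
}

#' Merge overlapping read pairs
#'
#' Merges mates oriented toward each other when their 3' overlap is at least
#' `min_overlap` bp, allowing one mismatch per 10 bp of overlap. The largest
#' acceptable overlap is used; merged length is `len1 + len2 - overlap`.
#' Unmergeable pairs are dropped (and counted in the `n_unmerged` attribute).
#'
#' @param pairs Tibble with columns `read1`, `read2` (and optionally
#'   `pair_id`).
#' @param min_overlap Minimum overlap in bp (default 10).
#' @return Tibble of merged reads: `pair_id`, `seq`, `overlap`.
#' @export
merge_read_pairs <- function(pairs, min_overlap = 10) {
  n <- nrow(pairs)
  r1 <- pairs$read1
  r2rc <- revcomp(pairs$read2)
  len1 <- nchar(r1)
  len2 <- nchar(r2rc)
  overlap <- rep(NA_integer_, n)
  pending <- seq_len(n)
  # exact pass, largest overlap first (vectorised per candidate overlap)
  for (o in seq(max(pmin(len1, len2)), min_overlap)) {
    if (!length(pending)) break
    ok <- pending[pmin(len1[pending], len2[pending]) >= o]
    if (!length(ok)) next
    hitv <- substr(r1[ok], len1[ok] - o + 1, len1[ok]) ==
      substr(r2rc[ok], 1, o)
    overlap[ok[hitv]] <- o
    pending <- setdiff(pending, ok[hitv])
  }
  # mismatch-tolerant pass for the remainder (1 mismatch per 10 bp)
  for (i in pending) {
    for (o in seq(min(len1[i], len2[i]), min_overlap)) {
      a <- utf8ToInt(substr(r1[i], len1[i] - o + 1, len1[i]))
      b <- utf8ToInt(substr(r2rc[i], 1, o))
      if (sum(a != b) <= o %/% 10) {
        overlap[i] <- o
        break
      }
    }
  }
  merged <- which(!is.na(overlap))
  out <- tibble(
    pair_id = (pairs$pair_id %||% sprintf("pair%06d", seq_len(n)))[merged],
    seq = paste0(r1[merged],
                 substr(r2rc[merged], overlap[merged] + 1, len2[merged])),
    overlap = overlap[merged]
  )
  attr(out, "n_unmerged") <- n - length(merged)
  out
}

#' Midpoint profile of merged reads on a repeat multimer
#'
#' Places each merged read at its best (lowest-mismatch) location on a
#' concatenation of `copies` consensus copies (both strands; default a
#' trimer), takes the placement midpoint `floor((start + end) / 2)` in
#' 0-based half-open coordinates, and folds it onto the monomer as
#' `midpoint mod L`. For tandem copies the folded offset is invariant to
#' which copy a multi-placed read is assigned to. Reads longer than the
#' multimer, or with more than `max_mismatch` mismatches everywhere, are
#' skipped and counted.
#'
#' @param merged Merged read tibble (`seq` column) for the ChIP set.
#' @param consensus Monomer consensus.
#' @param copies Number of concatenated copies (>= 3).
#' @param input Optional merged read tibble for the input (control) set.
#' @param max_mismatch Maximum placement mismatches (default 2).
#' @return A `midpoint_profile` tibble: `offset` (0..L-1), `chip`, `chip_cpm`
#'   and, when `input` is given, `input`, `input_cpm`.
#' @export
midpoint_profile <- function(merged, consensus, copies = 3, input = NULL,
                             max_mismatch = 2) {
  check_that(copies >= 3, "copies must be >= 3")
  L <- nchar(consensus)
  multimer <- strrep(consensus, copies)
  prof <- function(reads) {
    offs <- read_midpoint_offsets(reads$seq, multimer, L, max_mismatch)
    counts <- tabulate(offs + 1L, nbins = L)
    list(counts = counts, n_mapped = length(offs),
         n_skipped = nrow(reads) - length(offs))
  }
  ch <- prof(merged)
  out <- tibble(offset = 0:(L - 1L), chip = ch$counts,
                chip_cpm = 1e6 * ch$counts / max(1, ch$n_mapped))
  attr(out, "n_mapped_chip") <- ch$n_mapped
  attr(out, "n_skipped_chip") <- ch$n_skipped
  if (!is.null(input)) {
    inp <- prof(input)
    out$input <- inp$counts
    out$input_cpm <- 1e6 * inp$counts / max(1, inp$n_mapped)
    attr(out, "n_mapped_input") <- inp$n_mapped
    attr(out, "n_skipped_input") <- inp$n_skipped
  }
  attr(out, "monomer_length") <- L
  class(out) <- c("midpoint_profile", class(out))
  out
}

# best-placement midpoints mod L; exact PDict pass first, per-read
# mismatch-tolerant fallback for the rest
read_midpoint_offsets <- function(seqs, multimer, L, max_mismatch) {
  ml <- nchar(multimer)
  keep <- which(nchar(seqs) <= ml & !grepl("[^ACGT]", seqs))
  if (!length(keep)) return(integer(0))
  subj <- Biostrings::DNAString(multimer)
  subj_rc <- Biostrings::reverseComplement(subj)
  starts <- rep(NA_integer_, length(seqs))  # 1-based on forward multimer
  widths <- nchar(seqs)
  for (w in unique(widths[keep])) {
    grp <- keep[widths[keep] == w]
    pd <- Biostrings::PDict(Biostrings::DNAStringSet(unname(seqs[grp])))
    for (strand in c("+", "-")) {
      target <- if (strand == "+") subj else subj_rc
      sl <- Biostrings::startIndex(Biostrings::matchPDict(pd, target))
      hit <- which(lengths(sl) > 0 & is.na(starts[grp]))
      if (!length(hit)) next
      st <- vapply(sl[hit], `[`, integer(1), 1)
      if (strand == "-") st <- ml - (st + w - 1L) + 1L
      starts[grp[hit]] <- st
    }
  }
  # fallback: tolerate up to max_mismatch substitutions
  if (max_mismatch > 0) {
    for (i in keep[is.na(starts[keep])]) {
      pat <- Biostrings::DNAString(seqs[i])
      m <- Biostrings::matchPattern(pat, subj, max.mismatch = max_mismatch)
      if (length(m) > 0) {
        starts[i] <- BiocGenerics::start(m)[1]
        next
      }
      m <- Biostrings::matchPattern(pat, subj_rc,
                                    max.mismatch = max_mismatch)
      if (length(m) > 0) {
        starts[i] <- ml - (BiocGenerics::start(m)[1] + nchar(seqs[i]) - 1L) + 1L
      }
    }
  }
  ok <- which(!is.na(starts))
  s0 <- starts[ok] - 1L
  mids <- (s0 + s0 + widths[ok]) %/% 2L
  as.integer(mids %% L)
}

#' Call nucleosome-position peaks from a midpoint profile
#'
#' Smooths the ChIP/input ratio with a circular moving average, finds local
#' maxima with prominence at least `min_prominence` of the profile maximum,
#' ranks them by height, and labels them major/minor by a two-means split of
#' peak heights. When the profile has no input track, the raw smoothed ChIP
#' counts are used. All-zero input offsets receive a pseudocount of 1 (with a
#' warning).
#'
#' @param profile A `midpoint_profile`.
#' @param smoothing Circular smoothing window (bp, default 5).
#' @param min_prominence Minimum prominence as a fraction of the maximum
#'   smoothed signal (default 0.1).
#' @return Tibble of peaks: `offset`, `height`, `prominence`, `rank`,
#'   `class` (major/minor), ordered by rank.
#' @export
call_peaks <- function(profile, smoothing = 5, min_prominence = 0.1) {
  check_that(sum(profile$chip) > 0, "profile total must be > 0")
  sig <- if ("input" %in% names(profile)) {
    inp <- profile$input
    if (any(inp == 0)) {
      warn("zero input offsets: applying pseudocount 1")
      inp <- inp + 1
    }
    (profile$chip / sum(profile$chip)) / (inp / sum(inp))
  } else {
    profile$chip
  }
  s <- circular_smooth(sig, smoothing)
  L <- length(s)
  nxt <- c(2:L, 1)
  prv <- c(L, 1:(L - 1))
  is_max <- s > s[nxt] & s >= s[prv]
  peaks <- which(is_max)
  if (!length(peaks)) {
    return(tibble(offset = integer(0), height = numeric(0),
                  prominence = numeric(0), rank = integer(0),
                  class = character(0)))
  }
  prom <- vapply(peaks, function(p) circular_prominence(s, p), numeric(1))
  keep <- prom >= min_prominence * max(s)
  peaks <- peaks[keep]
  prom <- prom[keep]
  if (!length(peaks)) {
    return(tibble(offset = integer(0), height = numeric(0),
                  prominence = numeric(0), rank = integer(0),
                  class = character(0)))
  }
  out <- tibble(offset = peaks - 1L, height = s[peaks], prominence = prom) |>
    arrange(desc(.data$height)) |>
    mutate(rank = row_number())
  out$class <- if (nrow(out) == 1 ||
                   max(out$height) - min(out$height) < 1e-12) "major" else {
    km <- stats::kmeans(out$height, centers = rbind(min(out$height),
                                                    max(out$height)))
    ifelse(km$cluster == 2, "major", "minor")
  }
  out
}

circular_smooth <- function(x, window) {
  if (window <= 1) return(x)
  half <- window %/% 2
  n <- length(x)
  xx <- c(tail(x, half), x, head(x, half))
  as.numeric(stats::filter(xx, rep(1 / (2 * half + 1), 2 * half + 1),
                           sides = 2))[(half + 1):(half + n)]
}

# prominence of peak p on a circular series: height above the higher of the
# two key saddles reached before a strictly higher point on either side
circular_prominence <- function(s, p) {
  n <- length(s)
  walk <- function(step) {
    lowest <- s[p]
    i <- p
    for (k in seq_len(n - 1)) {
      i <- ((i - 1 + step) %% n) + 1
      if (s[i] > s[p]) return(lowest)
      lowest <- min(lowest, s[i])
    }
    lowest
  }
  s[p] - max(walk(1), walk(-1))
}

#' Per-group identity summaries with pairwise Welch t tests
#'
#' Summarises identity-to-consensus values per group (mean, median,
#' quartiles) and performs a two-sided Welch t test for every group pair.
#' Zero-variance pairs are guarded: equal constant groups give `t = 0`,
#' `p = 1`; unequal constant groups are flagged with `p = 0`.
#'
#' @param groups Named list of numeric vectors, or a tibble with `group` and
#'   `identity` columns. At least 2 groups with n >= 2 each.
#' @return A list: `summary` (per-group tibble) and `tests` (tibble:
#'   `group1`, `group2`, `t`, `df`, `p`, `flag`).
#' @export
identity_stats <- function(groups) {
  if (is.data.frame(groups)) {
    groups <- split(groups$identity, groups$group)
  }
  check_that(length(groups) >= 2, "need >= 2 groups")
  check_that(all(lengths(groups) >= 2), "each group needs n >= 2")
  summ <- purrr::imap_dfr(groups, function(v, nm) {
    q <- quantile(v, c(0.25, 0.5, 0.75))
    tibble(group = nm, n = length(v), mean = mean(v), sd = stats::sd(v),
           q25 = q[[1]], median = q[[2]], q75 = q[[3]])
  })
  cmb <- utils::combn(names(groups), 2)
  tests <- purrr::map_dfr(seq_len(ncol(cmb)), function(j) {
    a <- groups[[cmb[1, j]]]
    b <- groups[[cmb[2, j]]]
    if (stats::sd(a) == 0 && stats::sd(b) == 0) {
      eq <- isTRUE(all.equal(mean(a), mean(b)))
      return(tibble(group1 = cmb[1, j], group2 = cmb[2, j],
                    t = if (eq) 0 else Inf * sign(mean(a) - mean(b)),
                    df = NA_real_, p = if (eq) 1 else 0,
                    flag = "zero_variance"))
    }
    tt <- stats::t.test(a, b, var.equal = FALSE)
    tibble(group1 = cmb[1, j], group2 = cmb[2, j],
           t = unname(tt$statistic), df = unname(tt$parameter),
           p = tt$p.value, flag = NA_character_)
  })
  list(summary = summ, tests = tests)
}
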