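# Independent brute-force oracles. These deliberately share no code with the
# package engines: plain character loops over every position.

oracle_hamming <- function(a, b) {
  sum(utf8ToInt(a) != utf8ToInt(b))
}

# plain string reverse complement, independent of the package's helper
oracle_rc <- function(s) {
  paste(rev(strsplit(chartr("ACGT", "TGCA", s), "")[[1]]), collapse = "")
}

# all placements of one read on named subject sequences, <= max_mm
# substitutions, both strands; start is 1-based on the forward strand.
# Naive: every window of every subject is compared to the read.
oracle_placements_one <- function(read, subjects, max_mm) {
  out <- list()
  w <- nchar(read)
  rc <- oracle_rc(read)
  read_ok <- !grepl("[^ACGT]", read)
  for (nm in names(subjects)) {
    subj <- subjects[[nm]]
    n <- nchar(subj)
    if (n < w) next
    wins <- substring(subj, 1:(n - w + 1), w:n)
    for (s in seq_along(wins)) {
      if (grepl("[^ACGT]", wins[s])) next
      if (read_ok && oracle_hamming(read, wins[s]) <= max_mm) {
        out[[length(out) + 1]] <- data.frame(subject = nm, strand = "+",
                                             start = s)
      }
      if (read_ok && oracle_hamming(rc, wins[s]) <= max_mm) {
        out[[length(out) + 1]] <- data.frame(subject = nm, strand = "-",
                                             start = s)
      }
    }
  }
  if (!length(out)) {
    return(data.frame(subject = character(0), strand = character(0),
                      start = integer(0)))
  }
  do.call(rbind, out)
}

oracle_placement_count <- function(read, subjects, max_mm) {
  nrow(oracle_placements_one(read, subjects, max_mm))
}

# naive per-position canonical k-mer profile against plain dictionaries
oracle_profile <- function(scaffold, a_seqs, b_seqs, k, repeat_threshold) {
  dict_of <- function(seqs) {
    kmers <- character(0)
    for (s in seqs) {
      for (p in seq_len(nchar(s) - k + 1)) {
        win <- substr(s, p, p + k - 1)
        if (grepl("[^ACGT]", win)) next
        rc <- oracle_rc(win)
        kmers <- c(kmers, if (rc < win) rc else win)
      }
    }
    table(kmers)
  }
  a_dict <- dict_of(a_seqs)
  b_dict <- dict_of(b_seqs)
  n <- nchar(scaffold) - k + 1
  a_count <- integer(n)
  b_cov <- logical(n)
  for (p in seq_len(n)) {
    win <- substr(scaffold, p, p + k - 1)
    if (grepl("[^ACGT]", win)) {
      a_count[p] <- NA
      b_cov[p] <- NA
      next
    }
    rc <- oracle_rc(win)
    can <- if (rc < win) rc else win
    a_count[p] <- if (can %in% names(a_dict)) a_dict[[can]] else 0L
    b_cov[p] <- can %in% names(b_dict)
  }
  data.frame(pos = seq_len(n) - 1L, a_count = a_count, b_covered = b_cov,
             repetitive = !is.na(a_count) & a_count >= repeat_threshold)
}

# exhaustive NG86 substitution counting for one codon pair by recursive
# enumeration over intermediate codons (not position permutations)
oracle_ng86_paths <- function(cd1, cd2) {
  stops <- c("TAA", "TAG", "TGA")
  code <- Biostrings::GENETIC_CODE
  recurse <- function(cur, target) {
    if (cur == target) {
      return(list(list(syn = 0, nonsyn = 0, blocked = FALSE)))
    }
    cc <- strsplit(cur, "")[[1]]
    tc <- strsplit(target, "")[[1]]
    res <- list()
    for (p in which(cc != tc)) {
      nxt <- cc
      nxt[p] <- tc[p]
      nxt_cd <- paste(nxt, collapse = "")
      step_block <- nxt_cd %in% stops && nxt_cd != target
      step_syn <- !(cur %in% stops) && !(nxt_cd %in% stops) &&
        code[[cur]] == code[[nxt_cd]]
      for (tailpath in recurse(nxt_cd, target)) {
        res[[length(res) + 1]] <- list(
          syn = tailpath$syn + as.numeric(step_syn),
          nonsyn = tailpath$nonsyn + as.numeric(!step_syn),
          blocked = tailpath$blocked || step_block
        )
      }
    }
    res
  }
  paths <- recurse(cd1, cd2)
  ok <- !vapply(paths, `[[`, logical(1), "blocked")
  use <- if (any(ok)) paths[ok] else paths
  c(syn = mean(vapply(use, `[[`, numeric(1), "syn")),
    nonsyn = mean(vapply(use, `[[`, numeric(1), "nonsyn")))
}

# brute-force single-linkage families: BFS over the identity graph
oracle_families <- function(ltr5, threshold) {
  n <- length(ltr5)
  adj <- matrix(FALSE, n, n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i < j) {
        adj[i, j] <- adj[j, i] <- align_identity(ltr5[i], ltr5[j]) >= threshold
      }
    }
  }
  comp <- rep(NA_integer_, n)
  cid <- 0
  for (s in seq_len(n)) {
    if (!is.na(comp[s])) next
    cid <- cid + 1
    queue <- s
    while (length(queue)) {
      v <- queue[1]
      queue <- queue[-1]
      if (!is.na(comp[v])) next
      comp[v] <- cid
      queue <- c(queue, which(adj[v, ] & is.na(comp)))
    }
  }
  comp
}

random_dna_str <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}
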