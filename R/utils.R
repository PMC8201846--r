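#' @importFrom rlang abort warn %||% .data
#' @importFrom dplyr mutate filter select arrange group_by summarise ungroup
#'   bind_rows bind_cols left_join n count distinct row_number desc pull
#'   rename across
#' @importFrom tibble tibble as_tibble
#' @importFrom stats median quantile rbinom rnorm rpois runif rexp setNames
#' @importFrom utils head tail
NULL

DNA_BASES <- c("A", "C", "G", "T")

#' Random DNA string
#'
#' Uniform i.i.d. sequence over A/C/G/T. Uses the current RNG state; wrap in
#' [withr::with_seed()] for reproducibility.
#'
#' @param n Length in bp.
#' @return A single character string.
#' @keywords internal
random_dna <- function(n) {
  paste(sample(DNA_BASES, n, replace = TRUE), collapse = "")
}

#' Reverse complement of character sequences
#'
#' @param x Character vector of DNA strings.
#' @return Character vector of reverse complements.
#' @export
revcomp <- function(x) {
  if (length(x) == 0) return(character(0))
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

# Substitute `n_sub` randomly chosen positions of `seq` with a different base.
# Positions are sampled without replacement; every substitution changes the base.
mutate_seq <- function(seq, n_sub) {
  len <- nchar(seq)
  n_sub <- min(n_sub, len)
  if (n_sub == 0) return(seq)
  pos <- sample.int(len, n_sub)
  chars <- strsplit(seq, "", fixed = TRUE)[[1]]
  for (p in pos) {
    chars[p] <- sample(setdiff(DNA_BASES, chars[p]), 1)
  }
  paste(chars, collapse = "")
}

# Poisson-distributed number of substitutions for a per-site rate.
mutate_seq_rate <- function(seq, per_site) {
  mutate_seq(seq, rpois(1, nchar(seq) * per_site))
}

#' Global alignment identity between two sequences
#'
#' Needleman-Wunsch global alignment (unit match/mismatch scores, affine gaps)
#' with identity defined as matches divided by alignment columns, in percent.
#'
#' @param a,b DNA strings.
#' @return Identity in `[0, 100]`.
#' @export
align_identity <- function(a, b) {
  aln <- Biostrings::pairwiseAlignment(
    Biostrings::DNAString(a), Biostrings::DNAString(b),
    type = "global",
    substitutionMatrix = Biostrings::nucleotideSubstitutionMatrix(
      match = 1, mismatch = -1
    ),
    gapOpening = 4, gapExtension = 1
  )
  p <- as.character(Biostrings::alignedPattern(aln))
  s <- as.character(Biostrings::alignedSubject(aln))
  cols <- nchar(p)
  matches <- sum(strsplit(p, "")[[1]] == strsplit(s, "")[[1]])
  100 * matches / cols
}

# stopifnot with a readable message
check_that <- function(cond, msg) {
  if (!isTRUE(cond)) abort(msg)
}

# Split a total length into `n` parts each >= min_len, at uniformly random
# internal cut points. Errors if infeasible.
random_partition <- function(total, n, min_len) {
  check_that(n * min_len <= total, "partition infeasible: n * min_len exceeds total")
  slack <- total - n * min_len
  if (n == 1) return(total)
  cuts <- sort(sample.int(slack + 1, n - 1, replace = TRUE) - 1)
  parts <- diff(c(0, cuts, slack)) + min_len
  parts
}
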