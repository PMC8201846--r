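#' Read and write FASTA
#'
#' Thin wrappers around [Biostrings::readDNAStringSet()] /
#' [Biostrings::writeXStringSet()] returning/accepting a tibble with columns
#' `name` and `seq`, so sequence sets flow through the same tabular interface
#' as everything else.
#'
#' @param path File path.
#' @param x Tibble with columns `name`, `seq` (or a named character vector /
#'   `DNAStringSet`).
#' @return `read_fasta()` returns a tibble with columns `name`, `seq`.
#' @export
read_fasta <- function(path) {
  ss <- Biostrings::readDNAStringSet(path)
  tibble(name = names(ss), seq = unname(as.character(ss)))
}

#' @rdname read_fasta
#' @export
write_fasta <- function(x, path) {
  ss <- as_dss(x)
  Biostrings::writeXStringSet(ss, path)
  invisible(path)
}

# coerce tibble(name, seq) / named character / DNAStringSet to DNAStringSet
as_dss <- function(x) {
  if (methods::is(x, "DNAStringSet")) return(x)
  if (is.data.frame(x)) {
    ss <- Biostrings::DNAStringSet(x$seq)
    nm_col <- intersect(c("name", "read_id", "scaffold"), names(x))[1]
    names(ss) <- if (!is.na(nm_col)) x[[nm_col]] else
      paste0("seq", seq_along(ss))
    return(ss)
  }
  ss <- Biostrings::DNAStringSet(x)
  if (is.null(names(ss))) names(ss) <- paste0("seq", seq_along(ss))
  ss
}

#' Read and write FASTQ
#'
#' Reads are tibbles with columns `read_id` and `seq`. Qualities are constant
#' Phred-33 'I' on write (the simulator does not model base quality) and are
#' dropped on read.
#'
#' @param path File path.
#' @param reads Tibble with columns `read_id`, `seq`.
#' @return `read_fastq()` returns a tibble with columns `read_id`, `seq`.
#' @export
read_fastq <- function(path) {
  ss <- Biostrings::readDNAStringSet(path, format = "fastq")
  tibble(read_id = names(ss), seq = unname(as.character(ss)))
}

#' @rdname read_fastq
#' @export
write_fastq <- function(reads, path) {
  ss <- Biostrings::DNAStringSet(reads$seq)
  names(ss) <- reads$read_id
  qual <- Biostrings::BStringSet(strrep("I", nchar(reads$seq)))
  Biostrings::writeXStringSet(ss, path, format = "fastq", qualities = qual)
  invisible(path)
}

#' Read and write BED intervals
#'
#' BED3+ as tab-separated text with 0-based half-open coordinates, matching the
#' coordinate convention used throughout the package. Columns beyond the first
#' three are written in the order given; `name`, `score`, `strand` are used for
#' columns 4-6 when present.
#'
#' @param path File path.
#' @param x Tibble with columns `chrom`, `start`, `end` and optionally `name`,
#'   `score`, `strand`.
#' @return `read_bed()` returns a tibble.
#' @export
read_bed <- function(path) {
  x <- readr::read_tsv(path, col_names = FALSE, show_col_types = FALSE,
                       progress = FALSE, comment = "#")
  nm <- c("chrom", "start", "end", "name", "score", "strand")
  names(x) <- nm[seq_len(min(ncol(x), 6))]
  x$start <- as.integer(x$start)
  x$end <- as.integer(x$end)
  as_tibble(x)
}

#' @rdname read_bed
#' @export
write_bed <- function(x, path) {
  cols <- intersect(c("chrom", "start", "end", "name", "score", "strand"),
                    names(x))
  readr::write_tsv(x[, cols], path, col_names = FALSE, progress = FALSE)
  invisible(path)
}

#' Write and read AGP 2.1
#'
#' Serialises a scaffold layout as an AGP 2.1 component table: `W` lines for
#' scaffolds (1-based inclusive object/component coordinates, orientation in
#' column 9) and `N` lines for gaps of known length (`scaffold`/`yes`/`map`
#' linkage evidence). `read_agp()` parses such a file back into the same
#' tibble, so the two are mutually inverse.
#'
#' @param agp Tibble as produced by [orient_and_build()] (`$agp`).
#' @param path File path.
#' @return `read_agp()` returns the AGP tibble.
#' @export
write_agp <- function(agp, path) {
  lines <- c("##agp-version\t2.1",
             vapply(seq_len(nrow(agp)), function(i) {
               paste(unlist(lapply(agp[i, ], as.character)), collapse = "\t")
             }, character(1)))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_agp
#' @export
read_agp <- function(path) {
  x <- readr::read_tsv(path, col_names = FALSE, comment = "#",
                       show_col_types = FALSE, progress = FALSE,
                       col_types = readr::cols(.default = readr::col_character()))
  names(x) <- c("object", "object_beg", "object_end", "part_number",
                "component_type", "col6", "col7", "col8", "col9")
  x |>
    mutate(across(c("object_beg", "object_end", "part_number"), as.integer)) |>
    as_tibble()
}

#' Write and read a presence matrix as TSV
#'
#' Long-format table (`scaffold`, `line`, `covered_fraction`, `call`); the
#' reader restores the `presence_matrix` class.
#'
#' @param pm A `presence_matrix` (see [call_presence()]).
#' @param path File path.
#' @return `read_presence_matrix()` returns a `presence_matrix` tibble.
#' @export
write_presence_matrix <- function(pm, path) {
  readr::write_tsv(as_tibble(pm), path, progress = FALSE)
  invisible(path)
}

#' @rdname write_presence_matrix
#' @export
read_presence_matrix <- function(path) {
  x <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  new_presence_matrix(as_tibble(x))
}

#' Write and read a line-panel specification as TSV
#'
#' One row per line with retained B intervals encoded as
#' `start-end` pairs separated by `;`, A-segment dosages as
#' `segment=copies` pairs separated by `;`, and the B copy number.
#'
#' @param panel A `line_panel` tibble (see [make_line_panel()]).
#' @param path File path.
#' @return `read_line_panel()` returns a `line_panel` tibble.
#' @export
write_line_panel <- function(panel, path) {
  enc <- tibble(
    line = panel$line,
    type = panel$type,
    b_copies = panel$b_copies,
    intervals = vapply(panel$retained, function(iv) {
      if (nrow(iv) == 0) return("")
      paste(sprintf("%d-%d", iv$start, iv$end), collapse = ";")
    }, character(1)),
    a_dosage = vapply(panel$a_dosage, function(d) {
      paste(sprintf("%s=%d", names(d), unname(d)), collapse = ";")
    }, character(1))
  )
  readr::write_tsv(enc, path, progress = FALSE)
  invisible(path)
}

#' @rdname write_line_panel
#' @export
read_line_panel <- function(path) {
  x <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  retained <- lapply(x$intervals, function(s) {
    if (is.na(s) || s == "") {
      return(tibble(start = integer(0), end = integer(0)))
    }
    parts <- strsplit(strsplit(s, ";", fixed = TRUE)[[1]], "-", fixed = TRUE)
    tibble(start = as.integer(vapply(parts, `[`, "", 1)),
           end = as.integer(vapply(parts, `[`, "", 2)))
  })
  a_dosage <- lapply(x$a_dosage, function(s) {
    kv <- strsplit(strsplit(s, ";", fixed = TRUE)[[1]], "=", fixed = TRUE)
    setNames(as.integer(vapply(kv, `[`, "", 2)), vapply(kv, `[`, "", 1))
  })
  out <- tibble(line = x$line, type = x$type,
                b_copies = as.integer(x$b_copies),
                retained = retained, a_dosage = a_dosage)
  class(out) <- c("line_panel", class(out))
  out
}
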