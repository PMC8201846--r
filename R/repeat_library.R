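#' Generate a synthetic repeat library
#'
#' Builds the monomer consensi and LTR retrotransposon templates that the
#' synthetic genome is assembled from. The library emulates the repeat classes
#' of a maize-like B chromosome: a B-specific tandem repeat concentrated in and
#' around the centromere, a 180-bp heterochromatic knob repeat shared with the
#' A chromosomes, a centromeric satellite, and a telomeric filler monomer. The
#' B-specific monomer is derived from the knob monomer by substitution so the
#' two are related on the sequence level but share less than 80% global
#' identity, which makes their discrimination non-trivial by construction.
#'
#' @param seed Integer seed; the library is deterministic for a fixed seed.
#' @param monomer_lengths Named integer vector of monomer lengths (bp) with
#'   names `b_specific`, `knob`, `centromeric_satellite`, `telomeric`.
#'   All lengths must be at least 20.
#' @param n_te_templates Number of LTR retrotransposon templates.
#' @param ltr_len LTR template length (bp, at least 100).
#' @param internal_len Internal-domain template length (bp).
#' @return A `repeat_library` list with elements `monomers` (named character
#'   vector) and `te_templates` (tibble: `family`, `ltr`, `internal`).
#' @examples
#' lib <- make_repeat_library(seed = 1)
#' nchar(lib$monomers[["knob"]])
#' @export
make_repeat_library <- function(seed = 1,
                                monomer_lengths = c(
                                  b_specific = 150, knob = 180,
                                  centromeric_satellite = 156, telomeric = 120
                                ),
                                n_te_templates = 4,
                                ltr_len = 300,
                                internal_len = 1500) {
  needed <- c("b_specific", "knob", "centromeric_satellite", "telomeric")
  check_that(all(needed %in% names(monomer_lengths)),
             "monomer_lengths must name b_specific, knob, centromeric_satellite, telomeric")
  check_that(all(monomer_lengths >= 20), "all monomer lengths must be >= 20")
  check_that(ltr_len >= 100, "ltr_len must be >= 100")
  withr::with_seed(seed, {
    knob <- random_dna(monomer_lengths[["knob"]])
    b_specific <- derive_related_monomer(knob, monomer_lengths[["b_specific"]])
    monomers <- c(
      b_specific = b_specific,
      knob = knob,
      centromeric_satellite = random_dna(monomer_lengths[["centromeric_satellite"]]),
      telomeric = random_dna(monomer_lengths[["telomeric"]])
    )
    te_templates <- tibble(
      family = sprintf("fam%02d", seq_len(n_te_templates)),
      ltr = vapply(seq_len(n_te_templates), function(i) random_dna(ltr_len),
                   character(1)),
      internal = vapply(seq_len(n_te_templates), function(i) random_dna(internal_len),
                        character(1))
    )
    structure(list(monomers = monomers, te_templates = te_templates,
                   ltr_len = ltr_len, seed = seed),
              class = "repeat_library")
  })
}

# b_specific = knob mutated then resized; the substitution load is scanned
# until the global identity lands in [50, 80), so the pair is related but
# separable whatever the requested length ratio.
derive_related_monomer <- function(knob, len, lo = 50, hi = 80) {
  for (frac in seq(0.30, 0.02, by = -0.02)) {
    for (attempt in 1:5) {
      x <- mutate_seq(knob, round(frac * nchar(knob)))
      if (nchar(x) > len) x <- substr(x, 1, len)
      if (nchar(x) < len) x <- paste0(x, random_dna(len - nchar(x)))
      id <- align_identity(x, knob)
      if (id >= lo && id < hi) return(x)
    }
  }
  abort("could not derive a related monomer within the identity band")
}

#' @export
print.repeat_library <- function(x, ...) {
  cat("<repeat_library>\n")
  cat("  monomers:",
      paste(sprintf("%s (%d bp)", names(x$monomers), nchar(x$monomers)),
            collapse = ", "), "\n")
  cat("  TE templates:", nrow(x$te_templates),
      sprintf("(LTR %d bp)", x$ltr_len), "\n")
  invisible(x)
}
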