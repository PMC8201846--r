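#' Simulate nucleosome-midpoint read pairs on a tandem repeat array
#'
#' Generates paired-end reads from a tandem array of `array_copies` monomer
#' copies. ChIP fragments are centred on planted nucleosome dyads (monomer
#' offsets, optionally weighted, with Gaussian positional jitter); input
#' fragments are uniform over the array, with fragment phase uniform modulo
#' the monomer length. Mates are oriented toward each other, as required by
#' [merge_read_pairs()]. True fragment midpoints (as monomer offsets) are
#' retained for recovery testing.
#'
#' @param monomer Monomer consensus sequence.
#' @param array_copies Number of monomer copies in the sampled array core.
#' @param dyad_positions Integer monomer offsets of the planted dyads
#'   (each `< nchar(monomer)`).
#' @param dyad_weights Relative weights (e.g. `c(2, 2, 1, 1, 1)` for two
#'   major and three minor positions); defaults to equal weights.
#' @param n_pairs Number of read pairs per set (> 0).
#' @param fragment_len Nucleosomal fragment length (bp, default 147).
#' @param read_len Read length (bp); must satisfy
#'   `2 * read_len - fragment_len >= 10` so that mates overlap mergeably.
#' @param sigma Gaussian jitter (bp) of ChIP fragment centres around the dyad.
#' @param seed Integer seed.
#' @return A list with tibbles `chip` and `input` (`pair_id`, `read1`,
#'   `read2`, `true_midpoint_offset`) plus the simulation parameters.
#' @export
simulate_midpoint_reads <- function(monomer, array_copies = 20,
                                    dyad_positions, dyad_weights = NULL,
                                    n_pairs = 10000, fragment_len = 147,
                                    read_len = 100, sigma = 5, seed = 1) {
  L <- nchar(monomer)
  check_that(all(dyad_positions >= 0 & dyad_positions < L),
             "dyad offsets must lie in [0, monomer length)")
  check_that(n_pairs > 0, "n_pairs must be > 0")
  check_that(2 * read_len - fragment_len >= 10,
             "mates must overlap by at least 10 bp for merging")
  dyad_weights <- dyad_weights %||% rep(1, length(dyad_positions))
  check_that(length(dyad_weights) == length(dyad_positions),
             "dyad_weights must match dyad_positions")
  # one padding copy each side so fragments never run off the template
  template <- strrep(monomer, array_copies + 2)
  pad <- L
  withr::with_seed(seed, {
    # ChIP: fragment centres on dyads, jittered
    di <- sample.int(length(dyad_positions), n_pairs, replace = TRUE,
                     prob = dyad_weights)
    copy <- sample.int(array_copies, n_pairs, replace = TRUE) - 1
    centre <- pad + copy * L + dyad_positions[di] +
      round(rnorm(n_pairs, 0, sigma))
    chip <- pairs_from_centres(template, centre, fragment_len, read_len, L,
                               "chip")
    # input: fragment start uniform over the array core -> midpoint phase
    # uniform modulo L
    start <- pad + floor(runif(n_pairs) * (array_copies * L))
    centre_i <- start + floor(fragment_len / 2)
    input <- pairs_from_centres(template, centre_i, fragment_len, read_len, L,
                                "input")
    list(chip = chip, input = input,
         params = list(monomer = monomer, L = L, array_copies = array_copies,
                       dyad_positions = dyad_positions,
                       dyad_weights = dyad_weights,
                       fragment_len = fragment_len, read_len = read_len,
                       sigma = sigma, seed = seed))
  })
}

pairs_from_centres <- function(template, centre, fragment_len, read_len, L,
                               prefix) {
  start <- centre - floor(fragment_len / 2)  # 0-based fragment start
  end <- start + fragment_len                # exclusive
  read1 <- substring(template, start + 1, start + read_len)
  read2 <- revcomp(substring(template, end - read_len + 1, end))
  tibble(
    pair_id = sprintf("%s_%06d", prefix, seq_along(centre)),
    read1 = read1, read2 = read2,
    true_midpoint_offset = as.integer((start + floor(fragment_len / 2)) %% L)
  )
}
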