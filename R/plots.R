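#' @importFrom ggplot2 autoplot ggplot aes geom_tile geom_line geom_col
#'   geom_point geom_hline facet_wrap labs scale_fill_manual theme_minimal
#' @export
ggplot2::autoplot

#' Plot a presence matrix
#'
#' Tile map of presence calls (scaffolds by lines), the visual analog of the
#' per-line coverage panels used to read off scaffold presence.
#'
#' @param object A `presence_matrix`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.presence_matrix <- function(object, ...) {
  t <- as_tibble(unclass_tbl(object))
  ggplot(t, aes(x = .data$line, y = .data$scaffold, fill = .data$call)) +
    geom_tile(colour = "grey30") +
    scale_fill_manual(values = c(present = "#1b7837", partial = "#fdb863",
                                 absent = "grey90",
                                 uninformative = "grey60")) +
    labs(x = "line", y = "scaffold", fill = "call") +
    theme_minimal()
}

#' Plot a nucleosome midpoint profile
#'
#' ChIP and (when present) input midpoint densities along the repeat monomer,
#' in counts per million mapped merged reads.
#'
#' @param object A `midpoint_profile`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.midpoint_profile <- function(object, ...) {
  t <- as_tibble(unclass_tbl(object))
  long <- t |>
    select("offset", dplyr::any_of(c("chip_cpm", "input_cpm"))) |>
    tidyr::pivot_longer(-"offset", names_to = "track", values_to = "cpm") |>
    mutate(track = sub("_cpm$", "", .data$track))
  ggplot(long, aes(x = .data$offset, y = .data$cpm, colour = .data$track)) +
    geom_line() +
    labs(x = "monomer offset (bp)", y = "midpoints per million reads",
         colour = NULL) +
    theme_minimal()
}

#' Plot a dosage profile
#'
#' Per-region normalised ratios against the haploid control, grouped by
#' segment, with the neutral (1x), gain (2x) and loss (0.5x) levels marked.
#'
#' @param object A `dosage_profile`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.dosage_profile <- function(object, ...) {
  ggplot(object$regions,
         aes(x = .data$segment, y = .data$ratio, colour = .data$library)) +
    geom_hline(yintercept = c(0.5, 1, 2), linetype = "dashed",
               colour = "grey60") +
    geom_point(position = ggplot2::position_jitter(width = 0.15),
               alpha = 0.6) +
    labs(x = "A segment", y = "normalised ratio vs control") +
    theme_minimal()
}

#' Plot a selection comparison
#'
#' Scatter of per-gene Ka/Ks with the B-involving comparison on the x axis
#' and the A-outgroup comparison on the y axis; points below the diagonal
#' indicate elevated Ka/Ks when the B copy is involved (relaxed purifying
#' selection).
#'
#' @param object A `selection_comparison`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.selection_comparison <- function(object, ...) {
  ggplot(object$ratios, aes(x = .data$kaks_b_a, y = .data$kaks_a_out)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed",
                         colour = "grey60") +
    geom_point(alpha = 0.6) +
    labs(x = "Ka/Ks (B vs A)", y = "Ka/Ks (A vs outgroup)") +
    theme_minimal()
}
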