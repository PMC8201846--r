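#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' Tidy a presence matrix
#'
#' @param x A `presence_matrix`.
#' @param ... Unused.
#' @return Long tibble: `scaffold`, `line`, `covered_fraction`, `call`.
#' @export
tidy.presence_matrix <- function(x, ...) {
  as_tibble(unclass_tbl(x))
}

#' @rdname tidy.presence_matrix
#' @export
glance.presence_matrix <- function(x, ...) {
  t <- as_tibble(unclass_tbl(x))
  tibble(n_scaffolds = dplyr::n_distinct(t$scaffold),
         n_lines = dplyr::n_distinct(t$line),
         n_partial = sum(t$call == "partial"),
         n_uninformative = sum(t$call == "uninformative"))
}

#' Tidy a scaffold layout
#'
#' @param x A `pseudo_layout`.
#' @param ... Unused.
#' @return The per-scaffold bin tibble.
#' @export
tidy.pseudo_layout <- function(x, ...) x$bins

#' @rdname tidy.pseudo_layout
#' @export
glance.pseudo_layout <- function(x, ...) {
  tibble(n_scaffolds = nrow(x$bins),
         n_bins = dplyr::n_distinct(x$bins$bin),
         n_unresolved = sum(x$bins$unresolved),
         n_conflict_cells = nrow(x$conflicts),
         n_unplaced = nrow(x$unplaced))
}

#' Tidy a dosage profile
#'
#' @param x A `dosage_profile`.
#' @param ... Unused.
#' @return The per-segment ratio tibble.
#' @export
tidy.dosage_profile <- function(x, ...) x$segments

#' @rdname tidy.dosage_profile
#' @export
glance.dosage_profile <- function(x, ...) {
  tibble(n_segments = dplyr::n_distinct(x$segments$segment),
         n_gain = sum(x$segments$class == "gain"),
         n_loss = sum(x$segments$class == "loss"),
         control = x$control)
}

#' Tidy a selection comparison
#'
#' @param x A `selection_comparison`.
#' @param ... Unused.
#' @return Per-triple Ka/Ks ratio tibble.
#' @export
tidy.selection_comparison <- function(x, ...) x$ratios

#' @rdname tidy.selection_comparison
#' @export
glance.selection_comparison <- function(x, ...) {
  tibble(median_b_a = x$medians[["b_a"]],
         median_b_out = x$medians[["b_out"]],
         median_a_out = x$medians[["a_out"]],
         wilcox_p = x$wilcox$p,
         n_triples = nrow(x$ratios),
         n_dropped = x$n_dropped)
}

unclass_tbl <- function(x) {
  class(x) <- setdiff(class(x), c("presence_matrix", "midpoint_profile"))
  x
}
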