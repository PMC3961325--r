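#' Convert a log10 expression ratio to a signed fold change
#'
#' Reporting convention for knockdown tables: a ratio `r >= 0` becomes the
#' fold change `10^r`, a negative ratio becomes `-10^(-r)`, so a log10 ratio
#' of -1.4 is printed as a -25.1-fold change. Odd symmetry holds:
#' `signed_fold_change(-r) == -signed_fold_change(r)`.
#'
#' @param log10_ratio Finite numeric vector of log10 expression ratios.
#' @return Signed fold changes, same length.
#' @export
signed_fold_change <- function(log10_ratio) {
  stopifnot(all(is.finite(log10_ratio)))
  ifelse(log10_ratio >= 0, 10^log10_ratio, -10^(-log10_ratio))
}

#' Call direct targets by combinatorial binding and knockdown criteria
#'
#' A gene is called a direct target when it is bound (a peak center within
#' the linking window of its TSS, as determined by [link_peaks_to_genes()])
#' *and* down-regulated in both knockdown channels with `p < p_threshold` and
#' log10 ratio `< lr_threshold` (strict inequalities throughout). Genes with
#' several expression records keep the record with the smallest
#' `max(p1, p2)`; genes lacking expression data are never called.
#'
#' @param expression Expression tibble (see [read_expression_table()]).
#' @param bound_genes Output of [link_peaks_to_genes()], or a character
#'   vector of bound gene symbols.
#' @param p_threshold P-value cutoff for both channels (default 0.01).
#' @param lr_threshold Log10-ratio cutoff for both channels (default -0.2;
#'   must be negative).
#' @return A tibble with one row per expression gene, sorted by
#'   `min(p1, p2)`: `symbol`, `bound`, `n_peaks`, `lr1`, `lr2`, `p1`, `p2`,
#'   signed fold changes `fc1`, `fc2`, and the `pass` flag. The signature is
#'   `symbol[pass]`.
#' @export
call_targets <- function(expression, bound_genes,
                         p_threshold = 0.01, lr_threshold = -0.2) {
  stopifnot(p_threshold > 0, p_threshold < 1, lr_threshold < 0)
  validate_expression(expression)
  if (is.character(bound_genes)) {
    bound_genes <- tibble(symbol = unique(bound_genes),
                          n_peaks = NA_integer_)
  }
  expr <- expression |>
    mutate(.pmax = pmax(.data$p1, .data$p2)) |>
    group_by(.data$symbol) |>
    slice_min(.data$.pmax, n = 1, with_ties = FALSE) |>
    ungroup() |>
    select(-".pmax")
  calls <- expr |>
    left_join(select(bound_genes, "symbol", "n_peaks"), by = "symbol") |>
    mutate(
      bound = .data$symbol %in% bound_genes$symbol,
      fc1 = signed_fold_change(.data$lr1),
      fc2 = signed_fold_change(.data$lr2),
      pass = .data$bound &
        .data$p1 < p_threshold & .data$p2 < p_threshold &
        .data$lr1 < lr_threshold & .data$lr2 < lr_threshold) |>
    arrange(pmin(.data$p1, .data$p2), .data$symbol) |>
    select("symbol", "bound", "n_peaks", "lr1", "lr2", "p1", "p2",
           "fc1", "fc2", "pass")
  calls
}

#' Summarise the direct-target signature for reporting
#'
#' @param calls Output of [call_targets()].
#' @return A tibble restricted to passing genes with columns `symbol`, `fc1`,
#'   `fc2`, `p1`, `p2`, `n_peaks` (empty, with header, when nothing passes).
#' @export
summarize_signature <- function(calls) {
  calls |>
    filter(.data$pass) |>
    select("symbol", "fc1", "fc2", "p1", "p2", "n_peaks")
}
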