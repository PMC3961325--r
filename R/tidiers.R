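#' Tidy the running sum of a KS/GSEA enrichment
#' @param x A `ks_enrichment` object.
#' @param ... Unused.
#' @return The per-rank running-sum tibble.
#' @method tidy ks_enrichment
#' @export
tidy.ks_enrichment <- function(x, ...) x$running

#' One-row summary of a KS/GSEA enrichment
#' @param x A `ks_enrichment` object.
#' @param ... Unused.
#' @return A one-row tibble with `es`, `es_position`, `n_hits`, `n_genes`,
#'   `weight`, and (after [ks_permutation_test()]) `p_value`, `nes`, `n_perm`.
#' @method glance ks_enrichment
#' @export
glance.ks_enrichment <- function(x, ...) {
  out <- tibble(es = x$es, es_position = x$es_position, n_hits = x$n_hits,
                n_genes = x$n_genes, weight = x$weight)
  if (!is.null(x$p_value)) {
    out$p_value <- x$p_value
    out$nes <- x$nes
    out$n_perm <- x$n_perm
    out$p_is_upper_bound <- x$p_is_upper_bound
  }
  out
}

#' Intersection symbols of a gene-set overlap
#' @param x An `overlap_result` object.
#' @param ... Unused.
#' @return A tibble with one row per shared symbol.
#' @method tidy overlap_result
#' @export
tidy.overlap_result <- function(x, ...) tibble(symbol = x$intersection)

#' One-row summary of a gene-set overlap
#' @param x An `overlap_result` object.
#' @param ... Unused.
#' @return A one-row tibble with the overlap counts, expected overlap,
#'   representation factor and hypergeometric p-value.
#' @method glance overlap_result
#' @export
glance.overlap_result <- function(x, ...) {
  tibble(n_a = x$n_a, n_b = x$n_b, k = x$k, N = x$N, expected = x$expected,
         representation_factor = x$representation_factor, p_value = x$p_value)
}

#' Per-group observed/expected events of a log-rank test
#' @param x A `logrank_result` object.
#' @param ... Unused.
#' @return The per-group tibble.
#' @method tidy logrank_result
#' @export
tidy.logrank_result <- function(x, ...) x$groups

#' One-row summary of a log-rank test
#' @param x A `logrank_result` object.
#' @param ... Unused.
#' @return A one-row tibble with `chisq`, `df`, `p_value`.
#' @method glance logrank_result
#' @export
glance.logrank_result <- function(x, ...) {
  tibble(chisq = x$chisq, df = x$df, p_value = x$p_value)
}

#' Per-group Kaplan-Meier curves of a stratified survival analysis
#' @param x A `stratified_survival` object.
#' @param ... Unused.
#' @return The long-format KM tibble (one row per group x time).
#' @method tidy stratified_survival
#' @export
tidy.stratified_survival <- function(x, ...) x$km

#' One-row summary of a stratified survival analysis
#' @param x A `stratified_survival` object.
#' @param ... Unused.
#' @return A one-row tibble with group sizes and the log-rank test.
#' @method glance stratified_survival
#' @export
glance.stratified_survival <- function(x, ...) {
  sizes <- table(x$scores$group)
  tibble(n = nrow(x$scores), n_low = as.integer(sizes[["low"]]),
         n_high = as.integer(sizes[["high"]]),
         chisq = x$test$chisq, p_value = x$test$p_value)
}

#' Histogram of a TSS-distance profile
#' @param x A `tss_profile` object.
#' @param ... Unused.
#' @return The histogram tibble (`mid`, `count`, optionally `null_mean`).
#' @method tidy tss_profile
#' @export
tidy.tss_profile <- function(x, ...) x$histogram
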