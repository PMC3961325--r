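#' Representation factor of a gene-set overlap
#'
#' The representation factor is the observed overlap divided by the overlap
#' expected by chance under a fixed gene universe: `RF = k / (nA * nB / N)`,
#' i.e. `k * N / (nA * nB)`. Values above 1 indicate more overlap than
#' expected between independent sets.
#'
#' @param k Observed overlap size.
#' @param nA,nB Sizes of the two sets.
#' @param N Universe size (total number of genes considered).
#' @return The representation factor (numeric scalar).
#' @export
representation_factor <- function(k, nA, nB, N) {
  stopifnot(k >= 0, k <= min(nA, nB), N >= max(nA, nB))
  if (nA * nB == 0) abort("representation factor undefined for empty sets")
  (k * N) / (nA * nB)
}

#' Exact hypergeometric upper-tail overlap probability
#'
#' The probability of observing `k` or more shared genes between a set of
#' size `nA` and a set of size `nB` drawn without replacement from a
#' universe of `N` genes: `P(X >= k)` with
#' `X ~ Hypergeometric(N, nB, nA)`. Computed in log space (via the
#' lgamma-based tail in [stats::phyper()]), so universes of 10^4-10^5 genes
#' are handled without underflow. Symmetric in `nA` and `nB`. The tail is
#' inclusive, matching the usual over-representation convention.
#'
#' @inheritParams representation_factor
#' @return The upper-tail probability in (0, 1].
#' @export
hypergeom_upper_tail <- function(k, nA, nB, N) {
  stopifnot(k >= 0, k <= min(nA, nB), N >= max(nA, nB))
  if (nA + nB > N + k) abort("infeasible counts: nA + nB must be <= N + k")
  phyper(k - 1, nB, N - nB, nA, lower.tail = FALSE)
}

#' Overlap statistics for two gene sets
#'
#' Computes the intersection of two symbol sets, the representation factor,
#' and the exact hypergeometric upper-tail p-value under a universe of `N`
#' genes (default 20000, the conventional size of the protein-coding human
#' gene universe).
#'
#' @param set_a,set_b Character vectors of gene symbols (deduplicated
#'   case-sensitively after trimming).
#' @param N Universe size; must be at least `|A union B|`.
#' @return An object of class `overlap_result`: a list with `n_a`, `n_b`,
#'   `k`, `N`, `expected`, `representation_factor`, `p_value`, and the
#'   sorted `intersection`.
#' @export
overlap_report <- function(set_a, set_b, N = 20000) {
  set_a <- unique(trimws(set_a)); set_b <- unique(trimws(set_b))
  if (N < length(union(set_a, set_b))) abort("universe smaller than the union of the sets")
  k <- length(intersect(set_a, set_b))
  structure(list(
    n_a = length(set_a), n_b = length(set_b), k = k, N = N,
    expected = length(set_a) * length(set_b) / N,
    representation_factor = representation_factor(k, length(set_a), length(set_b), N),
    p_value = hypergeom_upper_tail(k, length(set_a), length(set_b), N),
    intersection = sort(intersect(set_a, set_b))),
    class = "overlap_result")
}

#' @export
print.overlap_result <- function(x, ...) {
  cat(sprintf("Gene-set overlap: %d of %d x %d (universe %d)\n", x$k, x$n_a, x$n_b, x$N))
  cat(sprintf("  expected %.3f, representation factor %.3f, p = %.4g\n",
              x$expected, x$representation_factor, x$p_value))
  invisible(x)
}
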