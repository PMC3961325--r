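#' Rank an expression table for enrichment analysis
#'
#' Orders genes for the running-sum enrichment analysis of one knockdown
#' channel. With `key = "p_value"` the list puts down-regulated genes first,
#' sorted by ascending p-value (most significantly down at the top), followed
#' by the remaining genes sorted by descending p-value (most significantly
#' up at the bottom); the reported metric is the p-value. With
#' `key = "fold_change"` genes are sorted by ascending log10 ratio (most
#' down-regulated first) and the metric is the log ratio. Ties break by
#' symbol, so rankings are stable across runs.
#'
#' @param expression Expression tibble (see [read_expression_table()]).
#' @param key `"p_value"` or `"fold_change"`.
#' @param channel Knockdown channel, `1` or `2` (selects `lr1`/`p1` or
#'   `lr2`/`p2`).
#' @param descending Reverse the ranking direction; `rank_by(...,
#'   descending = TRUE)` is exactly the reverse of the default order.
#' @return A tibble with columns `symbol`, `metric`, `lr`, `p`, in rank
#'   order, carrying attributes `key` and `descending`.
#' @export
rank_by <- function(expression, key = c("p_value", "fold_change"),
                    channel = 1L, descending = FALSE) {
  key <- match.arg(key)
  stopifnot(channel %in% c(1L, 2L))
  lr <- if (channel == 1L) expression$lr1 else expression$lr2
  p <- if (channel == 1L) expression$p1 else expression$p2
  tab <- tibble(symbol = expression$symbol, lr = lr, p = p)
  if (anyDuplicated(tab$symbol)) abort("expression symbols must be unique for ranking")
  ord <- if (key == "p_value") {
    down <- tab$lr < 0
    order(!down, ifelse(down, tab$p, -tab$p), tab$symbol)
  } else {
    order(tab$lr, tab$symbol)
  }
  if (descending) ord <- rev(ord)
  out <- tab[ord, ]
  out$metric <- if (key == "p_value") out$p else out$lr
  out <- select(out, "symbol", "metric", "lr", "p")
  attr(out, "key") <- key
  attr(out, "descending") <- descending
  out
}

#' Running-sum (GSEA/KS) enrichment of a gene set in a ranked list
#'
#' Walks the ranked list accumulating a running sum: at each gene in the set
#' ("hit") it adds `|metric|^w / sum(|metric|^w over hits)` (for the classic
#' KS statistic `w = 0`, i.e. `1/n_hits`), and at each miss it subtracts
#' `1/(N - n_hits)`. The enrichment score ES is the running-sum value of
#' maximal absolute deviation from zero (first such position on ties). For
#' `w = 0` the sum returns to zero at the end of the list. Set members absent
#' from the ranked list are dropped with a warning.
#'
#' @param ranked A ranked list from [rank_by()], or any tibble with `symbol`
#'   and `metric` columns in rank order.
#' @param gene_set Character vector of gene symbols.
#' @param weight Weight exponent `w`: 0 (classic KS, default) or 1
#'   (metric-weighted GSEA).
#' @return An object of class `ks_enrichment`: a list with `es`, `es_position`,
#'   `n_hits`, `n_genes`, `weight`, and `running` (tibble `rank`, `symbol`,
#'   `hit`, `running_sum`).
#' @export
ks_enrichment <- function(ranked, gene_set, weight = 0) {
  stopifnot(weight %in% c(0, 1))
  if (is.character(ranked)) ranked <- tibble(symbol = ranked, metric = 1)
  symbols <- ranked$symbol
  N <- length(symbols)
  gene_set <- unique(gene_set)
  hit <- symbols %in% gene_set
  nh <- sum(hit)
  if (nh == 0L) abort("gene set does not intersect the ranked list")
  if (nh == N) abort("gene set covers the entire ranked list (no misses)")
  missing <- setdiff(gene_set, symbols)
  if (length(missing)) {
    warn(sprintf("%d gene(s) in the set are absent from the ranked list and were dropped",
                 length(missing)))
  }
  if (weight == 0) {
    inc <- rep(1 / nh, nh)
  } else {
    wts <- abs(ranked$metric[hit])^weight
    if (sum(wts) == 0) {
      warn("all hit metrics are zero; falling back to equal hit weights")
      wts <- rep(1, nh)
    }
    inc <- wts / sum(wts)
  }
  step <- numeric(N)
  step[hit] <- inc
  step[!hit] <- -1 / (N - nh)
  running <- cumsum(step)
  pos <- which.max(abs(running))
  structure(list(
    es = running[pos], es_position = pos, n_hits = nh, n_genes = N, weight = weight,
    running = tibble(rank = seq_len(N), symbol = symbols, hit = hit,
                     running_sum = running)),
    class = "ks_enrichment")
}

#' @export
print.ks_enrichment <- function(x, ...) {
  cat(sprintf("KS/GSEA enrichment: ES = %.4f at rank %d (%d hits / %d genes, w = %g)\n",
              x$es, x$es_position, x$n_hits, x$n_genes, x$weight))
  if (!is.null(x$p_value)) {
    cat(sprintf("  permutation p %s %.4g, NES = %.3f (%d permutations)\n",
                if (isTRUE(x$p_is_upper_bound)) "<" else "=", x$p_value,
                if (is.null(x$nes)) NA else x$nes, x$n_perm))
  }
  invisible(x)
}

#' Permutation p-value and NES for a running-sum enrichment
#'
#' Builds a null distribution of enrichment scores from random gene-label
#' sets of the same size drawn from the ranked list, then compares the
#' observed ES against null scores of the same sign:
#' `p = (1 + #\{|ES_null| >= |ES|, same sign\}) / (n_same_sign + 1)`. The
#' normalized enrichment score is `NES = ES / mean(|ES_null| of same sign)`.
#' When no null score shares the observed sign, `p` is reported as
#' `1/(n_perm + 1)` with `p_is_upper_bound` set and NES is `NA`.
#'
#' @inheritParams ks_enrichment
#' @param n_perm Number of label permutations (at least 100).
#' @return The [ks_enrichment()] object augmented with `p_value`, `nes`,
#'   `n_perm`, `p_is_upper_bound`, and the vector `null_es`.
#' @export
ks_permutation_test <- function(ranked, gene_set, weight = 0, n_perm = 1000L) {
  stopifnot(n_perm >= 100)
  obs <- ks_enrichment(ranked, gene_set, weight)
  symbols <- ranked$symbol
  null_es <- vapply(seq_len(n_perm), function(b) {
    ks_enrichment(ranked, sample(symbols, obs$n_hits), weight)$es
  }, 0)
  same <- null_es[sign(null_es) == sign(obs$es)]
  if (length(same) == 0L) {
    obs$p_value <- 1 / (n_perm + 1)
    obs$p_is_upper_bound <- TRUE
    obs$nes <- NA_real_
  } else {
    obs$p_value <- (1 + sum(abs(same) >= abs(obs$es))) / (length(same) + 1)
    obs$p_is_upper_bound <- FALSE
    obs$nes <- obs$es / mean(abs(same))
  }
  obs$n_perm <- n_perm
  obs$null_es <- null_es
  obs
}
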