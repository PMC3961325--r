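#' Randomly re-place peaks on the genome
#'
#' Builds a permutation-null peak set by moving every peak to a uniformly
#' random location on its own chromosome, preserving its length. The output
#' therefore has exactly the same multiset of (chromosome, length) pairs as
#' the input; only the start positions change, drawn uniformly on
#' `[0, chrom_length - length]`.
#'
#' @param peaks Peak tibble (see [read_bed()]).
#' @param genome Genome or index accepted by [genome_index()].
#' @return A peak tibble of the same size, names suffixed `_shuf`.
#' @export
shuffle_peaks <- function(peaks, genome) {
  gi <- genome_index(genome)
  len <- peaks$end - peaks$start
  chrom_len <- gi$length[match(peaks$chrom, gi$chrom)]
  if (anyNA(chrom_len)) abort("peak chromosome missing from genome index")
  if (any(len > chrom_len)) abort("peak longer than its chromosome; cannot shuffle")
  # uniform integer start on [0, chrom_len - len]
  start <- as.integer(floor(runif(nrow(peaks)) * (chrom_len - len + 1)))
  start <- pmin(start, chrom_len - len)  # guard the runif upper edge
  tibble(chrom = peaks$chrom, start = start, end = start + len,
         name = if (is.null(peaks$name)) NA_character_ else paste0(peaks$name, "_shuf"),
         score = NA_real_)
}

# Per-bp category lookup (one integer vector per chromosome, codes indexing
# c(feature_categories, "intergenic")). Built once, then classifying a peak
# center is a single subscript; permutation nulls over thousands of shuffles
# stay cheap. Agrees with classify_peaks() on category (asserted in tests);
# gene assignment is not represented here.
build_category_map <- function(genes, genome, config = annotation_config()) {
  gi <- genome_index(genome)
  feats <- feature_intervals(genes, config)
  maps <- lapply(seq_len(nrow(gi)), function(i) {
    L <- gi$length[i]
    m <- rep.int(7L, L)
    f <- feats[feats$chrom == gi$chrom[i], ]
    if (nrow(f)) {
      # fill lowest priority first so higher priority overwrites
      f <- f[order(-f$priority), ]
      for (j in seq_len(nrow(f))) {
        s <- max(f$start[j], 0L); e <- min(f$end[j], L)
        if (s < e) m[(s + 1L):e] <- f$priority[j]
      }
    }
    m
  })
  names(maps) <- gi$chrom
  maps
}

category_fraction <- function(chrom, centers, maps, category_code) {
  hit <- logical(length(centers))
  for (ch in unique(chrom)) {
    idx <- which(chrom == ch)
    m <- maps[[ch]]
    if (is.null(m)) next
    hit[idx] <- m[centers[idx] + 1L] == category_code
  }
  mean(hit)
}

#' Permutation test for feature-category enrichment of peaks
#'
#' Compares the observed fraction of peaks whose center falls in a genomic
#' feature category (e.g. promoter) against a null distribution obtained by
#' repeatedly re-placing length-matched peaks at random genomic locations
#' ([shuffle_peaks()]). The empirical p-value uses the add-one correction
#' `p = (1 + #\{null >= observed\}) / (B + 1)`, so with `B` permutations the
#' smallest attainable p is `1/(B+1)`; `no_exceedance` flags that case
#' (conventionally reported as `p < 1/(B+1)`).
#'
#' @inheritParams classify_peaks
#' @param genome Genome or index accepted by [genome_index()].
#' @param category One of `"promoter"`, `"utr5"`, `"exon"`, `"intron"`,
#'   `"utr3"`, `"downstream"`, `"intergenic"`.
#' @return A one-row tibble: `category`, `observed`, `null_mean`, `null_sd`,
#'   `p_value`, `n_permutations`, `no_exceedance`.
#' @export
permutation_enrichment <- function(peaks, genes, genome, category = "promoter",
                                   config = annotation_config()) {
  stopifnot(config$n_permutations >= 1)
  all_cats <- c(feature_categories, "intergenic")
  code <- match(match.arg(category, all_cats), all_cats)
  maps <- build_category_map(genes, genome, config)
  gi <- genome_index(genome)
  observed <- category_fraction(peaks$chrom, peak_centers(peaks), maps, code)
  B <- config$n_permutations
  null_frac <- vapply(seq_len(B), function(b) {
    sh <- shuffle_peaks(peaks, gi)
    category_fraction(sh$chrom, peak_centers(sh), maps, code)
  }, 0)
  exceed <- sum(null_frac >= observed)
  tibble(category = all_cats[code], observed = observed,
         null_mean = mean(null_frac), null_sd = sd(null_frac),
         p_value = (1 + exceed) / (B + 1),
         n_permutations = B, no_exceedance = exceed == 0L)
}
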