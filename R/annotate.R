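#' Annotation configuration
#'
#' Bundles the windows and permutation settings used across peak annotation:
#' a promoter is the `promoter_bp` region immediately upstream of the TSS, a
#' downstream region the `downstream_bp` region past the transcription
#' termination site, and a gene is called bound when a peak center lies within
#' `link_window_bp` of its TSS.
#'
#' @param promoter_bp Promoter width upstream of the TSS (bp). Default 2000.
#' @param downstream_bp Downstream width past the TTS (bp). Default 2000.
#' @param link_window_bp Peak-to-TSS linking window (bp). Default 20000.
#' @param n_permutations Number of random peak re-placements for permutation
#'   nulls. Default 1000.
#' @return A list with class `annotation_config`.
#' @export
annotation_config <- function(promoter_bp = 2000L, downstream_bp = 2000L,
                              link_window_bp = 20000L, n_permutations = 1000L) {
  stopifnot(promoter_bp > 0, downstream_bp > 0, link_window_bp > 0, n_permutations >= 1)
  structure(list(promoter_bp = as.integer(promoter_bp),
                 downstream_bp = as.integer(downstream_bp),
                 link_window_bp = as.integer(link_window_bp),
                 n_permutations = as.integer(n_permutations)),
            class = "annotation_config")
}

peak_centers <- function(peaks) as.integer(floor((peaks$start + peaks$end) / 2))

# Flatten gene models into prioritised feature intervals (0-based half-open).
# Category precedence (1 = highest): promoter > utr5 > exon > intron > utr3 >
# downstream. "exon" here means the CDS-overlapping exon portions (all exon
# blocks for non-coding transcripts), so the UTR categories are reachable.
feature_categories <- c("promoter", "utr5", "exon", "intron", "utr3", "downstream")

feature_intervals <- function(genes, config = annotation_config()) {
  rows <- vector("list", nrow(genes))
  for (i in seq_len(nrow(genes))) {
    g <- genes[i, ]
    es <- genes$exon_starts[[i]]; ee <- genes$exon_ends[[i]]
    plus <- g$strand == "+"
    coding <- g$cds_start < g$cds_end
    clip <- function(s, e, lo, hi) {
      s2 <- pmax(s, lo); e2 <- pmin(e, hi)
      keep <- s2 < e2
      list(start = s2[keep], end = e2[keep])
    }
    feats <- list()
    # promoter / downstream flank the transcript strand-aware
    feats$promoter <- if (plus) {
      list(start = max(0L, g$tx_start - config$promoter_bp), end = g$tx_start)
    } else {
      list(start = g$tx_end, end = g$tx_end + config$promoter_bp)
    }
    feats$downstream <- if (plus) {
      list(start = g$tx_end, end = g$tx_end + config$downstream_bp)
    } else {
      list(start = max(0L, g$tx_start - config$downstream_bp), end = g$tx_start)
    }
    if (coding) {
      utr_left <- clip(es, ee, g$tx_start, g$cds_start)   # 5' on +, 3' on -
      utr_right <- clip(es, ee, g$cds_end, g$tx_end)
      feats$utr5 <- if (plus) utr_left else utr_right
      feats$utr3 <- if (plus) utr_right else utr_left
      feats$exon <- clip(es, ee, g$cds_start, g$cds_end)
    } else {
      feats$exon <- list(start = es, end = ee)
    }
    # introns: transcript span minus exon blocks
    if (length(es) > 1L) {
      feats$intron <- list(start = ee[-length(ee)], end = es[-1L])
    }
    rows[[i]] <- bind_rows(lapply(names(feats), function(cat) {
      f <- feats[[cat]]
      if (length(f$start) == 0L) return(NULL)
      tibble(chrom = g$chrom, start = as.integer(f$start), end = as.integer(f$end),
             category = cat, symbol = g$symbol, tx_start = g$tx_start)
    }))
  }
  out <- bind_rows(rows)
  out$priority <- match(out$category, feature_categories)
  out
}

# Locate each position (0-based) in the prioritised feature table.
# Returns category + assigned gene; ties at equal priority break by
# (chrom, tx_start, symbol).
classify_positions <- function(chrom, pos, feats) {
  n <- length(pos)
  category <- rep("intergenic", n)
  symbol <- rep(NA_character_, n)
  for (ch in unique(chrom)) {
    idx <- which(chrom == ch)
    f <- feats[feats$chrom == ch, ]
    if (nrow(f) == 0L) next
    ov <- IRanges::findOverlaps(
      IRanges::IRanges(start = pos[idx] + 1L, width = 1L),
      IRanges::IRanges(start = f$start + 1L, end = f$end))
    if (length(ov) == 0L) next
    hits <- tibble(q = S4Vectors::queryHits(ov), s = S4Vectors::subjectHits(ov))
    hits$priority <- f$priority[hits$s]
    hits$tx_start <- f$tx_start[hits$s]
    hits$symbol <- f$symbol[hits$s]
    best <- hits |>
      arrange(.data$q, .data$priority, .data$tx_start, .data$symbol) |>
      distinct(.data$q, .keep_all = TRUE)
    category[idx[best$q]] <- f$category[best$s]
    symbol[idx[best$q]] <- best$symbol
  }
  tibble(category = category, symbol = symbol)
}

#' Classify peaks by genomic feature
#'
#' Assigns each peak to exactly one of promoter, 5'-UTR, exon, intron,
#' 3'-UTR, downstream or intergenic, by the location of its center point.
#' When the center falls in features of several (possibly overlapping) genes,
#' precedence is promoter > utr5 > exon > intron > utr3 > downstream;
#' remaining ties break deterministically by (chrom, tx_start, symbol).
#' Peaks on chromosomes with no annotated gene are intergenic (with a
#' warning).
#'
#' @param peaks Peak tibble (see [read_bed()]).
#' @param genes Gene model tibble (see [read_gene_models()]).
#' @param config An [annotation_config()].
#' @return The peak tibble with added `center`, `category` and `gene` columns.
#' @export
classify_peaks <- function(peaks, genes, config = annotation_config()) {
  stopifnot(nrow(peaks) >= 1)
  centers <- peak_centers(peaks)
  off <- setdiff(unique(peaks$chrom), unique(genes$chrom))
  if (length(off)) {
    warn(sprintf("peaks on chromosome(s) without annotation classified intergenic: %s",
                 paste(off, collapse = ", ")))
  }
  feats <- feature_intervals(genes, config)
  cls <- classify_positions(peaks$chrom, centers, feats)
  out <- peaks
  out$center <- centers
  out$category <- factor(cls$category, levels = c(feature_categories, "intergenic"))
  out$gene <- cls$symbol
  as_tibble(out)
}

#' Fraction of peaks per genomic feature category
#'
#' @inheritParams classify_peaks
#' @return A tibble with `category`, `n` and `fraction` (fractions sum to 1)
#'   over all seven categories, including empty ones.
#' @export
feature_distribution <- function(peaks, genes, config = annotation_config()) {
  if (nrow(peaks) == 0L) abort("feature_distribution requires at least one peak")
  cls <- classify_peaks(peaks, genes, config)
  tab <- table(cls$category)
  tibble(category = names(tab), n = as.integer(tab),
         fraction = as.integer(tab) / nrow(peaks))
}

#' Signed distance from each peak center to the nearest TSS
#'
#' For every peak, finds the transcription start site nearest to the peak
#' center by absolute genomic distance and reports a strand-aware signed
#' distance: negative when the center lies upstream (5') of the TSS, positive
#' downstream. Equidistant TSSs tie-break toward the gene earlier in
#' (chrom, tx_start, symbol) order. Peaks on chromosomes with no gene are
#' skipped with a warning.
#'
#' @inheritParams classify_peaks
#' @param breaks Histogram bin edges (bp, signed); distances outside the range
#'   are clipped into the extreme bins for the histogram only.
#' @param genome Optional genome (any form accepted by [genome_index()]);
#'   when supplied together with `n_permutations > 0`, a matched null
#'   histogram is computed by averaging the profile over random re-placements
#'   of length-matched peaks.
#' @param n_permutations Number of shuffles for the null histogram.
#' @return A list of class `tss_profile`: `distances` (tibble with `chrom`,
#'   `center`, `gene`, `distance`), `histogram` (tibble with `mid`, `count`,
#'   and `null_mean` when a null was computed), and `breaks`.
#' @export
tss_distance_profile <- function(peaks, genes,
                                 breaks = seq(-1e5, 1e5, by = 5e3),
                                 genome = NULL, n_permutations = 0L) {
  # one representative gene per distinct TSS position, chosen by the
  # (chrom, tx_start, symbol) tie rule, sorted by position for findInterval
  tss <- genes |>
    distinct(.data$chrom, .data$tx_start, .data$symbol, .data$tss, .data$strand) |>
    arrange(.data$chrom, .data$tx_start, .data$symbol) |>
    distinct(.data$chrom, .data$tss, .keep_all = TRUE) |>
    arrange(.data$chrom, .data$tss)
  by_chrom <- split(tss, tss$chrom)
  dist_one_set <- function(pk, quiet = FALSE) {
    centers <- peak_centers(pk)
    keep <- pk$chrom %in% tss$chrom
    if (!all(keep) && !quiet) {
      warn(sprintf("%d peak(s) on chromosomes without genes skipped", sum(!keep)))
    }
    out <- rep(NA_real_, nrow(pk))
    for (ch in unique(pk$chrom[keep])) {
      cand <- by_chrom[[ch]]
      idx <- which(pk$chrom == ch & keep)
      ctr <- centers[idx]
      i <- findInterval(ctr, cand$tss)          # last TSS position <= center
      lo <- pmax(i, 1L); hi <- pmin(i + 1L, nrow(cand))
      dlo <- abs(ctr - cand$tss[lo]); dlo[i < 1L] <- Inf
      dhi <- abs(ctr - cand$tss[hi]); dhi[i + 1L > nrow(cand)] <- Inf
      pick_hi <- dhi < dlo
      tie <- dhi == dlo & is.finite(dlo) & lo != hi
      if (any(tie)) {
        # equidistant flanking TSSs: earlier gene in (tx_start, symbol) wins
        earlier_hi <- cand$tx_start[hi] < cand$tx_start[lo] |
          (cand$tx_start[hi] == cand$tx_start[lo] & cand$symbol[hi] < cand$symbol[lo])
        pick_hi[tie] <- earlier_hi[tie]
      }
      j <- ifelse(pick_hi, hi, lo)
      d <- ctr - cand$tss[j]
      out[idx] <- ifelse(cand$strand[j] == "+", d, -d)
    }
    out[keep]
  }
  hist_counts <- function(d) {
    d <- pmin(pmax(d, breaks[1]), breaks[length(breaks)])
    as.vector(table(cut(d, breaks = breaks, include.lowest = TRUE)))
  }
  centers <- peak_centers(peaks)
  keep <- peaks$chrom %in% tss$chrom
  d <- dist_one_set(peaks)
  hist <- tibble(mid = (breaks[-1] + breaks[-length(breaks)]) / 2,
                 count = hist_counts(d))
  if (!is.null(genome) && n_permutations > 0L) {
    gi <- genome_index(genome)
    null_counts <- matrix(0, nrow = nrow(hist), ncol = n_permutations)
    for (b in seq_len(n_permutations)) {
      null_counts[, b] <- hist_counts(dist_one_set(shuffle_peaks(peaks, gi), quiet = TRUE))
    }
    hist$null_mean <- rowMeans(null_counts)
  }
  structure(list(
    distances = tibble(chrom = peaks$chrom[keep], center = centers[keep],
                       distance = d),
    histogram = hist, breaks = breaks), class = "tss_profile")
}

#' Link peaks to genes within a TSS window
#'
#' A gene is bound when at least one peak center lies within
#' `link_window_bp` of its TSS (inclusive boundary, `|center - TSS| <=`
#' window). Genes with several transcripts are linked through any of their
#' TSSs but reported once per symbol.
#'
#' @inheritParams classify_peaks
#' @return A tibble with one row per bound gene: `symbol`, `n_peaks`, and a
#'   list-column `peaks` of supporting peak row indices into `peaks`.
#' @export
link_peaks_to_genes <- function(peaks, genes, config = annotation_config()) {
  centers <- peak_centers(peaks)
  w <- config$link_window_bp
  hits <- vector("list", nrow(genes))
  for (ch in unique(genes$chrom)) {
    gidx <- which(genes$chrom == ch)
    pidx <- which(peaks$chrom == ch)
    if (!length(pidx)) next
    ov <- IRanges::findOverlaps(
      IRanges::IRanges(start = centers[pidx] + 1L, width = 1L),
      IRanges::IRanges(start = genes$tss[gidx] - w + 1L, end = genes$tss[gidx] + w + 1L))
    for (k in seq_along(ov)) {
      gi <- gidx[S4Vectors::subjectHits(ov)[k]]
      hits[[gi]] <- c(hits[[gi]], pidx[S4Vectors::queryHits(ov)[k]])
    }
  }
  per_tx <- tibble(symbol = genes$symbol, peak_idx = hits)
  bound <- per_tx |>
    group_by(.data$symbol) |>
    summarise(peaks = list(sort(unique(unlist(.data$peak_idx)))), .groups = "drop") |>
    mutate(n_peaks = lengths(.data$peaks)) |>
    filter(.data$n_peaks > 0L) |>
    arrange(.data$symbol) |>
    select("symbol", "n_peaks", "peaks")
  bound
}
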