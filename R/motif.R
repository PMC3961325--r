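IUPAC_CODES <- c(A = "A", C = "C", G = "G", T = "T",
                 R = "AG", Y = "CT", S = "CG", W = "AT", K = "GT", M = "AC",
                 B = "CGT", D = "AGT", H = "ACT", V = "ACG", N = "ACGT")

#' A degenerate IUPAC motif pattern
#'
#' Validates an IUPAC nucleotide string (e.g. the AP-1 consensus `TGAYTCA`,
#' where Y = C or T) and derives its reverse complement. Patterns must be at
#' least 4 bases long.
#'
#' @param iupac Motif string over the IUPAC alphabet.
#' @return A list of class `motif_pattern` with elements `iupac`, `revcomp`,
#'   and `length`.
#' @export
motif_pattern <- function(iupac) {
  iupac <- toupper(trimws(iupac))
  chars <- strsplit(iupac, "")[[1]]
  if (length(chars) < 4L) abort("motif must be at least 4 bases long")
  bad <- setdiff(chars, names(IUPAC_CODES))
  if (length(bad)) abort(sprintf("invalid IUPAC code(s): %s", paste(bad, collapse = ", ")))
  rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(iupac)))
  structure(list(iupac = iupac, revcomp = rc, length = length(chars)),
            class = "motif_pattern")
}

as_motif <- function(motif) {
  if (inherits(motif, "motif_pattern")) motif else motif_pattern(motif)
}

#' Scan a sequence for a degenerate motif on both strands
#'
#' Reports every offset at which the motif, or its reverse complement,
#' matches the sequence. Matching is case-insensitive; an `N` in the
#' *sequence* never matches any pattern position (ambiguity codes are
#' interpreted in the pattern only). Overlapping matches are all reported.
#'
#' @param seq A character string or [Biostrings::DNAString] over A/C/G/T/N.
#' @param motif A [motif_pattern()] or IUPAC string.
#' @return A tibble with `offset` (0-based match start on the forward
#'   sequence) and `strand` (`"+"` for the forward pattern, `"-"` for its
#'   reverse complement), sorted by offset then strand.
#' @export
scan_sequence <- function(seq, motif) {
  motif <- as_motif(motif)
  if (!methods::is(seq, "DNAString")) seq <- Biostrings::DNAString(toupper(as.character(seq)))
  if (motif$length > length(seq)) {
    return(tibble(offset = integer(), strand = character()))
  }
  fwd <- Biostrings::matchPattern(Biostrings::DNAString(motif$iupac), seq, fixed = "subject")
  rev <- Biostrings::matchPattern(Biostrings::DNAString(motif$revcomp), seq, fixed = "subject")
  out <- bind_rows(
    tibble(offset = BiocGenerics::start(fwd) - 1L, strand = "+"),
    tibble(offset = BiocGenerics::start(rev) - 1L, strand = "-"))
  if (motif$iupac == motif$revcomp) out <- filter(out, .data$strand == "+")
  arrange(out, .data$offset, .data$strand)
}

peak_sequences <- function(peaks, genome) {
  stopifnot(methods::is(genome, "DNAStringSet"))
  validate_peaks(peaks, genome_index = genome)
  seqs <- vector("list", nrow(peaks))
  for (ch in unique(peaks$chrom)) {
    idx <- which(peaks$chrom == ch)
    seqs[idx] <- as.list(Biostrings::extractAt(
      genome[[ch]], IRanges::IRanges(start = peaks$start[idx] + 1L, end = peaks$end[idx])))
  }
  Biostrings::DNAStringSet(seqs)
}

#' Fraction of peaks containing a motif
#'
#' A peak is a hit when its sequence carries at least one match to the motif
#' on either strand.
#'
#' @param peaks Peak tibble.
#' @param genome A named [Biostrings::DNAStringSet] covering all peak
#'   chromosomes.
#' @param motif A [motif_pattern()] or IUPAC string.
#' @return A one-row tibble: `n_peaks`, `hits`, `rate`.
#' @export
peak_hit_rate <- function(peaks, genome, motif) {
  motif <- as_motif(motif)
  seqs <- peak_sequences(peaks, genome)
  n_f <- Biostrings::vcountPattern(Biostrings::DNAString(motif$iupac), seqs, fixed = "subject")
  n_r <- Biostrings::vcountPattern(Biostrings::DNAString(motif$revcomp), seqs, fixed = "subject")
  hits <- sum(n_f + n_r > 0L)
  tibble(n_peaks = nrow(peaks), hits = hits, rate = hits / nrow(peaks))
}

#' Motif enrichment in peaks versus random genomic fragments
#'
#' Estimates the background probability `q` that a length-matched random
#' genomic fragment contains the motif, by pooling `n_background_sets`
#' independent shuffles of the peak set ([shuffle_peaks()]), then tests the
#' observed number of motif-containing peaks against `Binomial(n_peaks, q)`
#' (upper tail, `P(X >= observed)`). Fold enrichment is `observed rate / q`.
#' If no background fragment contains the motif while peaks do, the p-value
#' is reported as `1 / total background fragments` with `p_is_upper_bound`
#' set and `fold = Inf`.
#'
#' @inheritParams peak_hit_rate
#' @param n_background_sets Number of shuffled background sets to pool.
#' @return A one-row tibble: `n_peaks`, `hits`, `rate`, `background_rate`,
#'   `n_background`, `fold`, `p_value`, `p_is_upper_bound`.
#' @export
motif_enrichment_test <- function(peaks, genome, motif, n_background_sets = 10L) {
  stopifnot(n_background_sets >= 1)
  motif <- as_motif(motif)
  obs <- peak_hit_rate(peaks, genome, motif)
  gi <- genome_index(genome)
  bg_hits <- 0L; bg_n <- 0L
  for (b in seq_len(n_background_sets)) {
    bg <- peak_hit_rate(shuffle_peaks(peaks, gi), genome, motif)
    bg_hits <- bg_hits + bg$hits
    bg_n <- bg_n + bg$n_peaks
  }
  q <- bg_hits / bg_n
  if (q == 0 && obs$hits > 0) {
    p <- 1 / bg_n
    upper <- TRUE
    fold <- Inf
  } else {
    p <- pbinom(obs$hits - 1L, obs$n_peaks, q, lower.tail = FALSE)
    upper <- FALSE
    fold <- if (q > 0) obs$rate / q else NA_real_
  }
  tibble(n_peaks = obs$n_peaks, hits = obs$hits, rate = obs$rate,
         background_rate = q, n_background = bg_n,
         fold = fold, p_value = p, p_is_upper_bound = upper)
}
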