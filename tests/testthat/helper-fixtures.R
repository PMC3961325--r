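# Small in-code fixtures shared across tests. All coordinates 0-based
# half-open, matching the package convention.

# A hand-sized annotation: two + genes and one - gene on chr1, one + gene on
# chr2. gA spans [10000, 14000) with 3 exons and CDS [10300, 13700).
toy_genes <- function() {
  g <- tibble::tibble(
    symbol = c("gA", "gB", "gC", "gD"),
    chrom = c("chr1", "chr1", "chr1", "chr2"),
    strand = c("+", "-", "+", "+"),
    tx_start = c(10000L, 30000L, 60000L, 5000L),
    tx_end = c(14000L, 34000L, 64000L, 9000L),
    cds_start = c(10300L, 30300L, 60300L, 5300L),
    cds_end = c(13700L, 33700L, 63700L, 8700L),
    exon_count = c(3L, 3L, 1L, 1L),
    exon_starts = list(c(10000L, 11700L, 13300L), c(30000L, 31700L, 33300L),
                       60000L, 5000L),
    exon_ends = list(c(10600L, 12400L, 14000L), c(30600L, 32400L, 34000L),
                     64000L, 9000L)
  )
  wnttargets:::add_tss(g)
}

toy_index <- function() {
  tibble::tibble(chrom = c("chr1", "chr2"), length = c(100000L, 50000L))
}

make_peak <- function(chrom, start, end, name = NA_character_) {
  tibble::tibble(chrom = chrom, start = as.integer(start), end = as.integer(end),
                 name = name, score = NA_real_)
}

# random A/C/G/T string
random_seq <- function(n, with_n = 0) {
  alphabet <- c("A", "C", "G", "T")
  s <- sample(alphabet, n, replace = TRUE)
  if (with_n > 0) s[sample.int(n, with_n)] <- "N"
  paste(s, collapse = "")
}

# Independent sliding-window IUPAC scanner used as the oracle for
# scan_sequence: per-position character-set comparison, no Biostrings.
iupac_sets <- c(A = "A", C = "C", G = "G", T = "T",
                R = "AG", Y = "CT", S = "CG", W = "AT", K = "GT", M = "AC",
                B = "CGT", D = "AGT", H = "ACT", V = "ACG", N = "ACGT")
revcomp_chr <- function(s) {
  comp <- c(A = "T", C = "G", G = "C", T = "A", R = "Y", Y = "R", S = "S",
            W = "W", K = "M", M = "K", B = "V", D = "H", H = "D", V = "B", N = "N")
  paste(rev(comp[strsplit(s, "")[[1]]]), collapse = "")
}
oracle_scan <- function(seq, motif) {
  seq_chars <- strsplit(toupper(seq), "")[[1]]
  match_at <- function(pattern, off) {
    pc <- strsplit(pattern, "")[[1]]
    all(vapply(seq_along(pc), function(i) {
      sc <- seq_chars[off + i]
      sc %in% strsplit(iupac_sets[[pc[i]]], "")[[1]]  # N in seq matches nothing
    }, TRUE))
  }
  k <- nchar(motif)
  n <- length(seq_chars)
  rc <- revcomp_chr(motif)
  out <- list()
  for (off in 0:(n - k)) {
    if (match_at(motif, off)) out[[length(out) + 1]] <- c(off, "+")
    if (rc != motif && match_at(rc, off)) out[[length(out) + 1]] <- c(off, "-")
  }
  if (!length(out)) return(tibble::tibble(offset = integer(), strand = character()))
  m <- do.call(rbind, out)
  dplyr::arrange(tibble::tibble(offset = as.integer(m[, 1]), strand = m[, 2]),
                 offset, strand)
}

# Brute-force running-sum oracle for the KS/GSEA statistic: explicit loop,
# no shared code with ks_enrichment().
oracle_ks <- function(symbols, gene_set, metric = rep(1, length(symbols)), w = 0) {
  hit <- symbols %in% gene_set
  nh <- sum(hit)
  N <- length(symbols)
  denom_hit <- if (w == 0) nh else sum(abs(metric[hit])^w)
  run <- numeric(N)
  acc <- 0
  for (i in seq_len(N)) {
    acc <- acc + if (hit[i]) {
      if (w == 0) 1 / nh else abs(metric[i])^w / denom_hit
    } else {
      -1 / (N - nh)
    }
    run[i] <- acc
  }
  run
}

# Exact hypergeometric upper tail by direct enumeration of binomial
# coefficients (oracle; independent of phyper).
oracle_hyper_upper <- function(k, nA, nB, N) {
  if (k == 0) return(1)
  j <- k:min(nA, nB)
  sum(choose(nB, j) * choose(N - nB, nA - j)) / choose(N, nA)
}

small_sim_config <- function(...) {
  args <- list(n_chromosomes = 2L, chrom_length = 3e5, n_genes = 40L,
               n_targets = 8L, n_decoys = 8L, n_peaks = 80L,
               tss_offset_sd = 2000, tss_offset_max = 8000)
  override <- list(...)
  args[names(override)] <- override
  do.call(sim_config, args)
}
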