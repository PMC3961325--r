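test_that("peak centers classify into the seven feature categories", {
  genes <- toy_genes()
  cases <- list(
    list(make_peak("chr1", 8900, 9100), "promoter", "gA"),    # 1 kb upstream of + TSS
    list(make_peak("chr1", 10050, 10150), "utr5", "gA"),
    list(make_peak("chr1", 10350, 10450), "exon", "gA"),
    list(make_peak("chr1", 10950, 11050), "intron", "gA"),
    list(make_peak("chr1", 13750, 13850), "utr3", "gA"),
    list(make_peak("chr1", 14950, 15050), "downstream", "gA"),
    list(make_peak("chr1", 49950, 50050), "intergenic", NA),
    # minus-strand gene: promoter is the 2 kb at higher coordinates
    list(make_peak("chr1", 34950, 35050), "promoter", "gB"),
    list(make_peak("chr1", 28950, 29050), "downstream", "gB"),
    list(make_peak("chr1", 33750, 33850), "utr5", "gB"),
    list(make_peak("chr1", 30050, 30150), "utr3", "gB"))
  for (cs in cases) {
    cls <- classify_peaks(cs[[1]], genes)
    expect_equal(as.character(cls$category), cs[[2]])
    if (!is.na(cs[[3]])) expect_equal(cls$gene, cs[[3]])
  }
})

test_that("feature precedence resolves overlapping genes (exon beats intron)", {
  host <- tibble::tibble(
    symbol = "host", chrom = "chr1", strand = "+",
    tx_start = 1000L, tx_end = 20000L, cds_start = 1200L, cds_end = 19800L,
    exon_count = 2L, exon_starts = list(c(1000L, 19000L)),
    exon_ends = list(c(2000L, 20000L)))
  inner <- tibble::tibble(
    symbol = "inner", chrom = "chr1", strand = "+",
    tx_start = 5000L, tx_end = 9000L, cds_start = 5200L, cds_end = 8800L,
    exon_count = 1L, exon_starts = list(5000L), exon_ends = list(9000L))
  genes <- wnttargets:::add_tss(dplyr::bind_rows(host, inner))
  # center in inner's coding exon, which is also host's intron
  cls <- classify_peaks(make_peak("chr1", 6000, 6200), genes)
  expect_equal(as.character(cls$category), "exon")
  expect_equal(cls$gene, "inner")
  # promoter of inner overlapping host's intron wins too
  cls <- classify_peaks(make_peak("chr1", 4000, 4200), genes)
  expect_equal(as.character(cls$category), "promoter")
})

test_that("peaks on chromosomes without annotation are intergenic with a warning", {
  expect_warning(cls <- classify_peaks(make_peak("chrUn", 100, 200), toy_genes()),
                 "without annotation")
  expect_equal(as.character(cls$category), "intergenic")
})

test_that("feature fractions count each peak once and sum to one", {
  genes <- toy_genes()
  peaks <- dplyr::bind_rows(
    make_peak("chr1", 8900, 9100),   # promoter
    make_peak("chr1", 10350, 10450), # exon
    make_peak("chr1", 10950, 11050), # intron
    make_peak("chr1", 49950, 50050)) # intergenic
  fd <- feature_distribution(peaks, genes)
  expect_equal(sum(fd$fraction), 1, tolerance = 1e-12)
  expect_equal(fd$fraction[fd$category %in% c("promoter", "exon", "intron", "intergenic")],
               rep(0.25, 4))
  fd2 <- feature_distribution(make_peak("chr1", 49950, 50050), genes)
  expect_equal(fd2$fraction[fd2$category == "intergenic"], 1)
  expect_error(feature_distribution(peaks[0, ], genes), "at least one")
})

test_that("promoter fraction recovers a known planting rate", {
  set.seed(42)
  sim <- simulate_genome(small_sim_config())
  genes <- sim$genes
  n <- 400L
  planted <- runif(n) < 0.3
  # planted peaks: centered inside a random gene's promoter;
  # the rest at a fixed intergenic-safe spot far from all features
  pick <- sample.int(nrow(genes), n, replace = TRUE)
  center <- ifelse(genes$strand[pick] == "+",
                   genes$tx_start[pick] - sample(1:1999, n, replace = TRUE),
                   genes$tx_end[pick] + sample(0:1998, n, replace = TRUE))
  peaks <- tibble::tibble(chrom = ifelse(planted, genes$chrom[pick], "chr1"),
                          start = ifelse(planted, center - 50L, 2L),
                          end = ifelse(planted, center + 50L, 102L),
                          name = NA_character_, score = NA_real_)
  cls <- classify_peaks(peaks, genes)
  expect_true(all(as.character(cls$category[planted]) == "promoter"))
  frac <- mean(as.character(cls$category) == "promoter")
  expect_lt(abs(frac - 0.3), 3 * sqrt(0.3 * 0.7 / n))
})

test_that("per-bp category map agrees with interval classification", {
  set.seed(7)
  sim <- simulate_genome(small_sim_config())
  peaks <- simulate_peaks(sim)
  cls <- classify_peaks(peaks, sim$genes)
  maps <- wnttargets:::build_category_map(sim$genes, sim$genome)
  cats <- c(wnttargets:::feature_categories, "intergenic")
  for (cat in cats) {
    code <- match(cat, cats)
    expect_equal(
      wnttargets:::category_fraction(peaks$chrom, wnttargets:::peak_centers(peaks),
                                     maps, code),
      mean(as.character(cls$category) == cat))
  }
})

test_that("TSS distances are signed by gene orientation with deterministic ties", {
  genes <- toy_genes()
  expect_equal(tss_distance_profile(make_peak("chr1", 9950, 10050), genes)$distances$distance, 0)
  # 500 bp 5' of a + strand TSS
  expect_equal(tss_distance_profile(make_peak("chr1", 9450, 9550), genes)$distances$distance, -500)
  # inside a - strand transcript, 500 bp past its TSS -> +500
  expect_equal(tss_distance_profile(make_peak("chr1", 33449, 33549), genes)$distances$distance, 500)
  # equidistant pair: gene earlier in (chrom, tx_start, symbol) order wins
  pair <- wnttargets:::add_tss(tibble::tibble(
    symbol = c("early", "late"), chrom = "chr1", strand = "+",
    tx_start = c(1000L, 3000L), tx_end = c(2500L, 4500L),
    cds_start = c(1000L, 3000L), cds_end = c(2500L, 4500L),
    exon_count = 1L, exon_starts = list(1000L, 3000L),
    exon_ends = list(2500L, 4500L)))
  d <- tss_distance_profile(make_peak("chr1", 1950, 2050), pair)$distances$distance
  expect_equal(d, 1000)  # downstream of "early", not upstream of "late"
  expect_warning(tss_distance_profile(make_peak("chrUn", 0, 100), toy_genes()),
                 "skipped")
})

test_that("uniform peaks match their own shuffle-null TSS-distance histogram", {
  set.seed(19)
  sim <- simulate_genome(small_sim_config())
  gi <- genome_index(sim$genome)
  n <- 2000L
  start <- as.integer(floor(runif(n) * (3e5 - 200)))
  peaks <- tibble::tibble(chrom = sample(gi$chrom, n, replace = TRUE),
                          start = start, end = start + 200L,
                          name = NA_character_, score = NA_real_)
  prof <- tss_distance_profile(peaks, sim$genes, breaks = seq(-2e4, 2e4, 2e3),
                               genome = sim$genome, n_permutations = 20)
  h <- prof$histogram
  keep <- h$null_mean >= 5
  chisq <- sum((h$count[keep] - h$null_mean[keep])^2 / h$null_mean[keep])
  p <- pchisq(chisq, df = sum(keep) - 1, lower.tail = FALSE)
  expect_gt(p, 0.01)
})

test_that("peak-gene linking uses an inclusive 20-kb center-to-TSS window", {
  genes <- toy_genes()  # gD on chr2, TSS 5000
  expect_true("gD" %in% link_peaks_to_genes(make_peak("chr2", 25000, 25001), genes)$symbol)
  expect_false("gD" %in% link_peaks_to_genes(make_peak("chr2", 25001, 25002), genes)$symbol)
  two <- dplyr::bind_rows(make_peak("chr2", 4000, 4200), make_peak("chr2", 6000, 6200))
  bound <- link_peaks_to_genes(two, genes)
  expect_equal(bound$n_peaks[bound$symbol == "gD"], 2L)
  expect_equal(sum(bound$symbol == "gD"), 1L)
})

test_that("enlarging the link window never removes a bound gene", {
  set.seed(3)
  sim <- simulate_genome(small_sim_config())
  peaks <- simulate_peaks(sim)
  for (w in c(2000L, 10000L, 20000L)) {
    narrow <- link_peaks_to_genes(peaks, sim$genes, annotation_config(link_window_bp = w))
    wide <- link_peaks_to_genes(peaks, sim$genes, annotation_config(link_window_bp = w + 5000L))
    expect_true(all(narrow$symbol %in% wide$symbol))
  }
})
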