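test_that("simulated annotations satisfy all gene-model invariants", {
  set.seed(71)
  sim <- simulate_genome(sim_config())
  expect_equal(nrow(sim$genes), 200L)
  expect_silent(wnttargets:::validate_gene_models(sim$genes))
  gi <- genome_index(sim$genome)
  expect_true(all(sim$genes$tx_end <= gi$length[match(sim$genes$chrom, gi$chrom)]))
  expect_setequal(sim$truth$roles$role,
                  c("target", "decoy_one_channel", "decoy_unbound", "null"))
})

test_that("motif planting at rate 1 leaves a match in every bound-gene peak", {
  set.seed(72)
  sim <- simulate_genome(small_sim_config(motif_plant_rate = 1))
  planted <- sim$truth$peaks[!is.na(sim$truth$peaks$planted_gene), ]
  rate <- peak_hit_rate(planted, sim$genome, sim$truth$config$motif)
  expect_equal(rate$rate, 1)
  expect_equal(nrow(sim$truth$motif_sites), nrow(planted))
})

test_that("seeded simulation is byte-identical across runs", {
  a <- simulate_wnt_study(7)
  b <- simulate_wnt_study(7)
  expect_identical(as.character(a$sim$genome), as.character(b$sim$genome))
  expect_identical(a$peaks, b$peaks)
  expect_identical(a$expression, b$expression)
  expect_identical(a$cohort$clinical, b$cohort$clinical)
})

test_that("without background peaks every peak supports a bound gene", {
  cfg <- small_sim_config(n_peaks = 12L, n_targets = 8L, n_decoys = 8L)
  set.seed(73)
  sim <- simulate_genome(cfg)  # 8 targets + 4 one-channel decoys = 12 peaks
  expect_true(all(!is.na(sim$truth$peaks$planted_gene)))
  bound <- link_peaks_to_genes(simulate_peaks(sim), sim$genes)
  planted <- sim$truth$roles$symbol[sim$truth$roles$role == "target"]
  expect_true(all(planted %in% bound$symbol))
})

test_that("tight TSS offsets guarantee planted targets are linked", {
  set.seed(74)
  sim <- simulate_genome(small_sim_config(tss_offset_sd = 1))
  bound <- link_peaks_to_genes(simulate_peaks(sim), sim$genes)
  planted <- sim$truth$roles$symbol[sim$truth$roles$role == "target"]
  expect_true(all(planted %in% bound$symbol))
})

test_that("generated outputs pass every reader's validation on round-trip", {
  set.seed(75)
  sim <- simulate_genome(small_sim_config())
  peaks <- simulate_peaks(sim)
  expr <- simulate_expression(sim)
  dir <- withr::local_tempdir()
  write_bed(peaks, file.path(dir, "peaks.bed"))
  write_gene_models(sim$genes, file.path(dir, "genes.refflat"))
  write_genome(sim$genome, file.path(dir, "genome.fa"))
  write_expression_table(expr, file.path(dir, "expr.tsv"))
  genome2 <- read_genome(file.path(dir, "genome.fa"))
  peaks2 <- read_bed(file.path(dir, "peaks.bed"), genome_index = genome2)
  expect_equal(peaks2[c("chrom", "start", "end", "name")],
               peaks[c("chrom", "start", "end", "name")])
  expect_equal(as.data.frame(read_gene_models(file.path(dir, "genes.refflat"))),
               as.data.frame(sim$genes))
  expect_equal(read_expression_table(file.path(dir, "expr.tsv")), expr,
               tolerance = 1e-10)
  cohort <- simulate_cohort(small_sim_config(cohort_n = 30L), expr$symbol[1:5])
  write_clinical(cohort$clinical, file.path(dir, "clinical.tsv"))
  expect_equal(read_clinical(file.path(dir, "clinical.tsv")), cohort$clinical,
               tolerance = 1e-10)
})

test_that("cohort censoring and hazards behave as configured", {
  set.seed(76)
  none <- simulate_cohort(sim_config(censor_rate = 0, cohort_n = 50L), "G0001")
  expect_true(all(none$clinical$event == 1))
  hr1 <- simulate_cohort(sim_config(hazard_ratio = 1, cohort_n = 400L), "G0001")
  by_group <- split(hr1$clinical$time, hr1$group$true_group)
  expect_gt(suppressWarnings(stats::ks.test(by_group$high, by_group$low)$p.value), 0.01)
})

test_that("an effect-free simulation yields an essentially empty signature", {
  sizes <- vapply(1:20, function(s) {
    set.seed(900 + s)
    cfg <- small_sim_config(n_targets = 0L, n_decoys = 0L)
    sim <- simulate_genome(cfg)
    sig <- summarize_signature(call_targets(
      simulate_expression(sim),
      link_peaks_to_genes(simulate_peaks(sim), sim$genes)))
    nrow(sig)
  }, 0L)
  # joint chance of p < 0.01 in both channels and lr < -0.2 in both is ~1e-7
  expect_lte(mean(sizes), 0.1)
})
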