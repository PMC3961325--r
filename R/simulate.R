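#' Simulation configuration for the synthetic study
#'
#' Defaults describe the toy study the package validates itself on: a small
#' two-chromosome genome dense with genes, ChIP peaks whose lengths follow
#' the sonication fragment-size distribution (mean 320.6 bp), planted target
#' genes that are both bound (a peak near their TSS) and down-regulated in
#' both knockdown channels clear of the calling thresholds
#' (effect -0.5 log10 against the -0.2 cutoff; planted p-values below 1e-3
#' against the 0.01 cutoff), and a survival cohort of 232 samples with a
#' group hazard ratio of 2.
#'
#' @param n_chromosomes Number of chromosomes.
#' @param chrom_length Length of each chromosome (bp).
#' @param n_genes Number of gene models (tiled evenly across chromosomes).
#' @param n_targets Planted direct targets (bound + down in both channels).
#' @param n_decoys Decoy genes; half are bound but down-regulated in only
#'   one channel, half are down in both channels but unbound.
#' @param n_peaks Total peak count (bound-gene peaks plus uniform background).
#' @param peak_length_mean,peak_length_sd,peak_length_min Peak length draw:
#'   Normal, truncated below at `peak_length_min`.
#' @param tss_offset_sd Sd (bp) of the Normal peak-center offset from the
#'   TSS for bound genes, truncated at +/- `tss_offset_max`.
#' @param tss_offset_max Truncation bound for the TSS offset (bp).
#' @param link_window Peak-to-TSS linking window (bp) the downstream analysis
#'   will use; the generator keeps unbound decoys out of reach of any peak
#'   under this window.
#' @param effect Mean planted log10 expression ratio (negative = down).
#' @param noise_sd Sd of the log-ratio noise (all genes).
#' @param planted_p_max Planted p-values are Uniform(0, `planted_p_max`).
#' @param motif IUPAC motif planted into bound-gene peaks.
#' @param motif_plant_rate Probability a bound-gene peak receives a planted
#'   motif copy.
#' @param cohort_n Survival cohort size.
#' @param cohort_effect Expression shift (log2 units) added to signature
#'   genes in the high group.
#' @param cohort_noise_sd Per-gene expression noise sd in the cohort matrix.
#' @param base_hazard Baseline exponential event hazard.
#' @param hazard_ratio Hazard ratio applied to the shifted (high) group.
#' @param censor_rate Rate of the independent exponential censoring time.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_chromosomes = 2L, chrom_length = 2e6, n_genes = 200L,
                       n_targets = 40L, n_decoys = 40L, n_peaks = 300L,
                       peak_length_mean = 320.6, peak_length_sd = 60,
                       peak_length_min = 50,
                       tss_offset_sd = 5000, tss_offset_max = 20000,
                       link_window = 20000,
                       effect = -0.5, noise_sd = 0.1, planted_p_max = 1e-3,
                       motif = "TGAYTCA", motif_plant_rate = 0.8,
                       cohort_n = 232L, cohort_effect = 1, cohort_noise_sd = 1,
                       base_hazard = 0.1, hazard_ratio = 2, censor_rate = 0.05) {
  cfg <- as.list(environment())
  stopifnot(cfg$n_genes >= cfg$n_targets + cfg$n_decoys,
            cfg$chrom_length >= cfg$peak_length_mean,
            cfg$motif_plant_rate >= 0, cfg$motif_plant_rate <= 1,
            cfg$effect < 0, cfg$noise_sd >= 0)
  structure(cfg, class = "sim_config")
}

rtrunc_norm <- function(n, mean, sd, lower = -Inf, upper = Inf) {
  x <- rnorm(n, mean, sd)
  while (any(bad <- x < lower | x > upper)) {
    x[bad] <- rnorm(sum(bad), mean, sd)
  }
  x
}

#' Simulate a genome with gene models, peak footprints and planted motifs
#'
#' Generates an i.i.d. uniform A/C/G/T genome, tiles gene models evenly
#' across the chromosomes with alternating strand (each gene: 4 kb
#' transcript, 3 exons, internal CDS), designates the peak footprints (one
#' peak near the TSS of every bound gene -- planted targets and one-channel
#' decoys -- plus uniform background peaks), and plants concrete motif
#' instances into the sequence inside bound-gene footprints at the
#' configured rate. Peak placement happens here, at genome time, because the
#' sequence must carry the motif copies; [simulate_peaks()] materialises the
#' footprints recorded in the ground truth.
#'
#' Uses the session RNG; call `set.seed()` first (or use
#' [simulate_wnt_study()]) for reproducibility.
#'
#' @param config A [sim_config()].
#' @return A list of class `wnt_sim`: `genome` (DNAStringSet), `genes`
#'   (gene-model tibble), and `truth` with `roles` (tibble `symbol`, `role`
#'   in target / decoy_one_channel / decoy_unbound / null, and
#'   `decoy_channel`), `peaks`, `motif_sites`, and `config`.
#' @export
simulate_genome <- function(config = sim_config()) {
  cfg <- config
  chroms <- paste0("chr", seq_len(cfg$n_chromosomes))
  L <- as.integer(cfg$chrom_length)
  seq_vec <- lapply(chroms, function(ch) sample(c("A", "C", "G", "T"), L, replace = TRUE))
  names(seq_vec) <- chroms

  per_chrom <- ceiling(cfg$n_genes / cfg$n_chromosomes)
  slot <- floor(L / per_chrom)
  tx_len <- 4000L
  if (slot < tx_len + 2L * cfg$tss_offset_sd) abort("infeasible gene tiling for this genome size")
  rows <- list()
  i <- 0L
  for (ch in chroms) {
    for (s in seq_len(per_chrom)) {
      i <- i + 1L
      if (i > cfg$n_genes) break
      tx_start <- as.integer((s - 1L) * slot + floor((slot - tx_len) / 2))
      rows[[i]] <- tibble(
        symbol = sprintf("G%04d", i), chrom = ch,
        strand = if (i %% 2L == 1L) "+" else "-",
        tx_start = tx_start, tx_end = tx_start + tx_len,
        cds_start = tx_start + 300L, cds_end = tx_start + 3700L,
        exon_count = 3L,
        exon_starts = list(tx_start + c(0L, 1700L, 3300L)),
        exon_ends = list(tx_start + c(600L, 2400L, 4000L)))
    }
  }
  genes <- add_tss(bind_rows(rows))
  validate_gene_models(genes)

  # roles; unbound decoys must stay unbound by construction, so they are
  # drawn only from genes whose TSS no bound-gene peak can reach: bound-gene
  # peak centers lie within tss_offset_max of the bound TSS and linking uses
  # link_window, so clearance beyond their sum suffices. The random role
  # assignment is retried if it leaves too few clear genes.
  d1 <- floor(cfg$n_decoys / 2)
  d2 <- cfg$n_decoys - d1
  clearance <- cfg$tss_offset_max + cfg$link_window
  for (attempt in 1:100) {
    shuffled <- sample(genes$symbol)
    bound_pick <- shuffled[seq_len(cfg$n_targets + d1)]
    bound_tss <- genes[match(bound_pick, genes$symbol), c("chrom", "tss")]
    clear_of_bound <- vapply(seq_len(nrow(genes)), function(j) {
      bt <- bound_tss$tss[bound_tss$chrom == genes$chrom[j]]
      length(bt) == 0 || min(abs(genes$tss[j] - bt)) > clearance
    }, TRUE)
    candidates <- setdiff(genes$symbol[clear_of_bound], bound_pick)
    if (length(candidates) >= d2) break
    if (attempt == 100) abort("cannot place unbound decoys clear of bound genes; reduce counts")
  }
  roles <- tibble(symbol = genes$symbol, role = "null",
                  decoy_channel = NA_integer_)
  roles$role[roles$symbol %in% bound_pick[seq_len(cfg$n_targets)]] <- "target"
  one_ch <- bound_pick[cfg$n_targets + seq_len(d1)]
  roles$role[roles$symbol %in% one_ch] <- "decoy_one_channel"
  roles$decoy_channel[roles$symbol %in% one_ch] <- sample(1:2, d1, replace = TRUE)
  unb <- sample(candidates, d2)
  roles$role[roles$symbol %in% unb] <- "decoy_unbound"

  # peak footprints: one near the TSS of each bound gene, rest background
  bound_syms <- roles$symbol[roles$role %in% c("target", "decoy_one_channel")]
  bg <- genes[match(bound_syms, genes$symbol), ]
  n_bound <- nrow(bg)
  len_b <- as.integer(round(rtrunc_norm(n_bound, cfg$peak_length_mean,
                                        cfg$peak_length_sd, lower = cfg$peak_length_min)))
  off <- as.integer(round(rtrunc_norm(n_bound, 0, cfg$tss_offset_sd,
                                      lower = -cfg$tss_offset_max, upper = cfg$tss_offset_max)))
  ctr <- bg$tss + off
  start_b <- pmin(pmax(ctr - len_b %/% 2L, 0L), L - len_b)
  bound_peaks <- tibble(chrom = bg$chrom, start = start_b, end = start_b + len_b,
                        name = paste0("pk_", bound_syms), score = NA_real_,
                        planted_gene = bound_syms)
  n_bg <- cfg$n_peaks - n_bound
  if (n_bg < 0) abort("n_peaks smaller than the number of bound genes")
  bg_peaks <- NULL
  if (n_bg > 0) {
    len_g <- as.integer(round(rtrunc_norm(n_bg, cfg$peak_length_mean,
                                          cfg$peak_length_sd, lower = cfg$peak_length_min)))
    # unbound decoys are unbound by construction: background positions whose
    # center falls within the linking window of an unbound-decoy TSS are redrawn
    guard <- genes[match(unb, genes$symbol), c("chrom", "tss")]
    ch_g <- sample(chroms, n_bg, replace = TRUE)
    start_g <- as.integer(floor(runif(n_bg) * (L - len_g + 1)))
    near_guard <- function(ch, ctr) {
      vapply(seq_along(ch), function(j) {
        g <- guard$tss[guard$chrom == ch[j]]
        length(g) > 0 && min(abs(ctr[j] - g)) <= cfg$link_window
      }, TRUE)
    }
    while (any(bad <- near_guard(ch_g, start_g + len_g %/% 2L))) {
      ch_g[bad] <- sample(chroms, sum(bad), replace = TRUE)
      start_g[bad] <- as.integer(floor(runif(sum(bad)) * (L - len_g[bad] + 1)))
    }
    bg_peaks <- tibble(chrom = ch_g, start = start_g, end = start_g + len_g,
                       name = sprintf("pk_bg%03d", seq_len(n_bg)), score = NA_real_,
                       planted_gene = NA_character_)
  }
  peaks <- bind_rows(bound_peaks, bg_peaks)

  # plant motif copies inside bound-gene footprints
  motif <- as_motif(cfg$motif)
  sets <- strsplit(unname(IUPAC_CODES[strsplit(motif$iupac, "")[[1]]]), "")
  sites <- list()
  for (j in seq_len(n_bound)) {
    if (runif(1) > cfg$motif_plant_rate) next
    pk <- bound_peaks[j, ]
    if (pk$end - pk$start < motif$length) next
    pos <- pk$start + sample.int(pk$end - pk$start - motif$length + 1L, 1L) - 1L
    instance <- vapply(sets, function(s) if (length(s) == 1L) s else sample(s, 1L), "")
    seq_vec[[pk$chrom]][(pos + 1L):(pos + motif$length)] <- instance
    sites[[length(sites) + 1L]] <- tibble(chrom = pk$chrom, start = pos,
                                          end = pos + motif$length,
                                          peak = pk$name,
                                          instance = paste(instance, collapse = ""))
  }
  genome <- Biostrings::DNAStringSet(vapply(seq_vec, paste, "", collapse = ""))
  names(genome) <- chroms
  structure(list(
    genome = genome, genes = genes,
    truth = list(roles = roles, peaks = peaks,
                 motif_sites = bind_rows(sites), config = cfg)),
    class = "wnt_sim")
}

#' Materialise the simulated peak set
#'
#' Returns the peak intervals designated during [simulate_genome()] as a
#' standard peak tibble (bound-gene peaks first, then background), shuffled
#' in row order so file order carries no signal.
#'
#' @param sim A `wnt_sim` object from [simulate_genome()].
#' @return A peak tibble (`chrom`, `start`, `end`, `name`, `score`).
#' @export
simulate_peaks <- function(sim) {
  stopifnot(inherits(sim, "wnt_sim"))
  pk <- sim$truth$peaks[sample.int(nrow(sim$truth$peaks)), ]
  select(pk, "chrom", "start", "end", "name", "score")
}

#' Simulate the two-knockdown expression table
#'
#' Planted targets are down-regulated in both channels (`lr ~ Normal(effect,
#' noise_sd)`, `p ~ Uniform(0, planted_p_max)`); one-channel decoys carry the
#' effect in a single random channel; unbound decoys carry it in both (but
#' received no peak); null genes draw `lr ~ Normal(0, noise_sd)` and
#' `p ~ Uniform(0, 1)`.
#'
#' @param sim A `wnt_sim` object from [simulate_genome()].
#' @return An expression tibble (`symbol`, `lr1`, `p1`, `lr2`, `p2`).
#' @export
simulate_expression <- function(sim) {
  stopifnot(inherits(sim, "wnt_sim"))
  cfg <- sim$truth$config
  roles <- sim$truth$roles
  n <- nrow(roles)
  draw_channel <- function(planted) {
    lr <- rnorm(n, mean = ifelse(planted, cfg$effect, 0), sd = cfg$noise_sd)
    p <- runif(n, 0, ifelse(planted, cfg$planted_p_max, 1))
    list(lr = lr, p = p)
  }
  planted1 <- roles$role == "target" | roles$role == "decoy_unbound" |
    (roles$role == "decoy_one_channel" & roles$decoy_channel == 1L)
  planted2 <- roles$role == "target" | roles$role == "decoy_unbound" |
    (roles$role == "decoy_one_channel" & roles$decoy_channel == 2L)
  planted1[is.na(planted1)] <- FALSE
  planted2[is.na(planted2)] <- FALSE
  c1 <- draw_channel(planted1); c2 <- draw_channel(planted2)
  tibble(symbol = roles$symbol, lr1 = c1$lr, p1 = c1$p, lr2 = c2$lr, p2 = c2$p)
}

#' Simulate a survival cohort expressing a gene signature
#'
#' Half of the samples (the `high` group) receive an expression shift of
#' `cohort_effect` on the signature genes; all values otherwise draw
#' `Normal(0, cohort_noise_sd)` on the log2 scale. Event times are
#' exponential with hazard `base_hazard` (`low`) or `base_hazard *
#' hazard_ratio` (`high`); censoring times are independent exponential at
#' `censor_rate`, and the observed time is the earlier of the two.
#'
#' @param config A [sim_config()].
#' @param signature Character vector of signature gene symbols.
#' @param gene_symbols All gene symbols to include as matrix rows; defaults
#'   to the signature plus simulated null genes up to `config$n_genes`.
#' @return A list: `matrix` (genes x samples, log2 scale), `clinical`
#'   (tibble `sample`, `time`, `event`), `group` (tibble `sample`,
#'   `true_group`).
#' @export
simulate_cohort <- function(config, signature, gene_symbols = NULL) {
  stopifnot(length(signature) >= 1)
  cfg <- config
  if (is.null(gene_symbols)) {
    gene_symbols <- union(signature, sprintf("G%04d", seq_len(cfg$n_genes)))
  }
  stopifnot(all(signature %in% gene_symbols))
  n <- cfg$cohort_n
  samples <- sprintf("S%03d", seq_len(n))
  high <- logical(n)
  high[sample.int(n, n %/% 2L)] <- TRUE
  mat <- matrix(rnorm(length(gene_symbols) * n, 0, cfg$cohort_noise_sd),
                nrow = length(gene_symbols),
                dimnames = list(gene_symbols, samples))
  mat[signature, high] <- mat[signature, high] + cfg$cohort_effect
  hazard <- ifelse(high, cfg$base_hazard * cfg$hazard_ratio, cfg$base_hazard)
  t_event <- rexp(n, rate = hazard)
  t_cens <- if (cfg$censor_rate > 0) rexp(n, rate = cfg$censor_rate) else rep(Inf, n)
  list(matrix = mat,
       clinical = tibble(sample = samples, time = pmin(t_event, t_cens),
                         event = as.integer(t_event <= t_cens)),
       group = tibble(sample = samples,
                      true_group = ifelse(high, "high", "low")))
}

#' One seeded end-to-end synthetic study
#'
#' Convenience wrapper: seeds the RNG, simulates the genome (with gene
#' models, peak footprints and motif planting), the peak table, the
#' two-knockdown expression table, and a survival cohort whose signature is
#' the planted target set.
#'
#' @param seed Integer RNG seed.
#' @param config A [sim_config()].
#' @return A list: `sim` (the `wnt_sim`), `peaks`, `expression`, `cohort`,
#'   and `targets` (the planted target symbols).
#' @export
simulate_wnt_study <- function(seed, config = sim_config()) {
  set.seed(seed)
  sim <- simulate_genome(config)
  peaks <- simulate_peaks(sim)
  expression <- simulate_expression(sim)
  targets <- sim$truth$roles$symbol[sim$truth$roles$role == "target"]
  cohort <- simulate_cohort(config, targets)
  list(sim = sim, peaks = peaks, expression = expression,
       cohort = cohort, targets = targets)
}
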