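#' Read ChIP-seq peaks from a BED file
#'
#' Parses BED3/BED4(+score) records into a peak table. Coordinates are kept in
#' the BED convention used throughout the package: 0-based, half-open
#' `[start, end)`, so `end - start` is the peak length in bp.
#'
#' @param path Path to a tab-separated BED file. Lines starting with `#`,
#'   `track` or `browser` are skipped.
#' @param genome_index Optional genome index (see [genome_index()]); when
#'   supplied, peaks on unknown chromosomes or extending past the chromosome
#'   end are rejected.
#' @return A tibble with columns `chrom`, `start`, `end`, `name`, `score`,
#'   in file order.
#' @export
read_bed <- function(path, genome_index = NULL) {
  stopifnot(file.exists(path))
  lines <- readr::read_lines(path)
  keep <- !grepl("^(#|track\\b|browser\\b)", lines) & nzchar(trimws(lines))
  lineno <- which(keep)
  lines <- lines[keep]
  if (length(lines) == 0L) {
    return(tibble(chrom = character(), start = integer(), end = integer(),
                  name = character(), score = double()))
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 3L)) {
    abort(sprintf("BED line %d: fewer than 3 tab-separated columns", lineno[which(nf < 3L)[1]]))
  }
  peaks <- tibble(
    chrom = vapply(fields, `[[`, "", 1L),
    start = suppressWarnings(as.integer(vapply(fields, `[[`, "", 2L))),
    end   = suppressWarnings(as.integer(vapply(fields, `[[`, "", 3L))),
    name  = vapply(fields, function(f) if (length(f) >= 4L) f[[4L]] else NA_character_, ""),
    score = suppressWarnings(as.double(
      vapply(fields, function(f) if (length(f) >= 5L) f[[5L]] else NA_character_, "")))
  )
  bad <- which(is.na(peaks$start) | is.na(peaks$end))
  if (length(bad)) abort(sprintf("BED line %d: malformed coordinate", lineno[bad[1]]))
  validate_peaks(peaks, genome_index = genome_index, lineno = lineno)
  peaks
}

validate_peaks <- function(peaks, genome_index = NULL, lineno = seq_len(nrow(peaks))) {
  bad <- which(peaks$start < 0L | peaks$end <= peaks$start)
  if (length(bad)) {
    abort(sprintf("BED line %d: requires 0 <= start < end (got %d, %d)",
                  lineno[bad[1]], peaks$start[bad[1]], peaks$end[bad[1]]))
  }
  if (!is.null(peaks$score) && any(!is.na(peaks$score) & peaks$score < 0)) {
    abort("peak score must be non-negative")
  }
  if (!is.null(genome_index)) {
    gi <- genome_index(genome_index)
    len <- gi$length[match(peaks$chrom, gi$chrom)]
    bad <- which(is.na(len))
    if (length(bad)) {
      abort(sprintf("BED line %d: unknown chromosome '%s'", lineno[bad[1]], peaks$chrom[bad[1]]))
    }
    bad <- which(peaks$end > len)
    if (length(bad)) {
      abort(sprintf("BED line %d: peak extends past end of '%s'", lineno[bad[1]], peaks$chrom[bad[1]]))
    }
  }
  invisible(peaks)
}

#' Write peaks to a BED file
#'
#' @param peaks Peak tibble as returned by [read_bed()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_bed <- function(peaks, path) {
  cols <- c("chrom", "start", "end")
  out <- peaks[cols]
  if (!is.null(peaks$name) && any(!is.na(peaks$name))) {
    out$name <- ifelse(is.na(peaks$name), ".", peaks$name)
    if (!is.null(peaks$score) && any(!is.na(peaks$score))) {
      out$score <- ifelse(is.na(peaks$score), 0, peaks$score)
    }
  }
  readr::write_tsv(out, path, col_names = FALSE)
  invisible(path)
}

#' Read gene models from a refFlat-like table
#'
#' Expects the 10-column refFlat layout: gene symbol, chromosome, strand,
#' transcript start/end, CDS start/end, exon count, and comma-separated exon
#' start/end lists. All coordinates are 0-based half-open. The transcription
#' start site (TSS) is strand-aware: `tx_start` on `+`, `tx_end - 1` on `-`
#' (the last covered base, so the TSS is always a real position inside the
#' transcript); the termination site (TTS) is symmetric. Duplicate symbols are
#' retained as distinct transcript records.
#'
#' @param path Path to the annotation file. A header line is detected and
#'   skipped if the fourth column is non-numeric.
#' @return A tibble with one row per transcript: `symbol`, `chrom`, `strand`,
#'   `tx_start`, `tx_end`, `cds_start`, `cds_end`, `exon_count`,
#'   list-columns `exon_starts`/`exon_ends`, and derived `tss`, `tts`.
#' @export
read_gene_models <- function(path) {
  stopifnot(file.exists(path))
  lines <- readr::read_lines(path)
  lines <- lines[nzchar(trimws(lines)) & !grepl("^#", lines)]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  if (length(fields) && length(fields[[1]]) >= 4L &&
      is.na(suppressWarnings(as.integer(fields[[1]][[4L]])))) {
    fields <- fields[-1L]  # header
  }
  if (any(lengths(fields) < 10L)) abort("gene model rows need 10 tab-separated columns")
  parse_ints <- function(x) as.integer(strsplit(x, ",", fixed = TRUE)[[1]])
  genes <- tibble(
    symbol = trimws(vapply(fields, `[[`, "", 1L)),
    chrom = vapply(fields, `[[`, "", 2L),
    strand = vapply(fields, `[[`, "", 3L),
    tx_start = as.integer(vapply(fields, `[[`, "", 4L)),
    tx_end = as.integer(vapply(fields, `[[`, "", 5L)),
    cds_start = as.integer(vapply(fields, `[[`, "", 6L)),
    cds_end = as.integer(vapply(fields, `[[`, "", 7L)),
    exon_count = as.integer(vapply(fields, `[[`, "", 8L)),
    exon_starts = lapply(fields, function(f) parse_ints(f[[9L]])),
    exon_ends = lapply(fields, function(f) parse_ints(f[[10L]]))
  )
  validate_gene_models(genes)
  add_tss(genes)
}

add_tss <- function(genes) {
  mutate(genes,
         tss = ifelse(.data$strand == "+", .data$tx_start, .data$tx_end - 1L),
         tts = ifelse(.data$strand == "+", .data$tx_end - 1L, .data$tx_start))
}

validate_gene_models <- function(genes) {
  if (any(!genes$strand %in% c("+", "-"))) {
    abort(sprintf("strand must be '+' or '-' (gene '%s')",
                  genes$symbol[which(!genes$strand %in% c("+", "-"))[1]]))
  }
  if (any(genes$tx_start >= genes$tx_end)) abort("tx_start must be < tx_end")
  if (any(genes$cds_start > genes$cds_end |
          genes$cds_start < genes$tx_start | genes$cds_end > genes$tx_end)) {
    abort("CDS must lie within the transcript span")
  }
  for (i in seq_len(nrow(genes))) {
    es <- genes$exon_starts[[i]]; ee <- genes$exon_ends[[i]]
    if (length(es) != genes$exon_count[i] || length(ee) != genes$exon_count[i]) {
      abort(sprintf("gene '%s': exon_count does not match exon block lists", genes$symbol[i]))
    }
    if (any(ee <= es) || is.unsorted(es, strictly = TRUE) || any(es[-1] < ee[-length(ee)]) ||
        es[1] < genes$tx_start[i] || ee[length(ee)] > genes$tx_end[i]) {
      abort(sprintf("gene '%s': exons must be sorted, non-overlapping, within the transcript",
                    genes$symbol[i]))
    }
  }
  invisible(genes)
}

#' Write gene models to a refFlat-like table
#'
#' @param genes Gene model tibble as returned by [read_gene_models()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gene_models <- function(genes, path) {
  lines <- vapply(seq_len(nrow(genes)), function(i) {
    paste(genes$symbol[i], genes$chrom[i], genes$strand[i],
          genes$tx_start[i], genes$tx_end[i], genes$cds_start[i], genes$cds_end[i],
          genes$exon_count[i],
          paste0(paste(genes$exon_starts[[i]], collapse = ","), ","),
          paste0(paste(genes$exon_ends[[i]], collapse = ","), ","),
          sep = "\t")
  }, "")
  readr::write_lines(lines, path)
  invisible(path)
}

#' Read a two-knockdown expression table
#'
#' The table is a headered TSV with columns `symbol`, `lr1`, `p1`, `lr2`,
#' `p2`: per-gene log10 expression ratios (knockdown over control) and their
#' p-values for two independent siRNA knockdowns.
#'
#' @param path Path to the TSV.
#' @return A tibble with those five columns; symbols are whitespace-trimmed.
#' @export
read_expression_table <- function(path) {
  tab <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  need <- c("symbol", "lr1", "p1", "lr2", "p2")
  if (!all(need %in% names(tab))) {
    abort(sprintf("expression table must have columns: %s", paste(need, collapse = ", ")))
  }
  tab <- mutate(select(as_tibble(tab), dplyr::all_of(need)), symbol = trimws(.data$symbol))
  validate_expression(tab)
  tab
}

validate_expression <- function(tab) {
  if (any(!is.finite(tab$lr1)) || any(!is.finite(tab$lr2))) abort("log ratios must be finite")
  if (any(tab$p1 < 0 | tab$p1 > 1 | tab$p2 < 0 | tab$p2 > 1)) {
    abort("p-values must lie in [0, 1]")
  }
  invisible(tab)
}

#' Write an expression table
#' @param tab Expression tibble (see [read_expression_table()]).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_expression_table <- function(tab, path) {
  validate_expression(tab)
  readr::write_tsv(tab, path)
  invisible(path)
}

#' Read a gene set (one symbol per line)
#'
#' Lines starting with `#` are comments; symbols are whitespace-trimmed and
#' matched case-sensitively throughout the package (no alias resolution).
#'
#' @param path Path to the gene-set file.
#' @return A character vector of unique symbols.
#' @export
read_gene_set <- function(path) {
  lines <- trimws(readr::read_lines(path))
  unique(lines[nzchar(lines) & !startsWith(lines, "#")])
}

#' Write a gene set
#' @param genes Character vector of symbols.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gene_set <- function(genes, path) {
  readr::write_lines(unique(trimws(genes)), path)
  invisible(path)
}

#' Read a clinical follow-up table
#'
#' Headered TSV with columns `sample`, `time` (non-negative follow-up time,
#' arbitrary units) and `event` (1 = event observed, 0 = censored).
#'
#' @param path Path to the TSV.
#' @return A tibble with columns `sample`, `time`, `event`.
#' @export
read_clinical <- function(path) {
  tab <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  need <- c("sample", "time", "event")
  if (!all(need %in% names(tab))) {
    abort(sprintf("clinical table must have columns: %s", paste(need, collapse = ", ")))
  }
  tab <- select(as_tibble(tab), dplyr::all_of(need))
  validate_clinical(tab)
  tab
}

validate_clinical <- function(tab) {
  if (any(tab$time < 0)) abort("follow-up time must be non-negative")
  if (any(!tab$event %in% c(0, 1))) abort("event must be 0 (censored) or 1 (event)")
  invisible(tab)
}

#' Write a clinical table
#' @param tab Clinical tibble (see [read_clinical()]).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_clinical <- function(tab, path) {
  validate_clinical(tab)
  readr::write_tsv(tab, path)
  invisible(path)
}

#' Read a genome from FASTA
#'
#' @param path Path to an (uncompressed or gzipped) FASTA file.
#' @return A [Biostrings::DNAStringSet] named by chromosome.
#' @export
read_genome <- function(path) {
  Biostrings::readDNAStringSet(path)
}

#' Write a genome to FASTA
#' @param genome A named [Biostrings::DNAStringSet].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_genome <- function(genome, path) {
  Biostrings::writeXStringSet(genome, path)
  invisible(path)
}

#' Chromosome-length index of a genome
#'
#' Normalises the various ways a genome can be supplied (a `DNAStringSet`,
#' a named length vector, or an index tibble) into a `chrom`/`length` table
#' used for coordinate validation and peak shuffling.
#'
#' @param genome A named [Biostrings::DNAStringSet], a named numeric vector of
#'   chromosome lengths, or a data frame with columns `chrom` and `length`.
#' @return A tibble with columns `chrom` and `length`.
#' @export
genome_index <- function(genome) {
  if (is.data.frame(genome)) {
    stopifnot(all(c("chrom", "length") %in% names(genome)))
    gi <- as_tibble(genome[c("chrom", "length")])
  } else if (methods::is(genome, "DNAStringSet")) {
    gi <- tibble(chrom = names(genome), length = Biostrings::width(genome))
  } else if (is.numeric(genome) && !is.null(names(genome))) {
    gi <- tibble(chrom = names(genome), length = unname(genome))
  } else {
    abort("cannot interpret 'genome' as a genome index")
  }
  gi$length <- as.integer(gi$length)
  stopifnot(!anyDuplicated(gi$chrom), all(gi$length > 0L))
  gi
}

#' Read a genome index from a samtools .fai (or two-column) file
#'
#' Only the first two columns (sequence name, length) are used.
#'
#' @param path Path to the index file.
#' @return A tibble with columns `chrom` and `length`.
#' @export
read_genome_index <- function(path) {
  fields <- strsplit(readr::read_lines(path), "\t", fixed = TRUE)
  fields <- fields[lengths(fields) >= 2L]
  genome_index(tibble(chrom = vapply(fields, `[[`, "", 1L),
                      length = as.integer(vapply(fields, `[[`, "", 2L))))
}
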