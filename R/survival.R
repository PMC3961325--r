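#' Normalise an expression matrix for signature scoring
#'
#' Optionally log2-transforms linear intensities, then mean-centres each
#' sample (column), so after normalisation every sample column has mean zero.
#' Centring is idempotent: normalising twice equals normalising once.
#'
#' @param mat Numeric matrix, genes in rows (rownames = symbols), samples in
#'   columns (colnames = sample ids).
#' @param log2_transform Set `TRUE` when `mat` holds linear intensities;
#'   values must then be strictly positive. Default `FALSE` (values already
#'   on the log2 scale).
#' @return The normalised matrix.
#' @export
normalize_expression <- function(mat, log2_transform = FALSE) {
  stopifnot(is.matrix(mat), is.numeric(mat))
  if (log2_transform) {
    if (any(mat <= 0)) abort("log2 transform requires strictly positive intensities")
    mat <- log2(mat)
  }
  sweep(mat, 2L, colMeans(mat), "-")
}

#' Per-sample mean signature score
#'
#' Scores each sample by the unweighted mean expression of the signature
#' genes present in the matrix. Signature genes absent from the matrix rows
#' are dropped with a warning; at least one must be present.
#'
#' @param mat Normalised expression matrix (see [normalize_expression()]).
#' @param gene_set Character vector of signature gene symbols.
#' @return A tibble with columns `sample` and `score`.
#' @export
signature_score <- function(mat, gene_set) {
  gene_set <- unique(trimws(gene_set))
  present <- intersect(gene_set, rownames(mat))
  if (length(present) == 0L) abort("no signature gene present in the expression matrix")
  if (length(present) < length(gene_set)) {
    warn(sprintf("%d signature gene(s) absent from the matrix were dropped",
                 length(gene_set) - length(present)))
  }
  tibble(sample = colnames(mat),
         score = unname(colMeans(mat[present, , drop = FALSE])))
}

#' Split samples into high and low expressers at the median score
#'
#' Samples scoring strictly above the median are `high`; samples at or below
#' the median are `low` (ties at the median go to the low group). With an
#' even number of samples the median is the midpoint of the two central
#' order statistics.
#'
#' @param scores Tibble with columns `sample` and `score` (see
#'   [signature_score()]).
#' @return The tibble with an added `group` factor (`low`, `high`).
#' @export
median_split <- function(scores) {
  stopifnot(nrow(scores) >= 2)
  if (length(unique(scores$score)) == 1L) {
    abort("all scores identical; median split is degenerate")
  }
  m <- median(scores$score)
  mutate(scores, group = factor(ifelse(.data$score > m, "high", "low"),
                                levels = c("low", "high")))
}

#' Kaplan-Meier survival curve
#'
#' Product-limit estimate `S(t) = prod_(t_j <= t) (1 - d_j / n_j)` over the
#' distinct observed times. Times with only censoring reduce the at-risk
#' count without changing the estimate.
#'
#' @param records Clinical tibble with columns `time` and `event` (see
#'   [read_clinical()]).
#' @return A tibble with one row per distinct observed time: `time`,
#'   `n_risk`, `n_event`, `n_censor`, `survival`.
#' @export
km_estimate <- function(records) {
  stopifnot(nrow(records) >= 1)
  if (any(records$time < 0)) abort("follow-up time must be non-negative")
  if (any(!records$event %in% c(0, 1))) abort("event must be 0 or 1")
  fit <- survival::survfit(survival::Surv(time, event) ~ 1,
                           data = as.data.frame(records[c("time", "event")]))
  tibble(time = fit$time, n_risk = fit$n.risk, n_event = fit$n.event,
         n_censor = fit$n.censor, survival = fit$surv)
}

#' Two-group log-rank test
#'
#' Unweighted (Mantel-Haenszel) log-rank comparison of two survival groups:
#' at each event time the expected events in group 1 are `d * n1 / n` with
#' hypergeometric variance `d (n1/n)(1 - n1/n)(n - d)/(n - 1)`; the statistic
#' `(O1 - E1)^2 / V` is referred to a chi-square with 1 df. Times where only
#' one subject remains contribute no variance and are skipped.
#'
#' @param records_high,records_low Clinical tibbles with `time` and `event`
#'   columns for the two groups; at least one event overall.
#' @return An object of class `logrank_result`: a list with `chisq`, `df`,
#'   `p_value`, and a per-group tibble `groups` (`group`, `n`, `observed`,
#'   `expected`).
#' @export
log_rank_test <- function(records_high, records_low) {
  dat <- bind_rows(
    mutate(records_high[c("time", "event")], group = "high"),
    mutate(records_low[c("time", "event")], group = "low"))
  if (sum(dat$event) < 1) abort("log-rank test requires at least one event")
  sd_fit <- survival::survdiff(survival::Surv(time, event) ~ group,
                               data = as.data.frame(dat))
  chisq <- unname(sd_fit$chisq)
  structure(list(
    chisq = chisq, df = 1L,
    p_value = pchisq(chisq, df = 1, lower.tail = FALSE),
    groups = tibble(group = sub("^group=", "", names(sd_fit$n)),
                    n = as.integer(sd_fit$n),
                    observed = as.numeric(sd_fit$obs),
                    expected = as.numeric(sd_fit$exp))),
    class = "logrank_result")
}

#' @export
print.logrank_result <- function(x, ...) {
  cat(sprintf("Log-rank test: chi-square = %.4f (1 df), p = %.4g\n", x$chisq, x$p_value))
  print(x$groups)
  invisible(x)
}

#' Signature-based survival stratification
#'
#' The full prognostic analysis: normalise the expression matrix, score each
#' sample by mean signature expression, split the cohort at the median
#' score, estimate a Kaplan-Meier curve per group, and compare the groups
#' with the log-rank test.
#'
#' @param mat Expression matrix, genes x samples.
#' @param gene_set Signature gene symbols.
#' @param clinical Clinical tibble with `sample`, `time`, `event`; sample ids
#'   must match the matrix columns exactly (order-free).
#' @param log2_transform Passed to [normalize_expression()].
#' @return An object of class `stratified_survival`: a list with `scores`
#'   (tibble incl. `group`), `km` (per-group KM curves, long format), and
#'   `test` (a `logrank_result`).
#' @export
stratified_survival <- function(mat, gene_set, clinical, log2_transform = FALSE) {
  validate_clinical(clinical)
  if (!setequal(colnames(mat), clinical$sample) ||
      length(clinical$sample) != ncol(mat)) {
    abort("sample ids in the matrix and clinical table must match one-to-one")
  }
  norm <- normalize_expression(mat, log2_transform)
  scores <- median_split(signature_score(norm, gene_set))
  dat <- left_join(scores, clinical, by = "sample")
  if (min(table(dat$group)) < 2) abort("fewer than 2 samples in a group after the median split")
  km <- dat |>
    group_by(.data$group) |>
    dplyr::group_modify(~ km_estimate(.x)) |>
    ungroup()
  test <- log_rank_test(filter(dat, .data$group == "high"),
                        filter(dat, .data$group == "low"))
  structure(list(scores = dat, km = km, test = test),
            class = "stratified_survival")
}

#' @export
print.stratified_survival <- function(x, ...) {
  cat(sprintf("Signature survival stratification: %d samples (%s)\n",
              nrow(x$scores),
              paste(sprintf("%s n=%d", levels(x$scores$group),
                            table(x$scores$group)), collapse = ", ")))
  print(x$test)
  invisible(x)
}
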