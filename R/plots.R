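#' Plot a KS/GSEA running sum
#'
#' Running-sum curve over the ranked list with a rug of hit positions and
#' the enrichment-score extremum marked.
#'
#' @param object A `ks_enrichment` object.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot ks_enrichment
#' @export
autoplot.ks_enrichment <- function(object, ...) {
  run <- object$running
  ggplot2::ggplot(run, ggplot2::aes(x = .data$rank, y = .data$running_sum)) +
    ggplot2::geom_hline(yintercept = 0, colour = "grey70") +
    ggplot2::geom_line() +
    ggplot2::geom_rug(data = run[run$hit, ], sides = "b", length = ggplot2::unit(0.03, "npc")) +
    ggplot2::annotate("point", x = object$es_position, y = object$es, colour = "red") +
    ggplot2::labs(x = "Rank in list", y = "Running enrichment score",
                  title = sprintf("ES = %.3f (%d hits / %d genes)",
                                  object$es, object$n_hits, object$n_genes)) +
    ggplot2::theme_minimal()
}

#' Plot a peak-to-TSS distance profile
#'
#' Observed histogram of signed peak-center-to-nearest-TSS distances, with
#' the permutation-null mean overlaid when available.
#'
#' @param object A `tss_profile` object.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot tss_profile
#' @export
autoplot.tss_profile <- function(object, ...) {
  h <- object$histogram
  p <- ggplot2::ggplot(h, ggplot2::aes(x = .data$mid, y = .data$count)) +
    ggplot2::geom_col(fill = "steelblue", width = diff(object$breaks)[1] * 0.9) +
    ggplot2::labs(x = "Distance from peak center to nearest TSS (bp)",
                  y = "Peaks") +
    ggplot2::theme_minimal()
  if (!is.null(h$null_mean)) {
    p <- p + ggplot2::geom_line(ggplot2::aes(y = .data$null_mean), colour = "red")
  }
  p
}

#' Plot stratified Kaplan-Meier curves
#'
#' Step survival curves for the high and low signature-expression groups,
#' annotated with the log-rank p-value.
#'
#' @param object A `stratified_survival` object.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot stratified_survival
#' @export
autoplot.stratified_survival <- function(object, ...) {
  km <- object$km |>
    group_by(.data$group) |>
    dplyr::group_modify(~ bind_rows(tibble(time = 0, survival = 1),
                                    .x[c("time", "survival")])) |>
    ungroup()
  ggplot2::ggplot(km, ggplot2::aes(x = .data$time, y = .data$survival,
                                   colour = .data$group)) +
    ggplot2::geom_step() +
    ggplot2::scale_colour_manual(values = c(low = "blue", high = "red")) +
    ggplot2::coord_cartesian(ylim = c(0, 1)) +
    ggplot2::labs(x = "Time", y = "Survival",
                  title = sprintf("Log-rank p = %.3g", object$test$p_value)) +
    ggplot2::theme_minimal()
}
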