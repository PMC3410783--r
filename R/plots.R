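# ggplot2 displays for the main result types.

#' Bar chart of expression-pattern counts
#'
#' @param patterns Tibble from [classify_patterns()].
#' @param platform Axis label only.
#' @return A ggplot object.
#' @export
plot_pattern_counts <- function(patterns, platform = "mRNA") {
  counts <- count(patterns, .data$pattern)
  ggplot2::ggplot(counts, ggplot2::aes(x = .data$pattern, y = .data$n)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::labs(x = paste(platform, "expression pattern"),
                  y = "significant probes") +
    ggplot2::theme_minimal()
}

#' Bar chart of top enriched terms, ranked by overlap count
#'
#' @param records Tibble from [top_terms()].
#' @return A ggplot object.
#' @export
plot_top_terms <- function(records) {
  records <- mutate(records,
                    term_id = factor(.data$term_id,
                                     levels = rev(.data$term_id)))
  ggplot2::ggplot(records,
                  ggplot2::aes(x = .data$overlap, y = .data$term_id,
                               fill = -log10(.data$p_value))) +
    ggplot2::geom_col() +
    ggplot2::labs(x = "gene count", y = NULL, fill = "-log10 p") +
    ggplot2::theme_minimal()
}

#' Back-to-back bars comparing term enrichment between two gene lists
#'
#' Mirrors the "differentially affected" presentation: one bar per list per
#' term, terms ordered by the spread of their -log10 p-values.
#'
#' @param comparison Tibble from [compare_term_enrichment()].
#' @param max_n Terms shown (top by spread).
#' @return A ggplot object.
#' @export
plot_enrichment_comparison <- function(comparison, max_n = 10) {
  shown <- dplyr::slice_head(comparison, n = max_n)
  long <- shown %>%
    tidyr::pivot_longer(c("neg_log10_p_a", "neg_log10_p_b"),
                        names_to = "list", values_to = "neg_log10_p") %>%
    mutate(
      list = if_else(.data$list == "neg_log10_p_a", "list A", "list B"),
      term_id = factor(.data$term_id, levels = rev(shown$term_id))
    )
  ggplot2::ggplot(long,
                  ggplot2::aes(x = .data$neg_log10_p, y = .data$term_id,
                               fill = .data$list)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::labs(x = "-log10 p", y = NULL, fill = NULL) +
    ggplot2::theme_minimal()
}

#' @describeIn fit_standard_curve Standard curve with fitted line.
#' @param object A `standard_curve`.
#' @param log10_quantities,ct_values Optionally, the points used for the
#'   fit, to overlay them.
#' @export
autoplot.standard_curve <- function(object, log10_quantities = NULL,
                                    ct_values = NULL, ...) {
  p <- ggplot2::ggplot() +
    ggplot2::geom_abline(slope = object$slope, intercept = object$intercept,
                         colour = "steelblue") +
    ggplot2::labs(
      x = "log10 quantity", y = "CT",
      subtitle = sprintf("slope %.2f, efficiency %.0f%% (%s)",
                         object$slope, 100 * object$efficiency,
                         object$quality)) +
    ggplot2::theme_minimal()
  if (!is.null(log10_quantities)) {
    pts <- tibble(log10_q = log10_quantities, ct = ct_values)
    p <- p + ggplot2::geom_point(
      data = pts, ggplot2::aes(x = .data$log10_q, y = .data$ct))
  }
  p
}
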