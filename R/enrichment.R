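# Hypergeometric gene-set over-representation and the two-list comparison.

#' Construct a gene-set annotation
#'
#' @param terms Named list: term id -> character vector of member genes.
#' @param universe Character vector of all assayable genes (the reference
#'   list — e.g. every gene on the array); must cover all term members.
#' @param descriptions Optional named character vector of term descriptions.
#' @return An `annotation_set` object.
#' @export
annotation_set <- function(terms, universe, descriptions = NULL) {
  if (length(universe) == 0) abort("universe must be nonempty")
  universe <- unique(universe)
  terms <- lapply(terms, unique)
  stray <- setdiff(unique(unlist(terms)), universe)
  if (length(stray) > 0) {
    abort(paste0(length(stray), " term member(s) missing from the universe"))
  }
  if (is.null(descriptions)) {
    descriptions <- setNames(names(terms), names(terms))
  }
  structure(list(terms = terms, universe = universe,
                 descriptions = descriptions),
            class = "annotation_set")
}

#' @export
print.annotation_set <- function(x, ...) {
  cat("<annotation_set>", length(x$terms), "terms over",
      length(x$universe), "genes\n")
  invisible(x)
}

#' Hypergeometric over-representation test per term
#'
#' For each term, tests whether the gene list overlaps the term more than
#' chance under sampling without replacement from the universe:
#' `p = P(X >= overlap)` with `X ~ Hypergeometric(universe, term, list)`.
#' One-sided over-representation only; no multiple-testing correction is
#' applied here because the downstream report filters at nominal p (a BH
#' column can be added with [bh_adjust()] if wanted). Genes outside the
#' universe are dropped from the list with a warning.
#'
#' @param gene_list Character vector of genes of interest.
#' @param annotation An [annotation_set()].
#' @return A tibble: `term_id`, `overlap`, `list_size`, `term_size`,
#'   `universe_size`, `fold_enrichment`, `p_value`.
#' @export
enrich_terms <- function(gene_list, annotation) {
  gene_list <- unique(gene_list)
  outside <- setdiff(gene_list, annotation$universe)
  if (length(outside) > 0) {
    warn(paste0(length(outside), " gene(s) outside the universe dropped"))
    gene_list <- setdiff(gene_list, outside)
  }
  if (length(gene_list) == 0) abort("gene list is empty (after universe filtering)")
  n_univ <- length(annotation$universe)
  n_list <- length(gene_list)
  purrr::imap(annotation$terms, function(members, term) {
    k <- length(intersect(gene_list, members))
    m <- length(members)
    tibble(
      term_id = term,
      overlap = k,
      list_size = n_list,
      term_size = m,
      universe_size = n_univ,
      fold_enrichment = (k / n_list) / (m / n_univ),
      p_value = phyper(k - 1, m, n_univ - m, n_list, lower.tail = FALSE)
    )
  }) %>%
    list_rbind() %>%
    arrange(.data$p_value, .data$term_id)
}

#' Count-ranked top enriched terms
#'
#' Keeps terms with `p < alpha` and orders them by overlap count
#' descending (ties: smaller p first, then term id), truncated to `max_n` —
#' the "top 10 terms ranked by count" presentation convention.
#'
#' @param records Enrichment tibble from [enrich_terms()].
#' @param alpha Nominal significance threshold on the term p-value.
#' @param max_n Number of terms reported.
#' @return The filtered, reordered, truncated tibble.
#' @export
top_terms <- function(records, alpha = 0.05, max_n = 10) {
  records %>%
    filter(.data$p_value < alpha) %>%
    arrange(desc(.data$overlap), .data$p_value, .data$term_id) %>%
    dplyr::slice_head(n = max_n)
}

#' Compare term enrichment between two gene lists
#'
#' Runs the over-representation test on both lists and ranks terms by how
#' differently they are enriched: the spread is the population standard
#' deviation of the two `-log10(p)` values, `|x - y| / 2`. Any positive
#' multiple of `|x - y|` gives the same ordering; the sd-of-two convention
#' is recorded for reproducibility. Terms are returned sorted by spread
#' descending, ready for a diverging bar chart.
#'
#' @param list_a,list_b Two nonempty gene lists (e.g. miRNA-regulated vs
#'   non-miRNA-regulated responsive genes).
#' @param annotation An [annotation_set()].
#' @return A tibble: `term_id`, `neg_log10_p_a`, `neg_log10_p_b`, `spread`.
#' @export
compare_term_enrichment <- function(list_a, list_b, annotation) {
  if (length(list_a) == 0 || length(list_b) == 0) {
    abort("both gene lists must be nonempty")
  }
  a <- enrich_terms(list_a, annotation) %>%
    select("term_id", p_a = "p_value")
  b <- enrich_terms(list_b, annotation) %>%
    select("term_id", p_b = "p_value")
  inner_join(a, b, by = "term_id") %>%
    mutate(
      neg_log10_p_a = -log10(.data$p_a),
      neg_log10_p_b = -log10(.data$p_b),
      spread = abs(.data$neg_log10_p_a - .data$neg_log10_p_b) / 2
    ) %>%
    select("term_id", "neg_log10_p_a", "neg_log10_p_b", "spread") %>%
    arrange(desc(.data$spread), .data$term_id)
}
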