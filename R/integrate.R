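# Anti-correlation x predicted-target miRNA-mRNA pairing.

#' Build anti-correlated miRNA-mRNA candidate pairs
#'
#' Within each hyperoxia contrast group, every miRNA that went up is paired
#' with every mRNA probe that went down in the same group — the
#' anti-correlation heuristic for candidate repression. The pairing is set
#' logic on significance calls, not on correlation coefficients.
#'
#' @param sig_mirna,sig_mrna Significant-set tibbles from
#'   [select_significant()] for the two platforms.
#' @param groups Contrast groups to pair within (the hyperoxia groups B and
#'   C by default).
#' @return A tibble `mirna_id`, `probe_id`, `group`.
#' @export
candidate_pairs <- function(sig_mirna, sig_mrna, groups = c("B", "C")) {
  up <- sig_mirna %>%
    filter(.data$group %in% groups, .data$sign == "up") %>%
    select(mirna_id = "probe_id", "group")
  down <- sig_mrna %>%
    filter(.data$group %in% groups, .data$sign == "down") %>%
    select("probe_id", "group")
  inner_join(up, down, by = "group",
             relationship = "many-to-many") %>%
    select("mirna_id", "probe_id", "group") %>%
    arrange(.data$group, .data$mirna_id, .data$probe_id)
}

#' Intersect candidate pairs with a prediction database
#'
#' Keeps a candidate (miRNA, probe) pair when the probe's gene is among the
#' database's predicted targets of that miRNA. Probes absent from the probe
#' map cannot be looked up and are dropped (their count is recorded, not
#' raised — mirroring how identifier conversion silently loses transcripts).
#' The headline `n_pairs` counts distinct (miRNA, probe) pairs pooled over
#' groups, while `unique_mrnas` counts distinct target genes; both scales
#' are reported because several probes can interrogate one gene.
#'
#' @param candidates Candidate tibble from [candidate_pairs()].
#' @param db Prediction database tibble (`source`, `mirna_id`, `gene_id`).
#' @param probe_map Tibble (`probe_id`, `gene_id`).
#' @return A `pair_set` object; see [tidy.pair_set()] and
#'   [glance.pair_set()].
#' @export
intersect_predictions <- function(candidates, db, probe_map) {
  if (anyDuplicated(probe_map$probe_id)) {
    abort("probe_map must map each probe to exactly one gene")
  }
  source_name <- if (nrow(db) > 0) db$source[1] else "db"
  mapped <- candidates %>% left_join(probe_map, by = "probe_id")
  n_unmapped <- sum(is.na(mapped$gene_id))
  mapped <- filter(mapped, !is.na(.data$gene_id))
  kept <- mapped %>%
    semi_join(db, by = c("mirna_id", "gene_id")) %>%
    arrange(.data$group, .data$mirna_id, .data$probe_id)
  structure(
    list(
      source = source_name,
      pairs = kept,
      n_pairs = nrow(distinct(kept, .data$mirna_id, .data$probe_id)),
      unique_mrnas = sort(unique(kept$gene_id)),
      n_candidates = nrow(candidates),
      n_unmapped = n_unmapped
    ),
    class = "pair_set"
  )
}

#' @export
print.pair_set <- function(x, ...) {
  cat("<pair_set>", x$source, "-", x$n_pairs, "miRNA-mRNA probe pairs,",
      length(x$unique_mrnas), "unique mRNAs\n")
  invisible(x)
}

#' Tidy a pair set
#'
#' @param x A `pair_set`.
#' @param ... Unused.
#' @return The kept pairs as a tibble (`mirna_id`, `probe_id`, `gene_id`,
#'   `group`).
#' @export
tidy.pair_set <- function(x, ...) as_tibble(x$pairs)

#' Summarise a pair set
#'
#' @param x A `pair_set`.
#' @param ... Unused.
#' @return One-row tibble: source, pair and unique-mRNA counts, candidate
#'   and unmapped-probe counts.
#' @export
glance.pair_set <- function(x, ...) {
  tibble(
    source = x$source,
    n_pairs = x$n_pairs,
    n_unique_mrnas = length(x$unique_mrnas),
    n_candidates = x$n_candidates,
    n_unmapped = x$n_unmapped
  )
}

#' Genes called as targets by both databases
#'
#' @param a,b `pair_set` objects built from the same candidates.
#' @return Sorted character vector of shared target gene ids.
#' @export
cross_database_overlap <- function(a, b) {
  sort(intersect(a$unique_mrnas, b$unique_mrnas))
}

#' Per-miRNA expression and predicted-target summary
#'
#' One row per miRNA appearing in the pair set: its mean copy number per
#' cell and the number of distinct predicted target probes retained by the
#' database intersection, sorted by copy number descending. miRNAs lacking
#' a copy-number estimate are kept with `NA` rather than dropped.
#'
#' @param pair_set A `pair_set`.
#' @param copy_numbers Tibble (`mirna_id`, `copies`) of mean copies per
#'   cell, e.g. from [ct_to_copy_number()] on per-miRNA mean CT.
#' @return A tibble `mirna_id`, `mean_copies`, `n_targets`.
#' @export
per_mirna_target_table <- function(pair_set, copy_numbers) {
  tallies <- tidy(pair_set) %>%
    distinct(.data$mirna_id, .data$probe_id) %>%
    count(.data$mirna_id, name = "n_targets")
  tallies %>%
    left_join(copy_numbers, by = "mirna_id") %>%
    rename(mean_copies = "copies") %>%
    select("mirna_id", "mean_copies", "n_targets") %>%
    arrange(desc(.data$mean_copies))
}
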