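#' Simulate the hyperoxia study design
#'
#' Builds the sample layout of a neonatal hyperoxia time-course: room-air
#' (RA) animals at postnatal days P1, P14 and P29 and oxygen-exposed (O2)
#' animals at P14 and P29 only. There is no P1 O2 cell because exposure
#' starts at birth and the first harvest precedes any contrast of interest;
#' the study design this emulates used 2 RA and 3 O2 replicates per cell
#' (12 samples in total).
#'
#' @param reps_ra Replicates per room-air cell (>= 2).
#' @param reps_o2 Replicates per hyperoxia cell (>= 2).
#' @param seed Integer seed; the layout is deterministic but the seed is
#'   recorded so downstream generators can derive their own streams.
#' @return A tibble with columns `sample_id`, `timepoint` (P1/P14/P29),
#'   `treatment` (RA/O2) and `replicate`.
#' @examples
#' simulate_design(2, 3, seed = 7)
#' @export
simulate_design <- function(reps_ra = 2, reps_o2 = 3, seed = 1) {
  if (reps_ra < 2 || reps_o2 < 2) {
    abort("each design cell needs >= 2 replicates (within-cell variance is inestimable otherwise)")
  }
  cells <- tibble(
    timepoint = c("P1", "P14", "P29", "P14", "P29"),
    treatment = c("RA", "RA", "RA", "O2", "O2")
  )
  design <- cells %>%
    mutate(reps = if_else(.data$treatment == "RA", as.integer(reps_ra), as.integer(reps_o2))) %>%
    tidyr::uncount(.data$reps, .id = "replicate") %>%
    mutate(
      replicate = as.integer(.data$replicate),
      sample_id = sprintf("%s_%s_r%d", .data$timepoint, .data$treatment, .data$replicate)
    ) %>%
    select("sample_id", "timepoint", "treatment", "replicate")
  design
}

# Plant assignment shared by the mRNA and miRNA generators. Effects are
# placed so each contrast group's plant is orthogonal to the other two:
#   A (P29-RA vs P14-RA): shift P29.RA *and* P29.O2 (a developmental change
#       present under both treatments, so group C stays null);
#   B (P14-O2 vs P14-RA): shift P14.O2 only;
#   C (P29-O2 vs P29-RA): shift P29.O2 only;
#   BC (shared): shift P14.O2 and P29.O2 with a common sign.
plant_cells <- function(group) {
  switch(group,
    A  = c("P29.RA", "P29.O2"),
    B  = "P14.O2",
    C  = "P29.O2",
    BC = c("P14.O2", "P29.O2"),
    abort(paste0("unknown plant group: ", group))
  )
}

make_plants <- function(ids, n_per_group, n_shared_bc, effect_log2) {
  groups <- c(rep("A", n_per_group), rep("B", n_per_group),
              rep("C", n_per_group), rep("BC", n_shared_bc))
  n_plant <- length(groups)
  if (n_plant > length(ids)) {
    abort("requested plants exceed the number of features; planted sets must be disjoint")
  }
  if (n_plant == 0) {
    return(tibble(feature_id = character(), group = character(),
                  sign = integer(), effect_log2 = double()))
  }
  planted_ids <- sample(ids, n_plant)
  signs <- sample(c(-1L, 1L), n_plant, replace = TRUE)
  tibble(
    feature_id = planted_ids,
    group = groups,
    sign = signs,
    effect_log2 = effect_log2
  )
}

# Per-sample signed shift implied by a plant table (features x samples).
plant_shift_matrix <- function(plants, ids, design) {
  shift <- matrix(0, nrow = length(ids), ncol = nrow(design),
                  dimnames = list(ids, design$sample_id))
  if (nrow(plants) == 0) return(shift)
  cells <- cell_key(design$timepoint, design$treatment)
  for (i in seq_len(nrow(plants))) {
    in_cells <- cells %in% plant_cells(plants$group[i])
    shift[plants$feature_id[i], in_cells] <-
      plants$sign[i] * plants$effect_log2[i]
  }
  shift
}

new_ground_truth <- function(de_mrna = NULL, de_mirna = NULL, edges = NULL,
                             enriched_term = NA_character_, seed = NA_integer_) {
  structure(
    list(de_mrna = de_mrna, de_mirna = de_mirna, edges = edges,
         enriched_term = enriched_term, seed = as.integer(seed)),
    class = "ground_truth"
  )
}

#' @export
print.ground_truth <- function(x, ...) {
  n_mrna <- if (is.null(x$de_mrna)) 0 else nrow(x$de_mrna)
  n_mirna <- if (is.null(x$de_mirna)) 0 else nrow(x$de_mirna)
  n_edges <- if (is.null(x$edges)) 0 else nrow(x$edges)
  cat("<ground_truth>", n_mrna, "planted mRNA effects,", n_mirna,
      "planted miRNA effects,", n_edges, "planted edges\n")
  invisible(x)
}

#' Simulate a log2 mRNA expression matrix with planted differential expression
#'
#' Baseline per-probe means are drawn once, uniform on 4-12 log2 units (the
#' typical dynamic range of an expression array, chosen so a low-expression
#' filter has something to remove); planted probes are shifted by
#' `+/-effect_log2` in the design cells that make them differential in
#' exactly one contrast group (or in both B and C for shared plants), and
#' i.i.d. Gaussian noise with standard deviation `noise_sd` is added on the
#' log2 scale.
#'
#' @param design Design tibble from [simulate_design()].
#' @param n_probes Number of probes.
#' @param n_de_per_group Planted differential probes per contrast group
#'   (A, B, C); the three sets are disjoint.
#' @param effect_log2 Absolute planted shift, log2 units (> 0 unless a pure
#'   null matrix is wanted).
#' @param noise_sd Residual standard deviation, log2 units.
#' @param seed Integer seed.
#' @param n_shared_bc Optional extra probes planted with a common sign in
#'   both B and C cells (the "common to both groups" patterns).
#' @return A list with `matrix` (tibble: `probe_id` + one column per sample)
#'   and `truth` (a `ground_truth` object).
#' @export
simulate_mrna <- function(design, n_probes, n_de_per_group,
                          effect_log2, noise_sd, seed, n_shared_bc = 0) {
  check_design(design)
  if (3 * n_de_per_group + n_shared_bc > n_probes) {
    abort("n_de_per_group x 3 + n_shared_bc must not exceed n_probes (plants are disjoint)")
  }
  set.seed(derive_seed(seed, 11L))
  ids <- sprintf("probe%05d", seq_len(n_probes))
  baseline <- runif(n_probes, 4, 12)
  plants <- make_plants(ids, n_de_per_group, n_shared_bc, effect_log2)
  shift <- plant_shift_matrix(plants, ids, design)
  noise <- matrix(rnorm(n_probes * nrow(design), sd = noise_sd),
                  nrow = n_probes)
  m <- baseline + shift + noise
  dimnames(m) <- list(ids, design$sample_id)
  truth <- new_ground_truth(
    de_mrna = rename(plants, probe_id = "feature_id"),
    seed = seed
  )
  list(matrix = matrix_to_expr(m, "probe_id"), truth = truth)
}

#' Simulate a raw CT table for a TaqMan low-density miRNA array
#'
#' CT values are generated as `u6_ct + baseline dCT - planted shift + noise`,
#' under ideal PCR efficiency: one cycle per two-fold abundance change, so a
#' planted `effect_log2` of +1 lowers CT by exactly one cycle. Baseline dCT
#' values are drawn uniform on 2-12 cycles above U6. A fraction of
#' non-planted miRNAs can be forced above the 35-cycle detection ceiling in
#' every sample to exercise the ceiling rule downstream, and a `U6` control
#' row at `u6_ct` (plus noise) is always included. The generator emits raw
#' CT values; the ceiling itself is applied later by [apply_ct_ceiling()].
#'
#' @inheritParams simulate_mrna
#' @param n_mirnas Number of miRNAs (control row not counted).
#' @param u6_ct Mean CT of the U6 endogenous control, in (0, 40).
#' @param ceiling_fraction Fraction of miRNAs forced above the ceiling in
#'   all samples; drawn from non-planted rows only.
#' @return A list with `ct` (tibble: `mirna_id` + sample columns, including
#'   a `U6` row) and `truth` (a `ground_truth` object).
#' @export
simulate_mirna_ct <- function(design, n_mirnas, n_de_per_group,
                              effect_log2, noise_sd, u6_ct = 20,
                              ceiling_fraction = 0, seed, n_shared_bc = 0) {
  check_design(design)
  if (u6_ct <= 0 || u6_ct >= 40) abort("u6_ct must lie in (0, 40)")
  if (ceiling_fraction < 0 || ceiling_fraction > 1) {
    abort("ceiling_fraction must lie in [0, 1]")
  }
  if (3 * n_de_per_group + n_shared_bc > n_mirnas) {
    abort("n_de_per_group x 3 + n_shared_bc must not exceed n_mirnas")
  }
  set.seed(derive_seed(seed, 23L))
  ids <- sprintf("miR-%04d", seq_len(n_mirnas))
  plants <- make_plants(ids, n_de_per_group, n_shared_bc, effect_log2)

  n_ceiling <- round(ceiling_fraction * n_mirnas)
  free_ids <- setdiff(ids, plants$feature_id)
  if (n_ceiling > length(free_ids)) {
    abort("ceiling_fraction would overwrite planted miRNAs; lower it or plant fewer")
  }
  ceiling_ids <- if (n_ceiling > 0) sample(free_ids, n_ceiling) else character()

  base_dct <- runif(n_mirnas, 2, 12)
  names(base_dct) <- ids
  # Forced rows sit 1.5-4.5 cycles above the 35-cycle ceiling in every sample.
  base_dct[ceiling_ids] <- (36.5 - u6_ct) + runif(n_ceiling, 0, 3)

  shift <- plant_shift_matrix(plants, ids, design)
  noise <- matrix(rnorm(n_mirnas * nrow(design), sd = noise_sd),
                  nrow = n_mirnas)
  ct <- u6_ct + base_dct - shift + noise
  dimnames(ct) <- list(ids, design$sample_id)
  u6_row <- u6_ct + rnorm(nrow(design), sd = noise_sd)
  ct <- rbind(ct, U6 = u6_row)
  truth <- new_ground_truth(
    de_mirna = rename(plants, mirna_id = "feature_id"),
    seed = seed
  )
  list(ct = matrix_to_expr(ct, "mirna_id"), truth = truth)
}

#' Map array probes to gene identifiers
#'
#' Synthetic counterpart of converting transcript identifiers to array probe
#' set identifiers: by default each probe maps to its own gene; setting
#' `probes_per_gene > 1` makes consecutive probes share a gene, reproducing
#' the many-probes-to-one-gene structure of real arrays (probe-level pair
#' counts then exceed unique-gene counts).
#'
#' @param probe_ids Character vector of probe identifiers.
#' @param probes_per_gene Number of consecutive probes sharing one gene.
#' @return A tibble with columns `probe_id`, `gene_id`.
#' @export
simulate_probe_map <- function(probe_ids, probes_per_gene = 1) {
  gene_idx <- (seq_along(probe_ids) - 1L) %/% as.integer(probes_per_gene) + 1L
  tibble(probe_id = probe_ids, gene_id = sprintf("gene%05d", gene_idx))
}

#' Plant miRNA-to-target repression edges consistent with the expression plants
#'
#' For every miRNA planted up-regulated in group B or C (including shared
#' B/C plants), draws up to `targets_per_mirna` target genes from the probes
#' planted down-regulated in the same group, mirroring the biological
#' assumption that an induced miRNA represses its targets in the same
#' condition. The result is the oracle for the anti-correlation x
#' prediction-database integration.
#'
#' @param truth_mirna,truth_mrna `ground_truth` objects from the two
#'   expression generators.
#' @param probe_map Tibble (`probe_id`, `gene_id`).
#' @param targets_per_mirna Targets drawn per (miRNA, group); capped at the
#'   number of available down-regulated probes.
#' @param seed Integer seed.
#' @return A `ground_truth` object combining both plant tables and holding
#'   the edge table (`mirna_id`, `probe_id`, `gene_id`, `group`).
#' @export
simulate_edges <- function(truth_mirna, truth_mrna, probe_map,
                           targets_per_mirna = 5, seed = 1) {
  set.seed(derive_seed(seed, 37L))
  up_mirnas <- truth_mirna$de_mirna %>%
    filter(.data$sign > 0, .data$group %in% c("B", "C", "BC"))
  down_probes <- truth_mrna$de_mrna %>%
    filter(.data$sign < 0, .data$group %in% c("B", "C", "BC"))
  # A shared-BC plant is down in both B and C; expand so same-group matching
  # sees it in either group.
  expand_bc <- function(tbl) {
    bind_rows(
      filter(tbl, .data$group != "BC"),
      tbl %>% filter(.data$group == "BC") %>% mutate(group = "B"),
      tbl %>% filter(.data$group == "BC") %>% mutate(group = "C")
    )
  }
  up_mirnas <- expand_bc(up_mirnas)
  down_probes <- expand_bc(down_probes)
  edges <- purrr::pmap(
    list(up_mirnas$mirna_id, up_mirnas$group),
    function(mid, grp) {
      pool <- down_probes$probe_id[down_probes$group == grp]
      if (length(pool) == 0) return(NULL)
      k <- min(targets_per_mirna, length(pool))
      tibble(mirna_id = mid, probe_id = sample(pool, k), group = grp)
    }
  ) %>% list_rbind()
  if (nrow(edges) > 0) {
    edges <- edges %>%
      left_join(probe_map, by = "probe_id") %>%
      distinct(.data$mirna_id, .data$probe_id, .data$gene_id, .data$group)
  } else {
    edges <- tibble(mirna_id = character(), probe_id = character(),
                    gene_id = character(), group = character())
  }
  new_ground_truth(
    de_mrna = truth_mrna$de_mrna,
    de_mirna = truth_mirna$de_mirna,
    edges = edges,
    seed = truth_mrna$seed
  )
}

#' Simulate a miRNA target-prediction database
#'
#' Emulates a computational target database (miRBase Targets, TargetScan):
#' each true planted edge is included with probability `1 - miss_rate`, and
#' each miRNA additionally receives `decoys_per_mirna` random non-target
#' genes from the universe. No (miRNA, gene) entry is duplicated.
#'
#' @param truth A `ground_truth` with an `edges` table.
#' @param decoys_per_mirna Decoy genes per miRNA.
#' @param miss_rate Probability a true edge is absent from the database.
#' @param universe Character vector of all gene ids (must cover the true
#'   edges' genes).
#' @param seed Integer seed.
#' @param source_name Label stored in the `source` column.
#' @return A tibble with columns `source`, `mirna_id`, `gene_id`.
#' @export
simulate_prediction_db <- function(truth, decoys_per_mirna, miss_rate,
                                   universe, seed, source_name = "db") {
  if (miss_rate < 0 || miss_rate > 1) abort("miss_rate must lie in [0, 1]")
  edges <- truth$edges
  if (is.null(edges)) abort("truth carries no planted edges")
  if (!all(edges$gene_id %in% universe)) {
    abort("universe must contain every gene in the planted edges")
  }
  set.seed(derive_seed(seed, 53L))
  true_edges <- edges %>%
    distinct(.data$mirna_id, .data$gene_id) %>%
    filter(runif(n()) >= miss_rate)
  true_by_mirna <- split(edges$gene_id, edges$mirna_id)
  decoys <- imap(true_by_mirna, function(targets, mid) {
    pool <- setdiff(universe, targets)
    k <- min(decoys_per_mirna, length(pool))
    if (k == 0) return(NULL)
    tibble(mirna_id = mid, gene_id = sample(pool, k))
  }) %>% list_rbind()
  bind_rows(true_edges, decoys) %>%
    distinct(.data$mirna_id, .data$gene_id) %>%
    mutate(source = source_name, .before = 1) %>%
    arrange(.data$mirna_id, .data$gene_id)
}

#' Simulate a gene-set annotation with one planted enrichable term
#'
#' Generates `n_terms` random gene sets over the universe plus one
#' designated term (`TERM_planted`). The planted term carries a bias factor:
#' [simulate_gene_list()] draws its members with `planted_list_bias`-fold
#' higher weight, so enrichment tests have a known top term.
#'
#' @param universe Character vector of gene ids.
#' @param n_terms Number of random (non-planted) terms.
#' @param planted_term_size Size of the planted term (<= length(universe)).
#' @param planted_list_bias Sampling weight multiplier for planted-term
#'   members when composing a biased gene list; 1 means no enrichment.
#' @param seed Integer seed.
#' @return An `annotation_set` object (see [annotation_set()]).
#' @export
simulate_annotation <- function(universe, n_terms, planted_term_size,
                                planted_list_bias = 1, seed = 1) {
  if (planted_term_size > length(universe)) {
    abort("planted_term_size must not exceed the universe size")
  }
  set.seed(derive_seed(seed, 67L))
  planted <- sample(universe, planted_term_size)
  terms <- list(TERM_planted = planted)
  if (n_terms > 0) {
    max_size <- max(2L, min(80L, floor(length(universe) / 2)))
    sizes <- sample(seq(5L, max_size), n_terms, replace = TRUE)
    random_terms <- lapply(sizes, function(k) sample(universe, k))
    names(random_terms) <- sprintf("TERM%04d", seq_len(n_terms))
    terms <- c(terms, random_terms)
  }
  ann <- annotation_set(terms, universe)
  attr(ann, "planted_term") <- "TERM_planted"
  attr(ann, "planted_bias") <- planted_list_bias
  ann
}

#' Draw a gene list biased toward the planted term
#'
#' Samples `n_genes` genes without replacement from the annotation's
#' universe, weighting members of the planted term by the annotation's bias
#' factor. With bias 1 the list is uniform and the planted term behaves like
#' any other.
#'
#' @param annotation An `annotation_set` from [simulate_annotation()].
#' @param n_genes List size.
#' @param seed Integer seed.
#' @return Character vector of gene ids.
#' @export
simulate_gene_list <- function(annotation, n_genes, seed = 1) {
  set.seed(derive_seed(seed, 79L))
  universe <- annotation$universe
  bias <- attr(annotation, "planted_bias") %||% 1
  planted <- annotation$terms[[attr(annotation, "planted_term") %||% ""]]
  w <- rep(1, length(universe))
  w[universe %in% planted] <- bias
  sample(universe, min(n_genes, length(universe)), prob = w)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Simulate a complete planted study
#'
#' One call producing every input the pipeline consumes: design, mRNA
#' matrix, miRNA CT table, probe map, planted edges, two partially
#' overlapping prediction databases and a gene-set annotation, all under a
#' single seed. Defaults reproduce the emulated study conditions: a 12-sample
#' design (2 RA / 3 O2 replicates), 2000 probes with 50 planted effects per
#' contrast group at 2.5 log2 units over noise sd 0.25, and 300 miRNAs with
#' 8 plants per group at 3 log2 units (miRNA fold changes on this platform
#' are large, hence the |4| fold-change gate downstream).
#'
#' @param seed Integer seed driving every generator.
#' @param reps_ra,reps_o2 Replicates per normoxia / hyperoxia cell.
#' @param n_probes,n_mrna_de,mrna_effect,mrna_sd mRNA generator settings.
#' @param n_mirnas,n_mirna_de,mirna_effect,mirna_sd miRNA generator settings.
#' @param n_shared_bc Shared B/C plants per platform.
#' @param u6_ct,ceiling_fraction CT generator settings.
#' @param targets_per_mirna Planted targets per induced miRNA.
#' @param decoys_per_mirna,miss_rate_a,miss_rate_b Prediction-database noise.
#' @param n_terms,planted_term_size,planted_list_bias Annotation settings.
#' @return A list: `design`, `mrna`, `ct`, `probe_map`, `truth`,
#'   `db_a`, `db_b`, `annotation`, `seed`.
#' @export
simulate_study <- function(seed = 1,
                           reps_ra = 2, reps_o2 = 3,
                           n_probes = 2000, n_mrna_de = 50,
                           mrna_effect = 2.5, mrna_sd = 0.25,
                           n_mirnas = 300, n_mirna_de = 8,
                           mirna_effect = 3, mirna_sd = 0.25,
                           n_shared_bc = 10,
                           u6_ct = 20, ceiling_fraction = 0.2,
                           targets_per_mirna = 5,
                           decoys_per_mirna = 20,
                           miss_rate_a = 0, miss_rate_b = 0.3,
                           n_terms = 50, planted_term_size = 40,
                           planted_list_bias = 5) {
  design <- simulate_design(reps_ra, reps_o2, seed)
  mrna <- simulate_mrna(design, n_probes, n_mrna_de, mrna_effect, mrna_sd,
                        seed, n_shared_bc = n_shared_bc)
  n_shared_mirna <- min(n_shared_bc, max(0L, n_mirnas - 3L * n_mirna_de))
  mirna <- simulate_mirna_ct(design, n_mirnas, n_mirna_de, mirna_effect,
                             mirna_sd, u6_ct = u6_ct,
                             ceiling_fraction = ceiling_fraction,
                             seed = seed,
                             n_shared_bc = min(4L, n_shared_mirna))
  probe_map <- simulate_probe_map(mrna$matrix$probe_id)
  truth <- simulate_edges(mirna$truth, mrna$truth, probe_map,
                          targets_per_mirna = targets_per_mirna, seed = seed)
  universe <- unique(probe_map$gene_id)
  db_a <- simulate_prediction_db(truth, decoys_per_mirna, miss_rate_a,
                                 universe, derive_seed(seed, 101L),
                                 source_name = "dbA")
  db_b <- simulate_prediction_db(truth, decoys_per_mirna, miss_rate_b,
                                 universe, derive_seed(seed, 103L),
                                 source_name = "dbB")
  annotation <- simulate_annotation(universe, n_terms, planted_term_size,
                                    planted_list_bias, seed)
  list(design = design, mrna = mrna$matrix, ct = mirna$ct,
       probe_map = probe_map, truth = truth,
       db_a = db_a, db_b = db_b, annotation = annotation,
       seed = as.integer(seed))
}
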