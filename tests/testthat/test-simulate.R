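test_that("study design has the hyperoxia layout and replicate structure", {
  d <- simulate_design(2, 3, seed = 7)
  expect_equal(nrow(d), 12)
  cells <- dplyr::count(d, timepoint, treatment)
  expect_equal(nrow(cells), 5)
  expect_false(any(cells$timepoint == "P1" & cells$treatment == "O2"))
  expect_equal(cells$n[cells$treatment == "RA"], rep(2L, 3))
  expect_equal(cells$n[cells$treatment == "O2"], rep(3L, 2))
  expect_false(anyDuplicated(d$sample_id) > 0)

  expect_equal(nrow(simulate_design(2, 2, seed = 1)), 10)
  expect_identical(simulate_design(2, 3, seed = 5), simulate_design(2, 3, seed = 5))
  expect_error(simulate_design(1, 3, seed = 1), "2 replicates")
})

test_that("mRNA generator plants the requested effects and nothing else", {
  d <- tiny_design()
  sim <- simulate_mrna(d, n_probes = 2000, n_de_per_group = 50,
                       effect_log2 = 2, noise_sd = 0.25, seed = 3)
  expect_equal(nrow(sim$truth$de_mrna), 150)
  expect_equal(as.vector(table(sim$truth$de_mrna$group)[c("A", "B", "C")]),
               rep(50L, 3))
  expect_false(anyDuplicated(sim$truth$de_mrna$probe_id) > 0)
  expect_true(all(sim$truth$de_mrna$effect_log2 > 0))

  # determinism: bit-identical under the same seed
  sim2 <- simulate_mrna(d, 2000, 50, 2, 0.25, seed = 3)
  expect_identical(sim$matrix, sim2$matrix)
  expect_identical(sim$truth$de_mrna, sim2$truth$de_mrna)

  expect_error(simulate_mrna(d, 100, 40, 2, 0.25, seed = 1), "disjoint")
})

test_that("zero planted effect yields a pure-null matrix with nonempty truth", {
  d <- tiny_design()
  sim <- simulate_mrna(d, 200, 10, effect_log2 = 0, noise_sd = 0.3, seed = 9)
  expect_equal(nrow(sim$truth$de_mrna), 30)
  m <- as.matrix(sim$matrix[-1])
  cells <- paste(d$timepoint, d$treatment, sep = ".")
  b_diff <- rowMeans(m[, cells == "P14.O2"]) - rowMeans(m[, cells == "P14.RA"])
  planted_b <- sim$matrix$probe_id %in%
    sim$truth$de_mrna$probe_id[sim$truth$de_mrna$group == "B"]
  # planted probes carry no shift when effect is zero
  expect_lt(max(abs(b_diff[planted_b])), 4 * 0.3)
})

test_that("planted group-B cell-mean difference matches the effect size", {
  d <- tiny_design()
  errs <- vapply(1:40, function(s) {
    sim <- simulate_mrna(d, 300, 10, effect_log2 = 2, noise_sd = 0.25, seed = s)
    m <- as.matrix(sim$matrix[-1])
    rownames(m) <- sim$matrix$probe_id
    cells <- paste(d$timepoint, d$treatment, sep = ".")
    plants <- dplyr::filter(sim$truth$de_mrna, group == "B")
    diff <- rowMeans(m[plants$probe_id, cells == "P14.O2", drop = FALSE]) -
      rowMeans(m[plants$probe_id, cells == "P14.RA", drop = FALSE])
    max(abs(diff - plants$sign * 2))
  }, 0)
  # each cell mean has sd <= noise_sd/sqrt(2); allow 3 sd on the difference
  expect_lt(stats::median(errs), 3 * 0.25 * sqrt(1 / 2 + 1 / 3))
  # and plants never leak into the group-A contrast
  sim <- simulate_mrna(d, 300, 10, effect_log2 = 2, noise_sd = 0.25, seed = 1)
  m <- as.matrix(sim$matrix[-1]); rownames(m) <- sim$matrix$probe_id
  cells <- paste(d$timepoint, d$treatment, sep = ".")
  b_ids <- sim$truth$de_mrna$probe_id[sim$truth$de_mrna$group == "B"]
  a_diff <- rowMeans(m[b_ids, cells == "P29.RA", drop = FALSE]) -
    rowMeans(m[b_ids, cells == "P14.RA", drop = FALSE])
  expect_lt(max(abs(a_diff)), 4 * 0.25)
})

test_that("CT generator encodes one cycle per two-fold change and a U6 row", {
  d <- tiny_design()
  sim <- simulate_mirna_ct(d, 100, 5, effect_log2 = 1, noise_sd = 0.2,
                           u6_ct = 20, seed = 4)
  expect_equal(sum(sim$ct$mirna_id == "U6"), 1)

  # planted 2-fold-up miRNA sits ~1 cycle lower in its effect cells
  shifts <- vapply(1:30, function(s) {
    sim <- simulate_mirna_ct(d, 100, 5, effect_log2 = 1, noise_sd = 0.2,
                             u6_ct = 20, seed = s)
    m <- as.matrix(sim$ct[-1]); rownames(m) <- sim$ct$mirna_id
    cells <- paste(d$timepoint, d$treatment, sep = ".")
    plants <- dplyr::filter(sim$truth$de_mirna, group == "B", sign > 0)
    if (nrow(plants) == 0) return(NA_real_)
    mean(rowMeans(m[plants$mirna_id, cells == "P14.RA", drop = FALSE]) -
           rowMeans(m[plants$mirna_id, cells == "P14.O2", drop = FALSE]))
  }, 0)
  expect_equal(mean(shifts, na.rm = TRUE), 1, tolerance = 0.1)

  expect_error(simulate_mirna_ct(d, 50, 2, 1, 0.2, u6_ct = 45, seed = 1),
               "u6_ct")
})

test_that("forced ceiling rows are constant 35 after the ceiling rule", {
  d <- tiny_design()
  sim <- simulate_mirna_ct(d, 50, 0, effect_log2 = 1, noise_sd = 0.2,
                           u6_ct = 20, ceiling_fraction = 1, seed = 2)
  clamped <- apply_ct_ceiling(sim$ct)
  m <- as.matrix(clamped[-1]); rownames(m) <- clamped$mirna_id
  non_control <- m[rownames(m) != "U6", ]
  expect_true(all(non_control == 35))
})

test_that("prediction databases contain true edges minus misses plus decoys", {
  study <- simulate_study(seed = 11, n_probes = 400, n_mrna_de = 20,
                          n_mirnas = 60, n_mirna_de = 5, n_shared_bc = 0,
                          n_terms = 5)
  truth <- study$truth
  universe <- unique(study$probe_map$gene_id)

  exact <- simulate_prediction_db(truth, decoys_per_mirna = 0, miss_rate = 0,
                                  universe = universe, seed = 1, source_name = "x")
  expect_setequal(
    paste(exact$mirna_id, exact$gene_id),
    unique(paste(truth$edges$mirna_id, truth$edges$gene_id)))

  none <- simulate_prediction_db(truth, decoys_per_mirna = 5, miss_rate = 1,
                                 universe = universe, seed = 1, source_name = "y")
  expect_equal(
    length(intersect(paste(none$mirna_id, none$gene_id),
                     paste(truth$edges$mirna_id, truth$edges$gene_id))), 0)

  db1 <- simulate_prediction_db(truth, 10, 0.3, universe, seed = 5, source_name = "a")
  db2 <- simulate_prediction_db(truth, 10, 0.3, universe, seed = 6, source_name = "b")
  k1 <- paste(db1$mirna_id, db1$gene_id); k2 <- paste(db2$mirna_id, db2$gene_id)
  ov <- length(intersect(k1, k2))
  expect_gt(ov, 0)                      # share surviving true edges
  expect_lt(ov, min(length(k1), length(k2)))  # but differ through decoys/misses
  expect_false(anyDuplicated(k1) > 0)
})

test_that("planted edges link up-miRNAs to down-genes within the same group", {
  study <- simulate_study(seed = 3, n_probes = 500, n_mrna_de = 25,
                          n_mirnas = 80, n_mirna_de = 6, n_terms = 5)
  edges <- study$truth$edges
  expect_gt(nrow(edges), 0)
  mir <- study$truth$de_mirna
  mrna <- study$truth$de_mrna
  for (i in seq_len(nrow(edges))) {
    mg <- mir[mir$mirna_id == edges$mirna_id[i], ]
    pg <- mrna[mrna$probe_id == edges$probe_id[i], ]
    expect_true(mg$sign > 0 && mg$group %in% c("B", "C", "BC"))
    expect_true(pg$sign < 0)
    expect_true(edges$group[i] %in% c(pg$group, if (pg$group == "BC") c("B", "C")))
  }
})

test_that("annotation generator plants a designated term", {
  universe <- sprintf("g%03d", 1:300)
  ann <- simulate_annotation(universe, n_terms = 0, planted_term_size = 30,
                             planted_list_bias = 4, seed = 2)
  expect_equal(names(ann$terms), "TERM_planted")
  expect_equal(length(ann$terms$TERM_planted), 30)
  ann2 <- simulate_annotation(universe, n_terms = 10, planted_term_size = 30,
                              planted_list_bias = 4, seed = 2)
  expect_equal(length(ann2$terms), 11)
  expect_error(simulate_annotation(universe[1:10], 2, 30, 1, 1), "universe")
})
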