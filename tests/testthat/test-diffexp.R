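make_expr <- function(m, design) {
  dplyr::bind_cols(tibble::tibble(probe_id = rownames(m)),
                   tibble::as_tibble(m))
}

test_that("cell-means fit recovers noise-free means and flags degeneracy", {
  d <- tiny_design()
  cells <- paste(d$timepoint, d$treatment, sep = ".")
  mu <- c(P1.RA = 1, P14.RA = 2, P29.RA = 3, P14.O2 = 4, P29.O2 = 5)
  m <- matrix(mu[cells], nrow = 1, dimnames = list("p1", d$sample_id))
  fit <- fit_cell_means(make_expr(m, d), d)
  expect_equal(sort(fit$means[1, ]), sort(mu))
  expect_equal(fit$s2, c(p1 = 0))
  expect_equal(fit$df, 7)
  res <- test_contrasts(fit)
  expect_true(all(res$degenerate))
  expect_true(all(is.na(res$p_raw)))
})

test_that("pooled variance and contrast p agree with the sums-of-squares oracle", {
  d <- tiny_design()
  set.seed(10)
  m <- matrix(rnorm(20 * 12, mean = 8), nrow = 20,
              dimnames = list(sprintf("p%02d", 1:20), d$sample_id))
  fit <- fit_cell_means(make_expr(m, d), d)
  res <- test_contrasts(fit)
  specs <- contrast_groups()
  for (i in seq_len(nrow(specs))) {
    num <- paste(specs$num_timepoint[i], specs$num_treatment[i], sep = ".")
    den <- paste(specs$den_timepoint[i], specs$den_treatment[i], sep = ".")
    for (pr in rownames(m)) {
      o <- oracle_contrast(m[pr, ], d, num, den)
      row <- res[res$probe_id == pr & res$group == specs$group[i], ]
      expect_equal(row$log2_diff, o$diff, tolerance = 1e-10)
      expect_equal(row$p_raw, o$p, tolerance = 1e-10)
    }
  }
  # pooled variance equals the df-weighted mean of per-cell variances
  cells <- paste(d$timepoint, d$treatment, sep = ".")
  per_cell_var <- sapply(split(m[1, d$sample_id], cells), var)
  per_cell_n <- sapply(split(m[1, d$sample_id], cells), length)
  expect_equal(unname(fit$s2[1]),
               sum((per_cell_n - 1) * per_cell_var) / sum(per_cell_n - 1))
})

test_that("equal cell means give p = 1 and planted shifts give tiny p", {
  d <- tiny_design()
  m <- matrix(5, nrow = 1, ncol = 12, dimnames = list("flat", d$sample_id))
  m[1, 1:6] <- 5 + c(-1, 1, -1, 1, -1, 1) * 0.3  # equalize means, keep variance
  cells <- paste(d$timepoint, d$treatment, sep = ".")
  for (cl in unique(cells)) {  # recentre each cell to exactly 5
    idx <- which(cells == cl)
    m[1, idx] <- m[1, idx] - mean(m[1, idx]) + 5
  }
  res <- test_contrasts(fit_cell_means(make_expr(m, d), d))
  expect_equal(res$log2_diff, rep(0, 3))
  expect_equal(res$p_raw, rep(1, 3))

  set.seed(2)
  m2 <- matrix(rnorm(12, 6, 0.25), nrow = 1,
               dimnames = list("shift", d$sample_id))
  m2[1, cells == "P14.O2"] <- m2[1, cells == "P14.O2"] + 2
  res2 <- test_contrasts(fit_cell_means(make_expr(m2, d), d))
  expect_lt(res2$p_raw[res2$group == "B"], 1e-4)
})

test_that("signed fold change follows the reciprocal-negative convention", {
  expect_equal(signed_fold_change(c(1, -1, 0, 2.5)),
               c(2, -2, 1, 2^2.5))
  expect_true(all(abs(signed_fold_change(seq(-5, 5, 0.1))) >= 1))
})

test_that("BH adjustment matches hand step-up computations", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_adjust(0.03), 0.03)
  expect_equal(bh_adjust(c(0.005, 0.5)), c(0.01, 0.5))
  set.seed(3)
  for (i in 1:20) {
    p <- runif(sample(5:50, 1))^2
    expect_equal(bh_adjust(p), oracle_bh(p))
  }
  expect_error(bh_adjust(c(0.1, 0)), "p-values")
})

test_that("derived raw-p cutoff reproduces the q <= FDR selection", {
  expect_equal(bh_p_cutoff(c(0.001, 0.01, 0.02, 0.2, 0.5), 0.05), 0.02)
  expect_equal(bh_p_cutoff(c(0.9, 0.8), 0.05), 0)
  set.seed(4)
  for (i in 1:50) {
    p <- runif(200)^sample(1:3, 1)
    cut <- bh_p_cutoff(p, 0.05)
    expect_identical(p <= cut, bh_adjust(p) <= 0.05)
  }
})

test_that("significance selection applies both gates and is monotone", {
  res <- tibble::tibble(
    probe_id = c("a", "b", "c", "d"),
    group = "B",
    log2_diff = c(log2(5), log2(1.5), -2, 1.5),
    signed_fc = signed_fold_change(log2_diff),
    p_raw = c(0.1, 1e-5, 1e-5, 1e-4),
    q_bh = c(0.2, 0.001, 0.001, 0.01),
    degenerate = FALSE
  )
  sig <- select_significant(res, fc_cutoff = 2, fdr = 0.05)
  expect_setequal(sig$probe_id, c("c", "d"))   # a fails FDR, b fails FC
  expect_equal(sig$sign[sig$probe_id == "c"], "down")

  stricter_fc <- select_significant(res, fc_cutoff = 3, fdr = 0.05)
  stricter_q <- select_significant(res, fc_cutoff = 2, fdr = 0.005)
  expect_true(all(stricter_fc$probe_id %in% sig$probe_id))
  expect_true(all(stricter_q$probe_id %in% sig$probe_id))
})

test_that("pattern classification follows the per-platform numbering", {
  sig <- tibble::tibble(
    group = c("A", "A", "B", "B", "C", "C", "B", "C", "B", "C", "A", "B"),
    probe_id = c("a_up", "a_dn", "b_up", "b_dn", "c_up", "c_dn",
                 "bc_up", "bc_up", "bc_dis", "bc_dis", "ab", "ab"),
    sign = c("up", "down", "up", "down", "up", "down",
             "up", "up", "up", "down", "up", "down")
  )
  pat <- classify_patterns(sig, "mRNA")
  lab <- setNames(pat$pattern, pat$probe_id)
  expect_equal(lab[["a_up"]], "1")
  expect_equal(lab[["a_dn"]], "2")
  expect_equal(lab[["b_up"]], "3")
  expect_equal(lab[["b_dn"]], "4")
  expect_equal(lab[["bc_up"]], "5")
  expect_equal(lab[["c_up"]], "7")
  expect_equal(lab[["c_dn"]], "8")
  expect_equal(lab[["bc_dis"]], "discordant")
  expect_equal(lab[["ab"]], "4")  # hyperoxia membership outranks group A

  pat2 <- classify_patterns(sig, "miRNA")
  lab2 <- setNames(pat2$pattern, pat2$probe_id)
  expect_equal(lab2[["a_up"]], "2")   # miRNA numbering flips group A
  expect_equal(lab2[["a_dn"]], "1")
  expect_equal(lab2[["bc_up"]], "5")
  expect_equal(lab2[["c_up"]], "6")
  expect_equal(lab2[["c_dn"]], "discordant")  # no printed pattern: audit bucket
  # one label per significant probe
  expect_setequal(pat$probe_id, unique(sig$probe_id))
  expect_false(anyDuplicated(pat$probe_id) > 0)
})

test_that("expected_pattern maps plants to their platform labels", {
  plants <- tibble::tibble(group = c("A", "A", "B", "BC", "C"),
                           sign = c(1, -1, 1, 1, -1))
  expect_equal(expected_pattern(plants, "mRNA"), c("1", "2", "3", "5", "8"))
  expect_equal(expected_pattern(plants, "miRNA"), c("2", "1", "3", "5", NA))
})

test_that("delta-CT orientation makes induced miRNAs positive", {
  dct <- tibble::tibble(mirna_id = "m", s1 = 4, s2 = 2)
  expr <- delta_ct_to_expression(dct)
  expect_equal(unlist(expr[1, -1], use.names = FALSE), c(-4, -2))
})
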