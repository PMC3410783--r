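# Independent oracles used across tests: everything here is computed by
# brute force / enumeration, never by calling the code paths under test.

# Pooled-variance two-sample t-test from raw sample values, written as
# explicit sums of squares over all design cells.
oracle_contrast <- function(values, design, num_cell, den_cell) {
  cells <- paste(design$timepoint, design$treatment, sep = ".")
  split_vals <- split(values[design$sample_id], cells)
  sse <- sum(vapply(split_vals, function(v) sum((v - mean(v))^2), 0))
  df <- length(values) - length(split_vals)
  s2 <- sse / df
  v1 <- split_vals[[num_cell]]
  v2 <- split_vals[[den_cell]]
  diff <- mean(v1) - mean(v2)
  tt <- diff / sqrt(s2 * (1 / length(v1) + 1 / length(v2)))
  list(diff = diff, p = 2 * stats::pt(-abs(tt), df))
}

# Naive triple-loop candidate x database intersection.
oracle_intersection <- function(candidates, db, probe_map) {
  gene_of <- stats::setNames(probe_map$gene_id, probe_map$probe_id)
  kept <- list()
  for (i in seq_len(nrow(candidates))) {
    m <- candidates$mirna_id[i]
    p <- candidates$probe_id[i]
    g <- unname(gene_of[p])
    if (is.na(g)) next
    hit <- FALSE
    for (j in seq_len(nrow(db))) {
      if (db$mirna_id[j] == m && db$gene_id[j] == g) { hit <- TRUE; break }
    }
    if (hit) kept[[length(kept) + 1L]] <- data.frame(
      mirna_id = m, probe_id = p, gene_id = g, group = candidates$group[i])
  }
  if (length(kept) == 0) {
    return(data.frame(mirna_id = character(), probe_id = character(),
                      gene_id = character(), group = character()))
  }
  do.call(rbind, kept)
}

# Exhaustive hypergeometric upper tail: enumerate every n-subset of a
# universe of size N containing K marked elements and count draws with
# overlap >= k. Only feasible for small N.
oracle_hyper_p <- function(N, K, n, k) {
  draws <- utils::combn(N, n)
  marked <- seq_len(K)
  hits <- apply(draws, 2, function(d) sum(d %in% marked))
  mean(hits >= k)
}

# Hand step-up BH adjustment (independent of stats::p.adjust).
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p, decreasing = TRUE)
  ro <- order(o)
  pmin(1, cummin(m / (m:1) * p[o]))[ro]
}

tiny_design <- function() simulate_design(2, 3, seed = 1)

# The exact study behind the packaged demo config, regenerated from it.
run_demo_study <- function() {
  cfg <- read_run_config(system.file("extdata", "demo_config.yaml",
                                     package = "oxymir"))
  do.call(simulate_study, c(list(seed = cfg$seed), cfg$synthetic))
}
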