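# Cross-sample normalisation and probe filtering for the log2 mRNA matrix.

#' Quantile-normalise an expression matrix
#'
#' Forces every sample (column) onto the same empirical distribution: each
#' column's sorted values are replaced by the across-column mean of the
#' order statistics. Ties within a column receive the mean of their tied
#' ranks' reference values, which makes the procedure deterministic and
#' idempotent. This is the across-array normalisation core of standard
#' array preprocessing (the probe-level background model is out of scope
#' here; inputs are probe-set-level log2 values).
#'
#' @param expr_tbl Tibble: `probe_id` column plus one numeric column per
#'   sample (>= 2 samples).
#' @return Tibble of the same shape with normalised values.
#' @examples
#' m <- tibble::tibble(probe_id = c("a", "b", "c"), s1 = c(1, 2, 3), s2 = c(4, 5, 6))
#' quantile_normalize(m)
#' @export
quantile_normalize <- function(expr_tbl) {
  m <- expr_to_matrix(expr_tbl)
  if (!all(is.finite(m))) abort("expression values must be finite")
  if (ncol(m) < 2) {
    warn("single-column matrix: quantile normalization is the identity")
    return(expr_tbl)
  }
  ranks <- apply(m, 2, rank, ties.method = "average")
  sorted <- apply(m, 2, sort)
  reference <- rowMeans(sorted)
  # Interpolate the reference at (possibly fractional) average ranks so
  # tied values get the mean of their tied ranks' reference values.
  normed <- apply(ranks, 2, function(r) {
    lo <- floor(r); hi <- ceiling(r)
    (reference[lo] + reference[hi]) / 2
  })
  dimnames(normed) <- dimnames(m)
  out <- matrix_to_expr(normed, names(expr_tbl)[1])
  names(out) <- names(expr_tbl)
  out
}

#' Remove probes with low expression everywhere
#'
#' Drops probes whose maximum log2 value across all samples falls below
#' `min_log2` — i.e. probes low at every time point under every treatment,
#' which carry no usable signal for the contrasts. Probe order is preserved.
#'
#' @param expr_tbl Expression tibble.
#' @param min_log2 Retention threshold on the per-probe maximum (log2
#'   units). The default 5.0 sits in the lower quarter of a typical 4-12
#'   log2 array range.
#' @return Filtered tibble.
#' @export
filter_low_expression <- function(expr_tbl, min_log2 = 5) {
  m <- expr_to_matrix(expr_tbl)
  keep <- apply(m, 1, max) >= min_log2
  if (!any(keep)) {
    abort("low-expression filter removed every probe; lower min_log2")
  }
  expr_tbl[keep, , drop = FALSE]
}
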