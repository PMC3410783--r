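# TaqMan low-density-array CT processing: ceiling rule, U6 normalisation,
# absolute copy-number conversion, detection calls.

#' Quantification constants for TaqMan array CT data
#'
#' The conventional constants of TLDA miRNA quantification: undetectable or
#' late signals are clamped at 35 cycles; 40 cycles is the run length; copy
#' number per cell is `10^((40 - CT) / 3.34) / 22`, a formula whose slope
#' (3.34 cycles per 10-fold) encodes near-ideal PCR efficiency
#' (10^(1/3.34) is approximately 2) and whose divisor 22 folds in the
#' assumption of 30 pg total RNA per cell. The 30 pg figure is carried as
#' provenance only; it is already embodied in the divisor.
#'
#' @param ceiling_ct Detection ceiling, cycles.
#' @param max_cycles Total PCR cycles run.
#' @param log10_slope Cycles per 10-fold abundance change.
#' @param per_cell_divisor Divisor converting the exponential term to copies
#'   per cell.
#' @param rna_per_cell_pg Assumed total RNA per cell (metadata).
#' @return A named list of class `quant_constants`.
#' @export
quant_constants <- function(ceiling_ct = 35, max_cycles = 40,
                            log10_slope = 3.34, per_cell_divisor = 22,
                            rna_per_cell_pg = 30) {
  stopifnot(ceiling_ct > 0, max_cycles > 0, log10_slope > 0,
            per_cell_divisor > 0, rna_per_cell_pg > 0,
            ceiling_ct < max_cycles)
  structure(
    list(ceiling_ct = ceiling_ct, max_cycles = max_cycles,
         log10_slope = log10_slope, per_cell_divisor = per_cell_divisor,
         rna_per_cell_pg = rna_per_cell_pg),
    class = "quant_constants"
  )
}

#' Clamp CT values at the detection ceiling
#'
#' Every CT above the ceiling, and every undetected well (`NA`, coming from
#' empty fields or "Undetermined" in instrument exports), is replaced by the
#' ceiling value (35 cycles by default), the standard TLDA convention.
#' Values at or below the ceiling pass through unchanged.
#'
#' @param ct_tbl Tibble: `mirna_id` column plus one numeric column per
#'   sample; `NA` marks undetected wells.
#' @param constants A [quant_constants()] list.
#' @return The table with all values finite and `<= ceiling_ct`.
#' @examples
#' tbl <- tibble::tibble(mirna_id = c("miR-1", "U6"), s1 = c(37.2, 20), s2 = c(NA, 20.1))
#' apply_ct_ceiling(tbl)
#' @export
apply_ct_ceiling <- function(ct_tbl, constants = quant_constants()) {
  m <- expr_to_matrix(ct_tbl)
  if (any(m < 0, na.rm = TRUE)) abort("negative CT values are invalid")
  m[is.na(m)] <- constants$ceiling_ct
  m[m > constants$ceiling_ct] <- constants$ceiling_ct
  out <- matrix_to_expr(m, names(ct_tbl)[1])
  names(out) <- names(ct_tbl)
  out
}

#' Normalise CT values against an endogenous control (delta-CT)
#'
#' Subtracts the control row's CT from every miRNA's CT within each sample:
#' `dCT = CT_miRNA - CT_control`. Higher dCT means lower expression. The
#' control row (U6 small nuclear RNA on rodent miRNA arrays) is removed from
#' the output.
#'
#' @param ct_tbl CT tibble (ceiling already applied if desired).
#' @param control_id Row id of the endogenous control.
#' @return Tibble of dCT values, control row excluded.
#' @export
normalize_delta_ct <- function(ct_tbl, control_id = "U6") {
  ids <- ct_tbl[[1]]
  hits <- sum(ids == control_id)
  if (hits == 0) {
    abort(paste0("control row '", control_id, "' not found in CT table"))
  }
  if (hits > 1) {
    abort(paste0("control row '", control_id, "' appears ", hits, " times"))
  }
  m <- expr_to_matrix(ct_tbl)
  control <- m[control_id, ]
  dct <- sweep(m[ids != control_id, , drop = FALSE], 2, control, "-")
  out <- matrix_to_expr(dct, names(ct_tbl)[1])
  names(out) <- names(ct_tbl)
  out
}

#' Convert CT values to absolute copy number per cell
#'
#' Applies `copies = 10^((40 - CT) / 3.34) / 22` (constants configurable via
#' [quant_constants()]). The function is strictly decreasing in CT, and a
#' 3.34-cycle decrease multiplies the estimate by exactly 10.
#'
#' @param ct Numeric vector of CT values in `(0, max_cycles]`.
#' @param constants A [quant_constants()] list.
#' @return Copies per cell (positive numeric, same length as `ct`).
#' @examples
#' ct_to_copy_number(c(40, 36.66, 20.91))
#' @export
ct_to_copy_number <- function(ct, constants = quant_constants()) {
  if (any(!is.finite(ct)) || any(ct <= 0) || any(ct > constants$max_cycles)) {
    abort(paste0("CT values must lie in (0, ", constants$max_cycles, "]"))
  }
  10^((constants$max_cycles - ct) / constants$log10_slope) /
    constants$per_cell_divisor
}

#' Inverse of [ct_to_copy_number()]
#'
#' @param copies Positive copies-per-cell values.
#' @inheritParams ct_to_copy_number
#' @return CT values.
#' @export
copy_number_to_ct <- function(copies, constants = quant_constants()) {
  if (any(copies <= 0)) abort("copies must be positive")
  constants$max_cycles -
    constants$log10_slope * log10(copies * constants$per_cell_divisor)
}

#' Call detected miRNAs
#'
#' A miRNA counts as detected if its raw CT is strictly below the ceiling in
#' at least `min_fraction` of the samples of at least one design cell
#' (timepoint x treatment). The fraction default of 0.5 tolerates a single
#' dropout in a triplicate cell while still excluding rows that only ever
#' sit at the ceiling. The control row is never reported.
#'
#' @param ct_tbl CT tibble with ceiling applied.
#' @param design Design tibble matching the sample columns.
#' @param constants A [quant_constants()] list.
#' @param min_fraction Required within-cell fraction of sub-ceiling wells.
#' @param control_id Control row id to exclude.
#' @return Character vector of detected miRNA ids.
#' @export
detect_expressed <- function(ct_tbl, design, constants = quant_constants(),
                             min_fraction = 0.5, control_id = "U6") {
  if (min_fraction <= 0 || min_fraction > 1) {
    abort("min_fraction must lie in (0, 1]")
  }
  check_design(design)
  ids <- ct_tbl[[1]]
  m <- expr_to_matrix(ct_tbl)[ids != control_id, , drop = FALSE]
  if (nrow(m) == 0) return(character())
  cells <- cell_key(design$timepoint, design$treatment)
  names(cells) <- design$sample_id
  cells <- cells[colnames(m)]
  detected_in_cell <- vapply(unique(cells), function(cl) {
    sub <- m[, cells == cl, drop = FALSE]
    rowMeans(sub < constants$ceiling_ct) >= min_fraction
  }, logical(nrow(m)))
  rownames(m)[rowSums(as.matrix(detected_in_cell)) > 0]
}
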