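# Readers and writers for the plain-text interchange formats: wide TSV
# matrices, design CSV, prediction-database TSV, GMT annotation, ground
# truth JSON. Matrix readers are strict on purpose — instrument and array
# exports with ragged rows or duplicated ids should fail loudly, with line
# numbers.

read_wide_matrix <- function(path, id_name, na_markers = character()) {
  lines <- readLines(path)
  if (length(lines) < 2) abort(paste0(path, ": need a header line and at least one row"))
  # sentinel keeps trailing empty fields (strsplit would drop them)
  fields <- strsplit(paste0(lines, "\t\x03"), "\t", fixed = TRUE)
  fields <- lapply(fields, function(f) f[-length(f)])
  header <- fields[[1]]
  n_col <- length(header)
  if (n_col < 2) abort(paste0(path, ": header must name an id column and >= 1 sample"))
  widths <- lengths(fields[-1])
  ragged <- which(widths != n_col)
  if (length(ragged) > 0) {
    abort(paste0(path, ": ragged row at line ", ragged[1] + 1L,
                 " (", widths[ragged[1]], " fields, expected ", n_col, ")"))
  }
  ids <- vapply(fields[-1], `[[`, character(1), 1L)
  dup <- ids[duplicated(ids)]
  if (length(dup) > 0) {
    line <- which(ids == dup[1])[2] + 1L
    abort(paste0(path, ": duplicate id '", dup[1], "' at line ", line))
  }
  raw <- t(vapply(fields[-1], function(f) f[-1], character(n_col - 1L)))
  raw <- matrix(raw, ncol = n_col - 1L)
  is_marker <- matrix(raw %in% na_markers, nrow = nrow(raw))
  m <- suppressWarnings(matrix(as.numeric(raw), nrow = nrow(raw)))
  m[is_marker] <- NA
  bad <- which(is.na(m) & !is_marker, arr.ind = TRUE)
  if (nrow(bad) > 0) {
    abort(paste0(path, ": non-numeric value '", raw[bad[1, 1], bad[1, 2]],
                 "' at line ", bad[1, 1] + 1L, ", column ", bad[1, 2] + 1L))
  }
  dimnames(m) <- list(ids, header[-1])
  out <- matrix_to_expr(m, id_name)
  names(out) <- c(id_name, header[-1])
  out
}

write_wide_matrix <- function(tbl, path) {
  m <- expr_to_matrix(tbl)
  header <- paste(names(tbl), collapse = "\t")
  rows <- vapply(seq_len(nrow(m)), function(i) {
    paste(c(rownames(m)[i], format(m[i, ], digits = 15, trim = TRUE,
                                   scientific = FALSE)), collapse = "\t")
  }, character(1))
  writeLines(c(header, rows), path)
  invisible(path)
}

#' Read / write a log2 expression matrix TSV
#'
#' First column is the probe id, remaining columns one sample each. The
#' reader rejects ragged rows, duplicate probe ids and non-numeric values,
#' naming the offending line.
#'
#' @param path File path.
#' @return A tibble `probe_id` + sample columns.
#' @export
read_expression_tsv <- function(path) read_wide_matrix(path, "probe_id")

#' @rdname read_expression_tsv
#' @param expr_tbl Expression tibble to write.
#' @export
write_expression_tsv <- function(expr_tbl, path) write_wide_matrix(expr_tbl, path)

#' Read / write a raw CT table TSV
#'
#' Layout as [read_expression_tsv()] with miRNA ids in the first column.
#' Undetected wells may be encoded as empty fields, `Undetermined` or `NA`;
#' all are read as `NA` (and later clamped by [apply_ct_ceiling()]). The
#' endogenous-control row must be present.
#'
#' @param path File path.
#' @param control_id Required control row id.
#' @return A tibble `mirna_id` + sample columns.
#' @export
read_ct_tsv <- function(path, control_id = "U6") {
  out <- read_wide_matrix(path, "mirna_id",
                          na_markers = c("", "NA", "Undetermined"))
  if (!control_id %in% out$mirna_id) {
    abort(paste0(path, ": endogenous-control row '", control_id, "' is missing"))
  }
  out
}

#' @rdname read_ct_tsv
#' @param ct_tbl CT tibble to write.
#' @export
write_ct_tsv <- function(ct_tbl, path) write_wide_matrix(ct_tbl, path)

#' Read / write a design table CSV
#'
#' Columns `sample_id`, `timepoint`, `treatment`, `replicate`.
#'
#' @param path File path.
#' @return Design tibble.
#' @export
read_design_csv <- function(path) {
  design <- readr::read_csv(path, col_types = readr::cols(
    sample_id = readr::col_character(),
    timepoint = readr::col_character(),
    treatment = readr::col_character(),
    replicate = readr::col_integer()
  ))
  check_design(design)
}

#' @rdname read_design_csv
#' @param design Design tibble to write.
#' @export
write_design_csv <- function(design, path) {
  readr::write_csv(design, path)
  invisible(path)
}

#' Read / write a target-prediction database TSV
#'
#' Columns `source`, `mirna_id`, `gene_id`; duplicate (miRNA, gene) entries
#' are rejected.
#'
#' @param path File path.
#' @return Prediction tibble.
#' @export
read_predictions_tsv <- function(path) {
  db <- readr::read_tsv(path, col_types = readr::cols(
    source = readr::col_character(),
    mirna_id = readr::col_character(),
    gene_id = readr::col_character()
  ))
  if (anyDuplicated(db[, c("mirna_id", "gene_id")])) {
    abort(paste0(path, ": duplicate (mirna_id, gene_id) entries"))
  }
  db
}

#' @rdname read_predictions_tsv
#' @param db Prediction tibble to write.
#' @export
write_predictions_tsv <- function(db, path) {
  readr::write_tsv(db, path)
  invisible(path)
}

#' Read / write a probe-to-gene map TSV
#'
#' Columns `probe_id`, `gene_id`; one gene per probe.
#'
#' @param path File path.
#' @return Probe-map tibble.
#' @export
read_probe_map_tsv <- function(path) {
  pm <- readr::read_tsv(path, col_types = readr::cols(
    probe_id = readr::col_character(),
    gene_id = readr::col_character()
  ))
  if (anyDuplicated(pm$probe_id)) {
    abort(paste0(path, ": duplicate probe_id entries"))
  }
  pm
}

#' @rdname read_probe_map_tsv
#' @param probe_map Probe-map tibble to write.
#' @export
write_probe_map_tsv <- function(probe_map, path) {
  readr::write_tsv(probe_map, path)
  invisible(path)
}

#' Read / write gene-set annotation in GMT format
#'
#' One term per line: term id, description, then tab-separated member
#' genes. Because GMT carries no universe, `universe` defaults to the union
#' of all term members; pass the full assayed gene list when available.
#'
#' @param path File path.
#' @param universe Optional reference gene list.
#' @return An [annotation_set()].
#' @export
read_gmt <- function(path, universe = NULL) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  short <- which(lengths(fields) < 3)
  if (length(short) > 0) {
    abort(paste0(path, ": line ", short[1],
                 " has fewer than 3 fields (term, description, members...)"))
  }
  ids <- vapply(fields, `[[`, character(1), 1L)
  if (anyDuplicated(ids)) {
    abort(paste0(path, ": duplicate term '", ids[duplicated(ids)][1], "'"))
  }
  terms <- lapply(fields, function(f) unique(f[-(1:2)]))
  names(terms) <- ids
  descriptions <- setNames(vapply(fields, `[[`, character(1), 2L), ids)
  if (is.null(universe)) universe <- unique(unlist(terms))
  annotation_set(terms, universe, descriptions)
}

#' @rdname read_gmt
#' @param annotation Annotation to write.
#' @export
write_gmt <- function(annotation, path) {
  lines <- vapply(names(annotation$terms), function(id) {
    paste(c(id, annotation$descriptions[[id]], annotation$terms[[id]]),
          collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Read / write planted ground truth as JSON
#'
#' @param path File path.
#' @return A `ground_truth` object.
#' @export
read_ground_truth_json <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  as_tbl <- function(df) if (is.null(df) || length(df) == 0) NULL else as_tibble(df)
  new_ground_truth(
    de_mrna = as_tbl(x$de_mrna),
    de_mirna = as_tbl(x$de_mirna),
    edges = as_tbl(x$edges),
    enriched_term = x$enriched_term %||% NA_character_,
    seed = x$seed %||% NA_integer_
  )
}

#' @rdname read_ground_truth_json
#' @param truth A `ground_truth` to write.
#' @export
write_ground_truth_json <- function(truth, path) {
  jsonlite::write_json(unclass(truth), path, auto_unbox = TRUE,
                       digits = NA, null = "null", pretty = TRUE)
  invisible(path)
}
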