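# Internal helpers shared across modules.

# Expression-style tables are wide tibbles: an id column followed by one
# numeric column per sample. These helpers convert to/from a plain matrix.

expr_to_matrix <- function(tbl, id_col = 1L) {
  ids <- as.character(tbl[[id_col]])
  m <- as.matrix(tbl[, -id_col, drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- ids
  m
}

matrix_to_expr <- function(m, id_name) {
  out <- as_tibble(m, .name_repair = "minimal")
  out <- tibble(!!id_name := rownames(m)) %>% dplyr::bind_cols(out)
  out
}

sample_cols <- function(tbl, id_col = 1L) {
  names(tbl)[-id_col]
}

check_design <- function(design) {
  needed <- c("sample_id", "timepoint", "treatment")
  missing <- setdiff(needed, names(design))
  if (length(missing) > 0) {
    abort(paste0("design is missing column(s): ", paste(missing, collapse = ", ")))
  }
  if (anyDuplicated(design$sample_id)) {
    abort("design sample_id values must be unique")
  }
  invisible(design)
}

# Cell label "P14.O2" etc.; used as a grouping key throughout.
cell_key <- function(timepoint, treatment) paste(timepoint, treatment, sep = ".")

# Derive a stage seed from the run seed; keeps everything under one knob
# while decorrelating stages. Kept below 2^31 - 1.
derive_seed <- function(seed, offset) {
  as.integer((as.numeric(seed) * 1000003 + as.numeric(offset)) %% 2147483629)
}
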