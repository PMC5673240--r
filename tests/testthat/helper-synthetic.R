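# Small-scale generator configurations shared across test files.

small_cfg <- function(seed = 1, ...) {
  defaults <- list(n_cell_types = 20L, n_genes = 300L, n_lines = 8L,
                   cells_per_line = 12L, ephys_cells_per_line = 12L,
                   seed = seed)
  do.call(synthetic_config, utils::modifyList(defaults, list(...)))
}

small_run_config <- function(seed = 1, ...) {
  run_config(seed = seed, n_permutations = 100L, n_bootstrap = 10L, ...)
}

# A tiny hand-made expression matrix with metadata.
toy_expression <- function(values, scale = "log2_intensity",
                           types = rep("T1", ncol(values))) {
  if (is.null(rownames(values))) {
    rownames(values) <- sprintf("g%d", seq_len(nrow(values)))
  }
  if (is.null(colnames(values))) {
    colnames(values) <- sprintf("s%d", seq_len(ncol(values)))
  }
  expression_matrix(values, scale, tibble::tibble(
    sample_id = colnames(values), cell_type_label = types))
}

# A minimal valid measurement row, with overridable fields.
toy_measurement <- function(...) {
  defaults <- tibble::tibble(
    article_id = "A1", cell_type_label = "T1", property = "Vrest",
    value = -65, species = "mouse", preparation = "acute_slice",
    electrode = "patch", jxn_status = "not_corrected",
    jxn_offset_mV = NA_real_, age_lo_days = 14, age_hi_days = 14,
    rec_temp_C = 33
  )
  dots <- list(...)
  for (nm in names(dots)) defaults[[nm]] <- dots[[nm]]
  defaults
}
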