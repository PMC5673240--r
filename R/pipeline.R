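# End-to-end conveniences: raw inputs -> analysis-ready paired datasets.

#' Build an analysis-ready discovery dataset
#'
#' Chains the standard discovery-side pipeline: optional quantile
#' normalization of sample-level expression, cell-type summarization,
#' mean/variance gene filtering; measurement preprocessing, per-property
#' condition normalization, article-mean-then-median summarization; and
#' label pairing of the two sides (an explicit mapping with age-tolerance
#' matching can be supplied instead of identity labels).
#'
#' @param expression Sample-level [expression_matrix()].
#' @param ephys Curated measurement tibble (see [ephys_measurements()]).
#' @param cfg A [run_config()].
#' @param quantile_normalize Apply [quantile_normalize()] first?
#' @param normalize_conditions Fit and apply condition models?
#' @param thresholds Optional fixed `gene_filter_thresholds`.
#' @param mapping Optional cell-type mapping for [align_datasets()];
#'   `NULL` pairs identical labels.
#' @return List: `dataset` (a [paired_dataset()]), `thresholds`,
#'   `condition_models`, `records` (adjusted article-level measurements),
#'   `celltype_expression`, `celltype_ephys`.
#' @export
build_discovery_dataset <- function(expression, ephys, cfg = run_config(),
                                    quantile_normalize = TRUE,
                                    normalize_conditions = TRUE,
                                    thresholds = NULL, mapping = NULL) {
  m <- drop_flagged_samples(expression)
  if (quantile_normalize) m <- quantile_normalize(m)
  ct_expr <- summarize_expression_by_cell_type(m)
  filt <- if (is.null(thresholds)) filter_genes(ct_expr) else
    filter_genes(ct_expr, thresholds$mu_global, thresholds$sigma_global)

  rec <- preprocess_measurements(ephys, cfg)
  models <- list()
  if (normalize_conditions) {
    norm <- normalize_ephys_conditions(rec, cfg)
    rec <- norm$records
    models <- norm$models
  }
  ct_ephys <- summarize_ephys_by_cell_type(rec)

  ds <- if (is.null(mapping)) {
    pair_by_label(filt$expression, ct_ephys)
  } else {
    align_datasets(filt$expression, ct_ephys, mapping, cfg)
  }
  list(dataset = ds, thresholds = filt$thresholds, condition_models = models,
       records = rec, celltype_expression = filt$expression,
       celltype_ephys = ct_ephys)
}

#' Summarize per-cell ephys values to cre-line means
#'
#' @param cell_ephys Tibble of per-cell values: `cell_id`,
#'   `cell_type_label` (the line), `property`, `value`.
#' @param min_cells Minimum ephys cells per (line, property).
#' @return A [celltype_matrix()] of kind `"ephys"` (lines x properties)
#'   with per-line ephys cell counts attached as `cell_counts`.
#' @export
summarize_cell_ephys_by_line <- function(cell_ephys, min_cells = 10L) {
  df <- tibble::as_tibble(cell_ephys)
  stopifnot(all(c("cell_type_label", "property", "value") %in% names(df)))
  assert_property(df$property)
  per_line <- df |>
    dplyr::group_by(.data$cell_type_label, .data$property) |>
    dplyr::summarise(value = mean(.data$value), n_cells = dplyr::n(),
                     .groups = "drop") |>
    dplyr::filter(.data$n_cells >= min_cells)
  if (nrow(per_line) == 0) stop("No (line, property) has >= ", min_cells,
                                " ephys cells.", call. = FALSE)
  lines <- unique(per_line$cell_type_label)
  props <- ephys_property_codes()
  vals <- matrix(NA_real_, length(lines), length(props),
                 dimnames = list(lines, props))
  vals[cbind(match(per_line$cell_type_label, lines),
             match(per_line$property, props))] <- per_line$value
  out <- celltype_matrix(
    vals, tibble::tibble(cell_type = lines, age_days = NA_real_), "ephys")
  attr(out, "cell_counts") <- df |>
    dplyr::group_by(cell_type = .data$cell_type_label) |>
    dplyr::summarise(n_cells = dplyr::n_distinct(.data$cell_id),
                     .groups = "drop")
  out
}

#' Build an analysis-ready validation dataset from single-cell inputs
#'
#' Aggregates single-cell TPM expression to cre-line means (lines must be
#' sampled by at least `cfg$min_cells_per_line` cells in both the
#' transcriptomic and ephys arms) and pairs them with line-mean ephys.
#' The paired expression side is kept on the TPM scale: the rank-based
#' screen is invariant to the monotone log transform, and
#' [transfer_predict()] applies log2(TPM + 1) itself.
#'
#' @param expression Cell-level [expression_matrix()] on the `"tpm"`
#'   scale, cells labeled by line.
#' @param cell_ephys Per-cell ephys tibble (see
#'   [summarize_cell_ephys_by_line()]).
#' @param cfg A [run_config()].
#' @return List: `dataset` (a [paired_dataset()] of line-mean TPM vs
#'   line-mean ephys), `line_expression`, `line_ephys`.
#' @export
build_validation_dataset <- function(expression, cell_ephys,
                                     cfg = run_config()) {
  line_ephys <- summarize_cell_ephys_by_line(cell_ephys,
                                             cfg$min_cells_per_line)
  line_expr <- aggregate_single_cells(
    expression, cfg$min_cells_per_line,
    ephys_cell_counts = attr(line_ephys, "cell_counts"))
  ds <- pair_by_label(line_expr, line_ephys)
  list(dataset = ds, line_expression = line_expr, line_ephys = line_ephys)
}
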