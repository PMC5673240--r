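# Expression preprocessing: quantile normalization, probe collapse,
# cell-type summarization, mean/variance gene filtering, and single-cell
# aggregation by line.

#' Cell-type-level matrix container
#'
#' A cell-type x variable numeric matrix (expression or ephys summaries)
#' together with per-cell-type metadata (sample/article counts, age).
#'
#' @param values Numeric matrix, cell types in rows.
#' @param meta Tibble with a `cell_type` column matching rownames and any
#'   per-type annotation (e.g. `n_samples`, `age_days`).
#' @param kind `"expression"` or `"ephys"`.
#' @return An object of class `celltype_matrix`.
#' @export
celltype_matrix <- function(values, meta, kind = c("expression", "ephys")) {
  kind <- match.arg(kind)
  stopifnot(is.matrix(values), !is.null(rownames(values)), !is.null(colnames(values)))
  meta <- tibble::as_tibble(meta)
  stopifnot("cell_type" %in% names(meta),
            setequal(meta$cell_type, rownames(values)))
  meta <- meta[match(rownames(values), meta$cell_type), ]
  structure(list(values = values, meta = meta, kind = kind),
            class = "celltype_matrix")
}

#' @export
print.celltype_matrix <- function(x, ...) {
  cat(sprintf("<celltype_matrix:%s> %d cell types x %d %s\n", x$kind,
              nrow(x$values), ncol(x$values),
              if (x$kind == "expression") "genes" else "properties"))
  invisible(x)
}

#' Quantile-normalize an expression matrix across samples
#'
#' Forces every sample's empirical value distribution to the cross-sample
#' mean of order statistics (ties replaced by their average), so all
#' per-sample distributions coincide afterwards. Feature order is
#' preserved. Delegates to `limma::normalizeQuantiles()`.
#'
#' @param m An [expression_matrix()] with at least 2 samples.
#' @return The normalized `expression_matrix`.
#' @export
quantile_normalize <- function(m) {
  stopifnot(inherits(m, "expression_matrix"))
  if (ncol(m$values) < 2) {
    stop("Quantile normalization needs at least 2 samples.", call. = FALSE)
  }
  norm <- limma::normalizeQuantiles(m$values, ties = TRUE)
  dimnames(norm) <- dimnames(m$values)
  expression_matrix(norm, m$scale, m$sample_meta)
}

#' Collapse probes to genes by maximum across-sample variance
#'
#' For genes measured by several probes, the probe with the largest
#' across-sample variance represents the gene; exact variance ties keep the
#' probe appearing first in input order (reported in the attached summary).
#' Probes absent from the mapping are dropped.
#'
#' @param m An [expression_matrix()] whose features are probes.
#' @param probe_to_gene Data frame with columns `probe`, `gene` (or a named
#'   character vector `probe -> gene`). Each retained probe must map to
#'   exactly one gene.
#' @return An `expression_matrix` with one row per gene, carrying a
#'   `collapse_summary` attribute (tibble: `n_unmapped_probes`,
#'   `n_variance_ties`).
#' @export
collapse_probes_to_genes <- function(m, probe_to_gene) {
  stopifnot(inherits(m, "expression_matrix"))
  if (is.character(probe_to_gene) && !is.null(names(probe_to_gene))) {
    probe_to_gene <- tibble::tibble(probe = names(probe_to_gene),
                                    gene = unname(probe_to_gene))
  }
  probe_to_gene <- tibble::as_tibble(probe_to_gene)
  stopifnot(all(c("probe", "gene") %in% names(probe_to_gene)))
  if (nrow(probe_to_gene) == 0) stop("Empty probe-to-gene mapping.", call. = FALSE)
  if (anyDuplicated(probe_to_gene$probe)) {
    stop("A probe maps to more than one gene.", call. = FALSE)
  }
  probes <- rownames(m$values)
  mapped <- probes[probes %in% probe_to_gene$probe]
  n_unmapped <- length(probes) - length(mapped)
  if (length(mapped) == 0) stop("No probe in the matrix is mapped.", call. = FALSE)
  gene_of <- probe_to_gene$gene[match(mapped, probe_to_gene$probe)]
  v <- apply(m$values[mapped, , drop = FALSE], 1, stats::var)
  # first-in-input-order wins variance ties: stable order + strict '>'
  keep <- character(0)
  ties <- 0L
  for (g in unique(gene_of)) {
    idx <- which(gene_of == g)
    best <- idx[which.max(v[idx])]     # which.max is first-on-ties
    if (sum(v[idx] == v[best]) > 1) ties <- ties + 1L
    keep[g] <- mapped[best]
  }
  out <- m$values[keep, , drop = FALSE]
  rownames(out) <- names(keep)
  res <- expression_matrix(out, m$scale, m$sample_meta)
  attr(res, "collapse_summary") <- tibble::tibble(
    n_unmapped_probes = n_unmapped, n_variance_ties = ties
  )
  res
}

#' Drop samples flagged by upstream quality control
#'
#' Contamination screening (e.g. glial admixture) is accepted as an
#' upstream `qc_flag` column in the sample metadata; flagged samples are
#' removed.
#'
#' @param m An [expression_matrix()].
#' @return The filtered `expression_matrix`.
#' @export
drop_flagged_samples <- function(m) {
  stopifnot(inherits(m, "expression_matrix"))
  if (!"qc_flag" %in% names(m$sample_meta)) return(m)
  keep <- !isTRUE_vec(m$sample_meta$qc_flag)
  expression_matrix(m$values[, keep, drop = FALSE], m$scale,
                    m$sample_meta[keep, ])
}

isTRUE_vec <- function(x) !is.na(x) & x

#' Summarize expression to the cell-type level
#'
#' Each (cell type, gene) entry is the arithmetic mean over that type's
#' samples; per-type sample counts and mean annotated age are carried in
#' the metadata.
#'
#' @param m An [expression_matrix()] whose samples carry `cell_type_label`.
#' @return A [celltype_matrix()] of kind `"expression"` (cell types x
#'   genes).
#' @export
summarize_expression_by_cell_type <- function(m) {
  stopifnot(inherits(m, "expression_matrix"))
  labels <- m$sample_meta$cell_type_label
  if (any(is.na(labels) | labels == "")) {
    stop("Every sample needs a cell_type_label.", call. = FALSE)
  }
  types <- unique(labels)
  vals <- do.call(rbind, lapply(types, function(t) {
    rowMeans(m$values[, labels == t, drop = FALSE])
  }))
  dimnames(vals) <- list(types, rownames(m$values))
  meta <- m$sample_meta |>
    dplyr::group_by(cell_type = .data$cell_type_label) |>
    dplyr::summarise(
      n_samples = dplyr::n(),
      age_days = if (all(is.na(.data$age_days))) NA_real_ else
        mean(.data$age_days, na.rm = TRUE),
      .groups = "drop"
    )
  celltype_matrix(vals, meta, "expression")
}

#' Filter genes on mean and variability across cell types
#'
#' For each gene, computes its mean \eqn{\mu_g} and sample standard
#' deviation \eqn{\sigma_g} (n - 1 denominator) across cell types, and the
#' global cutoffs \eqn{\mu_{global} = mean_g(\mu_g)},
#' \eqn{\sigma_{global} = mean_g(\sigma_g)}. Genes with
#' \eqn{\mu_g > \mu_{global}} and \eqn{\sigma_g > \sigma_{global}} are
#' retained. Cutoffs may instead be fixed externally, in which case the
#' filter is idempotent.
#'
#' @param ct A [celltype_matrix()] of cell-type-summarized expression with
#'   at least 2 cell types.
#' @param mu_global,sigma_global Optional externally fixed cutoffs; when
#'   `NULL` they are derived from the data as above.
#' @return A list with `expression` (the filtered `celltype_matrix`) and
#'   `thresholds`, a `gene_filter_thresholds` object holding `mu_global`,
#'   `sigma_global` and the per-gene statistics.
#' @export
filter_genes <- function(ct, mu_global = NULL, sigma_global = NULL) {
  stopifnot(inherits(ct, "celltype_matrix"), ct$kind == "expression")
  if (nrow(ct$values) < 2) stop("Need >= 2 cell types to filter genes.", call. = FALSE)
  mu_g <- colMeans(ct$values)
  sigma_g <- apply(ct$values, 2, stats::sd)
  derived <- is.null(mu_global) || is.null(sigma_global)
  if (is.null(mu_global)) mu_global <- mean(mu_g)
  if (is.null(sigma_global)) sigma_global <- mean(sigma_g)
  keep <- mu_g > mu_global & sigma_g > sigma_global
  if (!any(keep)) stop("All genes removed by the mean/variance filter.", call. = FALSE)
  thresholds <- structure(
    list(
      mu_global = mu_global, sigma_global = sigma_global,
      derived_from_data = derived,
      per_gene = tibble::tibble(gene = colnames(ct$values), mu_g = mu_g,
                                sigma_g = sigma_g, retained = keep)
    ),
    class = "gene_filter_thresholds"
  )
  list(
    expression = celltype_matrix(ct$values[, keep, drop = FALSE], ct$meta,
                                 "expression"),
    thresholds = thresholds
  )
}

#' @export
print.gene_filter_thresholds <- function(x, ...) {
  cat(sprintf(
    "<gene_filter_thresholds> mu_global = %.4g, sigma_global = %.4g (%s); %d / %d genes retained\n",
    x$mu_global, x$sigma_global,
    if (x$derived_from_data) "derived" else "fixed",
    sum(x$per_gene$retained), nrow(x$per_gene)))
  invisible(x)
}

#' Aggregate single cells to cre-line-level expression
#'
#' Cells are grouped by their line label (`cell_type_label`); lines sampled
#' by fewer than `min_cells` cells are excluded, in either modality when a
#' per-line ephys cell count table is supplied. Retained lines are
#' summarized by the per-gene mean TPM.
#'
#' @param m An [expression_matrix()] on the `"tpm"` scale, samples grouped
#'   by line.
#' @param min_cells Minimum cells per line.
#' @param ephys_cell_counts Optional tibble (`cell_type`/`cell_type_label`,
#'   `n_cells`) of per-line ephys cell counts; lines below `min_cells`
#'   there are excluded too.
#' @return A [celltype_matrix()] of kind `"expression"` (lines x genes,
#'   mean TPM), with an `excluded_lines` attribute naming dropped lines.
#' @export
aggregate_single_cells <- function(m, min_cells = 10L, ephys_cell_counts = NULL) {
  stopifnot(inherits(m, "expression_matrix"), min_cells >= 1)
  if (m$scale != "tpm") {
    stop("aggregate_single_cells expects an expression matrix on the 'tpm' scale.",
         call. = FALSE)
  }
  counts <- table(m$sample_meta$cell_type_label)
  keep <- names(counts)[counts >= min_cells]
  if (!is.null(ephys_cell_counts)) {
    ec <- tibble::as_tibble(ephys_cell_counts)
    if ("cell_type_label" %in% names(ec) && !"cell_type" %in% names(ec)) {
      names(ec)[names(ec) == "cell_type_label"] <- "cell_type"
    }
    stopifnot(all(c("cell_type", "n_cells") %in% names(ec)))
    ok_ephys <- ec$cell_type[ec$n_cells >= min_cells]
    keep <- keep[keep %in% ok_ephys]
  }
  excluded <- setdiff(unique(m$sample_meta$cell_type_label), keep)
  if (length(keep) == 0) {
    stop("No line has >= ", min_cells, " cells in every modality.", call. = FALSE)
  }
  labels <- m$sample_meta$cell_type_label
  vals <- do.call(rbind, lapply(keep, function(l) {
    rowMeans(m$values[, labels == l, drop = FALSE])
  }))
  dimnames(vals) <- list(keep, rownames(m$values))
  meta <- tibble::tibble(cell_type = keep,
                         n_samples = as.integer(counts[keep]),
                         age_days = NA_real_)
  out <- celltype_matrix(vals, meta, "expression")
  attr(out, "excluded_lines") <- excluded
  out
}
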