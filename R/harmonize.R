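# Pairing expression cell types with ephys cell types into the unit of
# all screening and modeling: the paired cell-type dataset.

#' Paired cell-type dataset
#'
#' Cell types x genes expression alongside cell types x properties ephys
#' (with explicit missingness). Expression has no missing entries; the
#' ephys side may.
#'
#' @param expression Numeric matrix, cell types x genes (no `NA`s).
#' @param ephys Numeric matrix, same cell types x registered properties
#'   (`NA` = unmeasured).
#' @param provenance Tibble of per-cell-type source notes (at minimum a
#'   `cell_type` column).
#' @return An object of class `paired_dataset`.
#' @export
paired_dataset <- function(expression, ephys, provenance = NULL) {
  stopifnot(is.matrix(expression), is.matrix(ephys),
            identical(rownames(expression), rownames(ephys)))
  if (any(is.na(expression))) {
    stop("Expression side of a paired dataset cannot contain NA.", call. = FALSE)
  }
  assert_property(colnames(ephys))
  if (is.null(provenance)) {
    provenance <- tibble::tibble(cell_type = rownames(expression))
  }
  structure(
    list(expression = expression, ephys = ephys,
         provenance = tibble::as_tibble(provenance)),
    class = "paired_dataset"
  )
}

#' @export
print.paired_dataset <- function(x, ...) {
  n_per_prop <- colSums(!is.na(x$ephys))
  cat(sprintf("<paired_dataset> %d cell types x %d genes; ephys coverage %d-%d types per property\n",
              nrow(x$expression), ncol(x$expression),
              min(n_per_prop), max(n_per_prop)))
  invisible(x)
}

#' Align expression and ephys cell types into a paired dataset
#'
#' Pairs cell types via an explicit mapping table (the curation of which
#' labels denote the same biological population is input, not inferred).
#' When both sides of a pair carry an age annotation, the pair is kept
#' only if the ages agree within `cfg$age_match_tolerance_days`; pairs
#' lacking an age on either side match on label alone. Unmatched and
#' age-rejected types are listed in the provenance.
#'
#' @param expr A [celltype_matrix()] of cell-type expression (rows carry
#'   per-type ages in its metadata where known).
#' @param ephys A [celltype_matrix()] of cell-type ephys summaries.
#' @param mapping Tibble with columns `expression_label`, `ephys_label`
#'   and optionally `age_days` (overrides the expression-side age).
#' @param cfg A [run_config()].
#' @return A [paired_dataset()] whose rows are the matched expression
#'   labels; its provenance records each pair's source labels and ages,
#'   and an `unmatched` attribute lists rejected pairs with reasons.
#' @export
align_datasets <- function(expr, ephys, mapping, cfg = run_config()) {
  stopifnot(inherits(expr, "celltype_matrix"), expr$kind == "expression",
            inherits(ephys, "celltype_matrix"), ephys$kind == "ephys")
  mapping <- tibble::as_tibble(mapping)
  stopifnot(all(c("expression_label", "ephys_label") %in% names(mapping)))
  bad <- setdiff(mapping$expression_label, rownames(expr$values))
  if (length(bad) > 0) {
    stop("Mapping refers to unknown expression type(s): ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  bad <- setdiff(mapping$ephys_label, rownames(ephys$values))
  if (length(bad) > 0) {
    stop("Mapping refers to unknown ephys type(s): ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  expr_age <- expr$meta$age_days[match(mapping$expression_label, expr$meta$cell_type)]
  if ("age_days" %in% names(mapping)) {
    expr_age <- dplyr::coalesce(mapping$age_days, expr_age)
  }
  ephys_age <- ephys$meta$age_days[match(mapping$ephys_label, ephys$meta$cell_type)]
  both <- !is.na(expr_age) & !is.na(ephys_age)
  ok <- !both | abs(expr_age - ephys_age) <= cfg$age_match_tolerance_days
  unmatched <- tibble::tibble(
    expression_label = mapping$expression_label[!ok],
    ephys_label = mapping$ephys_label[!ok],
    reason = sprintf("age mismatch: %.1f vs %.1f d (tolerance %.1f)",
                     expr_age[!ok], ephys_age[!ok],
                     cfg$age_match_tolerance_days)
  )
  mapping <- mapping[ok, ]
  if (nrow(mapping) == 0) {
    stop("No cell-type pair survives the mapping and age-tolerance rules.",
         call. = FALSE)
  }
  prov <- tibble::tibble(
    cell_type = mapping$expression_label,
    ephys_label = mapping$ephys_label,
    age_expr_days = expr_age[ok],
    age_ephys_days = ephys_age[ok]
  )
  ds <- paired_dataset(
    expression = expr$values[mapping$expression_label, , drop = FALSE],
    ephys = ephys$values[mapping$ephys_label, , drop = FALSE] |>
      `rownames<-`(mapping$expression_label),
    provenance = prov
  )
  attr(ds, "unmatched") <- unmatched
  ds
}

#' Restrict two datasets to their common gene universe
#'
#' Both inputs are restricted to the sorted intersection of their gene
#' sets, column-aligned so downstream comparisons are positional.
#'
#' @param a A [paired_dataset()].
#' @param b A second [paired_dataset()] or a [celltype_matrix()] of
#'   expression.
#' @return A list `(a, b)` restricted to the common genes, with an
#'   `n_common` attribute.
#' @export
intersect_genes <- function(a, b) {
  genes_of <- function(x) {
    if (inherits(x, "paired_dataset")) colnames(x$expression)
    else if (inherits(x, "celltype_matrix")) colnames(x$values)
    else stop("Unsupported input to intersect_genes.", call. = FALSE)
  }
  common <- sort(intersect(genes_of(a), genes_of(b)))
  if (length(common) == 0) stop("No genes in common.", call. = FALSE)
  restrict <- function(x) {
    if (inherits(x, "paired_dataset")) {
      paired_dataset(x$expression[, common, drop = FALSE], x$ephys, x$provenance)
    } else {
      out <- celltype_matrix(x$values[, common, drop = FALSE], x$meta, x$kind)
      out
    }
  }
  out <- list(a = restrict(a), b = restrict(b))
  attr(out, "n_common") <- length(common)
  out
}

#' Build a paired dataset directly from matched containers
#'
#' Identity pairing for datasets (like a cre-line validation arm) whose
#' expression and ephys summaries already share cell-type labels.
#'
#' @param expr,ephys [celltype_matrix()] containers sharing row labels.
#' @return A [paired_dataset()] over the common labels.
#' @export
pair_by_label <- function(expr, ephys) {
  common <- intersect(rownames(expr$values), rownames(ephys$values))
  if (length(common) == 0) stop("No shared cell-type labels.", call. = FALSE)
  paired_dataset(expr$values[common, , drop = FALSE],
                 ephys$values[common, , drop = FALSE])
}
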