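# broom-style tidy()/glance() methods for the package's fitted objects.

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a sparse ephys model into a coefficient table
#'
#' @param x A [fit_two_stage()] model.
#' @param ... Unused.
#' @return Tibble: `term` (gene id or `"(Intercept)"`), `estimate` (on the
#'   standardized response scale).
#' @export
tidy.sparse_ephys_model <- function(x, ...) {
  tibble::tibble(
    term = c("(Intercept)", x$selected_genes),
    estimate = c(x$intercept, unname(x$coefficients))
  )
}

#' @rdname tidy.sparse_ephys_model
#' @export
glance.sparse_ephys_model <- function(x, ...) {
  tibble::tibble(
    property = x$property, transform = x$transform,
    n_selected = length(x$selected_genes),
    lambda_stage1 = x$fit_meta$lambda_stage1 %||% NA_real_,
    lambda_stage2 = x$fit_meta$lambda_stage2 %||% NA_real_
  )
}

#' Tidy a condition model into a coefficient table
#'
#' @param x A [fit_condition_model()] result.
#' @param ... Unused.
#' @return Tibble: `term`, `estimate`, `term_type` (`"cell_type"` or
#'   `"condition"`).
#' @export
tidy.condition_model <- function(x, ...) {
  tibble::tibble(
    term = c("(Intercept)", names(x$coefficients)),
    estimate = c(unname(x$intercept), unname(x$coefficients)),
    term_type = c("intercept",
                  ifelse(names(x$coefficients) %in% x$celltype_terms,
                         "cell_type", "condition"))
  )
}

#' @rdname tidy.condition_model
#' @export
glance.condition_model <- function(x, ...) {
  tibble::tibble(
    property = x$property, transform = x$transform,
    lambda = x$fit_diagnostics$lambda_min,
    n_records = x$fit_diagnostics$n_records,
    n_articles = x$fit_diagnostics$n_articles
  )
}

#' Tidy a leave-one-out evaluation into its per-cell-type predictions
#'
#' @param x An [evaluate_loocv()] result.
#' @param ... Unused.
#' @return The `predictions` tibble (modeling scale).
#' @export
tidy.model_evaluation <- function(x, ...) x$predictions

#' @rdname tidy.model_evaluation
#' @export
glance.model_evaluation <- function(x, ...) {
  tibble::tibble(property = x$property, r2_loocv = x$r2_loocv,
                 n_celltypes = nrow(x$predictions))
}

#' Tidy a transfer evaluation into its per-line predictions
#'
#' @param x A [transfer_predict()] result.
#' @param ... Unused.
#' @return The `predictions` tibble (standardized scale).
#' @export
tidy.transfer_evaluation <- function(x, ...) x$predictions

#' @rdname tidy.transfer_evaluation
#' @export
glance.transfer_evaluation <- function(x, ...) {
  tibble::tibble(property = x$property, r2_transfer = x$r2_transfer,
                 r2_transfer_unity = x$r2_transfer_unity,
                 n_lines = nrow(x$predictions))
}

#' Tidy a permutation test into its null distribution
#'
#' @param x A [permutation_null()] result.
#' @param ... Unused.
#' @return Tibble: `permutation`, `statistic_value`.
#' @export
tidy.permutation_test <- function(x, ...) {
  tibble::tibble(permutation = seq_along(x$null), statistic_value = x$null)
}

#' @rdname tidy.permutation_test
#' @export
glance.permutation_test <- function(x, ...) {
  tibble::tibble(property = x$property, statistic = x$statistic,
                 observed = x$observed, p_value = x$p_value,
                 n_permutations = x$n_permutations)
}

#' Tidy gene-filter thresholds into per-gene statistics
#'
#' @param x A `gene_filter_thresholds` object from [filter_genes()].
#' @param ... Unused.
#' @return The per-gene tibble (`gene`, `mu_g`, `sigma_g`, `retained`).
#' @export
tidy.gene_filter_thresholds <- function(x, ...) x$per_gene

#' @rdname tidy.gene_filter_thresholds
#' @export
glance.gene_filter_thresholds <- function(x, ...) {
  tibble::tibble(mu_global = x$mu_global, sigma_global = x$sigma_global,
                 derived_from_data = x$derived_from_data,
                 n_retained = sum(x$per_gene$retained),
                 n_genes = nrow(x$per_gene))
}
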