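#' Run configuration
#'
#' Collects the tunable constants used across the pipeline in one validated
#' object. Defaults follow the study design the package implements: BH
#' significance grid \{0.01, 0.05, 0.1\}, cross-dataset consistency rule
#' |r_s| > 0.3, 1000 permutations, 100 bootstrap resamples, elastic-net
#' mixing weight 0.99 over a 100-value penalty path, at least 10 cells per
#' cre-line, and +/- 2.5 day age matching when pairing age-annotated cell
#' types.
#'
#' @param seed Integer seed controlling every stochastic step. Stochastic
#'   operations draw from named substreams derived from it, so adding genes
#'   to a simulation does not perturb unrelated draws.
#' @param bh_alpha_levels Numeric vector of FDR thresholds at which
#'   significance counts are reported.
#' @param consistency_abs_r Magnitude a validation-side correlation must
#'   exceed (with matching sign) for a discovered gene-property pair to be
#'   called consistent.
#' @param n_permutations Number of label shuffles for permutation null
#'   distributions.
#' @param n_bootstrap Number of stratified bootstrap resamples for model
#'   performance variability.
#' @param enet_alpha Elastic-net mixing weight (1 = lasso).
#' @param enet_nlambda Length of the penalty path.
#' @param min_cells_per_line Minimum cells per cre-line (in each modality,
#'   when both are supplied) for a line to enter the validation dataset.
#' @param age_match_tolerance_days Tolerance for matching age-annotated
#'   expression and ephys cell types.
#' @param min_celltypes_per_property Minimum number of cell types with a
#'   non-missing property value for that property to be screened or modeled.
#' @param inner_nfolds Folds for the internal cross-validation that selects
#'   the elastic-net penalty: an integer, or `"loo"` for leave-one-out.
#' @param exclusions Tibble/data frame with columns `cell_type_label` and
#'   `property`: measurements removed during preprocessing (e.g. a property
#'   known to be unreliable for one cell type).
#' @return An object of class `run_config` (a validated named list).
#' @examples
#' cfg <- run_config(seed = 42)
#' cfg$consistency_abs_r
#' @export
run_config <- function(seed = 1L,
                       bh_alpha_levels = c(0.01, 0.05, 0.1),
                       consistency_abs_r = 0.3,
                       n_permutations = 1000L,
                       n_bootstrap = 100L,
                       enet_alpha = 0.99,
                       enet_nlambda = 100L,
                       min_cells_per_line = 10L,
                       age_match_tolerance_days = 2.5,
                       min_celltypes_per_property = 5L,
                       inner_nfolds = 10L,
                       exclusions = NULL) {
  stopifnot(
    length(seed) == 1, is.finite(seed),
    all(bh_alpha_levels > 0 & bh_alpha_levels < 1),
    length(consistency_abs_r) == 1, consistency_abs_r > 0, consistency_abs_r < 1,
    n_permutations >= 1, n_bootstrap >= 1,
    enet_alpha > 0, enet_alpha <= 1,
    enet_nlambda >= 2,
    min_cells_per_line >= 1,
    age_match_tolerance_days >= 0,
    min_celltypes_per_property >= 3
  )
  if (!identical(inner_nfolds, "loo")) {
    stopifnot(is.numeric(inner_nfolds), inner_nfolds >= 3)
    inner_nfolds <- as.integer(inner_nfolds)
  }
  if (is.null(exclusions)) {
    exclusions <- tibble::tibble(cell_type_label = character(), property = character())
  } else {
    exclusions <- tibble::as_tibble(exclusions)
    stopifnot(all(c("cell_type_label", "property") %in% names(exclusions)))
    assert_property(exclusions$property)
  }
  structure(
    list(
      seed = as.integer(seed),
      bh_alpha_levels = sort(bh_alpha_levels),
      consistency_abs_r = consistency_abs_r,
      n_permutations = as.integer(n_permutations),
      n_bootstrap = as.integer(n_bootstrap),
      enet_alpha = enet_alpha,
      enet_nlambda = as.integer(enet_nlambda),
      min_cells_per_line = as.integer(min_cells_per_line),
      age_match_tolerance_days = age_match_tolerance_days,
      min_celltypes_per_property = as.integer(min_celltypes_per_property),
      inner_nfolds = inner_nfolds,
      exclusions = exclusions
    ),
    class = "run_config"
  )
}

#' @export
print.run_config <- function(x, ...) {
  cat("<run_config>\n")
  for (nm in setdiff(names(x), "exclusions")) {
    cat(sprintf("  %-28s %s\n", nm, paste(format(x[[nm]]), collapse = ", ")))
  }
  cat(sprintf("  %-28s %d pair(s)\n", "exclusions", nrow(x$exclusions)))
  invisible(x)
}

#' Read a run configuration from a YAML or JSON file
#'
#' Unknown keys are rejected; missing keys fall back to the defaults of
#' [run_config()]. `exclusions` may be given as a list of
#' `{cell_type_label, property}` records.
#'
#' @param path Path to a `.yaml`/`.yml` or `.json` file.
#' @return A `run_config` object.
#' @export
read_run_config <- function(path) {
  raw <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  known <- names(formals(run_config))
  bad <- setdiff(names(raw), known)
  if (length(bad) > 0) {
    stop("Unknown configuration key(s): ", paste(bad, collapse = ", "), call. = FALSE)
  }
  if (!is.null(raw$exclusions)) {
    raw$exclusions <- dplyr::bind_rows(lapply(raw$exclusions, tibble::as_tibble))
  }
  do.call(run_config, raw)
}

#' Write a run configuration to YAML
#'
#' @param cfg A `run_config`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_run_config <- function(cfg, path) {
  stopifnot(inherits(cfg, "run_config"))
  out <- unclass(cfg)
  out$exclusions <- if (nrow(cfg$exclusions) == 0) NULL else
    lapply(seq_len(nrow(cfg$exclusions)), function(i) as.list(cfg$exclusions[i, ]))
  yaml::write_yaml(out, path)
  invisible(path)
}
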