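# Univariate screen: per-gene Spearman correlations with each ephys
# property, per-property BH FDR, significance counting, and cross-dataset
# consistency statistics with a permutation null.

#' Spearman correlation with a two-sided p-value
#'
#' Average-rank Spearman correlation; the p-value uses the t approximation
#' `t = r * sqrt((n - 2) / (1 - r^2))` on `n - 2` degrees of freedom
#' (asymptotic, matching the standard implementation's behavior under
#' ties). `r_s = +/-1` reports the smallest representable positive
#' p-value. Zero variance in either vector gives an undefined (`NA`)
#' result, which downstream operations exclude.
#'
#' @param x,y Paired numeric vectors without missing values.
#' @return One-row tibble: `r_s`, `p_value`, `n`.
#' @examples
#' spearman_with_p(1:5, c(3, 1, 2, 5, 4)) # r_s = 0.6
#' @export
spearman_with_p <- function(x, y) {
  stopifnot(length(x) == length(y), !anyNA(x), !anyNA(y))
  n <- length(x)
  r <- spearman_vector(matrix(x, ncol = 1), y)
  tibble::tibble(r_s = r, p_value = spearman_p_from_r(r, n), n = n)
}

#' Benjamini-Hochberg step-up adjusted p-values
#'
#' Step-up FDR adjustment, capped at 1 and monotone in the input p-values.
#' Delegates to `stats::p.adjust(method = "BH")` after validating the
#' inputs lie in (0, 1].
#'
#' @param p Numeric vector of p-values in (0, 1].
#' @return Adjusted p-values, same order as the input.
#' @examples
#' bh_adjust(c(0.01, 0.02, 0.03)) # all 0.03
#' @export
bh_adjust <- function(p) {
  if (any(is.na(p)) || any(p <= 0 | p > 1)) {
    stop("p-values must lie in (0, 1].", call. = FALSE)
  }
  stats::p.adjust(p, method = "BH")
}

#' Screen every gene against every ephys property
#'
#' For each property with at least `cfg$min_celltypes_per_property` cell
#' types carrying a non-missing value, computes the Spearman correlation
#' of every gene's expression with the property across those cell types
#' (pairwise-complete), with BH adjustment applied within property only
#' (not across properties). Genes with zero expression variance over the
#' complete cell types are excluded and logged.
#'
#' @param dataset A [paired_dataset()], typically gene-filtered.
#' @param cfg A [run_config()].
#' @return Tibble with one row per (gene, property): `gene`, `property`,
#'   `n_celltypes`, `r_s`, `p_value`, `p_adj`. Attributes:
#'   `significance_counts` (per property x `cfg$bh_alpha_levels` gene
#'   counts), `skipped_properties`, `dropped_genes`.
#' @export
screen_correlations <- function(dataset, cfg = run_config()) {
  stopifnot(inherits(dataset, "paired_dataset"))
  X <- dataset$expression
  out <- list()
  skipped <- character(0)
  dropped <- tibble::tibble(gene = character(), property = character())
  for (p in colnames(dataset$ephys)) {
    y <- dataset$ephys[, p]
    ok <- !is.na(y)
    if (sum(ok) < cfg$min_celltypes_per_property) {
      if (any(ok)) {
        warning("Property ", p, " has only ", sum(ok),
                " complete cell types; skipped.", call. = FALSE)
        skipped <- c(skipped, p)
      }
      next
    }
    r <- spearman_vector(X[ok, , drop = FALSE], y[ok])
    undef <- is.na(r)
    if (any(undef)) {
      dropped <- dplyr::bind_rows(dropped, tibble::tibble(
        gene = colnames(X)[undef], property = p))
    }
    pv <- spearman_p_from_r(r[!undef], sum(ok))
    out[[p]] <- tibble::tibble(
      gene = colnames(X)[!undef],
      property = p,
      n_celltypes = sum(ok),
      r_s = r[!undef],
      p_value = pv,
      p_adj = bh_adjust(pv)
    )
  }
  res <- dplyr::bind_rows(out)
  counts <- tidyr::crossing(property = names(out), alpha = cfg$bh_alpha_levels) |>
    dplyr::rowwise() |>
    dplyr::mutate(n_significant = sum(res$p_adj[res$property == .data$property] <
                                        .data$alpha)) |>
    dplyr::ungroup()
  attr(res, "significance_counts") <- counts
  attr(res, "skipped_properties") <- skipped
  attr(res, "dropped_genes") <- dropped
  class(res) <- c("correlation_screen", class(res))
  res
}

#' Overall cross-dataset consistency for one property
#'
#' Spearman rank correlation between the discovery and validation r_s
#' vectors over their common genes (undefined correlations excluded
#' pairwise).
#'
#' @param disc,val Screen result tibbles (from [screen_correlations()]).
#' @param property Registered property code.
#' @return The rank correlation (scalar).
#' @export
consistency_overall <- function(disc, val, property) {
  assert_property(property)
  d <- disc[disc$property == property, c("gene", "r_s")]
  v <- val[val$property == property, c("gene", "r_s")]
  j <- dplyr::inner_join(d, v, by = "gene", suffix = c("_disc", "_val"))
  if (nrow(j) < 10) {
    stop("Fewer than 10 common genes for property '", property, "'.",
         call. = FALSE)
  }
  spearman_vector(matrix(j$r_s_disc, ncol = 1), j$r_s_val)
}

#' Per-gene cross-dataset consistency
#'
#' A (gene, property) pair discovered in the discovery dataset
#' (`p_adj < alpha`) is consistent iff the validation correlation has the
#' same sign and `|r_s|` exceeds `cfg$consistency_abs_r`. Discovered genes
#' absent from the validation screen are counted as not evaluable and
#' reported separately.
#'
#' @param disc,val Screen result tibbles.
#' @param cfg A [run_config()].
#' @param alpha Discovery FDR threshold.
#' @return List with `pairs` (per discovered pair: `gene`, `property`,
#'   `r_disc`, `r_val`, `evaluable`, `consistent`) and `summary` (per
#'   property: `n_discovered`, `n_consistent`, `pct_consistent`,
#'   `n_not_evaluable`).
#' @export
consistency_per_gene <- function(disc, val, cfg = run_config(), alpha = 0.05) {
  d <- disc[disc$p_adj < alpha, c("gene", "property", "r_s")]
  names(d)[3] <- "r_disc"
  v <- val[, c("gene", "property", "r_s")]
  names(v)[3] <- "r_val"
  pairs <- dplyr::left_join(d, v, by = c("gene", "property")) |>
    dplyr::mutate(
      evaluable = !is.na(.data$r_val),
      consistent = .data$evaluable &
        sign(.data$r_disc) == sign(.data$r_val) &
        abs(.data$r_val) > cfg$consistency_abs_r
    )
  summary <- pairs |>
    dplyr::group_by(.data$property) |>
    dplyr::summarise(
      n_discovered = dplyr::n(),
      n_consistent = sum(.data$consistent),
      pct_consistent = 100 * sum(.data$consistent) / dplyr::n(),
      n_not_evaluable = sum(!.data$evaluable),
      .groups = "drop"
    )
  list(pairs = pairs, summary = summary)
}

# Validation-side r_s vector for one property under a permutation of the
# link between ephys rows and expression rows. perm[i] gives the ephys row
# paired with expression row i; identity when NULL.
val_r_under_perm <- function(X, y, perm = NULL) {
  if (!is.null(perm)) y <- y[perm]
  ok <- !is.na(y)
  if (sum(ok) < 4) return(rep(NA_real_, ncol(X)))
  spearman_vector(X[ok, , drop = FALSE], y[ok])
}

#' Permutation null for a cross-dataset consistency statistic
#'
#' Shuffles the pairing between the validation dataset's ephys rows and
#' expression rows (each modality's internal structure intact), recomputes
#' the validation correlations and the chosen statistic per shuffle, and
#' reports the one-sided add-one-smoothed p-value
#' `p = (1 + #\{null >= observed\}) / (n_permutations + 1)`. With 1000
#' permutations a statistic exceeding every null value is reported as
#' p = 1/1001, conventionally printed "< 0.001".
#'
#' @param val_dataset The validation [paired_dataset()] (at least 4 cell
#'   types).
#' @param disc A discovery screen result tibble.
#' @param statistic `"overall_rho"` or `"pct_consistent"`.
#' @param cfg A [run_config()] (supplies `n_permutations` >= 100, the
#'   consistency rule and the seed).
#' @param property Registered property code.
#' @param alpha Discovery FDR threshold for `"pct_consistent"`.
#' @return An object of class `permutation_test`: list with `observed`,
#'   `null` (numeric vector), `p_value`, `statistic`, `property`,
#'   `n_permutations`.
#' @export
permutation_null <- function(val_dataset, disc,
                             statistic = c("overall_rho", "pct_consistent"),
                             cfg = run_config(), property, alpha = 0.05) {
  statistic <- match.arg(statistic)
  assert_property(property)
  stopifnot(inherits(val_dataset, "paired_dataset"), cfg$n_permutations >= 100)
  n <- nrow(val_dataset$expression)
  if (n < 4) stop("Need at least 4 cell types to permute.", call. = FALSE)

  d <- disc[disc$property == property, , drop = FALSE]
  genes <- intersect(colnames(val_dataset$expression), d$gene)
  if (length(genes) < 10) {
    stop("Fewer than 10 genes shared between discovery records and the ",
         "validation dataset for '", property, "'.", call. = FALSE)
  }
  d <- d[match(genes, d$gene), ]
  if (statistic == "pct_consistent") {
    # only discovered genes enter the statistic; dropping the rest leaves
    # every permuted value identical and saves the bulk of the ranking work
    keep <- d$p_adj < alpha
    if (any(keep)) {
      d <- d[keep, , drop = FALSE]
      genes <- genes[keep]
    }
  }
  X <- val_dataset$expression[, genes, drop = FALSE]
  y <- val_dataset$ephys[, property]

  stat_fun <- if (statistic == "overall_rho") {
    function(r_val) {
      ok <- !is.na(r_val)
      spearman_vector(matrix(d$r_s[ok], ncol = 1), r_val[ok])
    }
  } else {
    discovered <- d$p_adj < alpha
    if (!any(discovered)) {
      stop("No discovered genes at p_adj < ", alpha, " for '", property,
           "'.", call. = FALSE)
    }
    function(r_val) {
      rv <- r_val[discovered]
      ok <- !is.na(rv)
      if (!any(ok)) return(NA_real_)
      100 * sum(sign(d$r_s[discovered][ok]) == sign(rv[ok]) &
                  abs(rv[ok]) > cfg$consistency_abs_r) / sum(discovered)
    }
  }

  observed <- stat_fun(val_r_under_perm(X, y))
  B <- cfg$n_permutations
  null <- with_substream(cfg$seed, paste0("permnull_", property, "_", statistic), {
    if (!anyNA(y)) {
      # complete ephys: the complete-case set never changes, so rank once
      # and push all permutations through a single cross-product
      rx <- apply(X, 2, rank)
      rx <- sweep(rx, 2, colMeans(rx))
      sx <- sqrt(colSums(rx^2))
      ry <- rank(y); ry <- ry - mean(ry); sy <- sqrt(sum(ry^2))
      P <- replicate(B, ry[sample.int(n)])
      R <- crossprod(rx, P) / (sx %o% rep(sy, B))
      R[sx == 0, ] <- NA_real_
      apply(R, 2, stat_fun)
    } else {
      vapply(seq_len(B), function(b) {
        stat_fun(val_r_under_perm(X, y, sample.int(n)))
      }, numeric(1))
    }
  })
  structure(
    list(observed = observed, null = null,
         p_value = (1 + sum(null >= observed, na.rm = TRUE)) / (B + 1),
         statistic = statistic, property = property, n_permutations = B),
    class = "permutation_test"
  )
}

#' @export
print.permutation_test <- function(x, ...) {
  ptxt <- if (x$p_value < 1 / x$n_permutations) "< 0.001" else
    sprintf("%.3g", x$p_value)
  cat(sprintf("<permutation_test> %s / %s: observed = %.3f, p %s (B = %d)\n",
              x$property, x$statistic, x$observed,
              if (startsWith(ptxt, "<")) ptxt else paste("=", ptxt),
              x$n_permutations))
  invisible(x)
}

#' Full cross-dataset consistency table
#'
#' For every property screened in both datasets: the overall rank
#' correlation of the two r_s vectors with its permutation p-value, and
#' the count/percentage of discovered genes (discovery `p_adj < alpha`)
#' that are consistent in the validation dataset, with its permutation
#' p-value. Properties with no discovered gene report only the overall
#' statistics.
#'
#' @param disc Discovery screen result.
#' @param val_dataset Validation [paired_dataset()].
#' @param cfg A [run_config()].
#' @param alpha Discovery FDR threshold.
#' @return Tibble with one row per property: `property`, `overall_rho`,
#'   `overall_p`, `n_discovered`, `n_consistent`, `pct_consistent`,
#'   `consistency_p`.
#' @export
consistency_results <- function(disc, val_dataset, cfg = run_config(),
                                alpha = 0.05) {
  val <- screen_correlations(val_dataset, cfg)
  props <- intersect(unique(disc$property), unique(val$property))
  rows <- lapply(props, function(p) {
    overall <- permutation_null(val_dataset, disc, "overall_rho", cfg, p)
    d <- disc[disc$property == p & disc$gene %in% colnames(val_dataset$expression), ]
    n_disc <- sum(d$p_adj < alpha)
    if (n_disc > 0) {
      cons <- permutation_null(val_dataset, disc, "pct_consistent", cfg, p,
                               alpha = alpha)
      tibble::tibble(
        property = p, overall_rho = overall$observed, overall_p = overall$p_value,
        n_discovered = n_disc,
        n_consistent = as.integer(round(cons$observed * n_disc / 100)),
        pct_consistent = cons$observed, consistency_p = cons$p_value
      )
    } else {
      tibble::tibble(
        property = p, overall_rho = overall$observed, overall_p = overall$p_value,
        n_discovered = 0L, n_consistent = NA_integer_,
        pct_consistent = NA_real_, consistency_p = NA_real_
      )
    }
  })
  dplyr::bind_rows(rows)
}
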