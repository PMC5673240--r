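# Ephys measurement preprocessing, cell-type summarization, and the
# derived single-cell features (adaptation ratio, capacitance, maximal
# firing rate sweep).

#' Filter and standardize curated ephys measurements
#'
#' Applies the preprocessing rules used before condition modeling:
#' \itemize{
#'   \item keep only acute-slice preparations from mouse, rat or guinea pig;
#'   \item collapse reported age ranges to their geometric mean and drop
#'     recordings from animals aged 2 days or less;
#'   \item median-impute missing ages and recording temperatures from the
#'     non-missing values of the remaining records;
#'   \item remove any (cell type, property) pairs listed in
#'     `cfg$exclusions`;
#'   \item revert liquid-junction-potential corrections: records with
#'     `jxn_status == "corrected"` and a known `jxn_offset_mV` have the
#'     offset added back on the voltage-valued properties (Vrest, APthr)
#'     and their status set to `"post_corrected"`.
#' }
#'
#' @param records Measurement tibble (see [ephys_measurements()]).
#' @param cfg A [run_config()].
#' @return The filtered tibble with an added `age_days` column (collapsed,
#'   imputed) and imputed `rec_temp_C`; a `filter_log` attribute records
#'   how many rows each rule removed.
#' @export
preprocess_measurements <- function(records, cfg = run_config()) {
  df <- ephys_measurements(records)
  log <- list(n_input = nrow(df))

  keep <- df$preparation == "acute_slice"
  log$n_removed_preparation <- sum(!keep)
  df <- df[keep, ]

  keep <- df$species %in% c("mouse", "rat", "guinea_pig")
  log$n_removed_species <- sum(!keep)
  df <- df[keep, ]

  df$age_days <- dplyr::case_when(
    !is.na(df$age_lo_days) & !is.na(df$age_hi_days) ~
      exp((log(df$age_lo_days) + log(df$age_hi_days)) / 2),
    !is.na(df$age_lo_days) ~ df$age_lo_days,
    !is.na(df$age_hi_days) ~ df$age_hi_days,
    TRUE ~ NA_real_
  )
  keep <- is.na(df$age_days) | df$age_days > 2
  log$n_removed_age <- sum(!keep)
  df <- df[keep, ]

  if (nrow(cfg$exclusions) > 0) {
    drop <- paste(df$cell_type_label, df$property) %in%
      paste(cfg$exclusions$cell_type_label, cfg$exclusions$property)
    log$n_removed_exclusions <- sum(drop)
    df <- df[!drop, ]
  } else {
    log$n_removed_exclusions <- 0L
  }

  log$n_imputed_age <- sum(is.na(df$age_days))
  log$n_imputed_temp <- sum(is.na(df$rec_temp_C))
  if (any(is.na(df$age_days))) {
    df$age_days[is.na(df$age_days)] <- stats::median(df$age_days, na.rm = TRUE)
  }
  if (any(is.na(df$rec_temp_C))) {
    df$rec_temp_C[is.na(df$rec_temp_C)] <- stats::median(df$rec_temp_C, na.rm = TRUE)
  }

  revert <- df$jxn_status == "corrected" & !is.na(df$jxn_offset_mV) &
    df$property %in% c("Vrest", "APthr")
  log$n_ljp_reverted <- sum(revert)
  df$value[revert] <- df$value[revert] + df$jxn_offset_mV[revert]
  df$jxn_status[revert] <- "post_corrected"

  attr(df, "filter_log") <- tibble::as_tibble(log)
  df
}

#' Summarize adjusted measurements to cell-type medians
#'
#' Per (cell type, property): measurements are first averaged within each
#' article, then the median is taken across articles. Cell types with no
#' article for a property are missing for that property.
#'
#' @param records Preprocessed (and typically condition-adjusted)
#'   measurement tibble with an `age_days` column.
#' @return A [celltype_matrix()] of kind `"ephys"` (cell types x the 11
#'   registered properties, `NA` where unmeasured), whose metadata carries
#'   each type's median article age. An `article_counts` attribute holds
#'   the per-(type, property) article counts.
#' @export
summarize_ephys_by_cell_type <- function(records) {
  df <- tibble::as_tibble(records)
  stopifnot(all(c("cell_type_label", "property", "value", "article_id") %in% names(df)))
  assert_property(df$property)
  per_article <- df |>
    dplyr::group_by(.data$cell_type_label, .data$property, .data$article_id) |>
    dplyr::summarise(value = mean(.data$value), .groups = "drop")
  per_type <- per_article |>
    dplyr::group_by(.data$cell_type_label, .data$property) |>
    dplyr::summarise(value = stats::median(.data$value),
                     n_articles = dplyr::n(), .groups = "drop")
  types <- unique(df$cell_type_label)
  props <- ephys_property_codes()
  vals <- matrix(NA_real_, length(types), length(props),
                 dimnames = list(types, props))
  vals[cbind(match(per_type$cell_type_label, types),
             match(per_type$property, props))] <- per_type$value
  age_meta <- if ("age_days" %in% names(df)) {
    df |>
      dplyr::group_by(cell_type = .data$cell_type_label) |>
      dplyr::summarise(age_days = stats::median(.data$age_days, na.rm = TRUE),
                       .groups = "drop")
  } else {
    tibble::tibble(cell_type = types, age_days = NA_real_)
  }
  out <- celltype_matrix(vals, age_meta, "ephys")
  attr(out, "article_counts") <- per_type[, c("cell_type_label", "property", "n_articles")]
  out
}

#' Spike-frequency adaptation ratio
#'
#' First inter-spike interval divided by the mean inter-spike interval of
#' the maximal-firing sweep. Adapting trains (lengthening intervals) give
#' values below 1, approaching 0 for strong adaptation; a constant train
#' gives exactly 1.
#'
#' @param isis Ordered inter-spike intervals (ms), all positive.
#' @return The adaptation ratio (dimensionless).
#' @examples
#' compute_sfa(c(10, 20, 30)) # 0.5
#' @export
compute_sfa <- function(isis) {
  if (length(isis) < 1 || any(!is.finite(isis)) || any(isis <= 0)) {
    stop("isis must be one or more positive inter-spike intervals.", call. = FALSE)
  }
  isis[1] / mean(isis)
}

#' Membrane capacitance from time constant and input resistance
#'
#' \eqn{C_m = \tau / R_{in}}; with \eqn{\tau} in ms and \eqn{R_{in}} in
#' MOhm the ratio is in nF, reported in pF.
#'
#' @param tau_ms Membrane time constant, ms (> 0).
#' @param rin_Mohm Input resistance, MOhm (> 0).
#' @return Capacitance in pF.
#' @examples
#' derive_capacitance(20, 200) # 100 pF
#' @export
derive_capacitance <- function(tau_ms, rin_Mohm) {
  if (any(!is.finite(tau_ms)) || any(!is.finite(rin_Mohm)) ||
      any(tau_ms <= 0) || any(rin_Mohm <= 0)) {
    stop("tau_ms and rin_Mohm must be positive.", call. = FALSE)
  }
  1000 * tau_ms / rin_Mohm
}

#' Pick the maximal-firing sweep and its rate
#'
#' Returns the sweep eliciting the greatest number of spikes (first on
#' ties, with the tie noted) and its firing rate.
#'
#' @param spike_counts_per_sweep Integer spike counts, one per sweep.
#' @param sweep_duration_s Stimulus duration per sweep, seconds (> 0).
#' @return A list with `sweep` (1-based index), `fr_max_hz`, `tie`
#'   (logical) and `all_zero` (logical flag when no sweep spiked).
#' @examples
#' select_max_rate_sweep(c(2, 10, 7), 1) # sweep 2, 10 Hz
#' @export
select_max_rate_sweep <- function(spike_counts_per_sweep, sweep_duration_s) {
  stopifnot(length(spike_counts_per_sweep) >= 1, sweep_duration_s > 0)
  counts <- spike_counts_per_sweep
  i <- which.max(counts)
  list(
    sweep = i,
    fr_max_hz = counts[i] / sweep_duration_s,
    tie = sum(counts == counts[i]) > 1,
    all_zero = all(counts == 0)
  )
}
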