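# Shared containers and delimited-text I/O.
#
# File dialect: UTF-8, tab-delimited by default with comma auto-detection;
# "NA" and the empty string both parse as missing. Gene/probe identifiers
# are opaque strings treated as stable keys; no identifier translation is
# performed. Units are fixed per property (see ephys_properties()).

SPECIES_LEVELS     <- c("mouse", "rat", "guinea_pig", "other")
PREPARATION_LEVELS <- c("acute_slice", "in_vivo", "culture", "other")
ELECTRODE_LEVELS   <- c("patch", "perforated_patch", "sharp", "unreported")
JXN_LEVELS         <- c("corrected", "not_corrected", "unreported", "post_corrected")
EXPRESSION_SCALES  <- c("log2_intensity", "tpm", "log2_tpm1", "zscore")

#' Construct an expression matrix container
#'
#' A feature (probe or gene) by sample matrix together with its measurement
#' scale and per-sample metadata. All downstream expression operations accept
#' and return this container.
#'
#' @param values Numeric matrix, features in rows, samples in columns, with
#'   unique dimnames. Non-finite entries are rejected.
#' @param scale One of `"log2_intensity"`, `"tpm"`, `"log2_tpm1"`,
#'   `"zscore"`.
#' @param sample_meta Data frame with one row per sample: `sample_id`
#'   (matching the column names), `cell_type_label`, and optionally
#'   `age_days` (non-negative or `NA`), `platform`, and a logical `qc_flag`
#'   marking samples failing upstream quality control.
#' @return An object of class `expression_matrix`.
#' @export
expression_matrix <- function(values, scale, sample_meta) {
  scale <- match.arg(scale, EXPRESSION_SCALES)
  stopifnot(is.matrix(values), is.numeric(values))
  if (any(!is.finite(values))) {
    stop("Expression values contain non-finite entries.", call. = FALSE)
  }
  fid <- rownames(values); sid <- colnames(values)
  if (is.null(fid) || is.null(sid)) {
    stop("values must carry feature and sample dimnames.", call. = FALSE)
  }
  dup <- fid[duplicated(fid)]
  if (length(dup) > 0) {
    stop("Duplicated feature id(s): ", paste(unique(dup), collapse = ", "),
         call. = FALSE)
  }
  if (anyDuplicated(sid)) {
    stop("Duplicated sample id(s): ",
         paste(unique(sid[duplicated(sid)]), collapse = ", "), call. = FALSE)
  }
  sample_meta <- tibble::as_tibble(sample_meta)
  stopifnot(all(c("sample_id", "cell_type_label") %in% names(sample_meta)))
  missing_meta <- setdiff(sid, sample_meta$sample_id)
  if (length(missing_meta) > 0) {
    stop("No metadata for sample(s): ", paste(missing_meta, collapse = ", "),
         call. = FALSE)
  }
  sample_meta <- sample_meta[match(sid, sample_meta$sample_id), ]
  if (!"age_days" %in% names(sample_meta)) sample_meta$age_days <- NA_real_
  if (any(!is.na(sample_meta$age_days) & sample_meta$age_days < 0)) {
    stop("Negative age_days in sample metadata.", call. = FALSE)
  }
  structure(
    list(values = values, scale = scale, sample_meta = sample_meta),
    class = "expression_matrix"
  )
}

#' @export
print.expression_matrix <- function(x, ...) {
  cat(sprintf("<expression_matrix> %d features x %d samples [%s]\n",
              nrow(x$values), ncol(x$values), x$scale))
  cat(sprintf("  cell types: %d\n", dplyr::n_distinct(x$sample_meta$cell_type_label)))
  invisible(x)
}

#' @export
dim.expression_matrix <- function(x) dim(x$values)

# Read a delimited file as a character data frame, tab by default with
# comma auto-detection from the header line.
read_delim_auto <- function(path) {
  header <- readLines(path, n = 1)
  delim <- if (grepl("\t", header)) "\t" else ","
  readr::read_delim(path, delim = delim, col_types = readr::cols(.default = "c"),
                    na = c("", "NA"), progress = FALSE,
                    show_col_types = FALSE)
}

#' Read an expression matrix and its sample metadata
#'
#' Expects delimited text (tab by default, comma auto-detected): first
#' column feature id, header row of sample ids, and a sibling metadata table
#' keyed by `sample_id`.
#'
#' @param path Matrix file.
#' @param scale Measurement scale of the stored values (see
#'   [expression_matrix()]).
#' @param meta_path Metadata file; defaults to `path` with `_meta` inserted
#'   before the extension.
#' @return An `expression_matrix`.
#' @export
read_expression_matrix <- function(path, scale, meta_path = default_meta_path(path)) {
  df <- read_delim_auto(path)
  fid <- df[[1]]
  dup <- unique(fid[duplicated(fid)])
  if (length(dup) > 0) {
    stop("Duplicated feature id(s) in ", path, ": ",
         paste(dup, collapse = ", "), call. = FALSE)
  }
  raw <- as.matrix(df[, -1, drop = FALSE])
  vals <- suppressWarnings(array(as.numeric(raw), dim = dim(raw)))
  if (any(is.na(vals) & !is.na(raw))) {
    idx <- which(is.na(vals) & !is.na(raw), arr.ind = TRUE)[1, ]
    stop(sprintf("Non-numeric expression value at feature '%s', sample '%s': '%s'",
                 fid[idx[1]], colnames(raw)[idx[2]], raw[idx[1], idx[2]]),
         call. = FALSE)
  }
  if (any(is.na(vals))) {
    idx <- which(is.na(vals), arr.ind = TRUE)[1, ]
    stop(sprintf("Missing expression value at feature '%s', sample '%s'",
                 fid[idx[1]], colnames(raw)[idx[2]]), call. = FALSE)
  }
  dimnames(vals) <- list(fid, colnames(raw))
  meta <- read_delim_auto(meta_path)
  meta <- type_sample_meta(meta)
  expression_matrix(vals, scale, meta)
}

default_meta_path <- function(path) {
  sub("(\\.[A-Za-z0-9]+)$", "_meta\\1", path)
}

type_sample_meta <- function(meta) {
  meta <- tibble::as_tibble(meta)
  if ("age_days" %in% names(meta)) meta$age_days <- as.numeric(meta$age_days)
  if ("qc_flag" %in% names(meta)) meta$qc_flag <- as.logical(meta$qc_flag)
  meta
}

#' Write an expression matrix (and its metadata) to tab-delimited text
#'
#' @param m An `expression_matrix`.
#' @param path Matrix output file.
#' @param meta_path Metadata output file (default as in
#'   [read_expression_matrix()]).
#' @return `path`, invisibly.
#' @export
write_expression_matrix <- function(m, path, meta_path = default_meta_path(path)) {
  stopifnot(inherits(m, "expression_matrix"))
  df <- tibble::as_tibble(m$values, rownames = "feature_id")
  readr::write_tsv(df, path, progress = FALSE)
  readr::write_tsv(m$sample_meta, meta_path, progress = FALSE)
  invisible(path)
}

#' Construct/validate a table of curated ephys measurements
#'
#' One row per article-level measurement of one property for one cell type,
#' with the methodological metadata needed for cross-study normalization.
#' Categorical fields are validated against their closed level sets; ages
#' are in days; recording temperature in degrees Celsius.
#'
#' @param df Data frame with columns `article_id`, `cell_type_label`,
#'   `property`, `value`, `species`, `preparation`, `electrode`,
#'   `jxn_status`, and optionally `jxn_offset_mV`, `age_lo_days`,
#'   `age_hi_days`, `rec_temp_C`. Missing optional columns are added as
#'   `NA`.
#' @return A validated tibble (class `tbl_df`).
#' @export
ephys_measurements <- function(df) {
  df <- tibble::as_tibble(df)
  required <- c("article_id", "cell_type_label", "property", "value",
                "species", "preparation", "electrode", "jxn_status")
  miss <- setdiff(required, names(df))
  if (length(miss) > 0) {
    stop("Missing ephys table column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  for (col in c("jxn_offset_mV", "age_lo_days", "age_hi_days", "rec_temp_C")) {
    if (!col %in% names(df)) df[[col]] <- NA_real_
    df[[col]] <- suppressWarnings(as.numeric(df[[col]]))
  }
  df$value <- suppressWarnings(as.numeric(df$value))
  if (any(is.na(df$value))) {
    stop("Non-numeric or missing ephys value at row ",
         which(is.na(df$value))[1], call. = FALSE)
  }
  assert_property(df$property)
  check_enum <- function(x, levels, what) {
    x <- tolower(trimws(x))
    bad <- setdiff(unique(x), levels)
    if (length(bad) > 0) {
      stop("Unknown ", what, " level(s): ", paste(bad, collapse = ", "),
           call. = FALSE)
    }
    x
  }
  df$species     <- check_enum(df$species, SPECIES_LEVELS, "species")
  df$preparation <- check_enum(df$preparation, PREPARATION_LEVELS, "preparation")
  df$electrode   <- check_enum(df$electrode, ELECTRODE_LEVELS, "electrode")
  df$jxn_status  <- check_enum(df$jxn_status, JXN_LEVELS, "jxn_status")
  both <- !is.na(df$age_lo_days) & !is.na(df$age_hi_days)
  if (any(both & df$age_lo_days > df$age_hi_days)) {
    stop("age_lo_days > age_hi_days at row ",
         which(both & df$age_lo_days > df$age_hi_days)[1], call. = FALSE)
  }
  df[, c(required, "jxn_offset_mV", "age_lo_days", "age_hi_days", "rec_temp_C")]
}

#' Read a curated ephys measurement table
#'
#' Delimited text, one row per measurement. An `age_days` column may give a
#' point age (`"16"`) or a range (`"14-20"`), which is split into
#' `age_lo_days`/`age_hi_days`; alternatively those two columns may be given
#' directly. Enum fields parse case-insensitively; empty cells mean missing.
#'
#' @param path Input file.
#' @return A validated tibble of measurements (see [ephys_measurements()]).
#' @export
read_ephys_table <- function(path) {
  df <- read_delim_auto(path)
  if ("age_days" %in% names(df) &&
      !all(c("age_lo_days", "age_hi_days") %in% names(df))) {
    parts <- strsplit(ifelse(is.na(df$age_days), "", df$age_days), "-", fixed = TRUE)
    df$age_lo_days <- vapply(parts, function(p) {
      if (length(p) == 0) NA_real_ else as.numeric(p[1])
    }, numeric(1))
    df$age_hi_days <- vapply(parts, function(p) {
      if (length(p) == 0) NA_real_ else as.numeric(p[length(p)])
    }, numeric(1))
    df$age_days <- NULL
  }
  ephys_measurements(df)
}

#' Write an ephys measurement table to tab-delimited text
#'
#' @param records Measurement tibble (validated by [ephys_measurements()]).
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_ephys_table <- function(records, path) {
  readr::write_tsv(ephys_measurements(records), path, progress = FALSE)
  invisible(path)
}

#' Read a cell-type mapping table
#'
#' Two-column delimited file `(expression_label, ephys_label)`, with an
#' optional third column `age_days` annotating the expression-side age.
#'
#' @param path Input file.
#' @return Tibble with columns `expression_label`, `ephys_label` and
#'   optionally `age_days`.
#' @export
read_celltype_mapping <- function(path) {
  df <- read_delim_auto(path)
  stopifnot(ncol(df) >= 2)
  names(df)[1:2] <- c("expression_label", "ephys_label")
  if (ncol(df) >= 3) {
    names(df)[3] <- "age_days"
    df$age_days <- as.numeric(df$age_days)
  }
  tibble::as_tibble(df)
}
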