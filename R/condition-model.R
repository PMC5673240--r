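# Cross-study normalization of curated ephys measurements.
#
# Each property is modeled additively on its modeling scale as
#   value ~ cell type + species + junction-potential status + electrode
#           + bs(log10(age), 5 df) + bs(temperature, 5 df)
# with an elastic-net penalty (mixing weight 0.99, 100-value path) chosen
# by cross-validation grouped by article. Cell-type terms are part of the
# fit but never of the adjustment: adjusting them away would erase the
# biology under study.

CONDITION_FACTORS <- c("species", "jxn_status", "electrode")

# Categorical dummy columns for the levels seen at fit time, reference =
# most frequent level. Returns NULL for single-level (dropped) terms.
factor_columns <- function(x, levels_by_freq, term) {
  if (length(levels_by_freq) < 2) return(NULL)
  non_ref <- levels_by_freq[-1]
  cols <- vapply(non_ref, function(l) as.numeric(x == l), numeric(length(x)))
  if (is.null(dim(cols))) cols <- matrix(cols, nrow = length(x))
  colnames(cols) <- paste0(term, "=", non_ref)
  cols
}

spline_columns <- function(x, def, clamp = TRUE) {
  if (def$boundary[1] >= def$boundary[2]) {
    # covariate was constant at fit time: no spline term
    return(list(cols = NULL, clamped = rep(FALSE, length(x))))
  }
  clamped <- x < def$boundary[1] | x > def$boundary[2]
  if (clamp) x <- pmin(pmax(x, def$boundary[1]), def$boundary[2])
  cols <- splines::bs(x, knots = def$knots, Boundary.knots = def$boundary,
                      degree = 3, intercept = FALSE)
  colnames(cols) <- paste0(def$name, "_bs", seq_len(ncol(cols)))
  list(cols = cols, clamped = clamped)
}

# Condition-term design (everything except cell type) at given covariates.
condition_design <- function(df, spec) {
  blocks <- list()
  unseen <- rep(FALSE, nrow(df))
  for (term in CONDITION_FACTORS) {
    lv <- spec$factor_levels[[term]]
    unseen <- unseen | !(df[[term]] %in% lv)
    cb <- factor_columns(df[[term]], lv, term)
    if (!is.null(cb)) blocks[[term]] <- cb
  }
  sa <- spline_columns(log10(df$age_days), spec$spline_age)
  st <- spline_columns(df$rec_temp_C, spec$spline_temp)
  if (!is.null(sa$cols)) blocks$age <- sa$cols
  if (!is.null(st$cols)) blocks$temp <- st$cols
  X <- if (length(blocks) > 0) do.call(cbind, blocks) else
    matrix(numeric(0), nrow = nrow(df), ncol = 0)
  list(X = X, unseen = unseen, clamped = sa$clamped | st$clamped)
}

most_frequent_first <- function(x) names(sort(table(x), decreasing = TRUE))

#' Fit a cross-study condition-normalization model for one property
#'
#' Fits the additive model described above on article-level records, with
#' the penalty selected by internal cross-validation (folds grouped by
#' article so duplicated records never straddle folds; seeded). Reference
#' conditions default to the most frequent level of each categorical term
#' and the dataset median of log10(age) and temperature. Spline boundary
#' knots are fixed to the observed covariate range; prediction beyond them
#' clamps to the boundary and flags the record.
#'
#' @param records Preprocessed measurements (from
#'   [preprocess_measurements()]; must carry `age_days` and `rec_temp_C`).
#' @param property A registered property code present in `records`.
#' @param cfg A [run_config()] (supplies `enet_alpha`, `enet_nlambda`,
#'   `seed`).
#' @return A serializable object of class `condition_model`: coefficients,
#'   intercept, factor level sets, spline definitions, reference
#'   conditions, transform, and fit diagnostics (chosen penalty,
#'   cross-validated error).
#' @export
fit_condition_model <- function(records, property, cfg = run_config()) {
  assert_property(property)
  df <- tibble::as_tibble(records)
  stopifnot(all(c("age_days", "rec_temp_C") %in% names(df)))
  df <- df[df$property == property, ]
  if (dplyr::n_distinct(df$cell_type_label) < 2 || nrow(df) < 10) {
    stop("Need >= 2 cell types and >= 10 records for property '", property,
         "'.", call. = FALSE)
  }
  y <- to_model_scale(df$value, property)

  factor_levels <- list()
  for (term in CONDITION_FACTORS) {
    lv <- most_frequent_first(df[[term]])
    if (length(lv) < 2) {
      warning("Term '", term, "' has a single level ('", lv,
              "') and is dropped from the condition model for ", property, ".",
              call. = FALSE)
    }
    factor_levels[[term]] <- lv
  }
  make_spline_def <- function(x, name) {
    # df = 5 cubic B-spline without intercept: 2 interior knots at the
    # tertiles of the observed covariate (splines::bs default placement)
    qs <- stats::quantile(x, probs = c(1, 2) / 3, names = FALSE)
    list(name = name, knots = unique(qs), boundary = range(x))
  }
  spec <- list(
    factor_levels = factor_levels,
    spline_age = make_spline_def(log10(df$age_days), "log10_age"),
    spline_temp = make_spline_def(df$rec_temp_C, "rec_temp")
  )

  cond <- condition_design(df, spec)
  ct_levels <- most_frequent_first(df$cell_type_label)
  Xct <- factor_columns(df$cell_type_label, ct_levels, "cell_type")
  X <- cbind(Xct, cond$X)

  articles <- unique(df[, c("article_id", "cell_type_label")])
  nfolds <- min(10, max(3, nrow(articles)))
  foldid <- with_substream(cfg$seed, paste0("condition_folds_", property), {
    # folds grouped by article and stratified by cell type, so every
    # training fold sees (nearly) every cell type
    fold_of_article <- integer(nrow(articles))
    start <- 0L
    for (ct in unique(articles$cell_type_label)) {
      idx <- which(articles$cell_type_label == ct)
      fold_of_article[idx] <- 1L +
        (start + sample(seq_along(idx)) - 1L) %% nfolds
      start <- start + length(idx)
    }
    fold_of_article[match(df$article_id, articles$article_id)]
  })
  # cell-type terms are left unpenalized: shrinking them lets genuine
  # cell-type differences leak into condition terms they are confounded
  # with (age especially), which the adjustment would then wrongly remove
  pf <- if (ncol(cond$X) == 0) rep(1, ncol(X)) else
    c(rep(0, ncol(Xct)), rep(1, ncol(cond$X)))
  cvfit <- glmnet::cv.glmnet(X, y, alpha = cfg$enet_alpha,
                             nlambda = cfg$enet_nlambda, foldid = foldid,
                             grouped = FALSE, standardize = TRUE,
                             penalty.factor = pf, thresh = 1e-10)
  beta <- as.numeric(stats::coef(cvfit, s = "lambda.min"))
  names(beta) <- c("(Intercept)", colnames(X))

  reference <- list(
    species = factor_levels$species[1],
    jxn_status = factor_levels$jxn_status[1],
    electrode = factor_levels$electrode[1],
    log10_age = stats::median(log10(df$age_days)),
    rec_temp_C = stats::median(df$rec_temp_C)
  )
  structure(
    list(
      property = property,
      transform = if (is_log10_property(property)) "log10" else "identity",
      intercept = beta[1],
      coefficients = beta[-1],
      condition_terms = colnames(cond$X),
      celltype_terms = colnames(Xct),
      spec = spec,
      reference_conditions = reference,
      fit_diagnostics = list(
        lambda_min = cvfit$lambda.min,
        cvm_min = min(cvfit$cvm),
        n_records = nrow(df),
        n_articles = length(articles),
        nfolds = nfolds
      )
    ),
    class = "condition_model"
  )
}

#' @export
print.condition_model <- function(x, ...) {
  cat(sprintf("<condition_model> %s [%s scale], %d records / %d articles\n",
              x$property, x$transform, x$fit_diagnostics$n_records,
              x$fit_diagnostics$n_articles))
  cat(sprintf("  lambda = %.4g; %d of %d condition coefficients nonzero\n",
              x$fit_diagnostics$lambda_min,
              sum(x$coefficients[x$condition_terms] != 0),
              length(x$condition_terms)))
  invisible(x)
}

#' Adjust measurements to reference experimental conditions
#'
#' Each value is moved to the model's reference conditions on the modeling
#' scale: `adjusted = observed - (predicted at observed covariates -
#' predicted at reference covariates)`, using only the condition terms
#' (species, junction potential, electrode, age and temperature splines);
#' cell-type terms are biological signal and are never adjusted. Values
#' are back-transformed for log10 properties. Records with a categorical
#' level unseen at fit time are left unadjusted and flagged; records whose
#' age or temperature falls outside the spline boundary are adjusted at
#' the clamped boundary value and flagged.
#'
#' @param model A [fit_condition_model()] result.
#' @param records Preprocessed measurements for the model's property.
#' @return The records tibble with `value` adjusted, the original in
#'   `value_raw`, and an `adjust_flag` column (`"ok"`, `"unseen_level"`,
#'   `"clamped"`).
#' @export
adjust_measurements <- function(model, records) {
  stopifnot(inherits(model, "condition_model"))
  df <- tibble::as_tibble(records)
  df <- df[df$property == model$property, ]
  if (nrow(df) == 0) return(df)
  stopifnot(all(c("age_days", "rec_temp_C") %in% names(df)))

  obs <- condition_design(df, model$spec)
  ref_df <- tibble::tibble(
    species = model$reference_conditions$species,
    jxn_status = model$reference_conditions$jxn_status,
    electrode = model$reference_conditions$electrode,
    age_days = 10^model$reference_conditions$log10_age,
    rec_temp_C = model$reference_conditions$rec_temp_C
  )
  ref <- condition_design(ref_df, model$spec)
  beta <- model$coefficients[model$condition_terms]
  delta <- as.numeric(obs$X %*% beta) - as.numeric(ref$X %*% beta)
  delta[obs$unseen] <- 0

  y <- to_model_scale(df$value, model$property)
  df$value_raw <- df$value
  df$value <- from_model_scale(y - delta, model$property)
  df$adjust_flag <- dplyr::case_when(
    obs$unseen ~ "unseen_level",
    obs$clamped ~ "clamped",
    TRUE ~ "ok"
  )
  df
}

#' Serialize / read a condition model as JSON
#'
#' @param model A `condition_model`.
#' @param path Output / input path.
#' @return `path` invisibly (write); a `condition_model` (read).
#' @export
write_condition_model <- function(model, path) {
  stopifnot(inherits(model, "condition_model"))
  out <- unclass(model)
  out$coefficients <- as.list(out$coefficients)
  jsonlite::write_json(out, path, digits = NA, na = "null", auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_condition_model
#' @export
read_condition_model <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  raw$coefficients <- unlist(raw$coefficients)
  raw$spec$spline_age$knots <- as.numeric(raw$spec$spline_age$knots)
  raw$spec$spline_temp$knots <- as.numeric(raw$spec$spline_temp$knots)
  structure(raw, class = "condition_model")
}

#' Fit condition models and adjust a full measurement table
#'
#' Convenience wrapper: for every property with enough records, fits the
#' condition model and adjusts its measurements; properties with too few
#' records pass through unadjusted.
#'
#' @param records Preprocessed measurements.
#' @param cfg A [run_config()].
#' @return A list with `records` (all properties, adjusted where possible)
#'   and `models` (named list of `condition_model`s).
#' @export
normalize_ephys_conditions <- function(records, cfg = run_config()) {
  df <- tibble::as_tibble(records)
  models <- list()
  pieces <- list()
  for (p in intersect(ephys_property_codes(), unique(df$property))) {
    sub <- df[df$property == p, ]
    fit_ok <- dplyr::n_distinct(sub$cell_type_label) >= 2 && nrow(sub) >= 10
    if (fit_ok) {
      models[[p]] <- fit_condition_model(df, p, cfg)
      pieces[[p]] <- adjust_measurements(models[[p]], df)
    } else {
      sub$value_raw <- sub$value
      sub$adjust_flag <- "unadjusted"
      pieces[[p]] <- sub
    }
  }
  list(records = dplyr::bind_rows(pieces), models = models)
}
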