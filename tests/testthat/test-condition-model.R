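# Helper: article-level Vrest records with a planted temperature slope and
# otherwise homogeneous metadata-independent structure.
temp_effect_records <- function(seed, slope = 0.5, n_types = 15,
                                articles_per_type = 6) {
  withr::with_seed(seed, {
    types <- sprintf("T%02d", seq_len(n_types))
    base <- rnorm(n_types, -65, 6)
    df <- tidyr::crossing(cell_type_label = types,
                          k = seq_len(articles_per_type))
    n <- nrow(df)
    df$article_id <- sprintf("A%04d", seq_len(n))
    df$property <- "Vrest"
    df$rec_temp_C <- round(runif(n, 22, 36), 1)
    df$age_lo_days <- df$age_hi_days <- round(runif(n, 12, 60))
    df$species <- sample(c("mouse", "rat"), n, TRUE)
    df$preparation <- "acute_slice"
    df$electrode <- sample(c("patch", "sharp"), n, TRUE, prob = c(0.8, 0.2))
    df$jxn_status <- sample(c("not_corrected", "unreported"), n, TRUE)
    df$jxn_offset_mV <- NA_real_
    df$value <- base[match(df$cell_type_label, types)] +
      slope * (df$rec_temp_C - 29) + rnorm(n, 0, 1)
    list(records = ephys_measurements(df[, -2]),
         latent = stats::setNames(base, types))
  })
}

residual_temp_slope <- function(records) {
  res <- records$value - ave(records$value, records$cell_type_label)
  unname(coef(lm(res ~ records$rec_temp_C))[2])
}

test_that("a planted temperature effect is removed by condition adjustment", {
  sim <- temp_effect_records(seed = 21)
  rec <- preprocess_measurements(sim$records)
  fit <- fit_condition_model(rec, "Vrest", run_config(seed = 21))
  adj <- adjust_measurements(fit, rec)
  expect_lte(abs(residual_temp_slope(adj)), 0.2 * 0.5)
  expect_lt(abs(residual_temp_slope(adj)), abs(residual_temp_slope(rec)))
  # per-type medians approach the latent values after adjustment
  rmse <- function(r) {
    ct <- summarize_ephys_by_cell_type(r)
    sqrt(mean((ct$values[names(sim$latent), "Vrest"] - sim$latent)^2))
  }
  expect_lt(rmse(adj), rmse(rec))
})

test_that("zero metadata variation reduces the model to cell-type means", {
  rec <- dplyr::bind_rows(lapply(1:12, function(i) {
    toy_measurement(article_id = sprintf("A%d", i),
                    cell_type_label = sprintf("T%d", (i - 1) %% 4 + 1),
                    value = -70 + 2 * ((i - 1) %% 4))
  }))
  rec <- suppressWarnings(preprocess_measurements(rec))
  fit <- suppressWarnings(fit_condition_model(rec, "Vrest", run_config()))
  adj <- adjust_measurements(fit, rec)
  expect_equal(adj$value, adj$value_raw, tolerance = 1e-6)
})

test_that("duplicating every record leaves the fit unchanged under grouped folds", {
  sim <- temp_effect_records(seed = 4, n_types = 8, articles_per_type = 5)
  rec <- preprocess_measurements(sim$records)
  cfg <- run_config(seed = 4)
  f1 <- fit_condition_model(rec, "Vrest", cfg)
  f2 <- fit_condition_model(dplyr::bind_rows(rec, rec), "Vrest", cfg)
  expect_equal(f1$coefficients, f2$coefficients, tolerance = 1e-8)
  expect_equal(f1$intercept, f2$intercept, tolerance = 1e-8)
})

test_that("adjustment moves records to reference conditions by the model's own delta", {
  # hand-built model with a pure temperature effect: no factor terms, no
  # age spline, known spline coefficients
  sdef <- list(name = "rec_temp", knots = c(28, 32), boundary = c(20, 40))
  w <- c(2, -1, 0.5, 1.5, -0.5)
  model <- structure(list(
    property = "Vrest", transform = "identity", intercept = -65,
    coefficients = stats::setNames(w, paste0("rec_temp_bs", 1:5)),
    condition_terms = paste0("rec_temp_bs", 1:5),
    celltype_terms = character(0),
    spec = list(
      factor_levels = list(species = "mouse", jxn_status = "not_corrected",
                           electrode = "patch"),
      spline_age = list(name = "log10_age", knots = numeric(0),
                        boundary = c(1, 1)),
      spline_temp = sdef),
    reference_conditions = list(species = "mouse",
                                jxn_status = "not_corrected",
                                electrode = "patch", log10_age = log10(14),
                                rec_temp_C = 33)
  ), class = "condition_model")
  f_temp <- function(t) {
    as.numeric(splines::bs(t, knots = sdef$knots,
                           Boundary.knots = sdef$boundary, degree = 3) %*% w)
  }
  rec <- dplyr::bind_rows(
    toy_measurement(article_id = "A1", rec_temp_C = 25, value = f_temp(25)),
    toy_measurement(article_id = "A2", rec_temp_C = 35, value = f_temp(35)),
    toy_measurement(article_id = "A3", rec_temp_C = 33, value = f_temp(33))
  )
  rec$age_days <- 14
  adj <- adjust_measurements(model, rec)
  # records differing only in temperature agree after adjustment
  expect_equal(adj$value[1], adj$value[2], tolerance = 1e-8)
  # both land at the value predicted at the reference temperature
  expect_equal(adj$value[1], f_temp(33), tolerance = 1e-8)
  # a record already at reference conditions is untouched
  expect_equal(adj$value[3], adj$value_raw[3], tolerance = 1e-12)
})

test_that("unseen covariate levels and out-of-range covariates are flagged", {
  sim <- temp_effect_records(seed = 9, n_types = 6, articles_per_type = 5)
  rec <- preprocess_measurements(sim$records)
  fit <- fit_condition_model(rec, "Vrest", run_config(seed = 9))
  new <- rec[1:2, ]
  new$species[1] <- "guinea_pig"     # never seen at fit time
  new$rec_temp_C[2] <- 50            # beyond the boundary knots
  adj <- adjust_measurements(fit, new)
  expect_equal(adj$adjust_flag, c("unseen_level", "clamped"))
  expect_equal(adj$value[1], adj$value_raw[1])
})

test_that("condition models serialize to JSON and adjust identically after reload", {
  sim <- temp_effect_records(seed = 13, n_types = 6, articles_per_type = 5)
  rec <- preprocess_measurements(sim$records)
  fit <- fit_condition_model(rec, "Vrest", run_config(seed = 13))
  path <- withr::local_tempfile(fileext = ".json")
  write_condition_model(fit, path)
  fit2 <- read_condition_model(path)
  expect_equal(adjust_measurements(fit2, rec)$value,
               adjust_measurements(fit, rec)$value, tolerance = 1e-10)
})

test_that("log10 properties stay positive through normalization and summarization", {
  cfg <- small_cfg(seed = 6)
  d <- generate_discovery_dataset(cfg, default_ground_truth(cfg, n_planted = 5))
  rc <- small_run_config(seed = 6)
  rec <- preprocess_measurements(d$ephys, rc)
  fit <- fit_condition_model(rec, "Rin", rc)
  adj <- adjust_measurements(fit, rec)
  expect_true(all(adj$value > 0))
  ct <- summarize_ephys_by_cell_type(adj)
  expect_true(all(ct$values[, "Rin"] > 0, na.rm = TRUE))
  expect_error(
    fit_condition_model(dplyr::mutate(rec, value = ifelse(
      property == "Rin" & dplyr::row_number() == which(property == "Rin")[1],
      -5, value)), "Rin", rc),
    "Non-positive")
})
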