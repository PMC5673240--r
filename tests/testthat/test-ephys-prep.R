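test_that("measurement preprocessing applies the inclusion and standardization rules", {
  rec <- dplyr::bind_rows(
    toy_measurement(article_id = "A1", age_lo_days = 14, age_hi_days = 20),
    toy_measurement(article_id = "A2", preparation = "in_vivo"),
    toy_measurement(article_id = "A3", species = "other"),
    toy_measurement(article_id = "A4", age_lo_days = 1, age_hi_days = 2),
    toy_measurement(article_id = "A5", rec_temp_C = 32),
    toy_measurement(article_id = "A6", rec_temp_C = 36),
    toy_measurement(article_id = "A7", rec_temp_C = NA_real_)
  )
  out <- preprocess_measurements(rec)
  # acute slice + allowed species + age > 2 d
  expect_setequal(out$article_id, c("A1", "A5", "A6", "A7"))
  # P14-P20 age range collapses to the geometric mean
  expect_equal(out$age_days[out$article_id == "A1"], sqrt(14 * 20),
               tolerance = 1e-12)
  # missing temperature imputed by the median of {33, 32, 36, 33}
  expect_equal(out$rec_temp_C[out$article_id == "A7"], 33)
  log <- attr(out, "filter_log")
  expect_equal(log$n_removed_preparation, 1)
  expect_equal(log$n_removed_species, 1)
  expect_equal(log$n_removed_age, 1)
})

test_that("median temperature imputation uses the stated rule", {
  rec <- dplyr::bind_rows(
    toy_measurement(article_id = "A1", rec_temp_C = 32),
    toy_measurement(article_id = "A2", rec_temp_C = 34),
    toy_measurement(article_id = "A3", rec_temp_C = 36),
    toy_measurement(article_id = "A4", rec_temp_C = NA_real_)
  )
  out <- preprocess_measurements(rec)
  expect_equal(out$rec_temp_C[out$article_id == "A4"], 34)
})

test_that("junction-potential corrections are reverted on voltage properties only", {
  rec <- dplyr::bind_rows(
    toy_measurement(article_id = "A1", value = -75, jxn_status = "corrected",
                    jxn_offset_mV = 10),
    toy_measurement(article_id = "A2", property = "APamp", value = 80,
                    jxn_status = "corrected", jxn_offset_mV = 10),
    toy_measurement(article_id = "A3", value = -65, jxn_status = "corrected",
                    jxn_offset_mV = NA_real_)
  )
  out <- preprocess_measurements(rec)
  expect_equal(out$value[out$article_id == "A1"], -65)   # offset added back
  expect_equal(out$jxn_status[out$article_id == "A1"], "post_corrected")
  expect_equal(out$value[out$article_id == "A2"], 80)    # amplitude untouched
  expect_equal(out$jxn_status[out$article_id == "A2"], "corrected")
  expect_equal(out$value[out$article_id == "A3"], -65)   # unknown offset: no-op
})

test_that("configured exclusions remove (cell type, property) pairs", {
  rec <- dplyr::bind_rows(
    toy_measurement(article_id = "A1", cell_type_label = "G42", property = "APthr"),
    toy_measurement(article_id = "A2", cell_type_label = "G42", property = "Vrest")
  )
  cfg <- run_config(exclusions = tibble::tibble(cell_type_label = "G42",
                                                property = "APthr"))
  out <- preprocess_measurements(rec, cfg)
  expect_identical(out$property, "Vrest")
})

test_that("cell-type summarization takes article means then the cross-article median", {
  rec <- dplyr::bind_rows(
    toy_measurement(article_id = "A1", value = -60),
    toy_measurement(article_id = "A1", value = -62),   # article mean -61
    toy_measurement(article_id = "A2", value = -65),
    toy_measurement(article_id = "A3", value = -70)
  )
  rec$age_days <- 14
  ct <- summarize_ephys_by_cell_type(rec)
  expect_equal(unname(ct$values["T1", "Vrest"]), -65)   # median(-61, -65, -70)
  expect_true(all(is.na(ct$values["T1", setdiff(colnames(ct$values), "Vrest")])))
  counts <- attr(ct, "article_counts")
  expect_equal(counts$n_articles[counts$property == "Vrest"], 3)

  ctp <- summarize_ephys_by_cell_type(rec[sample.int(nrow(rec)), ])
  expect_equal(ctp$values, ct$values)
})

test_that("spike-frequency adaptation is first over mean inter-spike interval", {
  expect_equal(compute_sfa(c(20, 20, 20)), 1)
  expect_equal(compute_sfa(c(10, 20, 30)), 0.5)
  expect_equal(compute_sfa(42), 1)
  expect_error(compute_sfa(numeric(0)), "positive")
  expect_error(compute_sfa(c(10, -5)), "positive")
})

test_that("capacitance derives from tau over input resistance in pF", {
  expect_equal(derive_capacitance(20, 200), 100)
  expect_equal(derive_capacitance(10, 100), 100)
  expect_error(derive_capacitance(10, 0), "positive")
})

test_that("the maximal-firing sweep is the argmax, first on ties", {
  s <- select_max_rate_sweep(c(2, 10, 7), 1)
  expect_equal(s$sweep, 2)
  expect_equal(s$fr_max_hz, 10)
  expect_false(s$tie)

  tie <- select_max_rate_sweep(c(5, 5), 1)
  expect_equal(tie$sweep, 1)
  expect_true(tie$tie)

  expect_equal(select_max_rate_sweep(4, 0.5)$fr_max_hz, 8)
  zero <- select_max_rate_sweep(c(0, 0), 1)
  expect_equal(zero$fr_max_hz, 0)
  expect_true(zero$all_zero)
})
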