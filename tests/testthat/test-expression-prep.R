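test_that("quantile normalization equalizes per-sample distributions to the mean order statistics", {
  m <- toy_expression(cbind(s1 = c(1, 2, 3), s2 = c(4, 5, 6)),
                      types = c("T1", "T2"))
  qn <- quantile_normalize(m)
  expect_equal(unname(qn$values[, "s1"]), c(2.5, 3.5, 4.5))
  expect_equal(unname(qn$values[, "s2"]), c(2.5, 3.5, 4.5))

  # identical samples are a fixed point
  m2 <- toy_expression(cbind(s1 = c(3, 1, 2), s2 = c(3, 1, 2)))
  expect_equal(quantile_normalize(m2)$values, m2$values, tolerance = 1e-12)

  # arbitrary input: all per-sample sorted vectors coincide afterwards
  set.seed(41)
  m3 <- toy_expression(matrix(rnorm(60), nrow = 10))
  qn3 <- quantile_normalize(m3)$values
  ref <- unname(sort(qn3[, 1]))
  for (j in 2:ncol(qn3)) {
    expect_equal(unname(sort(qn3[, j])), ref, tolerance = 1e-12)
  }

  expect_error(quantile_normalize(toy_expression(cbind(s1 = 1:3))),
               "at least 2 samples")
})

test_that("probe collapse keeps the most variable probe per gene, first on ties", {
  v <- rbind(p1 = c(1, 2, 3),    # var 1
             p2 = c(1, 3, 5),    # var 4 -> wins gene A
             p3 = c(7, 8, 9),    # tie with p4 (var 1) -> p3 wins gene B
             p4 = c(0, 1, 2),
             p5 = c(5, 5, 5),    # single-probe gene C
             p6 = c(9, 9, 9))    # unmapped, dropped
  m <- toy_expression(v)
  map <- tibble::tibble(probe = c("p1", "p2", "p3", "p4", "p5"),
                        gene = c("A", "A", "B", "B", "C"))
  out <- collapse_probes_to_genes(m, map)
  expect_setequal(rownames(out$values), c("A", "B", "C"))
  expect_equal(unname(out$values["A", ]), c(1, 3, 5))
  expect_equal(unname(out$values["B", ]), c(7, 8, 9))
  expect_equal(unname(out$values["C", ]), c(5, 5, 5))
  log <- attr(out, "collapse_summary")
  expect_equal(log$n_unmapped_probes, 1)
  expect_equal(log$n_variance_ties, 1)
  expect_error(collapse_probes_to_genes(m, map[0, ]), "Empty")
})

test_that("cell-type summarization averages samples and ignores sample order", {
  v <- cbind(a = c(7, 1), b = c(9, 3), c = c(2, 8))
  m <- toy_expression(v, types = c("T1", "T1", "T2"))
  ct <- summarize_expression_by_cell_type(m)
  expect_equal(unname(ct$values["T1", ]), c(8, 2))
  expect_equal(unname(ct$values["T2", ]), c(2, 8))
  expect_equal(ct$meta$n_samples, c(2L, 1L))

  perm <- c(3, 1, 2)
  mp <- toy_expression(v[, perm], types = c("T1", "T1", "T2")[perm])
  ctp <- summarize_expression_by_cell_type(mp)
  expect_equal(ctp$values[rownames(ct$values), ], ct$values)
})

test_that("gene filtering retains high-mean high-variance genes and matches brute force", {
  # externally fixed cutoffs: the mu_g > 7.5 & sigma_g > 0.75 rule
  v <- cbind(hi = c(7, 8, 9),          # mu 8, sd 1 -> retained
             lo = c(5, 6, 7),          # mu 6 -> dropped
             flat = c(8, 8.1, 8.2))    # sd 0.1 -> dropped
  ct <- celltype_matrix(`rownames<-`(v, paste0("T", 1:3)) ,
                        tibble::tibble(cell_type = paste0("T", 1:3)),
                        "expression")
  res <- filter_genes(ct, mu_global = 7.5, sigma_global = 0.75)
  expect_identical(colnames(res$expression$values), "hi")

  # data-derived cutoffs against an explicit brute-force oracle
  set.seed(7)
  v2 <- matrix(rnorm(5 * 7, mean = 7), 5, 7,
               dimnames = list(paste0("T", 1:5), paste0("g", 1:7)))
  ct2 <- celltype_matrix(v2, tibble::tibble(cell_type = rownames(v2)),
                         "expression")
  res2 <- filter_genes(ct2)
  mu <- apply(v2, 2, mean); sg <- apply(v2, 2, sd)
  keep_oracle <- colnames(v2)[mu > mean(mu) & sg > mean(sg)]
  expect_setequal(colnames(res2$expression$values), keep_oracle)
  expect_equal(res2$thresholds$mu_global, mean(mu))
  expect_equal(res2$thresholds$sigma_global, mean(sg))

  # identical gene rows share a fate
  v3 <- cbind(a = c(7, 9, 11), b = c(7, 9, 11), c = c(6, 6.1, 6.2))
  ct3 <- celltype_matrix(`rownames<-`(v3, paste0("T", 1:3)),
                         tibble::tibble(cell_type = paste0("T", 1:3)),
                         "expression")
  res3 <- filter_genes(ct3)
  expect_setequal(colnames(res3$expression$values), c("a", "b"))

  # fixed-threshold filtering is idempotent
  again <- filter_genes(res$expression, 7.5, 0.75)
  expect_identical(colnames(again$expression$values),
                   colnames(res$expression$values))
})

test_that("single-cell aggregation enforces the minimum-cells rule in both modalities", {
  set.seed(3)
  lines <- c(rep("L1", 9), rep("L2", 12), rep("L3", 15))
  v <- matrix(rexp(2 * length(lines)), nrow = 2,
              dimnames = list(c("g1", "g2"), sprintf("c%02d", seq_along(lines))))
  m <- toy_expression(v, scale = "tpm", types = lines)
  agg <- aggregate_single_cells(m, min_cells = 10)
  expect_setequal(rownames(agg$values), c("L2", "L3"))   # L1 has 9 cells
  expect_identical(attr(agg, "excluded_lines"), "L1")

  # a line failing the ephys-side count is excluded too
  agg2 <- aggregate_single_cells(
    m, 10, ephys_cell_counts = tibble::tibble(cell_type = c("L2", "L3"),
                                              n_cells = c(30, 4)))
  expect_identical(rownames(agg2$values), "L2")

  # mean TPM arithmetic
  v2 <- matrix(c(0, 10, 4, 6), nrow = 1,
               dimnames = list("g", c("a", "b", "c", "d")))
  m2 <- toy_expression(v2, scale = "tpm", types = rep("L", 4))
  expect_equal(unname(aggregate_single_cells(m2, 2)$values["L", "g"]), 5)
})

test_that("flagged samples are dropped before analysis", {
  v <- cbind(s1 = c(1, 2), s2 = c(3, 4), s3 = c(5, 6))
  meta <- tibble::tibble(sample_id = colnames(v),
                         cell_type_label = "T1",
                         qc_flag = c(FALSE, TRUE, NA))
  m <- expression_matrix(`rownames<-`(v, c("g1", "g2")), "log2_intensity", meta)
  out <- drop_flagged_samples(m)
  expect_identical(colnames(out$values), c("s1", "s3"))
})
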