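# Brute-force oracles, independent of the implementation path.
oracle_spearman <- function(x, y) stats::cor(rank(x), rank(y))
oracle_bh <- function(p) {
  m <- length(p)
  i <- order(p)
  stepup <- p[i] * m / seq_len(m)
  adj_sorted <- rev(cummin(rev(stepup)))
  out <- numeric(m); out[i] <- pmin(adj_sorted, 1)
  out
}

test_that("spearman_with_p matches hand values and the rank-then-Pearson oracle", {
  expect_equal(spearman_with_p(1:4, c(10, 20, 30, 40))$r_s, 1)
  expect_equal(spearman_with_p(1:4, c(40, 30, 20, 10))$r_s, -1)
  # d^2-sum 8 at n = 5: 1 - 6*8/(5*24) = 0.6
  expect_equal(spearman_with_p(1:5, c(3, 1, 2, 5, 4))$r_s, 0.6)

  withr::with_seed(99, {
    for (i in 1:100) {
      n <- sample(5:40, 1)
      x <- rnorm(n)
      y <- if (i %% 2 == 0) rnorm(n) else sample(round(rnorm(n)), n, TRUE)
      res <- spearman_with_p(x, y)
      expect_equal(res$r_s, oracle_spearman(x, y), tolerance = 1e-10)
      ct <- suppressWarnings(
        cor.test(x, y, method = "spearman", exact = FALSE))
      expect_equal(res$r_s, unname(ct$estimate), tolerance = 1e-10)
      if (abs(res$r_s) < 1) {
        expect_equal(res$p_value, ct$p.value, tolerance = 1e-8)
      }
    }
  })
  # perfect correlations report the smallest positive p, never zero
  expect_gt(spearman_with_p(1:6, 2 * (1:6))$p_value, 0)
})

test_that("bh_adjust matches the step-up oracle and rejects bad input", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  expect_equal(bh_adjust(0.2), 0.2)
  expect_equal(bh_adjust(c(0.05, 0.5)), c(0.10, 0.5))
  withr::with_seed(7, {
    for (i in 1:50) {
      p <- runif(sample(1:200, 1))
      expect_equal(bh_adjust(p), oracle_bh(p), tolerance = 1e-12)
    }
  })
  expect_error(bh_adjust(c(0.1, 0)), "p-values")
  expect_error(bh_adjust(c(0.1, 1.2)), "p-values")
})

make_paired <- function(seed = 1, n = 15, g = 40, planted = TRUE) {
  withr::with_seed(seed, {
    X <- matrix(rnorm(n * g), n, g,
                dimnames = list(sprintf("T%02d", 1:n), sprintf("g%03d", 1:g)))
    eph <- matrix(NA_real_, n, 11,
                  dimnames = list(rownames(X), ephys_property_codes()))
    eph[, "Vrest"] <- if (planted) X[, 1] + rnorm(n, 0, 0.2) else rnorm(n)
    eph[, "Rin"] <- rlnorm(n)
    paired_dataset(X, eph)
  })
}

test_that("the screen applies per-property BH, drops degenerate genes, and skips sparse properties", {
  ds <- make_paired(seed = 2)
  ds$expression[, "g002"] <- 5                     # constant gene
  ds$ephys[4:15, "Rin"] <- NA                      # only 3 complete types
  cfg <- small_run_config()
  scr <- suppressWarnings(screen_correlations(ds, cfg))
  expect_false("g002" %in% scr$gene)
  expect_true("g002" %in% attr(scr, "dropped_genes")$gene)
  expect_false("Rin" %in% scr$property)
  expect_true("Rin" %in% attr(scr, "skipped_properties"))
  # BH within property reproduces bh_adjust of that property's p-values
  sub <- scr[scr$property == "Vrest", ]
  expect_equal(sub$p_adj, bh_adjust(sub$p_value), tolerance = 1e-12)
  expect_true(all(sub$p_adj >= sub$p_value))
  # the planted gene is the top hit with the right sign
  expect_equal(sub$gene[which.min(sub$p_adj)], "g001")
  expect_gt(sub$r_s[sub$gene == "g001"], 0)
})

test_that("screen results are invariant to strictly increasing expression transforms", {
  ds <- make_paired(seed = 5)
  tpm <- ds
  tpm$expression <- 2^ds$expression        # monotone transform (TPM-like)
  cfg <- small_run_config()
  a <- screen_correlations(ds, cfg)
  b <- screen_correlations(tpm, cfg)
  expect_equal(a$r_s, b$r_s, tolerance = 1e-12)
  expect_equal(a$p_adj, b$p_adj, tolerance = 1e-12)
})

test_that("overall consistency is the rank correlation of the two r_s vectors", {
  ds <- make_paired(seed = 3)
  cfg <- small_run_config()
  scr <- screen_correlations(ds, cfg)
  expect_equal(consistency_overall(scr, scr, "Vrest"), 1)
  neg <- scr; neg$r_s <- -neg$r_s
  expect_equal(consistency_overall(scr, neg, "Vrest"), -1)
  expect_error(consistency_overall(scr[1:3, ], scr, "Vrest"), "10 common")
})

test_that("per-gene consistency applies the sign and |r_s| > 0.3 rules", {
  disc <- tibble::tibble(gene = c("a", "b", "c", "d"), property = "Vrest",
                         r_s = c(0.5, 0.5, 0.5, 0.6),
                         p_value = 1e-4, p_adj = c(1e-3, 1e-3, 1e-3, 0.2))
  val <- tibble::tibble(gene = c("a", "b", "c"), property = "Vrest",
                        r_s = c(0.4, 0.2, -0.6), p_value = 0.1, p_adj = 0.5)
  out <- consistency_per_gene(disc, val, run_config(), alpha = 0.05)
  got <- stats::setNames(out$pairs$consistent, out$pairs$gene)
  expect_true(got[["a"]])     # sign match, |0.4| > 0.3
  expect_false(got[["b"]])    # magnitude too small
  expect_false(got[["c"]])    # sign flip
  expect_false("d" %in% out$pairs$gene)   # not discovered at alpha
  expect_equal(out$summary$pct_consistent, 100 * 1 / 3)
})

test_that("the permutation null is seeded, bounded, and add-one smoothed", {
  cfg <- small_cfg(seed = 14)
  # a strong shared signal concentrated on one property, so the observed
  # cross-dataset consistency exceeds every shuffle
  tr <- ground_truth(
    planted_effects = tibble::tibble(
      gene = sprintf("G%04d", 1:30), property = "Vrest",
      direction = rep(c("+", "-"), 15), target_abs_spearman = 0.9),
    n_genes = cfg$n_genes)
  d <- generate_discovery_dataset(cfg, tr)
  built <- suppressWarnings(build_discovery_dataset(
    d$expression, d$ephys, small_run_config(seed = 14),
    normalize_conditions = FALSE))
  scr <- screen_correlations(built$dataset, small_run_config(seed = 14))
  v <- generate_validation_dataset(cfg, tr)
  vb <- build_validation_dataset(v$expression, v$cell_ephys,
                                 small_run_config(seed = 14))
  cfg_p <- small_run_config(seed = 14)
  pt <- permutation_null(vb$dataset, scr, "overall_rho", cfg_p, "Vrest")
  pt2 <- permutation_null(vb$dataset, scr, "overall_rho", cfg_p, "Vrest")
  expect_identical(pt$null, pt2$null)                      # determinism
  expect_gte(pt$p_value, 1 / (cfg_p$n_permutations + 1))   # lower bound
  expect_lte(pt$p_value, 1)
  expect_length(pt$null, cfg_p$n_permutations)
  # shared planted signal: observed consistency beats every shuffle
  expect_equal(pt$p_value, 1 / (cfg_p$n_permutations + 1))
})

test_that("permutation of a dataset with missing ephys uses the slow path consistently", {
  ds <- make_paired(seed = 8, n = 12)
  ds$ephys[c(2, 5), "Vrest"] <- NA
  disc <- screen_correlations(make_paired(seed = 9, n = 12),
                              small_run_config())
  cfg <- small_run_config(seed = 8)
  pt <- permutation_null(ds, disc, "overall_rho", cfg, "Vrest")
  expect_length(pt$null, cfg$n_permutations)
  expect_true(all(is.finite(pt$null)))
})
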