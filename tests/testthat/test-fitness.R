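test_that("count normalization applies the pseudocount symmetrically", {
  m <- matrix(c(10, 10, 0, 99), nrow = 2,
              dimnames = list(c("a", "b"), c("s1", "s2")))
  f0 <- to_frequencies(m, pseudocount = 0)
  expect_equal(unname(f0[, "s1"]), c(0.5, 0.5))
  f <- to_frequencies(m, pseudocount = 0.5)
  expect_equal(unname(f[, "s2"]), c(0.5 / 100, 99.5 / 100))
  expect_equal(unname(colSums(f)), c(1, 1), tolerance = 1e-12)

  single <- matrix(7, 1, 1, dimnames = list("a", "s"))
  expect_equal(unname(to_frequencies(single)[1, 1]), 1)

  zero <- matrix(c(5, 0), nrow = 1, dimnames = list("a", c("ok", "empty")))
  expect_error(to_frequencies(zero), "empty")
})

test_that("log2 fold change is computed within replicates then summarized", {
  f_start <- matrix(c(0.01, 0.99, 0.02, 0.98), nrow = 2,
                    dimnames = list(c("a", "b"), c("r1", "r2")))
  f_end <- matrix(c(0.04, 0.96, 0.08, 0.92), nrow = 2,
                  dimnames = list(c("a", "b"), c("r1", "r2")))
  lfc <- log2_fold_change(f_end, f_start)
  expect_equal(unname(lfc$log2fc_replicates["a", ]), c(2, 2))
  expect_equal(lfc$log2fc_mean[["a"]], 2)
  # no change means exactly zero
  same <- log2_fold_change(f_start, f_start)
  expect_equal(unname(same$log2fc_mean), c(0, 0))
  expect_equal(unname(same$log2fc_sd), c(0, 0))
  # a 30-fold shift lands at log2(30) ~ 4.91
  f30 <- f_start
  f30["a", ] <- f_start["a", ] * 30
  expect_equal(log2_fold_change(f30, f_start)$log2fc_mean[["a"]],
               log2(30))
  expect_error(log2_fold_change(f_end[, 1, drop = FALSE], f_start),
               "unpaired")
  expect_error(log2_fold_change(f_end - 0.5, f_start), "positive")
})

test_that("Welch test matches an independent textbook implementation", {
  set.seed(42)
  cases <- list(
    list(a = c(1, 2, 3), b = c(4, 5, 6)),
    list(a = c(0.1, 0.5, 0.9, 1.4), b = c(2.2, 2.3)),
    list(a = rnorm(5, sd = 4), b = rnorm(7, sd = 0.2)),
    list(a = c(-3, 0, 2, 8), b = c(1, 1.1, 0.9, 1.2, 1.05)))
  for (cs in cases) {
    got <- welch_t_test(cs$a, cs$b)
    exp <- welch_oracle(cs$a, cs$b)
    expect_equal(got$t, exp$t, tolerance = 1e-10)
    expect_equal(got$df, exp$df, tolerance = 1e-10)
    expect_equal(got$p, exp$p, tolerance = 1e-10)
  }
  # identical groups: t = 0, p = 1
  same <- welch_t_test(c(1, 2, 3), c(1, 2, 3))
  expect_equal(same$t, 0)
  expect_equal(same$p, 1)
  # degenerate constant-and-equal groups
  flat <- welch_t_test(c(2, 2), c(2, 2))
  expect_equal(flat$t, 0)
  expect_equal(flat$p, 1)
  expect_error(welch_t_test(c(2, 2), c(3, 3)), "zero variance")
  expect_error(welch_t_test(1, c(1, 2)), "n >= 2")
})

test_that("Satterthwaite df shrinks under variance imbalance", {
  a <- c(10, 20, 30, 40)
  b <- c(1.00, 1.01, 0.99, 1.02)
  expect_lt(welch_t_test(a, b)$df, length(a) + length(b) - 2)
})

test_that("BH adjustment matches the brute-force step-up and its properties", {
  expect_equal(adjust_pvalues(0.03), 0.03)
  expect_equal(adjust_pvalues(c(0.01, 0.02, 0.03, 0.04)),
               rep(0.04, 4))
  expect_equal(adjust_pvalues(rep(1, 5)), rep(1, 5))

  set.seed(7)
  for (i in 1:20) {
    p <- runif(sample(2:40, 1))^sample(1:3, 1)
    adj <- adjust_pvalues(p)
    expect_equal(adj, bh_oracle(p), tolerance = 1e-12)
    expect_true(all(adj >= p))
    expect_true(all(adj <= 1))
    # monotone non-decreasing in the sorted-p order
    expect_false(is.unsorted(adj[order(p)]))
    # rank-idempotent: re-adjusting preserves the significance ordering
    # (monotone in adj; ties stay ties)
    expect_false(is.unsorted(adjust_pvalues(adj)[order(adj)]))
  }
  expect_error(adjust_pvalues(c(0.5, 1.2)), "\\[0, 1\\]")
  expect_error(adjust_pvalues(c(0.5, -0.1)), "\\[0, 1\\]")
  # alternative methods route through the requested correction
  expect_equal(adjust_pvalues(c(0.01, 0.04), method = "bonferroni"),
               c(0.02, 0.08))
})

test_that("volcano classes honour the inclusive fold-change boundary", {
  expect_equal(classify_volcano(0, 1), "neutral")
  expect_equal(classify_volcano(2, 0.04), "enriched")
  expect_equal(classify_volcano(-2, 0.04), "depleted")
  expect_equal(classify_volcano(-3, 0.2), "neutral")
  expect_equal(classify_volcano(1.99, 0.001), "neutral")
  expect_equal(classify_volcano(c(5, -5, 0.5), c(0.01, 0.01, 0.01)),
               c("enriched", "depleted", "neutral"))
})

test_that("pooled predictions follow the closed form and invert exactly", {
  f0 <- c(WT = 0.5, mut = 0.5)
  expect_equal(predict_frequencies(f0, c(1, 3), 0), f0)
  expect_equal(unname(predict_frequencies(f0, c(1, 3), 1)), c(0.25, 0.75))
  # 0^0 = 1: dead variants keep their mass at zero cycles only
  expect_equal(unname(predict_frequencies(f0, c(1, 0), 0)), c(0.5, 0.5))
  expect_equal(unname(predict_frequencies(f0, c(1, 0), 2)), c(1, 0))
  expect_error(predict_frequencies(f0, c(0, 0), 1), "extinct")

  # T cycles of prediction equal T chained selection updates
  set.seed(3)
  f <- runif(8); f <- f / sum(f)
  m <- runif(8)
  stepwise <- f
  for (i in 1:5) stepwise <- mating_cycle_update(stepwise, m)
  expect_equal(predict_frequencies(f, m, 5), stepwise, tolerance = 1e-12)

  # inference inverts prediction up to the reference scaling
  names(f) <- names(m) <- c("WT", paste0("v", 1:7))
  fT <- predict_frequencies(f, m, 5)
  m_hat <- infer_efficiencies(f, fT, 5, reference_variant = "WT")
  expect_equal(m_hat, m / m[["WT"]], tolerance = 1e-10)
  expect_equal(unname(infer_efficiencies(f, f, 3)), rep(1, 8))
  expect_error(infer_efficiencies(c(0, 1), c(0.5, 0.5), 1), "pseudocount")
  expect_error(infer_efficiencies(f, fT, 5, reference_variant = "nope"),
               "reference")
})

test_that("observed-vs-predicted agreement reports Pearson r and R^2", {
  x <- c(0.1, 0.4, 0.2, 0.3)
  expect_equal(compare_observed_predicted(x, x)$pearson_r, 1)
  anti <- compare_observed_predicted(x, -x)
  expect_equal(anti$pearson_r, -1)
  expect_equal(anti$r_squared, 1)

  y <- c(0.2, 0.5, 0.1, 0.2)
  got <- compare_observed_predicted(x, y)
  r_manual <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  expect_equal(got$pearson_r, r_manual, tolerance = 1e-12)
  expect_equal(got$r_squared, got$pearson_r^2, tolerance = 1e-12)
  expect_error(compare_observed_predicted(c(1, 2), c(1, 2)), "at least 3")
  expect_error(compare_observed_predicted(c(1, 1, 1), y[1:3]),
               "zero variance")
})

test_that("a condition contrasted against itself is identically zero", {
  set.seed(9)
  counts <- matrix(rpois(60, 500), nrow = 20,
                   dimnames = list(small_library$variants$variant_id,
                                   paste0("r", 1:3)))
  freq <- to_frequencies(counts)
  res <- condition_contrast(freq, freq)
  expect_true(all(res$log2fc_mean == 0))
  expect_true(all(res$class == "neutral"))
  expect_true(all(res$p_value == 1))
})

test_that("enrichment results carry replicate columns, stats and classes", {
  set.seed(10)
  start <- matrix(rpois(60, 1000), nrow = 20,
                  dimnames = list(small_library$variants$variant_id,
                                  paste0("r", 1:3)))
  end <- start
  end["T2Q", ] <- end["T2Q", ] * 40   # strong enrichment in every replicate
  res <- enrichment_results(to_frequencies(end), to_frequencies(start))
  expect_s3_class(res, "enrichment_result")
  expect_named(res, c("variant_id", "log2fc_rep1", "log2fc_rep2",
                      "log2fc_rep3", "log2fc_mean", "log2fc_sd",
                      "p_value", "adj_p", "class"))
  expect_true(all(res$adj_p >= res$p_value))
  expect_gt(res$log2fc_mean[res$variant_id == "T2Q"], 2)
  expect_equal(res$class[res$variant_id == "T2Q"], "enriched")
  path <- withr::local_tempfile(fileext = ".tsv")
  write_enrichment(res, path)
  expect_equal(nrow(utils::read.delim(path)), 20L)
})
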