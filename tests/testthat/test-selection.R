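test_that("binomial tails match brute-force summation exhaustively", {
  for (n in c(1:30)) {
    for (p0 in c(0.2, 0.5)) {
      for (k in 0:n) {
        expect_equal(binom_tail(n, k, p0, "ge"),
                     bf_binom_tail(n, k, p0, "ge"), tolerance = 1e-12)
        expect_equal(binom_tail(n, k, p0, "le"),
                     bf_binom_tail(n, k, p0, "le"), tolerance = 1e-12)
        expect_equal(binom_tail(n, k, p0, "two_sided"),
                     bf_binom_tail(n, k, p0, "two_sided"),
                     tolerance = 1e-12)
      }
    }
  }
  # spot checks at screen scale
  set.seed(5)
  for (r in 1:20) {
    n <- sample(100:2000, 1)
    k <- sample(0:n, 1)
    p0 <- runif(1, 0.05, 0.95)
    expect_equal(binom_tail(n, k, p0, "ge"), bf_binom_tail(n, k, p0, "ge"),
                 tolerance = 1e-9)
  }
})

test_that("reference tail values hold", {
  expect_equal(binom_tail(12, 6, 0.2, "ge"), 0.019406, tolerance = 1e-4)
  expect_equal(binom_tail(1, 0, 0.5, "two_sided"), 1)
  expect_lt(binom_tail(261, 176, 0.2, "ge"), 1e-6)
  # agreement with the established exact two-sided test
  expect_equal(binom_tail(261, 119, 0.5, "two_sided"),
               binom.test(119, 261, 0.5)$p.value, tolerance = 1e-12)
})

test_that("two-sided equal-split probability is symmetric", {
  set.seed(13)
  for (r in 1:40) {
    n <- sample(1:400, 1)
    k <- sample(0:n, 1)
    expect_equal(binom_tail(n, k, 0.5, "two_sided"),
                 binom_tail(n, n - k, 0.5, "two_sided"), tolerance = 1e-12)
  }
  expect_error(binom_tail(10, 11, 0.5), "0 <= k <= n")
  expect_error(binom_tail(10, 5, 1.2), "p0")
})

test_that("tallies conserve counts and classify calls", {
  set.seed(21)
  for (r in 1:20) {
    calls <- rand_calls(sample(5:200, 1))
    counts <- tally_selection(calls)
    expect_equal(counts$n_gt + counts$n_lt, counts$n_res)
    expect_equal(counts$n_snp, nrow(calls))
    expect_equal(counts$n_res,
                 sum(calls$decision != "insignificant"))
  }
})

test_that("annotations split significant calls; gaps warn", {
  calls <- tibble::tibble(
    rsid = paste0("rs", 1:4),
    gene_id = c("A", "A", "B", "C"),
    decision = c("excess_significant", "deficiency_significant",
                 "excess_significant", "excess_significant"))
  ann <- tibble::tibble(
    gene_id = c("A", "A", "B"),
    expression_direction = c("over", "under", "over"),
    potential_effect = c("increase", "decrease", "decrease"))
  expect_warning(counts <- tally_selection(calls, ann), "lack an annotation")
  expect_equal(counts$n_up, 1L)
  expect_equal(counts$n_dn, 2L)
  expect_equal(counts$n_unclassified, 1L)

  classes <- tibble::tibble(gene_id = c("A", "B"), class_label = "X")
  expect_error(tally_selection(calls, classes = classes), "class map")

  empty <- tally_selection(calls[0, ])
  expect_equal(empty$n_res, 0L)
  expect_equal(selection_report(empty)$p_norm_null, 1)
})

test_that("the published count table yields the printed probability bounds", {
  rep <- selection_report(selection_table1())
  total <- rep[rep$class_label == "TOTAL", ]
  expect_lt(total$p_norm_null, 1e-6)
  expect_gt(total$p_equal_null, 0.06)
  expect_lte(rep$p_norm_null[rep$class_label == "unique"], 0.025)
  expect_lte(rep$p_norm_null[rep$class_label == "paralogous"], 0.01)
  expect_lt(rep$p_norm_null[rep$class_label == "PAR1"], 1e-6)
  expect_lt(rep$p_norm_null[rep$class_label == "PAR2"], 1e-6)
})

test_that("a row at the null reports a central probability", {
  at_null <- tibble::tibble(class_label = "null", n_gene = 1L,
                            n_snp = 100L, n_res = 100L, n_gt = 20L,
                            n_lt = 80L, n_up = NA, n_dn = NA)
  p <- selection_report(at_null)$p_norm_null
  expect_gt(p, 0.4)
  expect_lt(p, 0.7)
})

test_that("simulated regimes are accepted or rejected as designed", {
  # genome-norm 1:4 tables look null; a 2:1 excess at screen scale is
  # overwhelmingly rejected
  null_tabs <- sim_counts(n_res = 261, improve_fraction = 0.2,
                          n_tables = 200, seed = 7)
  p_null <- selection_report(null_tabs)$p_norm_ge
  expect_gte(stats::median(p_null), 0.05)

  alt_tabs <- sim_counts(n_res = 261, improve_fraction = 2 / 3,
                         n_tables = 200, seed = 8)
  p_alt <- selection_report(alt_tabs)$p_norm_ge
  expect_gte(mean(p_alt < 1e-6), 0.95)
})
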