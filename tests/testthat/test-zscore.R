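est <- function(neglog, se = 0.2) tibble::tibble(neglog_kd = neglog, se = se)

test_that("the SHOX allele pair is called deficiency: significant", {
  call <- compare_alleles(est(20.31), est(19.21),
                          rsid = "rs1452787381", gene_id = "SHOX")
  expect_equal(call$delta_ln_kd, -1.10)
  expect_identical(call$decision, "deficiency_significant")
  expect_lt(call$alpha, 0.05)
  expect_equal(call$expression_ratio, exp(-1.10))
  expect_equal(call$kd_wt_nM, neglog_to_kd_nm(20.31))
})

test_that("identical estimates give a null call", {
  call <- compare_alleles(est(18.5), est(18.5))
  expect_equal(call$delta_ln_kd, 0)
  expect_equal(call$z, 0)
  expect_equal(call$alpha, 0.5)
  expect_identical(call$decision, "insignificant")
  expect_true(is.na(call$rank_rho))
})

test_that("allele swap negates delta and z and mirrors the decision", {
  set.seed(7)
  for (r in 1:50) {
    a <- est(runif(1, 14, 21), runif(1, 0.05, 0.5))
    b <- est(runif(1, 14, 21), runif(1, 0.05, 0.5))
    fwd <- compare_alleles(a, b)
    rev <- compare_alleles(b, a)
    expect_equal(rev$delta_ln_kd, -fwd$delta_ln_kd)
    expect_equal(rev$z, -fwd$z)
    expect_equal(rev$alpha, fwd$alpha)
    swap <- c(deficiency_significant = "excess_significant",
              excess_significant = "deficiency_significant",
              insignificant = "insignificant")
    expect_identical(rev$decision, unname(swap[fwd$decision]))
  }
})

test_that("significance is scale-consistent in sigma", {
  a <- est(19.0, 0.2)
  b <- est(18.2, 0.2)
  z1 <- compare_alleles(a, b)$z
  z3 <- compare_alleles(est(19.0, 0.6), est(18.2, 0.6))$z
  expect_equal(z3, z1 / 3)
})

test_that("every panel effect is significant at the default sigma", {
  # the smallest panel |delta| is 0.51; with sigma = 0.20 that gives
  # z = 1.80 and a one-sided alpha below 0.05
  odns <- odn_table2()
  wt <- odns[odns$allele_class == "WT", ]
  mn <- odns[odns$allele_class == "min", ]
  calls <- purrr::map_dfr(1:5, function(i) {
    compare_alleles(est(wt$predicted_neglog_kd[i]),
                    est(mn$predicted_neglog_kd[i]),
                    gene_id = wt$gene_id[i])
  })
  expect_true(all(calls$alpha < 0.05))
  expect_identical(sign(calls$delta_ln_kd), c(-1, 1, 1, 1, -1))
  expect_identical(calls$decision[1], "deficiency_significant")
})

test_that("ranks follow the alpha bins and are monotone", {
  expect_identical(assign_rank(1e-7), "A")
  expect_identical(assign_rank(0.04), "E")
  expect_identical(assign_rank(c(1e-6, 1e-4, 1e-3, 1e-2, 0.049)),
                   c("A", "B", "C", "D", "E"))
  grid <- sort(10^runif(200, -9, log10(0.0499)))
  ranks <- assign_rank(grid)
  expect_true(all(diff(match(ranks, LETTERS)) >= 0))
  expect_error(assign_rank(0.05), "insignificant")
  expect_error(assign_rank(0.6), "insignificant")
})

test_that("non-positive standard errors are a configuration error", {
  expect_error(compare_alleles(est(19, 0), est(18)), "positive")
})

test_that("scanning the panel fixture reproduces the published signs", {
  calls <- scan_snps(table2_promoters(), table2_snps())
  expect_equal(nrow(calls), 5L)
  expect_identical(calls$gene_id,
                   c("SHOX", "GTPBP6", "ASMT", "ZFY", "CDY2A"))
  expect_identical(sign(calls$delta_ln_kd), c(-1, 1, 1, 1, -1))
})

test_that("scans preserve order, validate genes and handle empty input", {
  proms <- table2_promoters()
  snps <- table2_snps()[c(3, 1, 5), ]
  calls <- scan_snps(proms, snps)
  expect_identical(calls$gene_id, snps$gene_id)

  empty <- scan_snps(proms, snps[0, ])
  expect_equal(nrow(empty), 0L)
  expect_true(all(c("rsid", "delta_ln_kd", "decision") %in% names(empty)))

  orphan <- snps
  orphan$gene_id[1] <- "NOPE"
  expect_error(scan_snps(proms, orphan), "NOPE")
})
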