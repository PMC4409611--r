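# Allele frequencies, Hardy-Weinberg equilibrium, call rate, concordance.

test_that("allele frequencies match the published cohort values", {
  vk <- genotype_counts(2, 68, 356)     # X = G (GG, GA, AA ordering)
  fr <- allele_frequencies(vk)
  expect_equal(round(fr[["p_x"]], 3), 0.085)
  expect_equal(round(fr[["p_y"]], 3), 0.915)

  cy <- genotype_counts(414, 18, 0)     # X = A, Y = C
  fr <- allele_frequencies(cy)
  expect_equal(round(fr[["p_x"]], 3), 0.979)
  expect_equal(round(fr[["p_y"]], 3), 0.021)

  fixed <- allele_frequencies(genotype_counts(0, 0, 100))
  expect_identical(unname(fixed), c(0, 1))
})

test_that("p_x + p_y = 1 exactly before rounding", {
  set.seed(31)
  for (i in 1:50) {
    cnt <- genotype_counts(rpois(1, 50), rpois(1, 50), rpois(1, 50))
    if (cnt$n == 0) next
    fr <- allele_frequencies(cnt)
    expect_identical(fr[["p_x"]] + fr[["p_y"]], 1)
  }
})

test_that("Hardy-Weinberg chi-square reproduces the published p-values", {
  vk <- hwe_test(genotype_counts(2, 68, 356))
  # hand-computed expected counts (3.04, 65.91, 357.05) give chi2 ~ 0.426
  expect_equal(vk$chi2, 0.426, tolerance = 2e-3)
  expect_equal(vk$expected[["n_xx"]], 3.04, tolerance = 2e-3)
  expect_equal(vk$expected[["n_xy"]], 65.92, tolerance = 2e-3)
  expect_equal(round(vk$p, 3), 0.514)
  expect_identical(vk$df, 1L)
  expect_equal(sum(vk$expected), 426)

  cy <- hwe_test(genotype_counts(414, 18, 0))
  expect_equal(round(cy$p, 3), 0.658)

  perfect <- hwe_test(genotype_counts(25, 50, 25))
  expect_equal(perfect$chi2, 0)
  expect_equal(perfect$p, 1)
})

test_that("HWE p-value is invariant under swapping the allele labels", {
  set.seed(13)
  for (i in 1:25) {
    a <- rpois(1, 30); b <- rpois(1, 60); c <- rpois(1, 30)
    if (a + b == 0 || b + c == 0) next
    h1 <- hwe_test(genotype_counts(a, b, c))
    h2 <- hwe_test(genotype_counts(c, b, a))
    expect_equal(h1$chi2, h2$chi2, tolerance = 1e-12)
    expect_equal(h1$p, h2$p, tolerance = 1e-12)
  }
})

test_that("monomorphic counts give a flagged degenerate result", {
  expect_warning(res <- hwe_test(genotype_counts(0, 0, 50)), "monomorphic")
  expect_true(res$degenerate)
  expect_equal(res$chi2, 0)
  expect_equal(res$p, 1)
})

test_that("failed-genotyping percentages match the published ones", {
  expect_identical(call_failure_rate(10, 436), 2.3)
  expect_identical(call_failure_rate(4, 436), 0.9)
  expect_identical(call_failure_rate(0, 436), 0)
  expect_error(call_failure_rate(5, 0), "at least 1")
  expect_error(call_failure_rate(7, 5), "between 0 and n_total")
})

test_that("concordance pairs by sample, excludes no-calls, and counts agreement", {
  mk <- function(ids, calls) data.frame(sample_id = ids, call = calls)
  # six paired samples, two per genotype, all agreeing
  a <- mk(paste0("s", 1:6), c("XX", "XX", "XY", "XY", "YY", "YY"))
  res <- concordance(a, a)
  expect_identical(res$n_compared, 6L)
  expect_identical(res$rate, 1)
  expect_identical(unname(diag(res$confusion)), c(2L, 2L, 2L))

  # fully discordant
  b <- mk(paste0("s", 1:6), c("XY", "XY", "YY", "YY", "XX", "XX"))
  expect_identical(concordance(a, b)$rate, 0)

  # 10 shared samples: 2 no-call pairs excluded, 7 of remaining 8 agree
  ids <- paste0("p", 1:10)
  x <- mk(ids, c("XX", "XX", "XY", "XY", "YY", "YY", "XX", "XY",
                 "NO_CALL", "XX"))
  y <- mk(ids, c("XX", "XX", "XY", "XY", "YY", "YY", "XX", "YY",
                 "XX", "NO_CALL"))
  res <- concordance(x, y)
  expect_identical(res$n_compared, 8L)
  expect_identical(res$n_agreeing, 7L)
  expect_equal(res$rate, 0.875)
  expect_identical(res$n_excluded, 2L)

  all_nc <- mk("q1", "NO_CALL")
  expect_error(concordance(all_nc, mk("q1", "XX")), "zero comparable")
  expect_error(concordance(mk("z", "XX"), mk("w", "XX")), "no samples shared")
})
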