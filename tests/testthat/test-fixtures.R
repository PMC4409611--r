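# Synthetic-data generation: template reconstruction, HWE cohort
# sampling, random loci.

test_that("template reconstruction reproduces both published assays end to end", {
  for (assay in list(ctpp_assay_vkorc1(), ctpp_assay_cyp2c9())) {
    expect_identical(validate_assay(assay), character(0))
    for (g in c("XX", "XY", "YY")) {
      bands <- simulated_bands(assay, g)
      expect_identical(bands, expected_band_pattern(assay, g))
      cl <- call_genotype(band_observation("s", bands), assay)
      expect_identical(cl$call, g)
    }
  }
})

test_that("reconstruction rejects geometrically impossible sizes", {
  vk <- ctpp_assay_vkorc1()
  expect_error(assay_from_primers(vk$f1$seq, vk$r1$seq, vk$f2$seq,
                                  vk$r2$seq, a = 40L, b = 208L),
               "at least d")
  expect_error(assay_from_primers(vk$f1$seq, vk$r1$seq, vk$f2$seq,
                                  vk$r2$seq, a = 119L, b = 45L),
               "at least")
  # confronting primers implying the same allele are not a CTPP pair
  expect_error(assay_from_primers("ACGTACGTAA", "TTTACGATCT",
                                  "ACGTACGTCGTA", "GGCCGGCCAA",
                                  a = 60L, b = 60L),
               "identical alleles")
})

test_that("no primer matches the synthetic template outside its footprint", {
  for (assay in list(ctpp_assay_vkorc1(), ctpp_assay_cyp2c9())) {
    loc <- assay$locus
    for (al in c(loc$allele_x, loc$allele_y)) {
      hap <- loc$template
      substr(hap, loc$snp_pos, loc$snp_pos) <- al
      for (p in list(assay$f1, assay$r1, assay$f2, assay$r2)) {
        pat <- if (p$strand == "+") p$seq else reverse_complement(p$seq)
        hits <- gregexpr(pat, hap, fixed = TRUE)[[1]]
        hits <- hits[hits != -1]
        expect_true(all(hits == p$start))
      }
    }
  }
})

test_that("HWE genotype sampling is seeded, reproducible and unbiased", {
  expect_identical(unique(sample_genotypes(0, 50, seed = 1)), "YY")
  expect_identical(unique(sample_genotypes(1, 50, seed = 1)), "XX")
  g1 <- sample_genotypes(0.3, 1000, seed = 42)
  g2 <- sample_genotypes(0.3, 1000, seed = 42)
  expect_identical(g1, g2)
  expect_false(identical(g1, sample_genotypes(0.3, 1000, seed = 43)))

  # frequency recovered within 3 binomial standard errors
  g <- sample_genotypes(0.085, 10000, seed = 7)
  fr <- allele_frequencies(as_genotype_counts(g))
  se <- sqrt(0.085 * 0.915 / (2 * 10000))
  expect_lt(abs(fr[["p_x"]] - 0.085), 3 * se)

  expect_error(sample_genotypes(1.2, 10, seed = 1), "probability")
  expect_error(sample_genotypes(0.5, 0, seed = 1), "at least 1")
})

test_that("sampled cohorts at n = 100000 are compatible with HWE", {
  ok <- 0L
  for (seed in 1:100) {
    g <- sample_genotypes(0.2, 100000, seed = seed)
    p <- suppressWarnings(hwe_test(as_genotype_counts(g))$p)
    if (p > 0.001) ok <- ok + 1L
  }
  expect_gte(ok, 99L)
})

test_that("random loci are seeded and collision-free across seeds", {
  l1 <- random_locus(60, 30, seed = 12)
  l2 <- random_locus(60, 30, seed = 12)
  expect_identical(l1, l2)
  expect_identical(nchar(l1$template), 60L)
  expect_identical(substr(l1$template, 30, 30), l1$allele_x)
  seqs <- vapply(1:100, function(s) random_locus(40, 20, seed = s)$template,
                 character(1))
  expect_identical(anyDuplicated(seqs), 0L)
  expect_error(random_locus(60, 1, seed = 1), "flank")
  expect_error(random_locus(60, 60, seed = 1), "flank")
})

test_that("sampling does not disturb the global RNG stream", {
  set.seed(123)
  before <- runif(1)
  set.seed(123)
  invisible(sample_genotypes(0.5, 10, seed = 99))
  after <- runif(1)
  expect_identical(before, after)
})
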