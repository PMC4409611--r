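# Geometry of the four-primer layout: fragment sizes, band patterns,
# invariant validation.

test_that("bundled assays reproduce the published fragment sizes", {
  vk <- ctpp_assay_vkorc1()
  fp <- fragment_pattern(vk)
  expect_identical(fp$a, 119L)
  expect_identical(fp$b, 208L)
  expect_identical(fp$d, nchar(vk$f2$seq) + nchar(vk$r1$seq))
  expect_identical(fp$c, 284L)

  cy <- ctpp_assay_cyp2c9()
  fp <- fragment_pattern(cy)
  expect_identical(c(fp$a, fp$b, fp$c), c(125L, 200L, 287L))
})

test_that("expected band patterns follow the allele logic", {
  vk <- ctpp_assay_vkorc1()
  expect_identical(expected_band_pattern(vk, "XX"), c(119L, 284L))
  expect_identical(expected_band_pattern(vk, "YY"), c(208L, 284L))
  expect_identical(expected_band_pattern(vk, "XY"), c(119L, 208L, 284L))
  # locus-specific labels map onto the same patterns
  expect_identical(expected_band_pattern(vk, "AA"),
                   expected_band_pattern(vk, "XX"))
  expect_identical(expected_band_pattern(vk, "GG"),
                   expected_band_pattern(vk, "YY"))
  cy <- ctpp_assay_cyp2c9()
  expect_identical(expected_band_pattern(cy, "*1*3"), c(125L, 200L, 287L))
  # heterozygote = union of the homozygote patterns
  expect_identical(expected_band_pattern(cy, "XY"),
                   sort(union(expected_band_pattern(cy, "XX"),
                              expected_band_pattern(cy, "YY"))))
  expect_error(expected_band_pattern(vk, "ZZ"), "unknown genotype")
})

test_that("validate_assay reports each broken invariant by name", {
  vk <- ctpp_assay_vkorc1()
  expect_identical(validate_assay(vk), character(0))

  # shift R1 off the SNP
  broken <- vk
  broken$r1 <- ctpp_primer(vk$r1$seq, "R1", vk$r1$start + 1L)
  v <- validate_assay(broken)
  expect_true(any(grepl("R1 3' end not anchored at SNP", v)))

  # swap the two forward primers (roles reassigned to pass construction)
  swapped <- vk
  swapped$f1 <- ctpp_primer(vk$f2$seq, "F1", vk$f2$start)
  swapped$f2 <- ctpp_primer(vk$f1$seq, "F2", vk$f1$start)
  expect_gt(length(validate_assay(swapped)), 0)

  # wrong allele-specific 3' base
  mut <- vk
  seq <- vk$f2$seq
  substr(seq, nchar(seq), nchar(seq)) <- "T"
  mut$f2 <- ctpp_primer(seq, "F2", vk$f2$start)
  expect_true(any(grepl("F2", validate_assay(mut))))

  expect_error(ctpp_assay(broken$f1, broken$r1, broken$f2, broken$r2,
                          broken$locus), "invalid CTPP assay")
})

test_that("locus and primer constructors enforce their invariants", {
  expect_error(snp_locus("ACGTACGT", 3, "G", "G"), "must differ")
  expect_error(snp_locus("ACGTACGT", 3, "A", "C"), "neither allele")
  expect_error(snp_locus("ACGTACGT", 9, "A", "C"), "within the template")
  expect_error(ctpp_primer("ACGTNACGT", "F1", 1), "invalid characters")
  expect_error(ctpp_primer("ACGTACGT", "F3", 1))
  loc <- snp_locus("ACGTACGT", 3, "G", "T", label = "toy")
  expect_identical(loc$snp_pos, 3L)
})

test_that("fragment-size identity c = a + b - (d - 1) holds on random designs", {
  n_checked <- 0L
  for (seed in 1:100) {
    loc <- random_designable_locus(seed)
    des <- design_assay(loc, lax_constraints(), max_results = 1L)
    if (!length(des)) next
    fp <- fragment_pattern(des[[1]])
    expect_identical(fp$c, fp$a + fp$b - (fp$d - 1L))
    expect_gte(fp$a, fp$d)
    expect_gte(fp$b, fp$d)
    n_checked <- n_checked + 1L
  }
  expect_gte(n_checked, 90L)
})
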