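# In-silico amplification and genotype calling.

test_that("simulated band sets reproduce the published gel lanes", {
  vk <- ctpp_assay_vkorc1()
  expect_identical(simulated_bands(vk, "GA"), c(119L, 208L, 284L))
  expect_identical(simulated_bands(vk, "AA"), c(119L, 284L))
  expect_identical(simulated_bands(vk, "GG"), c(208L, 284L))
  cy <- ctpp_assay_cyp2c9()
  expect_identical(simulated_bands(cy, "*1*1"), c(125L, 287L))
  expect_identical(simulated_bands(cy, "*1*3"), c(125L, 200L, 287L))
  expect_identical(simulated_bands(cy, "*3*3"), c(200L, 287L))
})

test_that("allele-specific products come only from their own haplotype", {
  vk <- ctpp_assay_vkorc1()
  amp <- simulate_pcr(vk, diploid_template(vk, "XY"))
  # haplotype 1 carries X: F1-R1 yes, F2-R2 no
  h1 <- amp[amp$haplotype == 1, ]
  h2 <- amp[amp$haplotype == 2, ]
  expect_true(any(h1$forward == "F1" & h1$reverse == "R1"))
  expect_false(any(h1$forward == "F2"))
  expect_true(any(h2$forward == "F2" & h2$reverse == "R2"))
  expect_false(any(h2$reverse == "R1"))
  # the common product comes from both haplotypes
  expect_identical(sum(amp$forward == "F1" & amp$reverse == "R2"), 2L)
})

test_that("simulation equals the expected pattern across random assays and genotypes", {
  checked <- 0L
  for (seed in 1:100) {
    loc <- random_designable_locus(seed + 1000)
    des <- design_assay(loc, lax_constraints(), max_results = 1L)
    if (!length(des)) next
    a <- des[[1]]
    for (g in c("XX", "XY", "YY")) {
      expect_identical(simulated_bands(a, g), expected_band_pattern(a, g))
      cl <- call_genotype(band_observation("s", simulated_bands(a, g)), a,
                          tolerance = 0)
      expect_identical(cl$call, g)
    }
    checked <- checked + 1L
  }
  expect_gte(checked, 90L)
})

test_that("genotype calling handles published patterns, noise and no-calls", {
  vk <- ctpp_assay_vkorc1()
  cy <- ctpp_assay_cyp2c9()
  expect_identical(call_genotype(band_observation("s", c(119, 284)),
                                 vk)$call, "XX")
  expect_identical(call_genotype(band_observation("s", c(119, 284)),
                                 vk)$label, "AA")
  expect_identical(call_genotype(band_observation("s", c(125, 200, 287)),
                                 cy)$call, "XY")
  expect_identical(call_genotype(band_observation("s", c(125, 200, 287)),
                                 cy)$label, "*1*3")

  # tolerance boundary: sizes off by 2 bp call at +-5 but not at +-1
  expect_identical(call_genotype(band_observation("s", c(121, 286)), vk,
                                 tolerance = 5)$call, "XX")
  noisy <- call_genotype(band_observation("s", c(121, 286)), vk,
                         tolerance = 1)
  expect_identical(noisy$call, "NO_CALL")

  only_common <- call_genotype(band_observation("s", 284), vk)
  expect_identical(only_common$call, "NO_CALL")
  expect_match(only_common$reason, "allele bands absent")

  blank <- call_genotype(band_observation("s", numeric(0)), vk)
  expect_identical(blank$call, "NO_CALL")
  expect_match(blank$reason, "no bands")

  extra <- call_genotype(band_observation("s", c(119, 284, 450)), vk)
  expect_identical(extra$call, "NO_CALL")
  expect_match(extra$reason, "extra band")

  no_common <- call_genotype(band_observation("s", c(119, 208)), vk)
  expect_identical(no_common$call, "NO_CALL")
  expect_match(no_common$reason, "common band absent")

  expect_error(call_genotype(band_observation("s", 100), vk,
                             tolerance = -1), "non-negative")
})

test_that("heterozygote lanes show three distinct bands whenever a != b", {
  for (seed in c(21, 22, 23)) {
    loc <- random_designable_locus(seed)
    des <- design_assay(loc, lax_constraints(), max_results = 1L)
    if (!length(des)) next
    fp <- fragment_pattern(des[[1]])
    lane <- simulated_bands(des[[1]], "XY")
    expect_true(fp$c %in% lane)
    if (fp$a != fp$b) expect_length(lane, 3L)
  }
})

test_that("the virtual gel rendering is deterministic and monotone", {
  vk <- ctpp_assay_vkorc1()
  lanes <- lapply(c("XX", "XY", "YY"), function(g)
    band_observation(g, simulated_bands(vk, g)))
  g1 <- render_gel(lanes)
  g2 <- render_gel(lanes)
  expect_identical(g1, g2)
  expect_length(g1, 17L)  # header + 16 rows
  # larger fragments sit higher on the gel
  txt <- unclass(g1)
  row_of <- function(size) grep(paste0(" ", size, " bp$"), txt)
  expect_lt(row_of(500), row_of(100))
  # an empty lane draws nothing but keeps its column
  ge <- render_gel(list(band_observation("blank", numeric(0))))
  expect_length(ge, 17L)
  expect_error(render_gel(list()), "non-empty")
})
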