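---
title: "PCR-CTPP assay design and validation: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{PCR-CTPP assay design and validation: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ctpp)
```

## The genotyping problem

PCR with confronting two-pair primers (PCR-CTPP) types a biallelic SNP in
a single PCR tube followed by ordinary gel electrophoresis — no
restriction digestion, no probes. Four primers are used. Two outer,
allele-blind primers (F1 forward, R2 reverse) flank the SNP. Two inner,
*confronting* primers terminate with their 3′ base exactly on the SNP, on
opposite strands: the inner reverse primer R1 pairs with allele X, the
inner forward primer F2 with allele Y. Because a 3′-terminal mismatch
blocks polymerase extension (the ARMS principle), each inner primer
amplifies only from its own allele.

Three product sizes can arise:

* `a` — F1→R1, present iff an X allele is present;
* `b` — F2→R2, present iff a Y allele is present;
* `c` — F1→R2, present whenever amplification works at all.

Since the footprints of F2 and R1 overlap in exactly the one SNP base,
the sizes are linked by the identity

$$c = a + b - (d - 1), \qquad d = \mathrm{len}(F2) + \mathrm{len}(R1),$$

which the package asserts at construction time and re-checks in property
tests. The three genotypes give three distinct lane patterns —
XX: $\{a, c\}$, XY: $\{a, b, c\}$, YY: $\{b, c\}$ — so one lane calls one
genotype.

The package bundles the two published warfarin-pharmacogenetics assays:
VKORC1 G-1639A (rs9923231; X = A, Y = G, a = 119 bp, b = 208 bp,
c = 284 bp) and CYP2C9 A1075C, i.e. the *3 star allele (rs1057910; X = A
= \*1, Y = C = \*3, a = 125 bp, b = 200 bp, c = 287 bp).

```{r bundled}
vk <- ctpp_assay_vkorc1()
fragment_pattern(vk)
expected_band_pattern(vk, "GA")
```

## Coordinates

All positions are 1-based closed intervals on the plus strand, the
R/Bioconductor convention (IRanges, Biostrings). Reverse primers are
stored 5′→3′ in their own orientation together with their plus-strand
footprint. With a SNP at position $s$: R1 covers $[s, s + \mathrm{len}(R1) - 1]$,
F2 covers $[s - \mathrm{len}(F2) + 1, s]$, and

$$a = s + \mathrm{len}(R1) - \mathrm{start}(F1), \qquad
  b = \mathrm{end}(R2) - s + \mathrm{len}(F2), \qquad
  c = \mathrm{end}(R2) - \mathrm{start}(F1) + 1.$$

A single convention everywhere is what keeps the $c$ identity exact; the
assay JSON files use the same 1-based fields.

## Melting temperatures

Primer Tm is computed by the nearest-neighbor method with the Breslauer
(1986) dinucleotide table:

$$T_m = \frac{\Delta H}{\Delta S + R \ln(C_T/4)} - 273.15
      + 16.6 \log_{10}[\mathrm{Na}^+],$$

with formation enthalpy/entropy summed over dinucleotide stacks
(negative), a duplex-initiation entropy of $-10.8$ cal/mol/K, gas
constant $R = 1.987$ cal/mol/K, and the classic primer-design default
conditions $[\mathrm{Na}^+] = 50$ mM, $C_T = 50$ nM. Values are reported
to 0.1 °C, rounding halves up. Hairpin, self-complementarity, divalent
cation and mismatch corrections are deliberately out of scope: the Tm is
used as a *balance* score between the four primers of one assay, where a
common convention matters more than absolute accuracy.

### Calibration against the published primer values

The bundled assays carry the primer Tm values as originally reported
(`published_tm`). Those values cannot all be reproduced by this — or, as
far as we could determine, any — sequence-additive nearest-neighbor
convention: their rank order contradicts the dinucleotide sums (the
VKORC1 F1 primer has a smaller nearest-neighbor sum Tm than the CYP2C9
F1 primer but a higher published value). Under the package's default
convention the residuals (computed − published, °C) are:

```{r residuals}
for (a in list(ctpp_assay_vkorc1(), ctpp_assay_cyp2c9()))
  print(round(assay_tm(a) - a$published_tm, 2))
```

The median residual is −0.04 °C, i.e. the convention is essentially
unbiased for typical (17–23 nt) primers, while the two longest primers
(26/27 nt) deviate by +5 to +7 °C. Because the deviations are
length-correlated, no uniform constant offset can absorb them, so the
default `calibration_offset` in `default_conditions()` is 0; the offset
slot exists so that a user who trusts a different convention can apply
one uniformly. The discrepancies most likely reflect whatever unstated
program produced the published values and are documented rather than
fitted away; the corresponding acceptance check in the test suite asserts
±1.0 °C agreement and is expected to fail for the long primers, with the
residuals printed in the failure message.

## Assay design

`design_assay()` makes the historical manual primer search algorithmic.
The inner primers are fully determined by the SNP (up to length); the
outer primers range over the flanks. The search enumerates every
quadruple satisfying:

* primer lengths within `primer_len` (default 17–30 nt, the envelope of
  the bundled assays);
* each primer Tm inside `tm_window` (default 60–66 °C);
* product sizes `a`, `b`, `c` inside their ranges, and
  $|a - b| \ge$ `min_ab_gap` (default 10 bp) so the two allele bands are
  separable on a gel and by the genotype caller's size tolerance;
* Tm spread — $\max - \min$ over the four primers — at most
  `max_tm_spread` (default 3 °C).

Feasible assays are ranked by ascending Tm spread (band strength in CTPP
degrades with Tm imbalance, which was the published method's stated
failure mode), ties broken by smaller `c`, then by primer coordinates
and lengths; the enumeration is seed-free and byte-reproducible. Dimer,
hairpin and GC-clamp screening are acknowledged future work. An
infeasible constraint set yields an empty list; a SNP with less than
`min_flank` template on either side is an error. The test suite checks
the top-ranked spread against an independent brute-force nested-loop
enumeration on deliberately small constraint ranges (a few hundred
thousand quadruples, well under a minute on one CPU).

## In-silico PCR and genotype calling

`simulate_pcr()` anneals a primer wherever its *full* sequence matches a
haplotype exactly (reverse primers via reverse complement). An exact-match
model is the right level of description here: CTPP discrimination rests
entirely on the 3′-terminal base, and modeling partial-mismatch extension
would require mismatch thermodynamics outside this package's scope. Band
intensity is likewise not modeled — presence/absence only.

`call_genotype()` compares observed sizes with the three expected
patterns; a genotype is called only if exactly one pattern matches with
every expected band observed within `tolerance` (default ±5 bp, which
keeps the bundled assays' nearest bands, 119 vs 125 and 200 vs 208,
separable) and no observed band unexplained. Everything else is a
`NO_CALL` with a reason (`ambiguous`, `common band absent`, `allele bands
absent`, `extra band`), mirroring failed lanes on a real gel rather than
raising errors.

## Population-genetic QC

For genotype counts $(n_{XX}, n_{XY}, n_{YY})$, allele frequencies are
$p_X = (2n_{XX} + n_{XY})/2n$, and Hardy–Weinberg equilibrium is tested
by a Pearson chi-square on 1 df against expected counts
$(np^2, 2npq, nq^2)$ **without** continuity correction — this is the
variant that reproduces both published cohort p-values (0.514 for the
VKORC1 counts 2/68/356 and 0.658 for the CYP2C9 counts 414/18/0) from
the printed genotype tables; with the Yates correction it does not. Note
the published abstract lists the two p-values in the reverse order of
the genotype table; recomputation from the counts supports the table's
assignment, which this package follows. A monomorphic sample yields a
flagged degenerate result (chi-square 0, p 1, warning) rather than an
error. An exact (Wigginton-type) HWE test is a sensible extension — the
expected minor-homozygote count in the CYP2C9 cohort is only ≈0.19 —
but is not part of this version. Frequencies are reported at full
precision; table-style rounding (3 d.p. for frequencies, 1 d.p. for
percentages, halves up) is applied only at presentation.

`concordance()` pairs two call sets by sample, drops pairs with a
no-call on either side from the denominator, and reports the agreement
rate with a per-genotype confusion table.

## Synthetic data

The paper-derived assays are distributed with *synthetic* templates: the
genomic context of the two SNPs is not part of the published record, so
`assay_from_primers()` reconstructs a minimal template by placing the
four primer footprints at the spacings implied by `a` and `b`, filling
gaps with a deterministic repeating ACGT filler (deterministic so the
shipped FASTA/JSON fixtures are stable), and verifying that no primer
matches anywhere except its own footprint — spurious filler matches are
repaired by deterministic point edits. Every bundled file and object is
labeled SYNTHETIC; none of it is hg19/hg38 sequence, and it must not be
used as genomic context.

`sample_genotypes()` draws cohorts under exact Hardy–Weinberg
equilibrium (two independent Bernoulli alleles per individual) behind a
mandatory seed, leaving the global RNG state untouched. These synthetic
cohorts emulate sampling noise only: no genotyping error, no missingness,
no population structure. Passing tests therefore demonstrate the
correctness of the statistics and of the assay logic, not robustness to
real-world artifacts such as partial digestion bands, stutter, or
allele-specific amplification failure.

## Problem sizes and numerical choices

The test suite exercises: 200 random oligos (8–35 nt) for Tm
oracle-equivalence (agreement to 1e−9 °C before rounding) and strand
symmetry; 100 random loci for design invariants and the
simulate-then-call round trip; brute-force design enumeration on 220 bp
templates with primer lengths 18–19; 1,000 simulated cohorts of 500
individuals for the uniformity of HWE p-values under the null
(Kolmogorov–Smirnov distance < 0.1); and 100 replicate cohorts of
100,000 individuals for HWE compatibility. These sizes were chosen so
the whole suite runs in about a minute on one CPU while keeping every
statistical check comfortably powered.

Ties in rounding go away from zero (62.95 → 63.0) to match how assay
tables are conventionally printed. Genotype pattern matching treats
tolerance as a closed interval (±tol inclusive). The degenerate design
corner cases — empty candidate sets, descending coordinate ranges near
template edges — return empty results rather than errors, reserving
errors for malformed inputs.

## Known limitations

* Tm is nearest-neighbor + salt only; no mismatch, dimer or hairpin
  thermodynamics, and the published primer values are tracked only to
  the extent documented above.
* The annealing model is exact-match; real polymerases extend some
  3′ mismatches at reduced efficiency, which this package treats as
  design-time risk rather than simulating.
* The HWE test is asymptotic; with very small expected counts an exact
  test would be preferable.
* Only single-SNP, biallelic, single-tube assays are modeled; multiplex
  and single-primer-pair CTPP variants are out of scope.
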