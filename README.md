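# ctpp — design, simulation and validation of PCR-CTPP SNP genotyping assays

`ctpp` is an R toolkit for **PCR with confronting two-pair primers
(PCR-CTPP)**, a single-tube, gel-readout SNP genotyping method used in
molecular epidemiology and pharmacogenetics where probe-based platforms
are too expensive. It is aimed at assay developers and epidemiology labs
who need to (i) design a CTPP primer set for a SNP, (ii) predict and
check the genotype-specific band patterns, (iii) call genotypes from
observed band sizes, and (iv) run the standard population-genetic QC on
the resulting genotype tables.

## The method in brief

Four primers surround a biallelic SNP. Outer primers F1/R2 are
allele-blind; inner *confronting* primers R1 (reverse) and F2 (forward)
both place their 3′-terminal base on the SNP, on opposite strands, each
matching one allele — a 3′ mismatch blocks extension (ARMS principle),
so each inner primer amplifies only its own allele. One reaction can
yield three products:

| product | primers | present when |
|---|---|---|
| `a` | F1→R1 | allele X present |
| `b` | F2→R2 | allele Y present |
| `c` | F1→R2 | always |

Because F2 and R1 overlap in exactly the SNP base, the sizes obey
`c = a + b − (d − 1)` with `d = len(F2) + len(R1)`. Lane patterns
`{a,c}`, `{a,b,c}`, `{b,c}` identify the genotypes XX, XY, YY. Primer
melting temperatures are computed by Breslauer nearest-neighbor
thermodynamics ([Na⁺] = 50 mM, C_T = 50 nM), and assay design minimizes
the Tm spread across the four primers, the method's main practical
failure mode.

Two ready-made warfarin-pharmacogenetics assays are bundled, with
**synthetic** reconstructed templates (not genomic sequence):
**VKORC1 G-1639A** (rs9923231) and **CYP2C9\*3** (rs1057910). A
Hardy-Weinberg chi-square test (1 df, no continuity correction), call
rate and inter-platform concordance complete the QC side, and a
synthetic-data generator (HWE cohorts, random loci, template
reconstruction) makes everything testable offline.

## Worked example

```r
library(ctpp)

vk <- ctpp_assay_vkorc1()
vk
#> CTPP assay 'VKORC1 G-1639A (rs9923231)'
#> SNP locus 'VKORC1 G-1639A (rs9923231) SYNTHETIC template': 304 bp template, A/G at position 113
#>   F1 + [  11..  32] Tm 63.8  5'-CACAGACGCCAGAGGAAGAGAG-3'
#>   F2 + [  87.. 113] Tm 71.5  5'-GAAGACCTGAAAAACAACCATTGGCCG-3'
#>   R1 - [ 113.. 129] Tm 64.7  5'-CGTGAGCCACCGCACCT-3'
#>   R2 - [ 273.. 294] Tm 62.4  5'-CTCAGCCTCCCAAGTAGTTTGG-3'
#>   fragments: a=119 b=208 c=284 (d=44)
```

The fragment block is the assay's fingerprint: a 119 bp product marks an
A (X) allele, 208 bp marks G (Y), and every sample shows the 284 bp
common product — so an AA lane reads {119, 284}, GA {119, 208, 284},
GG {208, 284}. Calling a sample from observed band sizes:

```r
call_genotype(band_observation("sample_03", c(119, 208, 284)), vk)
#> sample_03: XY (GA)
```

Cohort QC from a genotype count table (GG = 2, GA = 68, AA = 356 — the
bundled VKORC1 study cohort, counting X = G):

```r
cnt <- genotype_counts(2, 68, 356)
round(allele_frequencies(cnt), 3)
#>   p_x   p_y
#> 0.085 0.915
hwe_test(cnt)
#> Hardy-Weinberg chi-square = 0.426 (df = 1), p = 0.514
#>   expected counts: XX 3.04, XY 65.92, YY 357.04
```

The minor-allele (G) frequency is 0.085 and the cohort is compatible
with Hardy-Weinberg equilibrium (p = 0.514). Designing a fresh assay for
any locus and simulating its gel:

```r
loc <- random_locus(400, 200, seed = 42)
top <- design_assay(loc)[[1]]                 # lowest Tm-spread assay
render_gel(lapply(c("XX", "XY", "YY"), function(g)
  band_observation(g, simulated_bands(top, g))))
```

A command-line interface wraps the same operations
(`design`, `bands`, `simulate`, `call`, `hwe`, `concord`, `fixtures`):

```sh
Rscript "$(Rscript -e 'cat(system.file("cli", "ctpp.R", package = "ctpp"))')" \
    hwe --counts 2 68 356
#> n = 426 (XX 2, XY 68, YY 356)
#> allele frequency X = 0.085, Y = 0.915
#> Hardy-Weinberg chi-square = 0.426 (df = 1), p = 0.514
```

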