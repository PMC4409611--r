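# Synthetic-data generation. The package's ready-made assays carry
# SYNTHETIC templates reconstructed from the published primer sequences
# and fragment sizes -- they reproduce the assay geometry and band
# patterns exactly but are NOT genomic reference sequence and must not be
# used as hg19/hg38 context.

#' Reconstruct a full assay (with synthetic template) from four primers
#' and the two allele-product sizes
#'
#' Places the primer footprints on a synthetic plus strand at the spacings
#' implied by the X-allele product size \code{a} and Y-allele product size
#' \code{b}, fills the gaps with a deterministic repeating ACGT filler,
#' and verifies that no primer matches the template anywhere except its
#' own footprint (spurious filler matches are repaired deterministically).
#' The alleles are inferred from the confronting primers' 3' bases:
#' allele X is the complement of R1's 3' base, allele Y is F2's 3' base.
#' The template carries allele X at the SNP.
#'
#' @param f1,r1,f2,r2 primer sequences, 5'->3' in their own orientation.
#' @param a,b X-allele (F1-R1) and Y-allele (F2-R2) product sizes in bp.
#' @param label assay label.
#' @param conditions thermodynamic conditions attached to the assay.
#' @param genotype_labels,published_tm,notes metadata passed to
#'   [ctpp_assay()].
#' @param flank bases of filler outside the outer primers.
#' @return a valid \code{ctpp_assay} whose simulated band patterns equal
#'   the expected patterns by construction.
#' @export
assay_from_primers <- function(f1, r1, f2, r2, a, b, label = "",
                               conditions = default_conditions(),
                               genotype_labels = NULL, published_tm = NULL,
                               notes = NULL, flank = 10L) {
  f1 <- check_dna(f1, "F1"); r1 <- check_dna(r1, "R1")
  f2 <- check_dna(f2, "F2"); r2 <- check_dna(r2, "R2")
  lf1 <- nchar(f1); lr1 <- nchar(r1); lf2 <- nchar(f2); lr2 <- nchar(r2)
  d <- lf2 + lr1
  if (a < d || b < d)
    stop("product sizes must be at least d = len(F2) + len(R1) = ", d,
         " (got a = ", a, ", b = ", b, ")", call. = FALSE)
  if (a < lf1 + lr1)
    stop("a = ", a, " is too small to fit F1 upstream of the SNP ",
         "(need at least len(F1) + len(R1) = ", lf1 + lr1, ")",
         call. = FALSE)
  if (b < lf2 + lr2)
    stop("b = ", b, " is too small to fit R2 downstream of the SNP ",
         "(need at least len(F2) + len(R2) = ", lf2 + lr2, ")",
         call. = FALSE)

  allele_x <- complement_base(substr(r1, lr1, lr1))
  allele_y <- substr(f2, lf2, lf2)
  if (allele_x == allele_y)
    stop("R1 and F2 3' bases imply identical alleles (", allele_x,
         "): not a valid confronting pair", call. = FALSE)

  f1_start <- flank + 1L
  snp <- f1_start + a - lr1            # a = snp + len(R1) - start(F1)
  r2_end <- snp - lf2 + b              # b = end(R2) - snp + len(F2)
  tot <- r2_end + flank
  tmpl <- .filler(tot)

  # stamp footprints; R1 last so the SNP base ends up as allele X
  tmpl <- .stamp(tmpl, f1, f1_start)
  tmpl <- .stamp(tmpl, f2, snp - lf2 + 1L)
  tmpl <- .stamp(tmpl, reverse_complement(r2), r2_end - lr2 + 1L)
  tmpl <- .stamp(tmpl, reverse_complement(r1), snp)

  locus <- snp_locus(tmpl, snp, allele_x, allele_y,
                     label = paste0(label,
                                    if (nzchar(label)) " " else "",
                                    "SYNTHETIC template"))
  assay <- ctpp_assay(
    f1 = ctpp_primer(f1, "F1", f1_start),
    r1 = ctpp_primer(r1, "R1", snp),
    f2 = ctpp_primer(f2, "F2", snp - lf2 + 1L),
    r2 = ctpp_primer(r2, "R2", r2_end - lr2 + 1L),
    locus = locus, conditions = conditions, label = label,
    genotype_labels = genotype_labels, published_tm = published_tm,
    notes = notes)
  .repair_spurious_matches(assay)
}

# Ensure each primer matches each haplotype only at its own footprint;
# deterministically mutate filler bases to break any extra exact match.
.repair_spurious_matches <- function(assay, max_iter = 100L) {
  prm <- list(F1 = assay$f1, R1 = assay$r1, F2 = assay$f2, R2 = assay$r2)
  protected <- unique(unlist(lapply(prm, function(p) seq.int(p$start,
                                                             p$end))))
  for (iter in seq_len(max_iter)) {
    loc <- assay$locus
    haps <- list(.locus_haplotype(loc, loc$allele_x),
                 .locus_haplotype(loc, loc$allele_y))
    spurious <- NULL
    for (hap in haps) {
      for (p in prm) {
        pat <- if (p$strand == "+") p$seq else reverse_complement(p$seq)
        pos <- .match_positions(hap, pat)
        extra <- setdiff(pos, p$start)
        if (length(extra)) {
          # first mutable (filler) base inside the offending match
          span <- seq.int(extra[1], extra[1] + nchar(pat) - 1L)
          mut <- setdiff(span, c(protected, loc$snp_pos))
          if (!length(mut))
            stop("cannot repair spurious primer match overlapping only ",
                 "primer footprints", call. = FALSE)
          spurious <- mut[1]
          break
        }
      }
      if (!is.null(spurious)) break
    }
    if (is.null(spurious)) return(assay)
    base <- substr(assay$locus$template, spurious, spurious)
    nxt <- c(A = "C", C = "G", G = "T", T = "A")[[base]]
    assay$locus$template <- .stamp(assay$locus$template, nxt, spurious)
  }
  stop("failed to remove spurious primer matches after ", max_iter,
       " repairs", call. = FALSE)
}

#' Ready-made VKORC1 G-1639A (rs9923231) PCR-CTPP assay
#'
#' The published four-primer assay for the VKORC1 promoter variant that is
#' a principal determinant of warfarin dose requirement. Alleles:
#' X = A (variant, F1/R1, 119 bp product), Y = G (reference, F2/R2,
#' 208 bp product), common product 284 bp. The attached template is a
#' SYNTHETIC reconstruction from the primers and product sizes, not
#' genomic sequence. \code{published_tm} holds the primer melting
#' temperatures as originally reported.
#'
#' @return a \code{ctpp_assay}.
#' @examples
#' fragment_pattern(ctpp_assay_vkorc1())
#' @export
ctpp_assay_vkorc1 <- function() {
  assay_from_primers(
    f1 = "CACAGACGCCAGAGGAAGAGAG",
    r1 = "CGTGAGCCACCGCACCT",
    f2 = "GAAGACCTGAAAAACAACCATTGGCCG",
    r2 = "CTCAGCCTCCCAAGTAGTTTGG",
    a = 119L, b = 208L,
    label = "VKORC1 G-1639A (rs9923231)",
    genotype_labels = c(XX = "AA", XY = "GA", YY = "GG"),
    published_tm = c(F1 = 64.0, R1 = 65.1, F2 = 64.4, R2 = 62.1),
    notes = paste("X = A (-1639A, low-expression allele), Y = G.",
                  "SYNTHETIC template reconstructed from primers and",
                  "product sizes; not genomic reference."))
}

#' Ready-made CYP2C9 A1075C / CYP2C9*3 (rs1057910) PCR-CTPP assay
#'
#' The published four-primer assay for the CYP2C9 Ile359Leu variant
#' (star-allele *3) that sharply reduces S-warfarin clearance. Alleles:
#' X = A (*1 wild type, F1/R1, 125 bp product), Y = C (*3, F2/R2, 200 bp
#' product), common product 287 bp. The attached template is a SYNTHETIC
#' reconstruction, not genomic sequence. Note: one figure legend of the
#' original report labels this SNP "rs1570910"; the correct identifier
#' rs1057910 is used here.
#'
#' @return a \code{ctpp_assay}.
#' @export
ctpp_assay_cyp2c9 <- function() {
  assay_from_primers(
    f1 = "CCAGGAAGAGATTGAACGTGTGATTG",
    r1 = "TGGTGGGGAGAAGGTCAAT",
    f2 = "GCACGAGGTCCAGAGATACC",
    r2 = "GAGTTATGCACTTCTCTCACCCG",
    a = 125L, b = 200L,
    label = "CYP2C9 A1075C / *3 (rs1057910)",
    genotype_labels = c(XX = "*1*1", XY = "*1*3", YY = "*3*3"),
    published_tm = c(F1 = 61.6, R1 = 61.3, F2 = 61.7, R2 = 61.1),
    notes = paste("X = A (*1 wild type), Y = C (*3, Ile359Leu).",
                  "SYNTHETIC template reconstructed from primers and",
                  "product sizes; not genomic reference."))
}

#' Sample genotypes under Hardy-Weinberg equilibrium
#'
#' Each individual draws two alleles independently as Bernoulli(p_x).
#'
#' @param p_x frequency of allele X in \code{[0, 1]}.
#' @param n number of individuals (>= 1).
#' @param seed mandatory RNG seed; the global RNG state is untouched.
#' @return character vector of \code{"XX"}/\code{"XY"}/\code{"YY"}.
#' @export
sample_genotypes <- function(p_x, n, seed) {
  if (!is.numeric(p_x) || length(p_x) != 1L || is.na(p_x) || p_x < 0 ||
      p_x > 1)
    stop("p_x must be a probability in [0, 1]", call. = FALSE)
  if (!is.numeric(n) || length(n) != 1L || is.na(n) || n < 1)
    stop("n must be at least 1", call. = FALSE)
  .with_seed(seed, function() {
    x1 <- stats::rbinom(n, 1L, p_x)
    x2 <- stats::rbinom(n, 1L, p_x)
    c("YY", "XY", "XX")[x1 + x2 + 1L]
  })
}

#' Random SNP locus
#'
#' A uniformly random ACGT template with a biallelic SNP at the requested
#' position; allele X is the template base there, allele Y a different
#' base chosen at random.
#'
#' @param length template length.
#' @param snp_pos SNP position; must leave at least one base of flank on
#'   each side.
#' @param seed mandatory RNG seed.
#' @param label locus label.
#' @return a [snp_locus()].
#' @export
random_locus <- function(length, snp_pos, seed, label = "random locus") {
  if (!is.numeric(length) || length(length) != 1L || length < 3)
    stop("length must be at least 3", call. = FALSE)
  if (!is.numeric(snp_pos) || length(snp_pos) != 1L ||
      snp_pos < 2 || snp_pos > length - 1)
    stop("snp_pos must leave at least one base of flank on each side ",
         "(2..", length - 1, ")", call. = FALSE)
  .with_seed(seed, function() {
    bases <- c("A", "C", "G", "T")
    tmpl <- paste(sample(bases, length, replace = TRUE), collapse = "")
    ax <- substr(tmpl, snp_pos, snp_pos)
    ay <- sample(setdiff(bases, ax), 1L)
    snp_locus(tmpl, snp_pos, ax, ay, label = label)
  })
}
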