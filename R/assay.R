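# CTPP assay model. Coordinates are 1-based closed intervals on the plus
# strand throughout the package (the R/Bioconductor idiom). Reverse primers
# are stored 5'->3' in their own orientation with a plus-strand footprint
# [start, start + len - 1].
#
# Geometry of the four primers around a biallelic SNP at snp_pos:
#   F1 ----->                                 (outer forward, allele-blind)
#              F2 ----->|                     (inner forward, 3' base = allele Y)
#                       |<----- R1            (inner reverse, 3' base pairs allele X)
#                                   <----- R2 (outer reverse, allele-blind)
# The confronting inner primers F2 and R1 both terminate on the SNP base,
# on opposite strands, so each extends only from its own allele.

.PRIMER_ROLES <- c("F1", "R1", "F2", "R2")
.GENOTYPES <- c("XX", "XY", "YY")

#' SNP locus: a template strand with a biallelic site
#'
#' @param template plus-strand template sequence.
#' @param snp_pos 1-based position of the SNP in \code{template}.
#' @param allele_x,allele_y the two alleles (single bases, distinct). By
#'   CTPP convention the X allele is targeted by the F1/R1 pair and the Y
#'   allele by F2/R2.
#' @param label free-text locus name.
#' @return an object of class \code{snp_locus}.
#' @export
snp_locus <- function(template, snp_pos, allele_x, allele_y, label = "") {
  template <- check_dna(template, "template")
  n <- nchar(template)
  if (!is.numeric(snp_pos) || length(snp_pos) != 1L || is.na(snp_pos) ||
      snp_pos != as.integer(snp_pos) || snp_pos < 1L || snp_pos > n)
    stop("snp_pos must be an integer within the template (1..", n, ")",
         call. = FALSE)
  snp_pos <- as.integer(snp_pos)
  allele_x <- check_dna(allele_x, "allele_x")
  allele_y <- check_dna(allele_y, "allele_y")
  if (nchar(allele_x) != 1L || nchar(allele_y) != 1L)
    stop("alleles must be single bases", call. = FALSE)
  if (allele_x == allele_y)
    stop("allele_x and allele_y must differ", call. = FALSE)
  obs <- substr(template, snp_pos, snp_pos)
  if (!obs %in% c(allele_x, allele_y))
    stop("template base at snp_pos (", obs, ") is neither allele_x nor ",
         "allele_y", call. = FALSE)
  structure(list(template = template, snp_pos = snp_pos,
                 allele_x = allele_x, allele_y = allele_y,
                 label = as.character(label)),
            class = "snp_locus")
}

#' @export
print.snp_locus <- function(x, ...) {
  cat(sprintf("SNP locus%s: %d bp template, %s/%s at position %d\n",
              if (nzchar(x$label)) paste0(" '", x$label, "'") else "",
              nchar(x$template), x$allele_x, x$allele_y, x$snp_pos))
  invisible(x)
}

# template with a given allele substituted at the SNP
.locus_haplotype <- function(locus, allele) {
  .stamp(locus$template, allele, locus$snp_pos)
}

#' A CTPP primer
#'
#' @param seq primer sequence 5'->3' in its own orientation.
#' @param role one of \code{"F1"}, \code{"R1"}, \code{"F2"}, \code{"R2"}.
#' @param start 1-based plus-strand coordinate of the primer's leftmost
#'   template base (for reverse primers this is the 3'-end side).
#' @return an object of class \code{ctpp_primer} with derived fields
#'   \code{strand} (\code{"+"} for F1/F2, \code{"-"} for R1/R2),
#'   \code{end} (rightmost footprint coordinate) and
#'   \code{allele_specificity} (\code{"X"} for R1, \code{"Y"} for F2,
#'   \code{"none"} otherwise).
#' @export
ctpp_primer <- function(seq, role, start) {
  seq <- check_dna(seq, "primer sequence")
  role <- match.arg(role, .PRIMER_ROLES)
  if (!is.numeric(start) || length(start) != 1L || is.na(start) ||
      start != as.integer(start) || start < 1L)
    stop("start must be a positive integer coordinate", call. = FALSE)
  start <- as.integer(start)
  structure(list(seq = seq, role = role, start = start,
                 end = start + nchar(seq) - 1L,
                 strand = if (role %in% c("F1", "F2")) "+" else "-",
                 allele_specificity = switch(role, R1 = "X", F2 = "Y",
                                             "none")),
            class = "ctpp_primer")
}

#' @export
print.ctpp_primer <- function(x, ...) {
  cat(sprintf("%-2s %s strand [%d..%d] 5'-%s-3' (%d nt)\n", x$role, x$strand,
              x$start, x$end, x$seq, nchar(x$seq)))
  invisible(x)
}

#' Assemble a CTPP assay from four primers and a locus
#'
#' @param f1,r1,f2,r2 [ctpp_primer()] objects with matching roles.
#' @param locus a [snp_locus()].
#' @param conditions thermodynamic conditions used when scoring the assay.
#' @param label assay name.
#' @param genotype_labels optional named character vector translating the
#'   internal genotype codes \code{XX}, \code{XY}, \code{YY} into
#'   locus-specific names (e.g. \code{c(XX = "AA", XY = "GA", YY = "GG")}).
#' @param published_tm optional named numeric vector of externally reported
#'   primer melting temperatures (kept as metadata, not used in scoring).
#' @param notes free-text metadata.
#' @param validate stop on invariant violations (default). With
#'   \code{validate = FALSE} a malformed assay object is returned, which
#'   [validate_assay()] can then describe.
#' @return an object of class \code{ctpp_assay}.
#' @export
ctpp_assay <- function(f1, r1, f2, r2, locus,
                       conditions = default_conditions(), label = "",
                       genotype_labels = NULL, published_tm = NULL,
                       notes = NULL, validate = TRUE) {
  primers <- list(F1 = f1, R1 = r1, F2 = f2, R2 = r2)
  for (role in .PRIMER_ROLES) {
    p <- primers[[role]]
    if (!inherits(p, "ctpp_primer"))
      stop(role, " must be a ctpp_primer object", call. = FALSE)
    if (p$role != role)
      stop("primer passed as ", role, " has role ", p$role, call. = FALSE)
  }
  if (!inherits(locus, "snp_locus"))
    stop("locus must be a snp_locus object", call. = FALSE)
  if (!inherits(conditions, "ctpp_conditions"))
    stop("conditions must be a ctpp_conditions object", call. = FALSE)
  assay <- structure(list(f1 = f1, r1 = r1, f2 = f2, r2 = r2, locus = locus,
                          conditions = conditions,
                          label = as.character(label),
                          genotype_labels = genotype_labels,
                          published_tm = published_tm, notes = notes),
                     class = "ctpp_assay")
  if (validate) {
    bad <- validate_assay(assay)
    if (length(bad))
      stop("invalid CTPP assay:\n  - ", paste(bad, collapse = "\n  - "),
           call. = FALSE)
  }
  assay
}

#' Check every CTPP assay invariant
#'
#' Returns a character vector of human-readable violation descriptions,
#' empty when the assay is well formed: the confronting primers R1 and F2
#' must terminate on the SNP base with the correct allele-specific 3'
#' bases, every primer footprint must match the template (given its target
#' allele at the SNP), F1 must lie upstream of the SNP and of F2's start,
#' and R2 downstream symmetrically.
#'
#' @param assay a \code{ctpp_assay} (possibly built with
#'   \code{validate = FALSE}).
#' @return character vector of violations (empty if valid).
#' @export
validate_assay <- function(assay) {
  if (!inherits(assay, "ctpp_assay"))
    stop("assay must be a ctpp_assay object", call. = FALSE)
  v <- character()
  loc <- assay$locus
  n <- nchar(loc$template)
  snp <- loc$snp_pos
  hap_x <- .locus_haplotype(loc, loc$allele_x)
  hap_y <- .locus_haplotype(loc, loc$allele_y)
  p <- list(F1 = assay$f1, R1 = assay$r1, F2 = assay$f2, R2 = assay$r2)

  for (role in .PRIMER_ROLES) {
    if (p[[role]]$role != role)
      v <- c(v, sprintf("primer in slot %s has role %s", role, p[[role]]$role))
    if (p[[role]]$start < 1L || p[[role]]$end > n)
      v <- c(v, sprintf("%s footprint [%d..%d] outside template (1..%d)",
                        role, p[[role]]$start, p[[role]]$end, n))
  }
  if (length(v)) return(v)  # coordinates unusable; stop here

  # confronting inner primers anchored on the SNP
  if (p$R1$start != snp)
    v <- c(v, "R1 3' end not anchored at SNP")
  else if (substr(p$R1$seq, nchar(p$R1$seq), nchar(p$R1$seq)) !=
           complement_base(loc$allele_x))
    v <- c(v, "R1 3' base is not the complement of allele X")
  if (p$F2$end != snp)
    v <- c(v, "F2 3' end not anchored at SNP")
  else if (substr(p$F2$seq, nchar(p$F2$seq), nchar(p$F2$seq)) != loc$allele_y)
    v <- c(v, "F2 3' base is not allele Y")

  # footprint sequence identity on the haplotype each primer targets
  foot <- function(hap, pr) substr(hap, pr$start, pr$end)
  if (p$F1$seq != foot(hap_x, p$F1) || p$F1$seq != foot(hap_y, p$F1))
    v <- c(v, "F1 sequence does not match the template at its footprint")
  if (p$R2$seq != reverse_complement(foot(hap_x, p$R2)) ||
      p$R2$seq != reverse_complement(foot(hap_y, p$R2)))
    v <- c(v, "R2 sequence does not match the template at its footprint")
  if (p$R1$seq != reverse_complement(foot(hap_x, p$R1)))
    v <- c(v, "R1 sequence does not match the X-allele template at its footprint")
  if (p$F2$seq != foot(hap_y, p$F2))
    v <- c(v, "F2 sequence does not match the Y-allele template at its footprint")

  # outer primer placement
  if (p$F1$end > snp - 1L)
    v <- c(v, "F1 3' end reaches the SNP (must stop at least one base upstream)")
  if (p$F1$start >= p$F2$start)
    v <- c(v, "F1 does not start upstream of F2")
  if (p$R2$start < snp + 1L)
    v <- c(v, "R2 3' end reaches the SNP (must start at least one base downstream)")
  if (p$R2$end <= p$R1$end)
    v <- c(v, "R2 does not end downstream of R1")
  v
}

#' Fragment sizes of a CTPP assay
#'
#' Computes the three product sizes and the confronting-primer length sum:
#' \code{a}, the X-allele product (F1-R1); \code{b}, the Y-allele product
#' (F2-R2); \code{c}, the allele-independent outer product (F1-R2); and
#' \code{d = len(F2) + len(R1)}. Because F2 and R1 overlap by exactly the
#' one SNP base, the sizes obey \code{c = a + b - (d - 1)}, which is
#' re-asserted after computation.
#'
#' @param assay a valid \code{ctpp_assay}.
#' @return an object of class \code{ctpp_fragments}: a list with integer
#'   fields \code{a}, \code{b}, \code{c}, \code{d}.
#' @examples
#' fragment_pattern(ctpp_assay_vkorc1())  # a=119 b=208 c=284
#' @export
fragment_pattern <- function(assay) {
  bad <- validate_assay(assay)
  if (length(bad))
    stop("malformed assay:\n  - ", paste(bad, collapse = "\n  - "),
         call. = FALSE)
  snp <- assay$locus$snp_pos
  a <- (snp + nchar(assay$r1$seq) - 1L) - assay$f1$start + 1L
  b <- assay$r2$end - (snp - nchar(assay$f2$seq) + 1L) + 1L
  cc <- assay$r2$end - assay$f1$start + 1L
  d <- nchar(assay$f2$seq) + nchar(assay$r1$seq)
  stopifnot(cc == a + b - (d - 1L), a >= d, b >= d)
  structure(list(a = a, b = b, c = cc, d = d), class = "ctpp_fragments")
}

#' @export
print.ctpp_fragments <- function(x, ...) {
  cat(sprintf(
    "CTPP fragments: a = %d bp (X allele), b = %d bp (Y allele), c = %d bp (common), d = %d\n",
    x$a, x$b, x$c, x$d))
  invisible(x)
}

#' Expected gel band pattern for a genotype
#'
#' The X-allele product \code{a} appears whenever an X allele is present,
#' the Y-allele product \code{b} whenever a Y allele is present, and the
#' outer common product \code{c} always: \code{XX -> \{a, c\}},
#' \code{XY -> \{a, b, c\}}, \code{YY -> \{b, c\}}.
#'
#' @param assay a valid \code{ctpp_assay}.
#' @param genotype \code{"XX"}, \code{"XY"} or \code{"YY"} (locus-specific
#'   labels registered in the assay's \code{genotype_labels} are also
#'   accepted).
#' @return sorted integer vector of band sizes in bp.
#' @examples
#' expected_band_pattern(ctpp_assay_vkorc1(), "XY")  # 119 208 284
#' @export
expected_band_pattern <- function(assay, genotype) {
  genotype <- normalize_genotype(genotype, assay)
  fp <- fragment_pattern(assay)
  sizes <- switch(genotype,
                  XX = c(fp$a, fp$c),
                  XY = c(fp$a, fp$b, fp$c),
                  YY = c(fp$b, fp$c))
  sort(unique(as.integer(sizes)))
}

#' Translate a genotype label to the internal XX/XY/YY code
#'
#' @param genotype genotype label; internal codes pass through, assay
#'   \code{genotype_labels} (e.g. \code{"GA"}, \code{"*1*3"}) are mapped,
#'   and \code{"NO_CALL"} is preserved.
#' @param assay optional \code{ctpp_assay} supplying the label mapping.
#' @return one of \code{"XX"}, \code{"XY"}, \code{"YY"}, \code{"NO_CALL"}.
#' @export
normalize_genotype <- function(genotype, assay = NULL) {
  if (!is.character(genotype) || length(genotype) != 1L || is.na(genotype))
    stop("genotype must be a single string", call. = FALSE)
  if (genotype %in% c(.GENOTYPES, "NO_CALL")) return(genotype)
  if (!is.null(assay) && !is.null(assay$genotype_labels)) {
    hit <- names(assay$genotype_labels)[assay$genotype_labels == genotype]
    if (length(hit) == 1L) return(hit)
  }
  stop("unknown genotype label '", genotype,
       "' (expected XX, XY, YY or a registered assay label)", call. = FALSE)
}

#' Melting temperatures of the four assay primers
#'
#' @param assay a \code{ctpp_assay}.
#' @param round report to 0.1 degC (default).
#' @return named numeric vector (F1, R1, F2, R2) of Tm in degC computed
#'   under the assay's own conditions.
#' @export
assay_tm <- function(assay, round = TRUE) {
  vapply(list(F1 = assay$f1, R1 = assay$r1, F2 = assay$f2, R2 = assay$r2),
         function(p) melting_temperature(p$seq, assay$conditions,
                                         round = round),
         numeric(1))
}

#' @export
print.ctpp_assay <- function(x, ...) {
  cat(sprintf("CTPP assay%s\n",
              if (nzchar(x$label)) paste0(" '", x$label, "'") else ""))
  print(x$locus)
  tms <- assay_tm(x)
  for (role in c("f1", "f2", "r1", "r2")) {
    p <- x[[role]]
    cat(sprintf("  %-2s %s [%4d..%4d] Tm %.1f  5'-%s-3'\n", p$role, p$strand,
                p$start, p$end, tms[[p$role]], p$seq))
  }
  fp <- tryCatch(fragment_pattern(x), error = function(e) NULL)
  if (!is.null(fp))
    cat(sprintf("  fragments: a=%d b=%d c=%d (d=%d)\n", fp$a, fp$b, fp$c,
                fp$d))
  invisible(x)
}
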