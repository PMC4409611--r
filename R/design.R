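# Exhaustive, deterministic enumeration of CTPP assays for a locus.
# The paper-era practice was manual trial and error tuned by eye on the
# band balance; here the same search is made algorithmic: the confronting
# primers are fixed on the SNP by construction, the outer primers range
# over the flanks, and candidate quadruples are ranked by melting
# temperature balance (band strength in CTPP degrades with Tm imbalance).

#' Constraints for CTPP assay design
#'
#' Defaults reflect the envelope of the bundled published assays: primer
#' lengths 17-30 nt, primer Tm window 60-66 degC, at most 3 degC spread
#' across the four primers, allele products 80-300 bp and common product
#' up to 600 bp.
#'
#' @param primer_len length 2 integer range of primer lengths (nt).
#' @param tm_window length 2 numeric range of acceptable primer Tm (degC).
#' @param max_tm_spread maximum allowed max-min Tm difference across the
#'   four primers of one assay (degC).
#' @param a_range,b_range,c_range length 2 integer ranges for the X-allele,
#'   Y-allele and common product sizes (bp).
#' @param min_ab_gap minimum size difference between the two allele
#'   products (bp). The two allele bands must be separable on a gel --
#'   and the genotype caller needs them distinguishable at its size
#'   tolerance -- so assays with near-equal \code{a} and \code{b} are
#'   rejected.
#' @param min_flank minimum number of template bases required on each side
#'   of the SNP.
#' @return an object of class \code{ctpp_constraints}.
#' @export
design_constraints <- function(primer_len = c(17L, 30L),
                               tm_window = c(60, 66),
                               max_tm_spread = 3,
                               a_range = c(80L, 300L),
                               b_range = c(80L, 300L),
                               c_range = c(100L, 600L),
                               min_ab_gap = 10L,
                               min_flank = 50L) {
  rng <- function(x, nm, lo = 1) {
    if (!is.numeric(x) || length(x) != 2L || anyNA(x) || x[1] > x[2] ||
        x[1] < lo)
      stop(nm, " must be a non-empty range c(lo, hi) with lo >= ", lo,
           call. = FALSE)
    x
  }
  structure(list(primer_len = as.integer(rng(primer_len, "primer_len", 8)),
                 tm_window = rng(tm_window, "tm_window", -Inf),
                 max_tm_spread = max_tm_spread,
                 a_range = as.integer(rng(a_range, "a_range")),
                 b_range = as.integer(rng(b_range, "b_range")),
                 c_range = as.integer(rng(c_range, "c_range")),
                 min_ab_gap = as.integer(min_ab_gap),
                 min_flank = as.integer(min_flank)),
            class = "ctpp_constraints")
}

# all substrings of hap of lengths in len_range starting in starts;
# returns data.frame(start, len, end, tm)
.candidate_frame <- function(hap, starts, lens, cond) {
  g <- expand.grid(start = starts, len = lens, KEEP.OUT.ATTRS = FALSE)
  g$end <- g$start + g$len - 1L
  g <- g[g$start >= 1L & g$end <= nchar(hap), , drop = FALSE]
  if (!nrow(g)) return(cbind(g, tm = numeric(0)))
  g$tm <- vapply(seq_len(nrow(g)), function(i) {
    melting_temperature(substr(hap, g$start[i], g$end[i]), cond,
                        round = FALSE)
  }, numeric(1))
  g
}

#' Design CTPP assays for a SNP locus
#'
#' Enumerates every four-primer assay satisfying the CTPP geometry (R1 and
#' F2 3'-anchored on the SNP with allele-specific terminal bases, F1
#' upstream, R2 downstream), the length, Tm-window, Tm-spread and product
#' size constraints, and returns the feasible assays ranked by ascending
#' Tm spread, ties broken by smaller common product \code{c}, then by
#' primer start coordinates and lengths. The search is exhaustive and
#' deterministic: no randomness is involved, so identical inputs give
#' byte-identical output.
#'
#' @param locus a [snp_locus()].
#' @param constraints a [design_constraints()] object.
#' @param cond thermodynamic conditions for primer Tm.
#' @param max_results return at most this many top-ranked assays
#'   (default 20; \code{Inf} for all feasible).
#' @return list of \code{ctpp_assay} objects, each carrying its Tm spread
#'   in \code{$tm_spread}; empty list when no feasible assay exists.
#' @export
design_assay <- function(locus, constraints = design_constraints(),
                         cond = default_conditions(), max_results = 20L) {
  if (!inherits(locus, "snp_locus"))
    stop("locus must be a snp_locus object", call. = FALSE)
  if (!inherits(constraints, "ctpp_constraints"))
    stop("constraints must be a ctpp_constraints object", call. = FALSE)
  cs <- constraints
  snp <- locus$snp_pos
  n <- nchar(locus$template)
  if (snp - 1L < cs$min_flank || n - snp < cs$min_flank)
    stop("insufficient flank around the SNP: need at least ", cs$min_flank,
         " bases on each side, have ", snp - 1L, " upstream and ", n - snp,
         " downstream", call. = FALSE)

  hap_x <- .locus_haplotype(locus, locus$allele_x)
  hap_y <- .locus_haplotype(locus, locus$allele_y)
  lens <- seq.int(cs$primer_len[1], cs$primer_len[2])
  in_win <- function(df) df[df$tm >= cs$tm_window[1] &
                            df$tm <= cs$tm_window[2], , drop = FALSE]

  # inner confronting primers: anchored on the SNP
  r1 <- in_win(.candidate_frame(hap_x, snp, lens, cond))
  f2 <- .candidate_frame(hap_y, snp - lens + 1L, lens, cond)
  f2 <- in_win(f2[f2$end == snp, , drop = FALSE])

  # outer primers: F1 fully upstream of the SNP, R2 fully downstream
  safe_seq <- function(from, to) if (from > to) integer(0) else seq.int(from, to)
  f1_starts <- safe_seq(max(1L, snp + cs$primer_len[1] - cs$a_range[2]),
                        snp - cs$primer_len[1])
  f1 <- .candidate_frame(hap_x, f1_starts, lens, cond)
  f1 <- in_win(f1[f1$end <= snp - 1L, , drop = FALSE])
  r2_starts <- safe_seq(snp + 1L,
                        min(n, snp + cs$b_range[2]) - cs$primer_len[1] + 1L)
  r2 <- .candidate_frame(hap_x, r2_starts, lens, cond)
  r2 <- in_win(r2[r2$start >= snp + 1L, , drop = FALSE])

  if (!nrow(f1) || !nrow(r1) || !nrow(f2) || !nrow(r2)) return(list())

  # allele-specific pairs filtered by product size
  p1 <- expand.grid(i1 = seq_len(nrow(f1)), j1 = seq_len(nrow(r1)),
                    KEEP.OUT.ATTRS = FALSE)
  p1$a <- snp + r1$len[p1$j1] - f1$start[p1$i1]
  p1 <- p1[p1$a >= cs$a_range[1] & p1$a <= cs$a_range[2], , drop = FALSE]
  p2 <- expand.grid(i2 = seq_len(nrow(f2)), j2 = seq_len(nrow(r2)),
                    KEEP.OUT.ATTRS = FALSE)
  p2$b <- r2$end[p2$j2] - snp + f2$len[p2$i2]
  p2 <- p2[p2$b >= cs$b_range[1] & p2$b <= cs$b_range[2], , drop = FALSE]
  if (!nrow(p1) || !nrow(p2)) return(list())
  if (nrow(p1) * nrow(p2) > 5e7)
    stop("constraint ranges generate more than 5e7 primer combinations; ",
         "tighten the Tm window or size ranges", call. = FALSE)

  p1$lo <- pmin(f1$tm[p1$i1], r1$tm[p1$j1])
  p1$hi <- pmax(f1$tm[p1$i1], r1$tm[p1$j1])
  p2$lo <- pmin(f2$tm[p2$i2], r2$tm[p2$j2])
  p2$hi <- pmax(f2$tm[p2$i2], r2$tm[p2$j2])

  g <- expand.grid(k1 = seq_len(nrow(p1)), k2 = seq_len(nrow(p2)),
                   KEEP.OUT.ATTRS = FALSE)
  g$spread <- pmax(p1$hi[g$k1], p2$hi[g$k2]) -
    pmin(p1$lo[g$k1], p2$lo[g$k2])
  g <- g[g$spread <= cs$max_tm_spread, , drop = FALSE]
  if (!nrow(g)) return(list())
  g$cc <- r2$end[p2$j2[g$k2]] - f1$start[p1$i1[g$k1]] + 1L
  g <- g[g$cc >= cs$c_range[1] & g$cc <= cs$c_range[2] &
           abs(p1$a[g$k1] - p2$b[g$k2]) >= cs$min_ab_gap, , drop = FALSE]
  if (!nrow(g)) return(list())

  # deterministic ranking
  ord <- order(g$spread, g$cc,
               f1$start[p1$i1[g$k1]], f2$start[p2$i2[g$k2]],
               r1$len[p1$j1[g$k1]], r2$start[p2$j2[g$k2]],
               f1$len[p1$i1[g$k1]], f2$len[p2$i2[g$k2]],
               r2$len[p2$j2[g$k2]])
  g <- g[ord, , drop = FALSE]
  if (is.finite(max_results)) g <- utils::head(g, max_results)

  lapply(seq_len(nrow(g)), function(i) {
    i1 <- p1$i1[g$k1[i]]; j1 <- p1$j1[g$k1[i]]
    i2 <- p2$i2[g$k2[i]]; j2 <- p2$j2[g$k2[i]]
    assay <- ctpp_assay(
      f1 = ctpp_primer(substr(hap_x, f1$start[i1], f1$end[i1]), "F1",
                       f1$start[i1]),
      r1 = ctpp_primer(reverse_complement(substr(hap_x, r1$start[j1],
                                                 r1$end[j1])), "R1",
                       r1$start[j1]),
      f2 = ctpp_primer(substr(hap_y, f2$start[i2], f2$end[i2]), "F2",
                       f2$start[i2]),
      r2 = ctpp_primer(reverse_complement(substr(hap_x, r2$start[j2],
                                                 r2$end[j2])), "R2",
                       r2$start[j2]),
      locus = locus, conditions = cond,
      label = sprintf("%s design %d", locus$label, i))
    assay$tm_spread <- g$spread[i]
    assay
  })
}
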