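# Independent oracles, deliberately written without reusing any package
# internals beyond the public API they check.

# --- brute-force nearest-neighbor Tm: explicit per-dinucleotide loop over
#     its own copy of the Breslauer table ------------------------------------
oracle_tm <- function(seq, na = 0.05, ct = 5e-8, offset = 0) {
  dh <- c(AA = 9.1, AT = 8.6, TA = 6.0, CA = 5.8, GT = 6.5, CT = 7.8,
          GA = 5.6, CG = 11.9, GC = 11.1, GG = 11.0, TT = 9.1, AC = 6.5,
          TG = 5.8, AG = 7.8, TC = 5.6, CC = 11.0)
  ds <- c(AA = 24.0, AT = 23.9, TA = 16.9, CA = 12.9, GT = 17.3,
          CT = 20.8, GA = 13.5, CG = 27.8, GC = 26.7, GG = 26.6,
          TT = 24.0, AC = 17.3, TG = 12.9, AG = 20.8, TC = 13.5,
          CC = 26.6)
  h <- 0; s <- -10.8
  for (i in seq_len(nchar(seq) - 1L)) {
    di <- substr(seq, i, i + 1L)
    h <- h - dh[[di]] * 1000
    s <- s - ds[[di]]
  }
  h / (s + 1.987 * log(ct / 4)) - 273.15 + 16.6 * log10(na) + offset
}

random_oligo <- function(len) {
  paste(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = "")
}

# --- exhaustive CTPP design enumeration by nested loops ---------------------
# Returns the minimum four-primer Tm spread over every feasible quadruple,
# or NULL when none is feasible. tm_fun must give the same Tm the design
# search uses (the public melting_temperature), but feasibility logic is
# re-derived here from the assay geometry, independently of design_assay.
oracle_min_spread <- function(locus, primer_len, tm_window, max_spread,
                              a_range, b_range, c_range, ab_gap = 10L) {
  tmpl_x <- locus$template
  substr(tmpl_x, locus$snp_pos, locus$snp_pos) <- locus$allele_x
  tmpl_y <- locus$template
  substr(tmpl_y, locus$snp_pos, locus$snp_pos) <- locus$allele_y
  snp <- locus$snp_pos
  n <- nchar(tmpl_x)
  tm_of <- function(tmpl, from, to)
    melting_temperature(substr(tmpl, from, to), round = FALSE)
  lens <- seq.int(primer_len[1], primer_len[2])
  ok_win <- function(tm) tm >= tm_window[1] && tm <= tm_window[2]

  best <- Inf
  for (lr1 in lens) {
    if (snp + lr1 - 1L > n) next
    tm_r1 <- tm_of(tmpl_x, snp, snp + lr1 - 1L)
    if (!ok_win(tm_r1)) next
    for (lf2 in lens) {
      if (snp - lf2 + 1L < 1L) next
      tm_f2 <- tm_of(tmpl_y, snp - lf2 + 1L, snp)
      if (!ok_win(tm_f2)) next
      for (lf1 in lens) for (s1 in seq_len(snp - lf1)) {
        a <- snp + lr1 - s1
        if (a < a_range[1] || a > a_range[2]) next
        if (s1 >= snp - lf2 + 1L) next        # F1 must start before F2
        tm_f1 <- tm_of(tmpl_x, s1, s1 + lf1 - 1L)
        if (!ok_win(tm_f1)) next
        for (lr2 in lens) for (s2 in seq.int(snp + 1L, n - lr2 + 1L)) {
          e2 <- s2 + lr2 - 1L
          if (e2 <= snp + lr1 - 1L) next      # R2 must end after R1
          b <- e2 - snp + lf2
          if (b < b_range[1] || b > b_range[2]) next
          if (abs(a - b) < ab_gap) next
          cc <- e2 - s1 + 1L
          if (cc < c_range[1] || cc > c_range[2]) next
          tm_r2 <- tm_of(tmpl_x, s2, e2)
          if (!ok_win(tm_r2)) next
          tms <- c(tm_f1, tm_r1, tm_f2, tm_r2)
          spread <- max(tms) - min(tms)
          if (spread <= max_spread && spread < best) best <- spread
        }
      }
    }
  }
  if (is.finite(best)) best else NULL
}

# a random locus on which a lax constraint set is almost surely feasible
random_designable_locus <- function(seed, len = 300L, snp = 150L) {
  random_locus(len, snp, seed = seed)
}

lax_constraints <- function() {
  design_constraints(primer_len = c(18L, 20L), tm_window = c(-100, 200),
                     max_tm_spread = 200, a_range = c(60L, 100L),
                     b_range = c(60L, 100L), c_range = c(80L, 250L),
                     min_flank = 40L)
}
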