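# In-silico PCR on diploid templates and genotype calling from band sizes.
# Annealing is modeled as an exact full-length sequence match: the whole
# point of the confronting-primer layout is that a single 3'-terminal
# mismatch on the SNP base blocks extension, so allele-specific primers
# amplify only from their own allele. Band intensity is not modeled.

#' Diploid template for in-silico amplification
#'
#' Builds the two haplotype strands of an individual with the requested
#' genotype at an assay's (or locus') SNP.
#'
#' @param x a \code{ctpp_assay} or \code{snp_locus}.
#' @param genotype \code{"XX"}, \code{"XY"}, \code{"YY"} or a registered
#'   assay genotype label.
#' @return an object of class \code{ctpp_diploid} with fields
#'   \code{haplotype1}, \code{haplotype2}, \code{genotype},
#'   \code{snp_pos}.
#' @export
diploid_template <- function(x, genotype) {
  locus <- if (inherits(x, "ctpp_assay")) x$locus else x
  if (!inherits(locus, "snp_locus"))
    stop("x must be a ctpp_assay or snp_locus", call. = FALSE)
  genotype <- normalize_genotype(genotype,
                                 if (inherits(x, "ctpp_assay")) x else NULL)
  al <- switch(genotype,
               XX = c(locus$allele_x, locus$allele_x),
               XY = c(locus$allele_x, locus$allele_y),
               YY = c(locus$allele_y, locus$allele_y))
  structure(list(haplotype1 = .locus_haplotype(locus, al[1]),
                 haplotype2 = .locus_haplotype(locus, al[2]),
                 genotype = genotype, snp_pos = locus$snp_pos),
            class = "ctpp_diploid")
}

# all exact-match start positions of pattern in subject
.match_positions <- function(subject, pattern) {
  hits <- gregexpr(pattern, subject, fixed = TRUE)[[1]]
  if (hits[1] == -1L) integer(0) else as.integer(hits)
}

#' Simulate CTPP amplification on a diploid template
#'
#' Each primer anneals wherever its full sequence matches a haplotype
#' exactly (forward primers on the plus strand, reverse primers via their
#' reverse complement), including the 3'-terminal base -- so the
#' confronting allele-specific primers amplify only from their own allele.
#' Products are emitted for the primer pairings F1-R1 (X allele), F2-R2
#' (Y allele) and F1-R2 (common, any allele).
#'
#' @param assay a valid \code{ctpp_assay}.
#' @param tmpl a [diploid_template()] whose haplotypes have the assay's
#'   template length.
#' @return data.frame of amplicons with columns \code{size},
#'   \code{forward}, \code{reverse}, \code{haplotype}.
#' @seealso [simulated_bands()] for the collapsed band view.
#' @export
simulate_pcr <- function(assay, tmpl) {
  bad <- validate_assay(assay)
  if (length(bad))
    stop("malformed assay:\n  - ", paste(bad, collapse = "\n  - "),
         call. = FALSE)
  if (!inherits(tmpl, "ctpp_diploid"))
    stop("tmpl must be a ctpp_diploid object", call. = FALSE)
  if (nchar(tmpl$haplotype1) != nchar(assay$locus$template))
    stop("template/assay mismatch: haplotype length ",
         nchar(tmpl$haplotype1), " != assay template length ",
         nchar(assay$locus$template), call. = FALSE)
  pairs <- list(c("F1", "R1"), c("F2", "R2"), c("F1", "R2"))
  prm <- list(F1 = assay$f1, R1 = assay$r1, F2 = assay$f2, R2 = assay$r2)
  out <- list()
  for (h in 1:2) {
    hap <- tmpl[[paste0("haplotype", h)]]
    fw_pos <- lapply(prm[c("F1", "F2")], function(p)
      .match_positions(hap, p$seq))
    rv_pos <- lapply(prm[c("R1", "R2")], function(p)
      .match_positions(hap, reverse_complement(p$seq)))
    for (pr in pairs) {
      fstarts <- fw_pos[[pr[1]]]
      rstarts <- rv_pos[[pr[2]]]
      rlen <- nchar(prm[[pr[2]]]$seq)
      for (fs in fstarts) for (rs in rstarts) {
        size <- rs + rlen - 1L - fs + 1L
        if (rs > fs && size > 0L)
          out[[length(out) + 1L]] <- data.frame(
            size = size, forward = pr[1], reverse = pr[2], haplotype = h)
      }
    }
  }
  if (!length(out))
    return(data.frame(size = integer(0), forward = character(0),
                      reverse = character(0), haplotype = integer(0)))
  do.call(rbind, out)
}

#' Simulated band sizes for a genotype
#'
#' Convenience wrapper: builds the diploid template, runs [simulate_pcr()]
#' and collapses duplicate product sizes across haplotypes into the set of
#' visible gel bands.
#'
#' @inheritParams diploid_template
#' @param assay a valid \code{ctpp_assay}.
#' @return sorted integer vector of distinct band sizes (bp).
#' @examples
#' simulated_bands(ctpp_assay_vkorc1(), "XY")  # 119 208 284
#' @export
simulated_bands <- function(assay, genotype) {
  amp <- simulate_pcr(assay, diploid_template(assay, genotype))
  sort(unique(amp$size))
}

#' A per-sample band observation
#'
#' @param sample_id sample identifier.
#' @param sizes numeric vector of observed fragment sizes in bp (possibly
#'   noisy); must be positive. May be empty (a blank lane).
#' @return an object of class \code{band_observation}.
#' @export
band_observation <- function(sample_id, sizes) {
  if (!is.character(sample_id) || length(sample_id) != 1L || is.na(sample_id))
    stop("sample_id must be a single string", call. = FALSE)
  sizes <- as.numeric(sizes)
  if (anyNA(sizes) || any(sizes <= 0))
    stop("band sizes must be positive numbers", call. = FALSE)
  structure(list(sample_id = sample_id, sizes = sort(sizes)),
            class = "band_observation")
}

# does obs match the expected pattern: every expected band observed within
# tol, every observed band explained within tol
.pattern_matches <- function(obs, expected, tol) {
  if (!length(obs)) return(FALSE)
  exp_hit <- vapply(expected, function(e) any(abs(obs - e) <= tol),
                    logical(1))
  obs_hit <- vapply(obs, function(o) any(abs(expected - o) <= tol),
                    logical(1))
  all(exp_hit) && all(obs_hit)
}

#' Call a genotype from observed band sizes
#'
#' Compares the observed sizes against the three expected CTPP patterns.
#' A genotype is called only when exactly one pattern matches: every
#' expected band has an observed band within \code{tolerance} and no
#' observed band is left unexplained. Anything else is a no-call with a
#' diagnostic reason (mirroring failed genotyping on a real gel), never an
#' error.
#'
#' @param obs a [band_observation()].
#' @param assay a valid \code{ctpp_assay}.
#' @param tolerance size matching tolerance in bp (default 5, which keeps
#'   the bundled assays' nearby bands -- 119 vs 125 and 200 vs 208 --
#'   separable).
#' @return an object of class \code{ctpp_call}: list with
#'   \code{sample_id}, \code{call} (\code{XX}/\code{XY}/\code{YY}/
#'   \code{NO_CALL}), \code{label} (locus-specific genotype name when
#'   registered), \code{matched_bands} (observed -> expected mapping) and
#'   \code{reason} (for no-calls).
#' @examples
#' call_genotype(band_observation("s1", c(119, 284)), ctpp_assay_vkorc1())
#' @export
call_genotype <- function(obs, assay, tolerance = 5) {
  if (!inherits(obs, "band_observation"))
    stop("obs must be a band_observation", call. = FALSE)
  if (!is.numeric(tolerance) || length(tolerance) != 1L || tolerance < 0)
    stop("tolerance must be a single non-negative number", call. = FALSE)
  fp <- fragment_pattern(assay)
  patterns <- list(XX = c(fp$a, fp$c), XY = c(fp$a, fp$b, fp$c),
                   YY = c(fp$b, fp$c))
  hits <- names(patterns)[vapply(patterns, .pattern_matches,
                                 logical(1), obs = obs$sizes,
                                 tol = tolerance)]
  res <- list(sample_id = obs$sample_id, call = "NO_CALL", label = NULL,
              matched_bands = NULL, reason = NULL)
  class(res) <- "ctpp_call"
  if (length(hits) == 1L) {
    expected <- patterns[[hits]]
    res$call <- hits
    res$label <- if (!is.null(assay$genotype_labels))
      unname(assay$genotype_labels[[hits]]) else hits
    res$matched_bands <- data.frame(
      observed = obs$sizes,
      expected = vapply(obs$sizes,
                        function(o) expected[which.min(abs(expected - o))],
                        numeric(1)))
    return(res)
  }
  if (length(hits) > 1L) {
    res$reason <- paste("ambiguous: bands consistent with",
                        paste(hits, collapse = " and "))
    return(res)
  }
  # diagnose why nothing matched
  sizes <- obs$sizes
  res$reason <- if (!length(sizes)) {
    "no bands observed"
  } else if (!any(abs(sizes - fp$c) <= tolerance)) {
    "common band absent"
  } else if (!any(abs(sizes - fp$a) <= tolerance) &&
             !any(abs(sizes - fp$b) <= tolerance)) {
    "allele bands absent"
  } else {
    "extra band not matching any expected fragment"
  }
  res
}

#' @export
print.ctpp_call <- function(x, ...) {
  if (x$call == "NO_CALL")
    cat(sprintf("%s: NO_CALL (%s)\n", x$sample_id, x$reason))
  else
    cat(sprintf("%s: %s%s\n", x$sample_id, x$call,
                if (!is.null(x$label) && x$label != x$call)
                  paste0(" (", x$label, ")") else ""))
  invisible(x)
}

#' Call genotypes for a set of band observations
#'
#' @param observations list of [band_observation()] objects.
#' @param assay a valid \code{ctpp_assay}.
#' @param tolerance matching tolerance in bp.
#' @return data.frame with columns \code{sample_id}, \code{call},
#'   \code{label}, \code{reason}.
#' @export
call_genotypes <- function(observations, assay, tolerance = 5) {
  calls <- lapply(observations, call_genotype, assay = assay,
                  tolerance = tolerance)
  data.frame(
    sample_id = vapply(calls, `[[`, character(1), "sample_id"),
    call = vapply(calls, `[[`, character(1), "call"),
    label = vapply(calls, function(x)
      if (is.null(x$label)) NA_character_ else x$label, character(1)),
    reason = vapply(calls, function(x)
      if (is.null(x$reason)) "" else x$reason, character(1)))
}

#' Text rendering of a virtual gel
#'
#' Draws lanes of band observations next to a size ladder, larger
#' fragments on top, with a monotone log-scale size-to-row mapping.
#' Purely deterministic; intended for quick terminal inspection.
#'
#' @param lanes non-empty list of [band_observation()] objects.
#' @param ladder numeric vector of ladder fragment sizes (default 100 bp
#'   ladder, 100-500).
#' @param rows vertical resolution in character rows.
#' @return character vector of lines (class \code{ctpp_gel}), printable
#'   with \code{cat(x, sep = "\n")}.
#' @export
render_gel <- function(lanes, ladder = seq(100L, 500L, by = 100L),
                       rows = 16L) {
  if (!is.list(lanes) || !length(lanes))
    stop("lanes must be a non-empty list of band observations", call. = FALSE)
  ok <- vapply(lanes, inherits, logical(1), "band_observation")
  if (!all(ok))
    stop("every lane must be a band_observation", call. = FALSE)
  all_sizes <- c(ladder, unlist(lapply(lanes, `[[`, "sizes")))
  if (!length(all_sizes)) stop("nothing to draw", call. = FALSE)
  lo <- min(all_sizes); hi <- max(all_sizes)
  to_row <- function(s) {
    if (hi == lo) return(rep(1L, length(s)))
    # top row = largest size; log scale like gel migration
    1L + as.integer(round((log(hi) - log(s)) / (log(hi) - log(lo)) *
                            (rows - 1L)))
  }
  width <- 7L
  blank <- strrep(" ", width)
  band <- paste0(" ", strrep("=", width - 2L), " ")
  cols <- c(list(M = ladder), stats::setNames(lapply(lanes, `[[`, "sizes"),
                                              vapply(lanes, `[[`,
                                                     character(1),
                                                     "sample_id")))
  grid <- matrix(blank, nrow = rows, ncol = length(cols))
  for (j in seq_along(cols))
    for (r in to_row(cols[[j]])) grid[r, j] <- band
  header <- paste(formatC(names(cols), width = width), collapse = "")
  body <- apply(grid, 1L, paste, collapse = "")
  # annotate ladder rows with their sizes
  lad_rows <- to_row(ladder)
  ann <- rep("", rows)
  ann[lad_rows] <- paste0(" ", ladder, " bp")
  structure(c(header, paste0(body, ann)), class = "ctpp_gel")
}

#' @export
print.ctpp_gel <- function(x, ...) {
  cat(unclass(x), sep = "\n")
  invisible(x)
}
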