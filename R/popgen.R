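# Allele frequencies, Hardy-Weinberg equilibrium and inter-platform
# concordance for biallelic genotype data.

#' Genotype counts at a biallelic locus
#'
#' @param n_xx,n_xy,n_yy non-negative integer counts of the three
#'   genotypes.
#' @return an object of class \code{genotype_counts} with the total
#'   \code{n}.
#' @export
genotype_counts <- function(n_xx, n_xy, n_yy) {
  cnt <- c(n_xx = n_xx, n_xy = n_xy, n_yy = n_yy)
  if (!is.numeric(cnt) || length(cnt) != 3L || anyNA(cnt) ||
      any(cnt < 0) || any(cnt != as.integer(cnt)))
    stop("counts must be non-negative integers", call. = FALSE)
  structure(list(n_xx = as.integer(n_xx), n_xy = as.integer(n_xy),
                 n_yy = as.integer(n_yy),
                 n = as.integer(n_xx + n_xy + n_yy)),
            class = "genotype_counts")
}

#' Tabulate genotype labels into counts
#'
#' @param genotypes character vector of \code{"XX"}/\code{"XY"}/\code{"YY"}
#'   labels; \code{"NO_CALL"} entries are dropped.
#' @return a [genotype_counts()] object.
#' @export
as_genotype_counts <- function(genotypes) {
  genotypes <- genotypes[genotypes != "NO_CALL"]
  bad <- setdiff(unique(genotypes), .GENOTYPES)
  if (length(bad))
    stop("unknown genotype labels: ", paste(bad, collapse = ", "),
         call. = FALSE)
  genotype_counts(sum(genotypes == "XX"), sum(genotypes == "XY"),
                  sum(genotypes == "YY"))
}

#' @export
print.genotype_counts <- function(x, ...) {
  cat(sprintf("Genotype counts: XX = %d, XY = %d, YY = %d (n = %d)\n",
              x$n_xx, x$n_xy, x$n_yy, x$n))
  invisible(x)
}

#' Allele frequencies from genotype counts
#'
#' \eqn{p_X = (2 n_{XX} + n_{XY}) / (2n)}, \eqn{p_Y = 1 - p_X}. Full
#' precision is returned; round to 3 decimals for table-style reporting.
#'
#' @param counts a [genotype_counts()] object with \code{n >= 1}.
#' @return named numeric vector \code{c(p_x =, p_y =)}.
#' @examples
#' allele_frequencies(genotype_counts(2, 68, 356))  # 0.085 / 0.915
#' @export
allele_frequencies <- function(counts) {
  if (!inherits(counts, "genotype_counts"))
    stop("counts must be a genotype_counts object", call. = FALSE)
  if (counts$n < 1L)
    stop("at least one genotyped individual is required", call. = FALSE)
  p_x <- (2 * counts$n_xx + counts$n_xy) / (2 * counts$n)
  c(p_x = p_x, p_y = 1 - p_x)
}

#' Pearson chi-square test of Hardy-Weinberg equilibrium
#'
#' Compares observed genotype counts with the Hardy-Weinberg expectation
#' \eqn{(n p^2, 2npq, n q^2)} by a Pearson chi-square statistic on one
#' degree of freedom, without continuity correction. A monomorphic sample
#' carries no information about equilibrium and yields a degenerate
#' result (\code{chi2 = 0, p = 1}) with a warning.
#'
#' @param counts a [genotype_counts()] object with \code{n >= 1}.
#' @return an object of class \code{ctpp_hwe}: list with \code{chi2},
#'   \code{df = 1}, \code{p}, \code{expected} (named numeric of expected
#'   counts) and \code{degenerate}.
#' @examples
#' hwe_test(genotype_counts(2, 68, 356))  # p = 0.514
#' @export
hwe_test <- function(counts) {
  if (!inherits(counts, "genotype_counts"))
    stop("counts must be a genotype_counts object", call. = FALSE)
  if (counts$n < 1L)
    stop("at least one genotyped individual is required", call. = FALSE)
  fr <- allele_frequencies(counts)
  p <- fr[["p_x"]]; q <- fr[["p_y"]]
  expected <- c(n_xx = counts$n * p^2, n_xy = 2 * counts$n * p * q,
                n_yy = counts$n * q^2)
  if (p == 0 || q == 0) {
    warning("monomorphic sample: Hardy-Weinberg test is degenerate",
            call. = FALSE)
    res <- list(chi2 = 0, df = 1L, p = 1, expected = expected,
                degenerate = TRUE)
  } else {
    observed <- c(counts$n_xx, counts$n_xy, counts$n_yy)
    chi2 <- sum((observed - expected)^2 / expected)
    res <- list(chi2 = chi2, df = 1L,
                p = stats::pchisq(chi2, df = 1, lower.tail = FALSE),
                expected = expected, degenerate = FALSE)
  }
  class(res) <- "ctpp_hwe"
  res
}

#' @export
print.ctpp_hwe <- function(x, ...) {
  cat(sprintf("Hardy-Weinberg chi-square = %.3f (df = %d), p = %.3f%s\n",
              x$chi2, x$df, x$p,
              if (x$degenerate) " [degenerate: monomorphic]" else ""))
  cat(sprintf("  expected counts: XX %.2f, XY %.2f, YY %.2f\n",
              x$expected[["n_xx"]], x$expected[["n_xy"]],
              x$expected[["n_yy"]]))
  invisible(x)
}

#' Failed-genotyping percentage
#'
#' @param n_failed number of samples without a genotype call.
#' @param n_total total number of samples attempted (>= 1).
#' @return percentage, reported to 1 decimal (half-up).
#' @examples
#' call_failure_rate(10, 436)  # 2.3
#' @export
call_failure_rate <- function(n_failed, n_total) {
  if (!is.numeric(n_total) || length(n_total) != 1L || n_total < 1)
    stop("n_total must be at least 1", call. = FALSE)
  if (!is.numeric(n_failed) || length(n_failed) != 1L || n_failed < 0 ||
      n_failed > n_total)
    stop("n_failed must lie between 0 and n_total", call. = FALSE)
  round_half_up(100 * n_failed / n_total, 1L)
}

# normalise a call set to data.frame(sample_id, call)
.call_table <- function(x, what) {
  if (is.data.frame(x)) {
    if (!all(c("sample_id", "call") %in% names(x)))
      stop(what, " must have columns sample_id and call", call. = FALSE)
    return(x[, c("sample_id", "call")])
  }
  if (is.list(x) && all(vapply(x, inherits, logical(1), "ctpp_call")))
    return(data.frame(
      sample_id = vapply(x, `[[`, character(1), "sample_id"),
      call = vapply(x, `[[`, character(1), "call")))
  stop(what, " must be a data.frame with sample_id/call columns or a list ",
       "of ctpp_call objects", call. = FALSE)
}

#' Concordance between two genotype call sets
#'
#' Pairs calls by \code{sample_id}; pairs in which either platform gave a
#' no-call are excluded from the denominator. Reports the agreement rate
#' and the per-genotype confusion table.
#'
#' @param calls_a,calls_b data.frames with columns \code{sample_id},
#'   \code{call} (values \code{XX}/\code{XY}/\code{YY}/\code{NO_CALL}),
#'   or lists of \code{ctpp_call} objects.
#' @return list with \code{n_compared}, \code{n_agreeing}, \code{rate},
#'   \code{confusion} (table, rows = first call set), \code{n_excluded}.
#' @export
concordance <- function(calls_a, calls_b) {
  a <- .call_table(calls_a, "calls_a")
  b <- .call_table(calls_b, "calls_b")
  if (anyDuplicated(a$sample_id) || anyDuplicated(b$sample_id))
    stop("duplicated sample_id within a call set", call. = FALSE)
  m <- merge(a, b, by = "sample_id", suffixes = c("_a", "_b"))
  if (!nrow(m))
    stop("no samples shared between the two call sets", call. = FALSE)
  usable <- m$call_a != "NO_CALL" & m$call_b != "NO_CALL"
  cmp <- m[usable, , drop = FALSE]
  if (!nrow(cmp))
    stop("zero comparable pairs: every shared sample has a no-call",
         call. = FALSE)
  lev <- .GENOTYPES
  confusion <- table(factor(cmp$call_a, levels = lev),
                     factor(cmp$call_b, levels = lev),
                     dnn = c("calls_a", "calls_b"))
  list(n_compared = nrow(cmp),
       n_agreeing = sum(cmp$call_a == cmp$call_b),
       rate = sum(cmp$call_a == cmp$call_b) / nrow(cmp),
       confusion = confusion,
       n_excluded = sum(!usable))
}
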