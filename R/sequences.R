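#' @keywords internal
"_PACKAGE"

# Strict ACGT alphabet everywhere: degenerate IUPAC codes are rejected, never
# coerced, because a single ambiguity code under an allele-specific 3' base
# would silently void the discrimination logic.

.DNA_COMPLEMENT <- c(A = "T", C = "G", G = "C", T = "A")

#' Validate and normalise a DNA sequence
#'
#' Accepts a single string over \code{A,C,G,T} (case-insensitive; whitespace
#' is stripped so sequences can be pasted in the spaced style of primer
#' tables). Any other character, including degenerate IUPAC codes such as
#' \code{N} or \code{R}, is an error.
#'
#' @param x character scalar.
#' @param what label used in error messages.
#' @return the normalised upper-case sequence string.
#' @examples
#' check_dna("cac aga cgc")
#' @export
check_dna <- function(x, what = "sequence") {
  if (!is.character(x) || length(x) != 1L || is.na(x))
    stop(what, " must be a single character string", call. = FALSE)
  x <- toupper(gsub("[[:space:]]", "", x))
  if (nchar(x) == 0L)
    stop(what, " is empty", call. = FALSE)
  bad <- gsub("[ACGT]", "", x)
  if (nchar(bad) > 0L)
    stop(what, " contains invalid characters: ",
         paste(unique(strsplit(bad, "")[[1]]), collapse = ", "),
         " (only A/C/G/T are accepted)", call. = FALSE)
  x
}

#' Reverse complement of a DNA string
#'
#' @param x DNA string (validated with [check_dna()]).
#' @return the reverse complement, 5'->3'.
#' @examples
#' reverse_complement("ACCGT") # "ACGGT"
#' @export
reverse_complement <- function(x) {
  x <- check_dna(x)
  paste(rev(.DNA_COMPLEMENT[strsplit(x, "")[[1]]]), collapse = "")
}

#' Complement of single bases
#' @param x character vector of single bases.
#' @return complementary bases.
#' @export
complement_base <- function(x) {
  out <- .DNA_COMPLEMENT[toupper(x)]
  if (anyNA(out)) stop("invalid base: ", paste(x[is.na(out)], collapse = ", "),
                       call. = FALSE)
  unname(out)
}

# substring stamp: overwrite template[at .. at+nchar(piece)-1] with piece
.stamp <- function(template, piece, at) {
  substr(template, at, at + nchar(piece) - 1L) <- piece
  template
}

# deterministic filler: ACGTACGT... truncated to n bases
.filler <- function(n) {
  paste(rep_len(c("A", "C", "G", "T"), n), collapse = "")
}

# run fn with a temporary RNG seed, restoring global RNG state afterwards
.with_seed <- function(seed, fn) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed))
    stop("a single numeric seed is required", call. = FALSE)
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  fn()
}
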