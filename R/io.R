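# File formats: FASTA templates (via Biostrings), JSON assay records,
# TSV band observations / genotype tables. TSV files carry a header row;
# every reader/writer pair round-trips on canonical form.

#' Read named DNA sequences from a FASTA file
#'
#' Sequences are validated against the strict A/C/G/T alphabet; a
#' sequence containing any other character (including degenerate IUPAC
#' codes) is reported with the line number of the first offending line.
#'
#' @param path FASTA file.
#' @return named character vector of sequences.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  set <- tryCatch(Biostrings::readDNAStringSet(path),
                  error = function(e) stop("cannot parse FASTA ", path, ": ",
                                           conditionMessage(e),
                                           call. = FALSE))
  seqs <- as.character(set)
  for (i in seq_along(seqs)) {
    ok <- tryCatch({check_dna(seqs[[i]]); TRUE}, error = function(e) e)
    if (!isTRUE(ok)) {
      lines <- readLines(path, warn = FALSE)
      badline <- which(!startsWith(lines, ">") &
                         grepl("[^ACGTacgt[:space:]]", lines))[1]
      stop(path, if (!is.na(badline)) paste0(", line ", badline) else "",
           ", record '", names(seqs)[i], "': ", conditionMessage(ok),
           call. = FALSE)
    }
    seqs[[i]] <- check_dna(seqs[[i]])
  }
  seqs
}

#' Write named DNA sequences to a FASTA file
#'
#' @param seqs named character vector of sequences.
#' @param path output file.
#' @param width line wrap width.
#' @return \code{path}, invisibly.
#' @export
write_fasta <- function(seqs, path, width = 70L) {
  if (is.null(names(seqs)) || any(!nzchar(names(seqs))))
    stop("sequences must be named", call. = FALSE)
  set <- Biostrings::DNAStringSet(vapply(seqs, check_dna, character(1)))
  Biostrings::writeXStringSet(set, path, width = width)
  invisible(path)
}

#' Read a CTPP assay from its JSON record
#'
#' The schema (all coordinates 1-based):
#' \preformatted{
#' {"label": ...,
#'  "locus": {"template": ..., "snp_pos": ..., "allele_x": ...,
#'            "allele_y": ..., "label": ...},
#'  "primers": {"F1": {"seq": ..., "start": ...}, "R1": ..., "F2": ...,
#'              "R2": ...},
#'  "conditions": {"na": ..., "ct": ..., "calibration_offset": ...},
#'  "genotype_labels": {"XX": ..., "XY": ..., "YY": ...},   # optional
#'  "published_tm": {"F1": ..., ...},                       # optional
#'  "notes": ...}                                           # optional
#' }
#' The template may instead be given as \code{"fasta_ref"}: a path
#' (relative to the JSON file) plus \code{"record"} naming the FASTA
#' record.
#'
#' @param path JSON file.
#' @return a validated \code{ctpp_assay}.
#' @export
read_assay_json <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  x <- jsonlite::fromJSON(path, simplifyVector = TRUE)
  need <- function(obj, field, where) {
    if (is.null(obj[[field]]))
      stop(path, ": missing field '", field, "' in ", where, call. = FALSE)
    obj[[field]]
  }
  loc <- need(x, "locus", "assay record")
  template <- if (!is.null(loc$template)) {
    loc$template
  } else {
    ref <- need(loc, "fasta_ref", "locus")
    fa <- read_fasta(file.path(dirname(path), ref))
    rec <- if (!is.null(loc$record)) loc$record else names(fa)[1]
    if (!rec %in% names(fa))
      stop(path, ": record '", rec, "' not found in ", ref, call. = FALSE)
    fa[[rec]]
  }
  locus <- snp_locus(template, need(loc, "snp_pos", "locus"),
                     need(loc, "allele_x", "locus"),
                     need(loc, "allele_y", "locus"),
                     label = if (is.null(loc$label)) "" else loc$label)
  prm <- need(x, "primers", "assay record")
  mk <- function(role) {
    p <- need(prm, role, "primers")
    ctpp_primer(need(p, "seq", role), role, need(p, "start", role))
  }
  cond <- if (is.null(x$conditions)) default_conditions() else
    thermo_conditions(
      na = need(x$conditions, "na", "conditions"),
      ct = need(x$conditions, "ct", "conditions"),
      calibration_offset = if (is.null(x$conditions$calibration_offset)) 0
                           else x$conditions$calibration_offset)
  ctpp_assay(mk("F1"), mk("R1"), mk("F2"), mk("R2"), locus,
             conditions = cond,
             label = if (is.null(x$label)) "" else x$label,
             genotype_labels = if (is.null(x$genotype_labels)) NULL
                               else unlist(x$genotype_labels),
             published_tm = if (is.null(x$published_tm)) NULL
                            else unlist(x$published_tm),
             notes = x$notes)
}

#' Write a CTPP assay to JSON
#'
#' @param assay a \code{ctpp_assay}.
#' @param path output file.
#' @return \code{path}, invisibly.
#' @export
write_assay_json <- function(assay, path) {
  bad <- validate_assay(assay)
  if (length(bad))
    stop("refusing to write malformed assay:\n  - ",
         paste(bad, collapse = "\n  - "), call. = FALSE)
  pj <- function(p) list(seq = p$seq, start = p$start)
  rec <- list(
    label = assay$label,
    locus = list(template = assay$locus$template,
                 snp_pos = assay$locus$snp_pos,
                 allele_x = assay$locus$allele_x,
                 allele_y = assay$locus$allele_y,
                 label = assay$locus$label),
    primers = list(F1 = pj(assay$f1), R1 = pj(assay$r1),
                   F2 = pj(assay$f2), R2 = pj(assay$r2)),
    conditions = list(na = assay$conditions$na, ct = assay$conditions$ct,
                      calibration_offset =
                        assay$conditions$calibration_offset))
  if (!is.null(assay$genotype_labels))
    rec$genotype_labels <- as.list(assay$genotype_labels)
  if (!is.null(assay$published_tm))
    rec$published_tm <- as.list(assay$published_tm)
  if (!is.null(assay$notes)) rec$notes <- assay$notes
  jsonlite::write_json(rec, path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  invisible(path)
}

#' Read band observations from TSV
#'
#' Expected columns: \code{sample_id} and \code{sizes}, the latter a
#' comma-separated list of fragment sizes in bp (empty for a blank lane).
#'
#' @param path TSV file with header.
#' @return list of [band_observation()] objects.
#' @export
read_bands_tsv <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.delim(path, colClasses = "character")
  if (!all(c("sample_id", "sizes") %in% names(df)))
    stop(path, ": expected columns 'sample_id' and 'sizes'", call. = FALSE)
  lapply(seq_len(nrow(df)), function(i) {
    raw <- trimws(strsplit(df$sizes[i], ",", fixed = TRUE)[[1]])
    raw <- raw[nzchar(raw)]
    sizes <- suppressWarnings(as.numeric(raw))
    if (anyNA(sizes))
      stop(path, ", line ", i + 1L, ": non-numeric band size '",
           raw[which(is.na(sizes))[1]], "'", call. = FALSE)
    band_observation(df$sample_id[i], sizes)
  })
}

#' Write band observations to TSV
#'
#' @param observations list of [band_observation()] objects.
#' @param path output file.
#' @return \code{path}, invisibly.
#' @export
write_bands_tsv <- function(observations, path) {
  df <- data.frame(
    sample_id = vapply(observations, `[[`, character(1), "sample_id"),
    sizes = vapply(observations, function(o)
      paste(o$sizes, collapse = ","), character(1)))
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read a genotype table from TSV
#'
#' @param path TSV with header columns \code{sample_id}, \code{genotype}.
#' @return data.frame with columns \code{sample_id}, \code{call}.
#' @export
read_genotypes_tsv <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.delim(path, colClasses = "character")
  if (!all(c("sample_id", "genotype") %in% names(df)))
    stop(path, ": expected columns 'sample_id' and 'genotype'",
         call. = FALSE)
  bad <- which(!df$genotype %in% c(.GENOTYPES, "NO_CALL"))
  if (length(bad))
    stop(path, ", line ", bad[1] + 1L, ": unknown genotype '",
         df$genotype[bad[1]], "' (expected XX/XY/YY/NO_CALL)",
         call. = FALSE)
  data.frame(sample_id = df$sample_id, call = df$genotype)
}

#' Write a genotype table to TSV
#'
#' @param calls data.frame with columns \code{sample_id}, \code{call}.
#' @param path output file.
#' @return \code{path}, invisibly.
#' @export
write_genotypes_tsv <- function(calls, path) {
  df <- data.frame(sample_id = calls$sample_id, genotype = calls$call)
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
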