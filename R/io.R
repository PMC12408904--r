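# FASTA / FASTQ input-output and the per-read quality filter. File parsing is
# delegated to Biostrings; records are handed around as plain data frames
# (id, seq [, qual]) because the downstream mapping code is string-based.

#' Parse locus and allele from record names
#'
#' MLST schemes conventionally name alleles `<locus>_<number>`; the last
#' underscore splits locus from allele. The pattern can be overridden with any
#' regex with two capture groups (locus, allele).
#'
#' @param ids character vector of record names.
#' @param pattern regex with two capture groups; default splits on the last
#'   underscore.
#' @return data.frame with columns `locus` and `allele` (NA where no match).
#' @examples
#' parse_locus_ids(c("purA_7", "arcC_755"))
#' @export
parse_locus_ids <- function(ids, pattern = "^(.*)_([^_]+)$") {
  m <- regmatches(ids, regexec(pattern, ids))
  locus <- vapply(m, function(g) if (length(g) >= 3) g[2] else NA_character_, "")
  allele <- vapply(m, function(g) if (length(g) >= 3) g[3] else NA_character_, "")
  data.frame(locus = locus, allele = allele, stringsAsFactors = FALSE)
}

#' Read reference sequences from a FASTA file
#'
#' Sequences are uppercased and RNA-style U is mapped to T. Record ids are the
#' first whitespace-separated token of the header; loci/alleles are parsed from
#' the ids.
#'
#' @param path FASTA file (plain or gzip).
#' @param locus_pattern regex passed to [parse_locus_ids()].
#' @return data.frame with columns id, seq, locus, allele.
#' @export
read_fasta <- function(path, locus_pattern = "^(.*)_([^_]+)$") {
  if (!file.exists(path)) stop("FASTA file not found: ", path)
  set <- tryCatch(Biostrings::readBStringSet(path),
                  error = function(e) stop("failed to parse FASTA '", path, "': ",
                                           conditionMessage(e)))
  ids <- sub("\\s.*$", "", names(set))
  seqs <- chartr("uU", "tT", as.character(set))
  seqs <- toupper(seqs)
  if (length(ids)) {
    if (any(ids == "")) stop("FASTA '", path, "' contains an empty record id")
    if (anyDuplicated(ids)) {
      stop("duplicate record ids in '", path, "': ",
           paste(unique(ids[duplicated(ids)]), collapse = ", "))
    }
    if (any(nchar(seqs) == 0)) {
      stop("empty sequence for record(s): ",
           paste(ids[nchar(seqs) == 0], collapse = ", "))
    }
    bad <- grepl("[^ACGTN]", seqs)
    if (any(bad)) stop("non-ACGTN characters in record(s): ",
                       paste(ids[bad], collapse = ", "))
  }
  la <- parse_locus_ids(ids, locus_pattern)
  data.frame(id = ids, seq = seqs, locus = la$locus, allele = la$allele,
             stringsAsFactors = FALSE)
}

#' Write sequences to a FASTA file
#'
#' @param records data.frame with columns id and seq.
#' @param path output path.
#' @param width line width for wrapping.
#' @return Invisibly, `path`.
#' @export
write_fasta <- function(records, path, width = 70L) {
  set <- Biostrings::BStringSet(setNames(records$seq, records$id))
  Biostrings::writeXStringSet(set, path, width = width)
  invisible(path)
}

#' Read sequencing reads from a FASTQ file
#'
#' Phred+33 encoding is required; qualities outside [0, 93] are rejected
#' rather than reinterpreted. Gzip input is handled transparently.
#'
#' @param path FASTQ file (plain or gzip).
#' @return data.frame with columns id, seq, qual (ASCII Phred+33 string).
#' @export
read_fastq <- function(path) {
  if (!file.exists(path)) stop("FASTQ file not found: ", path)
  set <- tryCatch(
    Biostrings::readDNAStringSet(path, format = "fastq", with.qualities = TRUE),
    error = function(e) stop("failed to parse FASTQ '", path, "': ",
                             conditionMessage(e)))
  quals <- as.character(S4Vectors::mcols(set)$qualities)
  seqs <- toupper(as.character(set))
  if (length(seqs)) {
    qr <- range(utf8ToInt(paste(quals, collapse = "")))
    if (qr[1] < 33L || qr[2] > 126L) {
      stop("quality characters outside Phred+33 range in '", path, "'")
    }
  }
  data.frame(id = unname(sub("\\s.*$", "", names(set))), seq = unname(seqs),
             qual = unname(quals), stringsAsFactors = FALSE)
}

#' Write reads to a FASTQ file
#'
#' @param reads data.frame with columns id, seq, qual.
#' @param path output path; a `.gz` suffix triggers gzip compression.
#' @return Invisibly, `path`.
#' @export
write_fastq <- function(reads, path) {
  con <- if (grepl("\\.gz$", path)) gzfile(path, "w") else file(path, "w")
  on.exit(close(con))
  if (nrow(reads)) {
    writeLines(paste0("@", reads$id, "\n", reads$seq, "\n+\n", reads$qual), con)
  }
  invisible(path)
}

#' Mean Phred quality per read
#'
#' @param qual character vector of ASCII Phred+33 quality strings.
#' @return numeric vector of mean Phred scores (NaN for empty strings).
#' @export
mean_read_quality <- function(qual) {
  vapply(qual, function(s) mean(utf8ToInt(s)) - 33, numeric(1), USE.NAMES = FALSE)
}

#' Filter reads by mean Phred quality
#'
#' Retains exactly the reads whose mean per-base Phred score is at least
#' `min_q` (boundary inclusive), preserving input order. The aggregation is a
#' per-read mean, the usual read-level quality summary.
#'
#' @param reads data.frame with columns id, seq, qual.
#' @param min_q minimum mean Phred score (>= 0).
#' @return The filtered data.frame (a subsequence of the input rows).
#' @export
quality_filter <- function(reads, min_q = 10) {
  stopifnot(min_q >= 0)
  if (!nrow(reads) || min_q == 0) return(reads)
  reads[mean_read_quality(reads$qual) >= min_q, , drop = FALSE]
}

#' Write a typing report as TSV
#'
#' Columns: sample, locus, allele, score, depth, breadth_pct, identity_pct,
#' consistency, reassigned. Header comment lines (prefixed `#`) echo the
#' resolved configuration for provenance.
#'
#' @param report data.frame as produced by [run_type()].
#' @param path output path.
#' @param config optional named list echoed into `#` header lines.
#' @return Invisibly, `path`.
#' @export
write_typing_report <- function(report, path, config = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(config)) {
    writeLines(sprintf("# %s=%s", names(config),
                       vapply(config, function(x) paste(format(x), collapse = ","), "")),
               con)
  }
  write.table(report, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a typing report written by [write_typing_report()]
#'
#' @param path TSV path.
#' @return data.frame.
#' @export
read_typing_report <- function(path) {
  read.table(path, header = TRUE, sep = "\t", comment.char = "#",
             colClasses = c(allele = "character"), stringsAsFactors = FALSE)
}
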