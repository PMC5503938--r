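#' @importFrom methods is
NULL

# Shared alphabet for all sequences handled by the package. U is folded to T
# on ingest so RNA-exported catalogs and DNA reads interoperate.
.SNOFRAG_ALPHABET <- c("A", "C", "G", "T", "N")

#' Normalize a nucleotide sequence
#'
#' Uppercases, maps U to T, and validates that only A/C/G/T/N remain.
#'
#' @param x character vector of sequences.
#' @param context character scalar used in error messages.
#' @return normalized character vector.
#' @keywords internal
normalize_sequence <- function(x, context = "sequence") {
  x <- chartr("u", "U", toupper(x))
  x <- chartr("U", "T", x)
  bad <- grepl("[^ACGTN]", x)
  if (any(bad)) {
    stop(sprintf("%s contains characters outside {A,C,G,T,N,U} (first offender: '%s')",
                 context, x[which(bad)[1]]), call. = FALSE)
  }
  x
}

#' Build a snoRNA reference catalog from id/sequence vectors
#'
#' @param id character vector of unique record identifiers.
#' @param sequence character vector of nucleotide sequences (U allowed,
#'   mapped to T).
#' @param description optional character vector of free-text descriptions.
#' @return a `sno_catalog`: a data.frame with columns `id`, `description`,
#'   `sequence`, `length`.
#' @examples
#' sno_catalog(c("snoA", "snoB"), c("ACGTACGTACGT", "TTTTACGT"))
#' @export
sno_catalog <- function(id, sequence, description = rep("", length(id))) {
  stopifnot(length(id) == length(sequence), length(description) == length(id))
  id <- as.character(id)
  if (anyDuplicated(id)) {
    stop("catalog ids must be unique; duplicated: ",
         paste(unique(id[duplicated(id)]), collapse = ", "), call. = FALSE)
  }
  sequence <- normalize_sequence(as.character(sequence), "catalog sequence")
  if (any(nchar(sequence) < 1L)) stop("catalog sequences must be non-empty", call. = FALSE)
  out <- data.frame(id = id, description = as.character(description),
                    sequence = sequence, length = nchar(sequence),
                    stringsAsFactors = FALSE)
  class(out) <- c("sno_catalog", "data.frame")
  out
}

#' Read a FASTA reference catalog
#'
#' Parses a (possibly line-wrapped) multi-record FASTA file into a
#' [sno_catalog()]. Sequences are uppercased and U is converted to T.
#'
#' @param path path to a FASTA file.
#' @return a `sno_catalog` data.frame. An empty file yields an empty catalog
#'   with a warning.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (file.size(path) == 0L) {
    warning("empty FASTA file: ", path, call. = FALSE)
    return(sno_catalog(character(0), character(0)))
  }
  first <- substr(readLines(path, n = 1L, warn = FALSE), 1L, 1L)
  if (!identical(first, ">")) {
    stop("malformed FASTA (line 1 does not start with '>'): ", path, call. = FALSE)
  }
  set <- Biostrings::readBStringSet(path, format = "fasta")
  seqs <- as.character(set)
  if (any(nchar(seqs) == 0L)) {
    stop("FASTA record with empty sequence: ",
         names(set)[which(nchar(seqs) == 0L)[1]], call. = FALSE)
  }
  headers <- names(set)
  id <- sub("\\s.*$", "", headers)
  desc <- ifelse(grepl("\\s", headers), sub("^\\S+\\s+", "", headers), "")
  sno_catalog(id, unname(seqs), desc)
}

#' Write a catalog (or any id/sequence table) as FASTA
#'
#' @param catalog a `sno_catalog` or data.frame with `id`, `sequence`, and
#'   optionally `description` columns.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(catalog, path) {
  hdr <- catalog$id
  if (!is.null(catalog$description)) {
    hdr <- ifelse(nchar(catalog$description) > 0,
                  paste(catalog$id, catalog$description), catalog$id)
  }
  set <- Biostrings::BStringSet(catalog$sequence)
  names(set) <- hdr
  Biostrings::writeXStringSet(set, path, format = "fasta")
  invisible(path)
}

#' Read a small RNA-seq library (FASTA or FASTQ)
#'
#' Auto-detects the format from the first character ('>' FASTA, '@' FASTQ),
#' discards FASTQ qualities, and applies the read length window. The raw
#' (pre-filter) read count is retained because it is the default CPM
#' denominator: expression is computed against the total number of reads in
#' the library file, not the number surviving the length filter.
#'
#' @param path path to a FASTA or FASTQ read file.
#' @param min_len,max_len inclusive read length window (default 17-35 nt,
#'   the size range of the small RNA libraries this pipeline targets).
#' @param sample_id identifier for the library; defaults to the file name
#'   without extension.
#' @param subtype_label optional cohort label carried through to reports.
#' @param collapse if `TRUE`, collapse identical read sequences to a single
#'   entry with a `count` column. Off by default: every sequenced read
#'   instance counts once.
#' @return a `sample_library`: a list with `sample_id`, `subtype_label`,
#'   `total_reads` (pre-filter), `total_reads_filtered`, and `reads`
#'   (data.frame `id`, `sequence`, `length`, and `count` when collapsed).
#' @export
read_reads <- function(path, min_len = 17L, max_len = 35L,
                       sample_id = NULL, subtype_label = "",
                       collapse = FALSE) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (is.null(sample_id)) {
    sample_id <- sub("\\.(fa|fasta|fq|fastq)(\\.gz)?$", "", basename(path),
                     ignore.case = TRUE)
  }
  con <- if (grepl("\\.gz$", path)) gzfile(path) else file(path)
  first <- tryCatch(substr(readLines(con, n = 1L, warn = FALSE), 1L, 1L),
                    finally = close(con))
  if (length(first) == 0L) {
    warning("empty read file: ", path, call. = FALSE)
    set <- Biostrings::BStringSet()
  } else if (identical(first, ">")) {
    set <- Biostrings::readBStringSet(path, format = "fasta")
  } else if (identical(first, "@")) {
    set <- Biostrings::readBStringSet(path, format = "fastq")
  } else {
    stop("unrecognized read format (expected FASTA '>' or FASTQ '@'): ",
         path, call. = FALSE)
  }
  ids <- sub("\\s.*$", "", names(set))
  seqs <- normalize_sequence(unname(as.character(set)), "read sequence")
  sample_library(sample_id, ids, seqs, min_len = min_len, max_len = max_len,
                 subtype_label = subtype_label, collapse = collapse)
}

#' Construct a sample library from in-memory reads
#'
#' @param sample_id library identifier.
#' @param id read identifiers.
#' @param sequence read sequences.
#' @inheritParams read_reads
#' @return a `sample_library` (see [read_reads()]).
#' @export
sample_library <- function(sample_id, id, sequence, min_len = 17L,
                           max_len = 35L, subtype_label = "",
                           collapse = FALSE) {
  stopifnot(length(id) == length(sequence))
  sequence <- normalize_sequence(as.character(sequence), "read sequence")
  total_raw <- length(sequence)
  len <- nchar(sequence)
  keep <- len >= min_len & len <= max_len
  reads <- data.frame(id = as.character(id)[keep], sequence = sequence[keep],
                      length = len[keep], stringsAsFactors = FALSE)
  if (collapse && nrow(reads) > 0) {
    tab <- table(reads$sequence)
    reads <- data.frame(id = paste0("seq", seq_along(tab)),
                        sequence = names(tab),
                        length = nchar(names(tab)),
                        count = as.integer(tab),
                        stringsAsFactors = FALSE)
  }
  structure(list(sample_id = sample_id,
                 subtype_label = subtype_label,
                 total_reads = total_raw,
                 total_reads_filtered = nrow(reads),
                 collapsed = collapse,
                 reads = reads),
            class = "sample_library")
}

#' @export
print.sample_library <- function(x, ...) {
  cat(sprintf("sample_library '%s': %d reads (%d after length filter)%s\n",
              x$sample_id, x$total_reads, x$total_reads_filtered,
              if (nchar(x$subtype_label)) paste0(" [", x$subtype_label, "]") else ""))
  invisible(x)
}

#' Write a sample library to FASTQ
#'
#' Qualities are written as a constant placeholder ('I'); the pipeline is
#' quality-agnostic.
#'
#' @param library a `sample_library`.
#' @param path output FASTQ path.
#' @return `path`, invisibly.
#' @export
write_fastq <- function(library, path) {
  set <- Biostrings::DNAStringSet(library$reads$sequence)
  names(set) <- library$reads$id
  Biostrings::writeXStringSet(
    set, path, format = "fastq",
    qualities = Biostrings::BStringSet(strrep("I", Biostrings::width(set))))
  invisible(path)
}

#' Reverse complement of a nucleotide sequence
#'
#' @param sequence character vector over {A,C,G,T,N} (U accepted, mapped to
#'   T first).
#' @return reverse-complemented character vector.
#' @examples
#' reverse_complement("ACGT")   # "ACGT"
#' @export
reverse_complement <- function(sequence) {
  sequence <- normalize_sequence(sequence, "sequence")
  vapply(sequence, function(s) {
    as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
  }, character(1), USE.NAMES = FALSE)
}

#' Read a cohort sample manifest
#'
#' Tab-separated, with header. Required columns: `sample_id`,
#' `subtype_label`, and either `path` (read files) or the pre-counted pair
#' `total_reads` + `query_hits`. An optional logical `exclude` column drops
#' samples from the analysis (used e.g. for subtypes with too few samples).
#'
#' @param path path to the manifest TSV.
#' @return data.frame of manifest rows.
#' @export
read_manifest <- function(path) {
  if (!file.exists(path)) stop("manifest not found: ", path, call. = FALSE)
  m <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  need <- c("sample_id", "subtype_label")
  missing_cols <- setdiff(need, names(m))
  if (length(missing_cols)) {
    stop("manifest missing columns: ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  has_counts <- all(c("total_reads", "query_hits") %in% names(m))
  if (!has_counts && !("path" %in% names(m))) {
    stop("manifest needs either a 'path' column or 'total_reads'+'query_hits'",
         call. = FALSE)
  }
  m
}
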