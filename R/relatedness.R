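# Local-alignment relatedness screening between a snoRNA catalog and a
# miRNA hairpin catalog, and tripartite genome/snoRNA/read alignment views.
# The Smith-Waterman engine is Biostrings::pairwiseAlignment (affine gaps,
# gap cost = open + extend * gap_length); this module owns the scoring
# defaults, the identity bookkeeping over all alignment columns (gap
# columns included, as in BLAST), and the pass/fail screening thresholds.

#' Scoring and acceptance policy for relatedness screening
#'
#' Score defaults qualitatively mimic short-query blastn behavior; the
#' acceptance thresholds default to >= 85% identity over >= 40 alignment
#' columns.
#'
#' @param min_identity_pct minimum percent identity for a pair to pass.
#' @param min_aligned_length minimum alignment length (columns) to pass.
#' @param match,mismatch per-column substitution scores.
#' @param gap_open,gap_extend affine gap penalties (negative); a gap of
#'   length L costs `gap_open + L * gap_extend`.
#' @return a `relatedness_policy` list.
#' @export
relatedness_policy <- function(min_identity_pct = 85, min_aligned_length = 40,
                               match = 2, mismatch = -3,
                               gap_open = -5, gap_extend = -2) {
  stopifnot(min_identity_pct > 0, min_identity_pct <= 100,
            match > 0, mismatch < 0, gap_open <= 0, gap_extend <= 0)
  structure(list(min_identity_pct = min_identity_pct,
                 min_aligned_length = min_aligned_length,
                 match = match, mismatch = mismatch,
                 gap_open = gap_open, gap_extend = gap_extend),
            class = "relatedness_policy")
}

.substitution_matrix <- function(policy) {
  letters <- c("A", "C", "G", "T", "N")
  m <- matrix(policy$mismatch, 5, 5, dimnames = list(letters, letters))
  diag(m) <- policy$match
  # N is never credited as a match, not even against N
  m["N", ] <- policy$mismatch
  m[, "N"] <- policy$mismatch
  m
}

#' Best local alignment between two sequences
#'
#' Smith-Waterman local alignment under the policy's scoring scheme.
#' Percent identity is computed over all alignment columns including gap
#' columns. Coordinates are 0-based half-open on the original sequences.
#'
#' @param query,subject nucleotide strings (A/C/G/T/N; U mapped to T).
#' @param policy a [relatedness_policy()].
#' @param query_id,subject_id identifiers carried into the result.
#' @return a one-row data.frame (`local_alignment`) with `query_id`,
#'   `subject_id`, `identity_pct`, `aligned_length`, `query_start`,
#'   `query_end`, `subject_start`, `subject_end`, `n_matches`,
#'   `n_mismatches`, `n_gap_columns`, `score`, plus the gapped alignment
#'   strings in attributes `aligned_query` / `aligned_subject`.
#' @export
local_align <- function(query, subject, policy = relatedness_policy(),
                        query_id = "query", subject_id = "subject") {
  query <- normalize_sequence(query, "query")
  subject <- normalize_sequence(subject, "subject")
  stopifnot(nchar(query) > 0, nchar(subject) > 0)
  aln <- Biostrings::pairwiseAlignment(
    Biostrings::DNAString(query), Biostrings::DNAString(subject),
    type = "local", substitutionMatrix = .substitution_matrix(policy),
    gapOpening = abs(policy$gap_open), gapExtension = abs(policy$gap_extend))
  ap <- as.character(Biostrings::alignedPattern(aln))
  as_ <- as.character(Biostrings::alignedSubject(aln))
  width <- nchar(ap)
  nm <- Biostrings::nmatch(aln)
  nmm <- Biostrings::nmismatch(aln)
  ngap <- width - nm - nmm
  res <- data.frame(
    query_id = query_id, subject_id = subject_id,
    identity_pct = if (width > 0) 100 * nm / width else NA_real_,
    aligned_length = width,
    query_start = Biostrings::start(Biostrings::pattern(aln)) - 1L,
    query_end = Biostrings::end(Biostrings::pattern(aln)),
    subject_start = Biostrings::start(Biostrings::subject(aln)) - 1L,
    subject_end = Biostrings::end(Biostrings::subject(aln)),
    n_matches = nm, n_mismatches = nmm, n_gap_columns = ngap,
    score = Biostrings::score(aln),
    stringsAsFactors = FALSE)
  attr(res, "aligned_query") <- ap
  attr(res, "aligned_subject") <- as_
  class(res) <- c("local_alignment", "data.frame")
  res
}

#' Screen all snoRNA x hairpin pairs for sequence relatedness
#'
#' Aligns every snoRNA against every hairpin and reports the pairs whose
#' best local alignment passes both thresholds, together with summary means
#' over the passing pairs.
#'
#' @param snornas,hairpins [sno_catalog()] objects.
#' @param policy a [relatedness_policy()].
#' @return list with `results` (passing pairs, BLAST-tabular-like columns)
#'   and `summary` (`n_passing_pairs`, `n_query_passing`,
#'   `mean_identity_pct`, `mean_aligned_length`).
#' @export
screen_catalog_pairs <- function(snornas, hairpins,
                                 policy = relatedness_policy()) {
  if (nrow(snornas) == 0L || nrow(hairpins) == 0L) {
    stop("both catalogs must be non-empty", call. = FALSE)
  }
  rows <- list()
  for (i in seq_len(nrow(snornas))) {
    for (j in seq_len(nrow(hairpins))) {
      r <- local_align(snornas$sequence[i], hairpins$sequence[j], policy,
                       query_id = snornas$id[i], subject_id = hairpins$id[j])
      if (!is.na(r$identity_pct) &&
          r$identity_pct >= policy$min_identity_pct &&
          r$aligned_length >= policy$min_aligned_length) {
        attributes(r)[c("aligned_query", "aligned_subject")] <- NULL
        class(r) <- "data.frame"
        rows[[length(rows) + 1L]] <- r
      }
    }
  }
  results <- if (length(rows)) do.call(rbind, rows) else
    data.frame(query_id = character(0), subject_id = character(0),
               identity_pct = numeric(0), aligned_length = integer(0),
               query_start = integer(0), query_end = integer(0),
               subject_start = integer(0), subject_end = integer(0),
               n_matches = integer(0), n_mismatches = integer(0),
               n_gap_columns = integer(0), score = numeric(0),
               stringsAsFactors = FALSE)
  rownames(results) <- NULL
  summary <- list(
    n_passing_pairs = nrow(results),
    n_query_passing = length(unique(results$query_id)),
    mean_identity_pct = if (nrow(results)) mean(results$identity_pct) else NA_real_,
    mean_aligned_length = if (nrow(results)) mean(results$aligned_length) else NA_real_)
  list(results = results, summary = summary)
}

#' Write screening results as BLAST-tabular-style TSV
#'
#' Columns: qseqid, sseqid, pident, length, qstart, qend, sstart, send,
#' score (coordinates 1-based inclusive, as in BLAST outfmt 6).
#'
#' @param results the `results` data.frame from [screen_catalog_pairs()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_relatedness_tsv <- function(results, path) {
  out <- data.frame(qseqid = results$query_id, sseqid = results$subject_id,
                    pident = round(results$identity_pct, 2),
                    length = results$aligned_length,
                    qstart = results$query_start + 1L, qend = results$query_end,
                    sstart = results$subject_start + 1L, send = results$subject_end,
                    score = results$score, stringsAsFactors = FALSE)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Render a tripartite genome / snoRNA / read alignment view
#'
#' Stacks the genome window, the snoRNA, and a sequencing read 5' to 3'.
#' The marker line carries `|` where all three sequences agree (within the
#' read's span on the snoRNA), `*` where genome and snoRNA agree outside
#' the read span, and a blank where genome and snoRNA disagree.
#'
#' @param genome_window genomic nucleotide string the snoRNA aligns to.
#' @param snorna a one-row [sno_catalog()] entry or a nucleotide string.
#' @param read a read sequence; must occur exactly within the snoRNA.
#' @param policy a [relatedness_policy()] used for the genome::snoRNA local
#'   alignment.
#' @return character vector of display lines (class `tripartite_view`).
#' @export
render_tripartite <- function(genome_window, snorna, read,
                              policy = relatedness_policy()) {
  sno_seq <- if (is.data.frame(snorna)) snorna$sequence[1] else snorna
  sno_id <- if (is.data.frame(snorna)) snorna$id[1] else "snoRNA"
  sno_seq <- normalize_sequence(sno_seq, "snoRNA")
  read <- normalize_sequence(read, "read")
  read_at <- .find_occurrences(read, sno_seq)
  if (!length(read_at)) {
    stop("read is not contained in the snoRNA sequence", call. = FALSE)
  }
  read_start <- read_at[1]                        # 1-based on snoRNA
  read_end <- read_start + nchar(read) - 1L
  aln <- local_align(sno_seq, genome_window, policy,
                     query_id = sno_id, subject_id = "genome")
  gq <- strsplit(attr(aln, "aligned_query"), "")[[1]]    # snoRNA, gapped
  gs <- strsplit(attr(aln, "aligned_subject"), "")[[1]]  # genome, gapped
  # snoRNA coordinate of each alignment column (NA in snoRNA gap columns)
  sno_pos <- cumsum(gq != "-") + aln$query_start
  sno_pos[gq == "-"] <- NA_integer_
  read_line <- ifelse(!is.na(sno_pos) & sno_pos >= read_start & sno_pos <= read_end,
                      gq, " ")
  in_read <- !is.na(sno_pos) & sno_pos >= read_start & sno_pos <= read_end
  marker <- ifelse(gq == gs & gq != "-",
                   ifelse(in_read, "|", "*"), " ")
  lines <- c(paste0("genome  5' ", paste(gs, collapse = ""), " 3'"),
             paste0("           ", paste(marker, collapse = "")),
             paste0("snoRNA  5' ", paste(gq, collapse = ""), " 3'"),
             paste0("read    5' ", paste(read_line, collapse = ""), " 3'"))
  structure(lines, class = "tripartite_view")
}

#' @export
print.tripartite_view <- function(x, ...) {
  cat(unclass(x), sep = "\n")
  invisible(x)
}
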