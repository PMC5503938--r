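# Perfect-match placement of small RNA reads on a snoRNA reference catalog.
# Only full-read exact occurrences are reported: an accepted alignment of
# length L is necessarily a read of length L matching at 100% identity, so
# the length window is applied to the read itself.

#' Alignment policy for perfect-match read placement
#'
#' Two named presets encode the pipeline's two regimes:
#' [policy_cellline()] (16-28 nt, the two-cell-line screen) and
#' [policy_sra_survey()] (>= 16 nt, unbounded, the public-library survey).
#'
#' @param min_len minimum accepted match length in nt (inclusive).
#' @param max_len maximum accepted match length in nt; `Inf` for unbounded.
#' @param strands `"sense"` (default) or `"both"`. Small RNA-seq protocols
#'   are stranded and sdRNAs are sense fragments of their precursor, so
#'   antisense matching is opt-in.
#' @param multi_reference `"all"` (every placement of a read counts, the
#'   default) or `"best"` (only the first placement in deterministic order).
#' @return a `match_policy` list.
#' @export
match_policy <- function(min_len = 16L, max_len = 28L,
                         strands = c("sense", "both"),
                         multi_reference = c("all", "best")) {
  strands <- match.arg(strands)
  multi_reference <- match.arg(multi_reference)
  stopifnot(min_len >= 1L, is.infinite(max_len) || max_len >= min_len)
  structure(list(min_len = as.integer(min_len),
                 max_len = if (is.infinite(max_len)) Inf else as.integer(max_len),
                 strands = strands, multi_reference = multi_reference),
            class = "match_policy")
}

#' @rdname match_policy
#' @export
policy_cellline <- function() match_policy(16L, 28L)

#' @rdname match_policy
#' @export
policy_sra_survey <- function() match_policy(16L, Inf)

# All (overlapping) exact occurrences of `pattern` in `subject`; 1-based
# start positions. Overlap-aware successive fixed search.
.find_occurrences <- function(pattern, subject) {
  starts <- integer(0)
  from <- 1L
  np <- nchar(pattern)
  ns <- nchar(subject)
  while (from + np - 1L <= ns) {
    hit <- regexpr(pattern, substr(subject, from, ns), fixed = TRUE)
    if (hit < 0L) break
    s <- from + as.integer(hit) - 1L
    starts <- c(starts, s)
    from <- s + 1L
  }
  starts
}

# built once; data.frames are copy-on-write so sharing the constant is safe
.EMPTY_ALIGNMENTS <- data.frame(read_id = character(0),
                                snorna_id = character(0),
                                start = integer(0), end = integer(0),
                                match_length = integer(0),
                                strand = character(0),
                                stringsAsFactors = FALSE)

.empty_alignments <- function() .EMPTY_ALIGNMENTS

# Placements of one read sequence across the whole catalog; coordinates are
# 0-based half-open on the reference.
.match_one_sequence <- function(seq, catalog, policy) {
  n <- nchar(seq)
  if (n < policy$min_len || n > policy$max_len || grepl("N", seq, fixed = TRUE)) {
    return(.empty_alignments())
  }
  pats <- c("+" = seq)
  if (policy$strands == "both") {
    pats <- c(pats, "-" = reverse_complement(seq))
  }
  out <- list()
  for (i in seq_len(nrow(catalog))) {
    for (st in names(pats)) {
      starts1 <- .find_occurrences(pats[[st]], catalog$sequence[i])
      if (length(starts1)) {
        out[[length(out) + 1L]] <- data.frame(
          read_id = NA_character_, snorna_id = catalog$id[i],
          start = starts1 - 1L, end = starts1 - 1L + n,
          match_length = n, strand = st, stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(out)) return(.empty_alignments())
  do.call(rbind, out)
}

#' Find all perfect-match placements of a read on a catalog
#'
#' Returns every maximal exact occurrence of the full read within any
#' catalog sequence, provided the read length satisfies the policy window.
#' Reads containing N never match (they cannot be a 100% identity match).
#'
#' @param read a single read sequence (character) or a one-row read
#'   data.frame with `id` and `sequence`.
#' @param catalog a [sno_catalog()].
#' @param policy a [match_policy()].
#' @return data.frame with columns `read_id`, `snorna_id`, `start`, `end`
#'   (0-based half-open on the reference), `match_length`, `strand`. Empty
#'   when there is no match.
#' @export
find_perfect_matches <- function(read, catalog, policy = policy_cellline()) {
  if (nrow(catalog) == 0L) stop("catalog is empty", call. = FALSE)
  if (is.character(read)) {
    read <- data.frame(id = "read", sequence = read, stringsAsFactors = FALSE)
  }
  seq <- normalize_sequence(read$sequence[1], "read sequence")
  hits <- .match_one_sequence(seq, catalog, policy)
  if (nrow(hits)) hits$read_id <- read$id[1]
  hits <- hits[order(hits$snorna_id, hits$start, hits$strand), , drop = FALSE]
  rownames(hits) <- NULL
  if (policy$multi_reference == "best" && nrow(hits) > 1L) {
    hits <- hits[1L, , drop = FALSE]
  }
  hits
}

#' Align every read of a library against a catalog
#'
#' The workhorse of the screen: places all reads of a library on the
#' catalog under the policy and tallies per-snoRNA hit counts, where the
#' hit count of a snoRNA is the number of accepted (read, placement) pairs
#' on it. Output order is deterministic: read input order, then snoRNA id,
#' then start.
#'
#' @param library a `sample_library` (see [read_reads()]).
#' @param catalog a [sno_catalog()].
#' @param policy a [match_policy()].
#' @return list with `alignments` (data.frame as in
#'   [find_perfect_matches()]) and `hits` (data.frame `snorna_id`, `hits`,
#'   one row per catalog entry including zero rows).
#' @export
align_read_set <- function(library, catalog, policy = policy_cellline()) {
  if (nrow(catalog) == 0L) stop("catalog is empty", call. = FALSE)
  reads <- library$reads
  counts <- if (!is.null(reads$count)) reads$count else rep(1L, nrow(reads))

  # cheap containment pre-screen: a read absent from the concatenated
  # catalog (sense and, if enabled, antisense) cannot match anywhere
  concat <- paste(catalog$sequence, collapse = "#")
  maybe_hit <- function(u) {
    grepl(u, concat, fixed = TRUE) ||
      (policy$strands == "both" &&
         !grepl("N", u, fixed = TRUE) &&
         grepl(reverse_complement(u), concat, fixed = TRUE))
  }
  uniq <- unique(reads$sequence)
  per_seq <- lapply(uniq, function(u) {
    if (!maybe_hit(u)) return(.empty_alignments())
    h <- .match_one_sequence(u, catalog, policy)
    h <- h[order(h$snorna_id, h$start, h$strand), , drop = FALSE]
    if (policy$multi_reference == "best" && nrow(h) > 1L) {
      h <- h[1L, , drop = FALSE]
    }
    h
  })

  # assemble per-read alignments by indexing into the stacked placement
  # table (placements of read i = rows of per_seq[[si[i]]], repeated
  # counts[i] times), which keeps this O(total placements) instead of one
  # data.frame bind per read
  si <- match(reads$sequence, uniq)
  m <- vapply(per_seq, nrow, integer(1))
  stacked <- do.call(rbind, c(list(.empty_alignments()), per_seq))
  offset <- cumsum(c(0L, m))[seq_along(per_seq)]
  idx_parts <- lapply(seq_len(nrow(reads)), function(i) {
    mi <- m[si[i]]
    if (mi == 0L) return(integer(0))
    offset[si[i]] + rep(seq_len(mi), counts[i])
  })
  alignments <- stacked[unlist(idx_parts, use.names = FALSE), , drop = FALSE]
  alignments$read_id <- rep(reads$id, m[si] * counts)
  rownames(alignments) <- NULL

  tallied <- table(factor(alignments$snorna_id, levels = catalog$id))
  hits <- data.frame(snorna_id = catalog$id, hits = as.integer(tallied),
                     stringsAsFactors = FALSE)
  list(alignments = alignments, hits = hits)
}

#' Write alignments as TSV
#'
#' Columns: read_id, snorna_id, start, end, length, strand (coordinates
#' 0-based half-open).
#'
#' @param alignments alignment data.frame from [align_read_set()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_alignments <- function(alignments, path) {
  out <- alignments[, c("read_id", "snorna_id", "start", "end",
                        "match_length", "strand")]
  names(out)[5] <- "length"
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
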