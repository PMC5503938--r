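# Independent oracles used across the suite. These deliberately take the
# dumbest correct route (exhaustive scans, textbook DP) and share no code
# with the implementation paths they check.

# Brute-force perfect-match scan: every reference, every offset, substring
# comparison. Coordinates 0-based half-open, like the implementation.
oracle_matches <- function(read_seq, catalog, min_len = 16, max_len = Inf,
                           strands = "sense") {
  out <- data.frame(snorna_id = character(0), start = integer(0),
                    end = integer(0), strand = character(0),
                    stringsAsFactors = FALSE)
  n <- nchar(read_seq)
  if (n < min_len || n > max_len || grepl("N", read_seq, fixed = TRUE)) {
    return(out)
  }
  pats <- list("+" = read_seq)
  if (strands == "both") {
    comp <- chartr("ACGTN", "TGCAN", read_seq)
    pats[["-"]] <- paste(rev(strsplit(comp, "")[[1]]), collapse = "")
  }
  for (i in seq_len(nrow(catalog))) {
    ref <- catalog$sequence[i]
    L <- nchar(ref)
    for (st in names(pats)) {
      if (L < n) next
      for (off in 0:(L - n)) {
        if (substr(ref, off + 1, off + n) == pats[[st]]) {
          out <- rbind(out, data.frame(snorna_id = catalog$id[i],
                                       start = off, end = off + n,
                                       strand = st, stringsAsFactors = FALSE))
        }
      }
    }
  }
  out
}

# Textbook Gotoh local alignment (affine gaps, gap of length L costs
# open + ext * L), returning only the optimal score. Meant for short
# sequences; O(nm) in pure R.
oracle_sw_score <- function(q, s, match = 2, mismatch = -3,
                            gap_open = -5, gap_ext = -2) {
  qv <- strsplit(q, "")[[1]]
  sv <- strsplit(s, "")[[1]]
  n <- length(qv)
  m <- length(sv)
  H <- matrix(0, n + 1, m + 1)
  E <- matrix(-Inf, n + 1, m + 1)  # gap in query (consumes subject char)
  F <- matrix(-Inf, n + 1, m + 1)  # gap in subject (consumes query char)
  best <- 0
  for (i in 2:(n + 1)) {
    for (j in 2:(m + 1)) {
      sub <- if (qv[i - 1] == sv[j - 1] && qv[i - 1] != "N") match else mismatch
      E[i, j] <- max(H[i, j - 1] + gap_open + gap_ext, E[i, j - 1] + gap_ext)
      F[i, j] <- max(H[i - 1, j] + gap_open + gap_ext, F[i - 1, j] + gap_ext)
      H[i, j] <- max(0, H[i - 1, j - 1] + sub, E[i, j], F[i, j])
      if (H[i, j] > best) best <- H[i, j]
    }
  }
  best
}

random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# Small random catalog for matcher property tests
random_catalog <- function(n_seq = 5, max_len = 300) {
  lens <- sample(50:max_len, n_seq, replace = TRUE)
  sno_catalog(sprintf("ref%02d", seq_len(n_seq)),
              vapply(lens, random_dna, character(1)))
}

# Write a small FASTA fixture at a temp path
write_temp_fasta <- function(ids, seqs, descriptions = NULL) {
  path <- tempfile(fileext = ".fa")
  hdr <- if (is.null(descriptions)) ids else
    ifelse(nchar(descriptions) > 0, paste(ids, descriptions), ids)
  writeLines(paste0(">", hdr, "\n", seqs), path)
  path
}
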