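# Cohort analysis: quantify one query sdRNA across a labeled collection of
# small RNA-seq samples and compute per-subtype expression prevalence.

#' Round half away from zero
#'
#' Decimal rounding with ties going up (0.05 -> 0.1), the convention used
#' for prevalence percentages. Base R's round() rounds half to even.
#'
#' @param x numeric vector.
#' @param digits decimal places.
#' @return rounded numeric vector.
#' @export
round_half_up <- function(x, digits = 1L) {
  scale <- 10^digits
  floor(x * scale + 0.5 + sqrt(.Machine$double.eps)) / scale
}

#' Quantify a query sdRNA in one sample library
#'
#' Counts reads that perfectly match within the query sequence (full-read
#' exact occurrence, read length at or above the policy minimum; the
#' survey policy's unbounded maximum is the default) and converts the count
#' to CPM against the library's pre-filter read total.
#'
#' @param query query nucleotide string (e.g. a called sdRNA, or its
#'   parent snoRNA when quantifying at the precursor level).
#' @param library a `sample_library`.
#' @param policy a [match_policy()]; default [policy_sra_survey()].
#' @param expression_threshold CPM threshold for the expressed flag.
#' @param cpm_denominator `"raw"` (pre-filter read total, default) or
#'   `"filtered"` (reads surviving the length window).
#' @return one-row data.frame (`cohort_sample_result`): `sample_id`,
#'   `subtype_label`, `total_reads`, `query_hits`, `query_cpm`,
#'   `expressed`.
#' @export
quantify_query_in_sample <- function(query, library,
                                     policy = policy_sra_survey(),
                                     expression_threshold = 250,
                                     cpm_denominator = c("raw", "filtered")) {
  cpm_denominator <- match.arg(cpm_denominator)
  query <- normalize_sequence(query, "query")
  if (nchar(query) < policy$min_len) {
    stop("query is shorter than the policy minimum match length", call. = FALSE)
  }
  denom <- switch(cpm_denominator, raw = library$total_reads,
                  filtered = library$total_reads_filtered)
  if (denom <= 0) stop("library has no reads; cannot compute CPM", call. = FALSE)
  qcat <- sno_catalog("query", query)
  res <- align_read_set(library, qcat, policy)
  hits <- res$hits$hits[1]
  cpm <- compute_cpm(hits, denom)
  data.frame(sample_id = library$sample_id,
             subtype_label = library$subtype_label,
             total_reads = denom, query_hits = hits, query_cpm = cpm,
             expressed = flag_expressed(cpm, expression_threshold),
             stringsAsFactors = FALSE)
}

#' Per-subtype expression prevalence
#'
#' One row per subtype with the count of expressing samples and the
#' percentage `100 * n_expressed / n_total`, rounded half-up to one
#' decimal. Subtypes appear in first-occurrence order; empty subtype
#' labels are rejected.
#'
#' @param results data.frame of per-sample rows with `subtype_label` and
#'   `expressed` columns (e.g. rbind-ed [quantify_query_in_sample()]
#'   results, or pre-counted manifest rows run through [run_cohort()]).
#' @return data.frame: `subtype_label`, `n_expressed`, `n_total`,
#'   `percentage`.
#' @export
subtype_prevalence <- function(results) {
  if (any(is.na(results$subtype_label) | results$subtype_label == "")) {
    stop("every sample needs a non-empty subtype_label", call. = FALSE)
  }
  labels <- unique(results$subtype_label)
  rows <- lapply(labels, function(lbl) {
    grp <- results[results$subtype_label == lbl, , drop = FALSE]
    n <- nrow(grp)
    k <- sum(grp$expressed)
    data.frame(subtype_label = lbl, n_expressed = k, n_total = n,
               percentage = round_half_up(100 * k / n, 1L),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
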