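# Expression quantification in counts per million (CPM), expression
# flags, differential-overexpression tiers, and sdRNA processing-preference
# ratios. All threshold comparisons are inclusive (>=). The screen is
# threshold-based by design; no p-values or multiple-testing correction are
# computed, and the output should not be read as a statistical test.

#' Counts per million
#'
#' `cpm = raw_count / total_reads * 1e6`, stored unrounded.
#'
#' @param raw_count non-negative hit count(s).
#' @param total_reads library size (CPM denominator); must be positive.
#' @return numeric CPM value(s).
#' @examples
#' compute_cpm(250, 1e6)   # 250
#' @export
compute_cpm <- function(raw_count, total_reads) {
  if (any(total_reads <= 0)) stop("total_reads must be > 0", call. = FALSE)
  if (any(raw_count < 0)) stop("raw_count must be >= 0", call. = FALSE)
  raw_count / total_reads * 1e6
}

#' Flag a feature as expressed
#'
#' TRUE iff CPM is at or above the threshold (inclusive; default 250 CPM).
#'
#' @param cpm numeric CPM value(s).
#' @param threshold expression threshold in CPM.
#' @return logical vector.
#' @export
flag_expressed <- function(cpm, threshold = 250) {
  cpm >= threshold
}

.tier_label <- function(fold, tiers = c(5, 7.5, 75)) {
  labels <- c("none", paste0(">=", as.character(tiers), "x"))
  labels[findInterval(fold, tiers) + 1L]
}

#' Two-sample differential-overexpression table
#'
#' Fold change is pseudocount-stabilized:
#' `(cpm_a + pseudocount) / (cpm_b + pseudocount)`. A feature is
#' overexpressed (in a over b) when the fold change is at least
#' `overexpression_fold` and the feature is expressed (CPM at or above
#' `expression_threshold`) in at least one of the two samples. Tier labels
#' record the highest fold cutoff reached.
#'
#' @param records_a,records_b data.frames with `feature_id` and `cpm`
#'   columns for the two samples. Features present in only one sample get
#'   CPM 0 in the other, with a warning.
#' @param pseudocount CPM added to numerator and denominator.
#' @param expression_threshold CPM floor for the expression requirement.
#' @param overexpression_fold minimum fold change to call overexpression.
#' @param tiers ascending fold cutoffs for tier labels.
#' @return data.frame with `feature_id`, `cpm_a`, `cpm_b`, `fold_change`,
#'   `overexpressed`, `tier`.
#' @export
differential_table <- function(records_a, records_b, pseudocount = 0.1,
                               expression_threshold = 250,
                               overexpression_fold = 5,
                               tiers = c(5, 7.5, 75)) {
  features <- union(records_a$feature_id, records_b$feature_id)
  only_a <- setdiff(records_a$feature_id, records_b$feature_id)
  only_b <- setdiff(records_b$feature_id, records_a$feature_id)
  if (length(only_a) || length(only_b)) {
    warning("features present in only one sample treated as CPM 0 in the other: ",
            paste(c(only_a, only_b), collapse = ", "), call. = FALSE)
  }
  cpm_a <- records_a$cpm[match(features, records_a$feature_id)]
  cpm_b <- records_b$cpm[match(features, records_b$feature_id)]
  cpm_a[is.na(cpm_a)] <- 0
  cpm_b[is.na(cpm_b)] <- 0
  fold <- (cpm_a + pseudocount) / (cpm_b + pseudocount)
  over <- fold >= overexpression_fold &
    pmax(cpm_a, cpm_b) >= expression_threshold
  data.frame(feature_id = features, cpm_a = cpm_a, cpm_b = cpm_b,
             fold_change = fold, overexpressed = over,
             tier = .tier_label(fold, tiers), stringsAsFactors = FALSE)
}

#' Processing preference of an sdRNA relative to its parent snoRNA
#'
#' Within each sample the processing ratio is
#' `(sdrna_cpm + pseudocount) / (snorna_cpm + pseudocount)`; the preference
#' factor is the sample-a ratio over the sample-b ratio, and the snoRNA is
#' flagged preferentially processed in sample a when the factor is at least
#' `cutoff` (default 5.5, inclusive). Because sdRNA hits are counted as a
#' subset of parental snoRNA hits, within-sample ratios are at most ~1;
#' the cross-sample factor is unaffected by this convention.
#'
#' @param snorna_id feature identifier carried into the result.
#' @param sdrna_cpm_a,snorna_cpm_a sdRNA and parent CPM in sample a.
#' @param sdrna_cpm_b,snorna_cpm_b sdRNA and parent CPM in sample b.
#' @param pseudocount CPM stabilizer for near-zero denominators.
#' @param cutoff minimum preference factor (inclusive).
#' @return one-row data.frame: `snorna_id`, `processing_ratio_a`,
#'   `processing_ratio_b`, `preference_factor`, `preferential`.
#' @export
processing_preference <- function(snorna_id, sdrna_cpm_a, snorna_cpm_a,
                                  sdrna_cpm_b, snorna_cpm_b,
                                  pseudocount = 0.1, cutoff = 5.5) {
  ratio_a <- (sdrna_cpm_a + pseudocount) / (snorna_cpm_a + pseudocount)
  ratio_b <- (sdrna_cpm_b + pseudocount) / (snorna_cpm_b + pseudocount)
  factor <- ratio_a / ratio_b
  data.frame(snorna_id = snorna_id,
             processing_ratio_a = ratio_a, processing_ratio_b = ratio_b,
             preference_factor = factor, preferential = factor >= cutoff,
             stringsAsFactors = FALSE)
}
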