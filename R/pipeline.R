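# Orchestration of the two headline analyses: the two-sample
# compare-and-classify screen and the cohort prevalence survey. Every
# report directory embeds the fully resolved configuration so a run can be
# audited and reproduced.

#' Pipeline run configuration
#'
#' Houses every threshold of the screen, with the two alignment regimes as
#' named modes: `"cellline"` (perfect matches of 16-28 nt, the two-sample
#' screen) and `"sra_survey"` (perfect matches of >= 16 nt, unbounded, the
#' cohort survey).
#'
#' @param mode `"cellline"` or `"sra_survey"`; determines the match length
#'   window.
#' @param expression_threshold CPM at or above which a feature counts as
#'   expressed (default 250).
#' @param overexpression_fold minimum fold change for overexpression
#'   (default 5).
#' @param tiers ascending fold cutoffs for tier labels (default 5, 7.5,
#'   75).
#' @param preference_cutoff minimum cross-sample processing-preference
#'   factor (default 5.5).
#' @param fixed_threshold strict lower bound on the fixed-position
#'   fraction for an sdRNA call (default 0.90).
#' @param min_hits read-depth floor for an sdRNA call (default 10).
#' @param delta5,delta3 excision boundary tolerances in nt (defaults 0 and
#'   3).
#' @param pseudocount CPM pseudocount for ratio stabilization (default
#'   0.1).
#' @param cpm_denominator `"raw"` (pre-filter library total, default) or
#'   `"filtered"`.
#' @param min_read_len,max_read_len library read length window (default
#'   17-35 nt).
#' @param strands,multi_reference passed to [match_policy()].
#' @param seed seed recorded for stochastic stages.
#' @return a `run_config` list.
#' @export
run_config <- function(mode = c("cellline", "sra_survey"),
                       expression_threshold = 250,
                       overexpression_fold = 5,
                       tiers = c(5, 7.5, 75),
                       preference_cutoff = 5.5,
                       fixed_threshold = 0.90,
                       min_hits = 10L,
                       delta5 = 0L, delta3 = 3L,
                       pseudocount = 0.1,
                       cpm_denominator = c("raw", "filtered"),
                       min_read_len = 17L, max_read_len = 35L,
                       strands = "sense", multi_reference = "all",
                       seed = 1L) {
  mode <- match.arg(mode)
  cpm_denominator <- match.arg(cpm_denominator)
  stopifnot(expression_threshold > 0, overexpression_fold > 0,
            preference_cutoff > 0, fixed_threshold > 0, fixed_threshold < 1,
            min_hits >= 1, delta5 >= 0, delta3 >= 0, pseudocount > 0)
  structure(list(mode = mode,
                 expression_threshold = expression_threshold,
                 overexpression_fold = overexpression_fold,
                 tiers = tiers,
                 preference_cutoff = preference_cutoff,
                 fixed_threshold = fixed_threshold,
                 min_hits = as.integer(min_hits),
                 delta5 = as.integer(delta5), delta3 = as.integer(delta3),
                 pseudocount = pseudocount,
                 cpm_denominator = cpm_denominator,
                 min_read_len = as.integer(min_read_len),
                 max_read_len = as.integer(max_read_len),
                 strands = strands, multi_reference = multi_reference,
                 seed = as.integer(seed)),
            class = "run_config")
}

#' @rdname run_config
#' @param config a `run_config`.
#' @param path YAML file path.
#' @export
write_run_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' @rdname run_config
#' @export
read_run_config <- function(path) {
  vals <- yaml::yaml.load_file(path)
  do.call(run_config, vals)
}

.policy_from_config <- function(config) {
  match_policy(min_len = 16L,
               max_len = if (config$mode == "cellline") 28L else Inf,
               strands = config$strands,
               multi_reference = config$multi_reference)
}

# Alignments within delta tolerance of an interval family
.family_count <- function(alignments, interval, delta5, delta3) {
  if (nrow(alignments) == 0L) return(0L)
  sum(abs(alignments$start - interval[1]) <= delta5 &
        abs(alignments$end - interval[2]) <= delta3)
}

#' Two-sample snoRNA/sdRNA comparison screen
#'
#' Runs the full screen on two libraries against one catalog: perfect-match
#' alignment, per-snoRNA excision profiling and sdRNA calling in each
#' sample, CPM quantification, the differential-overexpression table with
#' fold tiers, and the processing-preference table (sample a relative to
#' sample b). When `out_dir` is given, all tables plus the resolved
#' configuration are written there as TSV/YAML.
#'
#' @param sample_a,sample_b read file paths (FASTA/FASTQ) or
#'   `sample_library` objects.
#' @param catalog a catalog FASTA path or a [sno_catalog()].
#' @param config a [run_config()].
#' @param out_dir optional report directory.
#' @return (invisibly) a list: `hits_a`, `hits_b`, `calls_a`, `calls_b`,
#'   `expression`, `differential`, `processing`, `config`.
#' @export
run_compare <- function(sample_a, sample_b, catalog,
                        config = run_config(), out_dir = NULL) {
  if (is.character(catalog)) catalog <- read_fasta(catalog)
  if (nrow(catalog) == 0L) stop("compare: catalog is empty", call. = FALSE)
  load_lib <- function(x, label) {
    if (is.character(x)) {
      read_reads(x, config$min_read_len, config$max_read_len)
    } else x
  }
  lib_a <- load_lib(sample_a, "a")
  lib_b <- load_lib(sample_b, "b")
  policy <- .policy_from_config(config)

  aln_a <- align_read_set(lib_a, catalog, policy)
  aln_b <- align_read_set(lib_b, catalog, policy)
  denom <- function(lib) switch(config$cpm_denominator,
                                raw = lib$total_reads,
                                filtered = lib$total_reads_filtered)

  profile_sample <- function(aln) {
    lapply(stats::setNames(catalog$id, catalog$id), function(s) {
      build_profile(aln$alignments[aln$alignments$snorna_id %in% s, , drop = FALSE],
                    delta5 = config$delta5, delta3 = config$delta3)
    })
  }
  prof_a <- profile_sample(aln_a)
  prof_b <- profile_sample(aln_b)
  call_sample <- function(profs) {
    do.call(rbind, lapply(catalog$id, function(s) {
      p <- profs[[s]]
      p$snorna_id <- s
      call_sdrna(p, catalog[catalog$id == s, , drop = FALSE],
                 fixed_threshold = config$fixed_threshold,
                 min_hits = config$min_hits)
    }))
  }
  calls_a <- call_sample(prof_a)
  calls_b <- call_sample(prof_b)

  cpm_a <- compute_cpm(aln_a$hits$hits, denom(lib_a))
  cpm_b <- compute_cpm(aln_b$hits$hits, denom(lib_b))
  expression <- data.frame(
    feature_id = catalog$id,
    raw_count_a = aln_a$hits$hits, cpm_a = cpm_a,
    expressed_a = flag_expressed(cpm_a, config$expression_threshold),
    raw_count_b = aln_b$hits$hits, cpm_b = cpm_b,
    expressed_b = flag_expressed(cpm_b, config$expression_threshold),
    stringsAsFactors = FALSE)

  differential <- differential_table(
    data.frame(feature_id = catalog$id, cpm = cpm_a),
    data.frame(feature_id = catalog$id, cpm = cpm_b),
    pseudocount = config$pseudocount,
    expression_threshold = config$expression_threshold,
    overexpression_fold = config$overexpression_fold,
    tiers = config$tiers)

  # Processing preference: the sdRNA interval of a snoRNA is taken from the
  # deeper sample's call so both samples are counted over the same family.
  processing <- do.call(rbind, lapply(catalog$id, function(s) {
    ca <- calls_a[calls_a$snorna_id == s, ]
    cb <- calls_b[calls_b$snorna_id == s, ]
    if (!(ca$is_fixed_position || cb$is_fixed_position)) return(NULL)
    ref_call <- if (!cb$is_fixed_position ||
                    (ca$is_fixed_position && ca$total_hits >= cb$total_hits)) ca else cb
    interval <- c(ref_call$start, ref_call$end)
    sd_hits_a <- .family_count(aln_a$alignments[aln_a$alignments$snorna_id == s, ],
                               interval, config$delta5, config$delta3)
    sd_hits_b <- .family_count(aln_b$alignments[aln_b$alignments$snorna_id == s, ],
                               interval, config$delta5, config$delta3)
    processing_preference(
      s,
      sdrna_cpm_a = compute_cpm(sd_hits_a, denom(lib_a)),
      snorna_cpm_a = cpm_a[catalog$id == s],
      sdrna_cpm_b = compute_cpm(sd_hits_b, denom(lib_b)),
      snorna_cpm_b = cpm_b[catalog$id == s],
      pseudocount = config$pseudocount,
      cutoff = config$preference_cutoff)
  }))
  if (is.null(processing)) {
    processing <- data.frame(snorna_id = character(0),
                             processing_ratio_a = numeric(0),
                             processing_ratio_b = numeric(0),
                             preference_factor = numeric(0),
                             preferential = logical(0))
  }

  result <- list(hits_a = aln_a$hits, hits_b = aln_b$hits,
                 alignments_a = aln_a$alignments, alignments_b = aln_b$alignments,
                 calls_a = calls_a, calls_b = calls_b,
                 expression = expression, differential = differential,
                 processing = processing, config = config)

  if (!is.null(out_dir)) {
    if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
    wt <- function(x, f) utils::write.table(
      x, file.path(out_dir, f), sep = "\t", quote = FALSE, row.names = FALSE)
    write_alignments(aln_a$alignments, file.path(out_dir, "alignments_a.tsv"))
    write_alignments(aln_b$alignments, file.path(out_dir, "alignments_b.tsv"))
    write_profiles(prof_a, file.path(out_dir, "profiles_a.tsv"))
    write_profiles(prof_b, file.path(out_dir, "profiles_b.tsv"))
    wt(calls_a, "calls_a.tsv")
    wt(calls_b, "calls_b.tsv")
    wt(expression, "expression.tsv")
    wt(differential, "differential.tsv")
    wt(processing, "processing.tsv")
    write_run_config(config, file.path(out_dir, "run_config.yaml"))
  }
  invisible(result)
}

#' Cohort prevalence survey for a query sdRNA
#'
#' Quantifies one query sequence across every manifest sample and reduces
#' the results to per-subtype expression prevalence. Manifest rows may
#' point at read files (`path` column) or carry pre-counted
#' `total_reads` + `query_hits` columns; rows with `exclude == TRUE` are
#' dropped, and rows whose read file is missing are skipped with a
#' warning and listed in the result.
#'
#' @param manifest manifest TSV path or data.frame (see [read_manifest()]).
#' @param query query sequence string, or a FASTA path whose first record
#'   is used. Not needed for fully pre-counted manifests.
#' @param config a [run_config()]; the survey mode's unbounded match
#'   window is used regardless of `config$mode`.
#' @param out_dir optional report directory (samples.tsv, prevalence.tsv,
#'   prevalence.json, run_config.yaml).
#' @return (invisibly) list with `samples`, `prevalence`, `skipped`,
#'   `config`.
#' @export
run_cohort <- function(manifest, query = NULL,
                       config = run_config(mode = "sra_survey"),
                       out_dir = NULL) {
  if (is.character(manifest)) manifest <- read_manifest(manifest)
  if ("exclude" %in% names(manifest)) {
    manifest <- manifest[!(manifest$exclude %in% TRUE), , drop = FALSE]
  }
  if (!is.null(query) && nchar(query) < 500 &&
      isTRUE(tryCatch(file.exists(query), condition = function(c) FALSE))) {
    qcat <- read_fasta(query)
    query <- qcat$sequence[1]
  }
  policy <- match_policy(16L, Inf, strands = config$strands,
                         multi_reference = config$multi_reference)
  has_counts <- all(c("total_reads", "query_hits") %in% names(manifest))

  rows <- list()
  skipped <- character(0)
  for (i in seq_len(nrow(manifest))) {
    row <- manifest[i, ]
    if (has_counts && !is.na(row$query_hits)) {
      cpm <- compute_cpm(row$query_hits, row$total_reads)
      rows[[length(rows) + 1L]] <- data.frame(
        sample_id = row$sample_id, subtype_label = row$subtype_label,
        total_reads = row$total_reads, query_hits = row$query_hits,
        query_cpm = cpm,
        expressed = flag_expressed(cpm, config$expression_threshold),
        stringsAsFactors = FALSE)
    } else {
      if (is.null(query)) {
        stop("manifest row ", row$sample_id,
             " has no counts and no query sequence was given", call. = FALSE)
      }
      if (is.null(row$path) || !file.exists(row$path)) {
        warning("sample file missing, skipped: ", row$sample_id, call. = FALSE)
        skipped <- c(skipped, row$sample_id)
        next
      }
      lib <- read_reads(row$path, config$min_read_len, config$max_read_len,
                        sample_id = row$sample_id,
                        subtype_label = row$subtype_label)
      rows[[length(rows) + 1L]] <- quantify_query_in_sample(
        query, lib, policy,
        expression_threshold = config$expression_threshold,
        cpm_denominator = config$cpm_denominator)
    }
  }
  if (!length(rows)) stop("no usable samples in manifest", call. = FALSE)
  samples <- do.call(rbind, rows)
  rownames(samples) <- NULL
  prevalence <- subtype_prevalence(samples)

  if (!is.null(out_dir)) {
    if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
    utils::write.table(samples, file.path(out_dir, "samples.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    utils::write.table(prevalence, file.path(out_dir, "prevalence.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    jsonlite::write_json(prevalence, file.path(out_dir, "prevalence.json"),
                         dataframe = "rows", digits = NA)
    write_run_config(config, file.path(out_dir, "run_config.yaml"))
  }
  invisible(list(samples = samples, prevalence = prevalence,
                 skipped = skipped, config = config))
}
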