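# Synthetic snoRNA catalogs, small RNA-seq libraries, and labeled cohorts
# with known ground truth. The generator emulates the statistical structure
# of processed-snoRNA small RNA-seq data: a dominant fixed-boundary
# fragment per snoRNA with exact 5' ends and small 3' jitter, a uniform
# degradation background, and optional off-target reads that share no
# 16-mer with the catalog so truth tables stay exact.

#' Simulation configuration
#'
#' Bundles every knob of the generator. A config plus its seed fully
#' determines all output.
#'
#' @param seed integer RNG seed.
#' @param n_snornas number of snoRNAs in the catalog.
#' @param snorna_length_range inclusive nt range for snoRNA lengths.
#' @param sdrna_length_range inclusive nt range for planted sdRNA lengths
#'   (default 21-29 nt, the observed biological range).
#' @param fidelity excision fidelity f: the expected fraction of each
#'   snoRNA's signal reads emitted exactly at the planted interval.
#' @param jitter3_max non-fixed signal reads get a 3' end shift drawn
#'   uniformly from {-jitter3_max..-1, 1..jitter3_max}; 5' ends are exact.
#' @param background_rate fraction of the library drawn as uniform random
#'   fragments of random snoRNAs (degradation background).
#' @param offtarget_rate fraction of the library drawn as random
#'   non-catalog sequence (rejection-sampled to share no 16-mer with the
#'   catalog).
#' @param library_size number of reads per simulated library.
#' @param target_cpm optional named numeric vector of per-snoRNA signal
#'   CPM targets (names matching catalog ids). When `NULL`, the signal
#'   mass `1e6 * (1 - background_rate - offtarget_rate)` is split equally.
#'   Per-feature read counts are set deterministically
#'   (`round(cpm * library_size / 1e6)`), so planted CPM is recovered up
#'   to rounding.
#' @param anchor5_prob probability that a planted sdRNA starts at the
#'   snoRNA 5' end (position 0) rather than at an internal position.
#' @return a `sim_config` list.
#' @export
sim_config <- function(seed = 1L, n_snornas = 10L,
                       snorna_length_range = c(60L, 300L),
                       sdrna_length_range = c(21L, 29L),
                       fidelity = 0.95, jitter3_max = 3L,
                       background_rate = 0.05, offtarget_rate = 0,
                       library_size = 20000L, target_cpm = NULL,
                       anchor5_prob = 0.5) {
  stopifnot(fidelity >= 0, fidelity <= 1,
            background_rate >= 0, offtarget_rate >= 0,
            background_rate + offtarget_rate <= 1,
            anchor5_prob >= 0, anchor5_prob <= 1,
            snorna_length_range[1] >= sdrna_length_range[2] + jitter3_max,
            library_size >= 0)
  structure(list(seed = as.integer(seed), n_snornas = as.integer(n_snornas),
                 snorna_length_range = as.integer(snorna_length_range),
                 sdrna_length_range = as.integer(sdrna_length_range),
                 fidelity = fidelity, jitter3_max = as.integer(jitter3_max),
                 background_rate = background_rate,
                 offtarget_rate = offtarget_rate,
                 library_size = as.integer(library_size),
                 target_cpm = target_cpm,
                 anchor5_prob = anchor5_prob),
            class = "sim_config")
}

.random_seq <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# Uniform integer draw on [lo, hi]; safe for degenerate ranges, unlike
# sample(seq(lo, hi)) which expands to 1:lo when lo == hi.
.sample_range <- function(lo, hi, n = 1L) {
  lo + sample.int(hi - lo + 1L, n, replace = TRUE) - 1L
}

#' Simulate a snoRNA catalog with planted sdRNA intervals
#'
#' Sequences are i.i.d. uniform over {A,C,G,T}. Each snoRNA gets one
#' planted sdRNA interval, 5'-anchored with probability `anchor5_prob` and
#' placed so that 3' jitter cannot run off the end of the precursor.
#'
#' @param config a [sim_config()].
#' @return list with `catalog` (a [sno_catalog()]) and `truth`
#'   (data.frame `snorna_id`, `length`, `sdrna_start`, `sdrna_end`,
#'   `sdrna_length`; coordinates 0-based half-open).
#' @export
simulate_catalog <- function(config = sim_config()) {
  set.seed(config$seed)
  n <- config$n_snornas
  lens <- .sample_range(config$snorna_length_range[1],
                        config$snorna_length_range[2], n)
  ids <- sprintf("sno%03d", seq_len(n))
  seqs <- vapply(lens, .random_seq, character(1))
  sd_len <- .sample_range(config$sdrna_length_range[1],
                          config$sdrna_length_range[2], n)
  max_start <- lens - sd_len - config$jitter3_max
  anchored <- stats::runif(n) < config$anchor5_prob
  start <- ifelse(anchored, 0L,
                  vapply(max_start,
                         function(m) if (m < 1L) 0L else sample.int(m, 1L),
                         integer(1)))
  truth <- data.frame(snorna_id = ids, length = lens,
                      sdrna_start = as.integer(start),
                      sdrna_end = as.integer(start + sd_len),
                      sdrna_length = sd_len, stringsAsFactors = FALSE)
  list(catalog = sno_catalog(ids, seqs), truth = truth)
}

# Hash set of all k-mers present in the catalog, for fast rejection checks
.catalog_kmer_set <- function(catalog, k = 16L) {
  env <- new.env(hash = TRUE, parent = emptyenv())
  for (s in catalog$sequence) {
    n <- nchar(s)
    if (n < k) next
    for (km in substring(s, seq_len(n - k + 1L), k:n)) {
      assign(km, TRUE, envir = env)
    }
  }
  env
}

# TRUE if any k-mer of `seq` is in the catalog k-mer set
.shares_kmer <- function(seq, kmer_set, k = 16L) {
  n <- nchar(seq)
  if (n < k) return(FALSE)
  kms <- substring(seq, seq_len(n - k + 1L), k:n)
  any(vapply(kms, exists, logical(1), envir = kmer_set, inherits = FALSE))
}

#' Simulate a small RNA-seq library from a catalog
#'
#' Emits a mixture of (i) exact planted-interval sdRNA reads (a binomial
#' `fidelity` fraction of each snoRNA's signal), (ii) 3'-jittered sdRNA
#' reads, (iii) uniform degradation background, and (iv) off-target reads.
#' Per-snoRNA signal read counts are deterministic given `target_cpm`
#' (see [sim_config()]); read lengths all fall in 17-35 nt.
#'
#' @param catalog,truth output of [simulate_catalog()].
#' @param config a [sim_config()].
#' @param fastq_path optional path; when given the library is also written
#'   as FASTQ (constant qualities).
#' @param sample_id library identifier.
#' @return list with `library` (a `sample_library`), `read_truth`
#'   (data.frame `read_id`, `origin` in
#'   {fixed, jitter, background, offtarget}, `snorna_id`, `start`, `end`),
#'   and `target_cpm` (the per-snoRNA signal CPM actually targeted).
#' @export
simulate_library <- function(catalog, truth, config = sim_config(),
                             fastq_path = NULL, sample_id = "sim_sample") {
  set.seed(config$seed + 1L)
  n <- config$library_size
  if (n == 0L) {
    warning("library_size is 0; returning an empty library", call. = FALSE)
    lib <- sample_library(sample_id, character(0), character(0))
    return(list(library = lib,
                read_truth = data.frame(read_id = character(0),
                                        origin = character(0),
                                        snorna_id = character(0),
                                        start = integer(0), end = integer(0),
                                        stringsAsFactors = FALSE),
                target_cpm = NULL))
  }
  signal_mass <- 1 - config$background_rate - config$offtarget_rate
  cpm <- config$target_cpm
  if (is.null(cpm)) {
    cpm <- stats::setNames(rep(signal_mass * 1e6 / nrow(catalog),
                               nrow(catalog)), catalog$id)
  }
  if (is.null(names(cpm)) || !all(names(cpm) %in% catalog$id)) {
    stop("target_cpm must be named by catalog ids", call. = FALSE)
  }
  n_per <- round(cpm * n / 1e6)
  n_signal <- sum(n_per)
  n_bg <- round(config$background_rate * n)
  n_ot <- max(0L, n - n_signal - n_bg)
  if (n_signal + n_bg > n) {
    stop("target_cpm plus background exceeds the library size", call. = FALSE)
  }

  parts <- list()
  add_part <- function(seqs, origin, sno, st, en) {
    parts[[length(parts) + 1L]] <<- data.frame(
      sequence = seqs, origin = origin, snorna_id = sno,
      start = st, end = en, stringsAsFactors = FALSE)
  }
  jit_choices <- c(-seq_len(config$jitter3_max), seq_len(config$jitter3_max))

  for (s in names(cpm)) {
    ns <- n_per[[s]]
    if (ns == 0L) next
    tr <- truth[truth$snorna_id == s, ]
    ref <- catalog$sequence[catalog$id == s]
    n_fix <- stats::rbinom(1L, ns, config$fidelity)
    ends <- rep(tr$sdrna_end, ns)
    if (ns - n_fix > 0L) {
      shift <- sample(jit_choices, ns - n_fix, replace = TRUE)
      ends[seq(n_fix + 1L, ns)] <- tr$sdrna_end + shift
    }
    add_part(substr(rep(ref, ns), tr$sdrna_start + 1L, ends),
             rep(c("fixed", "jitter"), c(n_fix, ns - n_fix)),
             rep(s, ns), rep(tr$sdrna_start, ns), ends)
  }

  if (n_bg > 0L) {
    idx <- sample.int(nrow(catalog), n_bg, replace = TRUE)
    len <- vapply(catalog$length[idx],
                  function(L) .sample_range(17L, min(35L, L)), integer(1))
    st <- vapply(catalog$length[idx] - len,
                 function(m) sample.int(m + 1L, 1L) - 1L, integer(1))
    add_part(substr(catalog$sequence[idx], st + 1L, st + len),
             rep("background", n_bg), catalog$id[idx], st, st + len)
  }

  if (n_ot > 0L) {
    kmer_set <- .catalog_kmer_set(catalog, 16L)
    # batch-generate candidates, then regenerate the (vanishingly rare)
    # ones sharing a catalog 16-mer
    gen_batch <- function(k) {
      lens <- .sample_range(17L, 35L, k)
      chars <- sample(c("A", "C", "G", "T"), sum(lens), replace = TRUE)
      vapply(split(chars, rep.int(seq_along(lens), lens)), paste,
             character(1), collapse = "")
    }
    cand <- gen_batch(n_ot)
    repeat {
      bad <- vapply(cand, .shares_kmer, logical(1), kmer_set = kmer_set,
                    k = 16L, USE.NAMES = FALSE)
      if (!any(bad)) break
      cand[bad] <- gen_batch(sum(bad))
    }
    add_part(unname(cand), rep("offtarget", n_ot),
             rep(NA_character_, n_ot), rep(NA_integer_, n_ot),
             rep(NA_integer_, n_ot))
  }

  all_parts <- do.call(rbind, parts)
  seqs <- all_parts$sequence
  origin <- all_parts$origin
  sno_of <- all_parts$snorna_id
  st_of <- all_parts$start
  en_of <- all_parts$end

  ids <- sprintf("read%06d", seq_along(seqs))
  lib <- sample_library(sample_id, ids, seqs)
  read_truth <- data.frame(read_id = ids, origin = origin,
                           snorna_id = sno_of, start = st_of, end = en_of,
                           stringsAsFactors = FALSE)
  if (!is.null(fastq_path)) write_fastq(lib, fastq_path)
  list(library = lib, read_truth = read_truth, target_cpm = cpm)
}

#' Simulate a subtype-labeled cohort with planted prevalence
#'
#' Produces a pre-counted cohort manifest in which, per subtype, exactly
#' `n_expressed` of `n_total` samples carry the query above the expression
#' threshold. Expression status is assigned deterministically (the first
#' `n_expressed` samples of each subtype); expressed samples get a CPM
#' drawn well above the threshold (10-50x), unexpressed samples well below
#' (0.001-0.1x), so realized prevalence equals the design exactly.
#'
#' @param design data.frame with `subtype_label`, `n_total`, `n_expressed`.
#' @param seed RNG seed.
#' @param total_reads library size recorded for every sample.
#' @param expression_threshold CPM threshold the design is planted around.
#' @param dir optional directory; when given, `manifest.tsv` is written
#'   there.
#' @return list with `manifest` (data.frame `sample_id`, `subtype_label`,
#'   `total_reads`, `query_hits`, `expressed_truth`) and
#'   `truth_prevalence` (the design with its implied percentage).
#' @export
simulate_cohort <- function(design, seed = 1L, total_reads = 1e6,
                            expression_threshold = 250, dir = NULL) {
  stopifnot(all(c("subtype_label", "n_total", "n_expressed") %in% names(design)),
            all(design$n_expressed <= design$n_total),
            nrow(design) > 0)
  set.seed(seed)
  rows <- list()
  for (i in seq_len(nrow(design))) {
    n <- design$n_total[i]
    k <- design$n_expressed[i]
    expressed <- seq_len(n) <= k
    cpm <- ifelse(expressed,
                  expression_threshold * stats::runif(n, 10, 50),
                  expression_threshold * stats::runif(n, 0.001, 0.1))
    hits <- round(cpm * total_reads / 1e6)
    rows[[i]] <- data.frame(
      sample_id = sprintf("%s_s%03d", gsub("[^A-Za-z0-9]+", "", design$subtype_label[i]),
                          seq_len(n)),
      subtype_label = design$subtype_label[i],
      total_reads = total_reads, query_hits = as.integer(hits),
      expressed_truth = expressed, stringsAsFactors = FALSE)
  }
  manifest <- do.call(rbind, rows)
  rownames(manifest) <- NULL
  truth <- design
  truth$percentage <- round_half_up(100 * design$n_expressed / design$n_total, 1L)
  if (!is.null(dir)) {
    if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
    utils::write.table(manifest, file.path(dir, "manifest.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }
  list(manifest = manifest, truth_prevalence = truth)
}
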