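# snofrag

Detection, quantification, and cohort-prevalence analysis of
**snoRNA-derived RNAs (sdRNAs)** from adapter-trimmed small RNA-seq
libraries.

Many small nucleolar RNAs (snoRNAs) are processed into short (~16–29 nt)
miRNA-like fragments. Given a snoRNA reference catalog (FASTA) and small
RNA-seq read files (FASTA/FASTQ, 17–35 nt), `snofrag`:

* places reads on the catalog by **perfect-match alignment** — an accepted
  alignment is a full read matching at 100% identity, 16–28 nt in the
  two-sample screen (`policy_cellline()`) or ≥ 16 nt unbounded in the
  survey mode (`policy_sra_survey()`);
* builds per-snoRNA **excision profiles** and calls an sdRNA when more
  than 90% of a snoRNA's reads share the modal fragment boundaries
  (exact 5′ end, ≤ 3 nt of 3′ heterogeneity) at ≥ 10 reads of depth —
  the signature separating fixed-position processing from degradation;
* quantifies expression in **counts per million**
  (`CPM = hits / total_reads × 1e6`), flags features expressed at
  ≥ 250 CPM, classifies two-sample overexpression at pseudocount-stabilized
  fold ≥ 5 with tiers at ≥ 5× / ≥ 7.5× / ≥ 75×, and computes sdRNA
  **processing preference** (cross-sample ratio of within-sample
  sdRNA:snoRNA ratios, cutoff ≥ 5.5);
* reduces a labeled cohort to **per-subtype prevalence**:
  `100 × n_expressed / n_total`, rounded half-up to one decimal;
* screens snoRNA vs miRNA-hairpin catalogs for **sequence relatedness**
  (Smith–Waterman local alignment, acceptance at ≥ 85% identity over
  ≥ 40 columns) and renders tripartite genome/snoRNA/read alignments;
* ships a **synthetic-data generator** (catalogs, libraries, cohorts with
  exact ground truth) so the whole pipeline is testable without any
  external download.

It is aimed at computational RNA biologists who want a small, auditable,
fully deterministic implementation of this screen rather than a
general-purpose read mapper.

## Worked example

```r
library(snofrag)

# A synthetic catalog of 5 snoRNAs, each with a planted sdRNA, and two
# libraries that differ 15-fold in signal for the first feature.
cfg <- sim_config(seed = 1, n_snornas = 5, library_size = 20000,
                  sdrna_length_range = c(21, 25), background_rate = 0)
sim <- simulate_catalog(cfg)
cfg_a <- cfg; cfg_a$target_cpm <- c(sno001 = 45000, sno002 = 3000,
                                    sno003 = 3000, sno004 = 3000, sno005 = 3000)
cfg_b <- cfg; cfg_b$seed <- 2; cfg_b$target_cpm <-
  setNames(rep(3000, 5), sim$catalog$id)
lib_a <- simulate_library(sim$catalog, sim$truth, cfg_a, sample_id = "a")$library
lib_b <- simulate_library(sim$catalog, sim$truth, cfg_b, sample_id = "b")$library

res <- run_compare(lib_a, lib_b, sim$catalog)
subset(res$differential, overexpressed)
#>   feature_id cpm_a cpm_b fold_change overexpressed   tier
#> 1     sno001 45000  3000    14.99953          TRUE >=7.5x
```

`sno001` is recovered at its planted ~15× fold, in the ≥ 7.5× tier; the
flat features sit at fold ≈ 1. `res$calls_a` lists the per-snoRNA sdRNA
calls (modal interval, fixed fraction, depth), and `res$processing` the
processing-preference factors.

Cohort prevalence from a pre-counted manifest:

```r
design <- data.frame(subtype_label = c("TNBC", "LuminalA", "LuminalB_HER2pos", "normal"),
                     n_total = c(29, 62, 14, 11), n_expressed = c(12, 24, 13, 0))
cohort <- simulate_cohort(design, seed = 1)
run_cohort(cohort$manifest)$prevalence
#>      subtype_label n_expressed n_total percentage
#> 1             TNBC          12      29       41.4
#> 2         LuminalA          24      62       38.7
#> 3 LuminalB_HER2pos          13      14       92.9
#> 4           normal           0      11        0.0
```

A thin CLI over the same functions lives at `inst/scripts/snofrag.R`
(subcommands `compare`, `cohort`, `simulate`, `relate`).

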