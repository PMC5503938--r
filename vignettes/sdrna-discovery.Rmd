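---
title: "Detecting and quantifying snoRNA-derived RNAs with snofrag"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting and quantifying snoRNA-derived RNAs with snofrag}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(snofrag)
```

## The problem

Small nucleolar RNAs (snoRNAs) are 60–300 nt guides for rRNA/snRNA
modification, but many are additionally processed into short (~16–29 nt)
miRNA-like fragments called snoRNA-derived RNAs (sdRNAs). Deciding whether
the short reads that stack on a snoRNA in a small RNA-seq library represent
such a *specifically excised* fragment — rather than random degradation of
the precursor — and then comparing sdRNA abundance across samples and
patient cohorts, is the job of this package.

The pipeline is deliberately simple and fully threshold-based, mirroring
the way such screens are run in practice:

1. **Perfect-match alignment.** Reads are placed on a snoRNA catalog only
   where the *entire* read matches at 100% identity. Two policy presets
   exist: `policy_cellline()` accepts matches of 16–28 nt (the two-sample
   screen) and `policy_sra_survey()` accepts ≥ 16 nt with no upper bound
   (the cohort survey). Because only full-read matches are accepted, the
   length window is a property of the read itself; reads containing `N`
   can never match.
2. **Excision profiling.** For each snoRNA, the (start, end) intervals of
   its aligned reads are tallied. The modal interval and the *fixed
   fraction* — the share of reads whose 5′ end matches the modal start
   within `delta5` and whose 3′ end matches the modal end within `delta3`
   — separate fixed-position processing from degradation. A snoRNA is
   called as producing an sdRNA when the fixed fraction strictly exceeds
   `fixed_threshold` (default 0.90) at a depth of at least `min_hits`
   reads.
3. **Quantification.** Expression is counts per million:
   `CPM = hits / total_reads × 1e6`, with `total_reads` the *pre-filter*
   library size by default. A feature is *expressed* at ≥ 250 CPM,
   *overexpressed* between two samples at a pseudocount-stabilized fold
   change ≥ 5 with expression in at least one sample, with tier labels at
   ≥ 5×, ≥ 7.5× and ≥ 75×; an sdRNA is *preferentially processed* when the
   cross-sample ratio of within-sample sdRNA:snoRNA ratios is ≥ 5.5.
4. **Cohort prevalence.** One query sdRNA is quantified across a labeled
   cohort; per subtype the package reports
   `100 × n_expressed / n_total`, rounded half-up to one decimal.

A local-alignment module (`local_align()`, `screen_catalog_pairs()`)
supports the companion question of sequence relatedness between snoRNA and
miRNA-hairpin catalogs, with acceptance thresholds of ≥ 85% identity over
≥ 40 alignment columns, and `render_tripartite()` draws the
genome/snoRNA/read stacking used to confirm an sdRNA's origin.

## Parameters that matter

| Parameter | Default | Meaning |
|---|---|---|
| match window (cell line) | 16–28 nt | accepted full-read match lengths in the two-sample screen |
| match window (survey) | ≥ 16 nt | accepted lengths in the cohort survey |
| `expression_threshold` | 250 CPM | inclusive floor for the expressed flag |
| `overexpression_fold` | 5 | inclusive fold floor, with tiers at 5 / 7.5 / 75 |
| `preference_cutoff` | 5.5 | inclusive floor for preferential processing |
| `fixed_threshold` | 0.90 | *strict* lower bound on the fixed fraction |
| `min_hits` | 10 | depth floor for an sdRNA call |
| `delta5`, `delta3` | 0, 3 nt | boundary tolerances for the modal family |
| `pseudocount` | 0.1 CPM | ratio stabilizer for near-zero denominators |
| `cpm_denominator` | `"raw"` | library total before (`raw`) or after (`filtered`) the 17–35 nt read filter |

Notes on the less obvious choices:

* **`delta5 = 0, delta3 = 3`.** sdRNA processing observed in this class of
  data has exact 5′ ends with 3′-length heterogeneity (fragments of
  21–29 nt from one precursor). The asymmetric tolerance encodes that;
  `delta5 = delta3 = 0` recovers strict exact-interval grouping, which is
  also what the parameter-recovery tests use so that the measured fixed
  fraction estimates the generator's fidelity parameter directly.
* **`min_hits = 10`.** A fixed fraction computed from a handful of reads
  is uninformative; the floor prevents sdRNA calls backed by 1–2 reads.
  It is this package's own guardrail, surfaced in every report.
* **`pseudocount = 0.1` CPM.** Fold changes against a feature absent in
  one sample are otherwise undefined; with the pseudocount a feature at
  300 CPM vs 0 CPM reports a fold of 3001 (tier ≥ 75×) instead of
  infinity. Raw CPMs are always reported alongside folds so the
  stabilization is auditable. Reciprocal folds multiply to exactly 1.
* **`cpm_denominator = "raw"`.** The natural denominator is the total
  number of reads in the library file. Whether that total should be taken
  before or after length filtering is genuinely ambiguous in practice, so
  both are carried in every `sample_library` and the switch is in
  `run_config()`.
* **Rounding.** Prevalence percentages are rounded half *up* to one
  decimal (13/14 → 92.9), not half-to-even as base `round()` would.
* **Inclusive thresholds.** Every `≥` cutoff (250 CPM, 5×, 5.5×, tiers) is
  inclusive; only `fixed_threshold` is strict (a fraction of exactly 0.90
  is *not* called fixed-position).
* **No statistics.** The screen is threshold-based by construction. No
  p-values, no multiple-testing correction; the package does not pretend
  otherwise, and the differential table should not be read as a test.

## The alignment engines

The perfect-match core is an overlap-aware exact-substring scan (every
placement of the full read, including overlapping ones, on every catalog
sequence). The unit and acceptance suites hold it equal to a brute-force
offset-by-offset oracle over random catalogs on both strands. Antisense
(`strands = "both"`) matching is off by default: small RNA-seq protocols
are stranded and sdRNAs are sense fragments of their precursors.
Multi-placement reads contribute one alignment per placement under the
default `multi_reference = "all"`; `"best"` keeps only the first placement
in deterministic (snoRNA id, start) order.

Local alignment for the relatedness screen is Smith–Waterman with affine
gaps, delegated to `Biostrings::pairwiseAlignment()` with scoring defaults
match +2, mismatch −3, gap open −5, gap extend −2 (a gap of length L costs
`open + L × extend`). These defaults qualitatively mimic short-query
nucleotide BLAST; the screen's published analogue states only acceptance
thresholds, not a scoring scheme, so the scheme is configurable. Percent
identity is computed over *all* alignment columns including gap columns
(the BLAST convention). `N` is scored as a mismatch against everything,
including itself. Among equal-scoring optimal alignments the engine's own
deterministic traceback preference decides which alignment is reported;
score, identity and aligned length — the quantities the screen thresholds
— are tie-independent, and the test suite checks the score against an
independent Gotoh dynamic program on short sequences. Only the single best
local alignment per pair is reported; secondary HSPs are out of scope.

## What the generator emulates — and what it does not

`simulate_catalog()` / `simulate_library()` / `simulate_cohort()` produce
data whose ground truth is known exactly:

* snoRNA sequences are i.i.d. uniform over {A,C,G,T}; each carries one
  planted sdRNA interval of 21–29 nt, anchored at the 5′ end with
  probability 0.5 (mirroring the 5′-derived fragment that motivates the
  pipeline) and otherwise internal.
* a library is a mixture of exact planted-interval reads (a binomial
  `fidelity` fraction of each snoRNA's signal), 3′-jittered reads (end
  shifted uniformly on {−3…−1, 1…3}; zero is excluded so that a
  "jittered" read genuinely leaves the planted interval and the measured
  fixed fraction under strict grouping estimates `fidelity` itself),
  uniform random snoRNA fragments of 17–35 nt (degradation background),
  and off-target reads rejection-sampled to share no 16-mer with the
  catalog, so they can never produce a ≥ 16 nt perfect match.
* per-snoRNA signal read counts are deterministic
  (`round(cpm × n / 1e6)`), not multinomial, so planted CPMs and fold
  tiers are recovered exactly up to rounding; only the fixed/jitter split
  and the background placements are stochastic.
* cohorts are planted as pre-counted manifests in which exactly
  `n_expressed` of `n_total` samples per subtype carry the query at
  10–50× the expression threshold and the rest at ≤ 0.1×, so realized
  prevalence equals the design exactly.

The generator does **not** model sequencing error (a perfect-match
pipeline discards erroneous reads wholesale, so error mainly deflates
counts), GC or ligation bias, adapter read-through, multi-snoRNA gene
families with shared subsequences, or realistic transcriptome background.
Passing recovery tests on this generator therefore demonstrates that the
pipeline's bookkeeping is correct under its own assumptions — not that
those assumptions hold in any particular real library.

## Numerical and degenerate-input conventions

* Coordinates are 0-based half-open everywhere internally; TSV writers
  for BLAST-style output convert to 1-based inclusive.
* Modal-interval ties break toward the 5′-most, then shortest fragment.
* An empty alignment set yields a profile with `total_hits = 0` and an
  `NA` fixed fraction; calling on it returns a no-call row with reason
  `"no hits"`. Calls below the depth floor carry
  `"insufficient depth"`; heterogeneous profiles carry
  `"boundary heterogeneity"`.
* U is silently mapped to T on every ingest path, so RNA-exported
  catalogs and DNA-space reads interoperate; any character outside
  {A,C,G,T,N,U} is an error, not a warning.
* `total_reads` of an empty library is 0 and any CPM computation against
  it is an error.
* All simulators are fully seed-determined; identical configs give
  byte-identical FASTQ and truth tables, and the pipeline's report
  writers are deterministic, so whole-run reruns are byte-identical.

## Problem sizes used by the test and acceptance suites

The suites are sized for a desk-scale machine: excision-fidelity recovery
uses single-snoRNA libraries of 2,000 reads (binomial SE of the fixed
fraction ≈ 0.005 at f = 0.95, comfortably inside the ±0.03 assertion);
CPM/fold recovery uses 20,000–50,000-read libraries where planted counts
are deterministic; oracle-equivalence suites run 200 random cases each;
cohort analyses use the 116-sample design the prevalence worked examples
require. These sizes are the package's validation choices, small enough
to run anywhere yet large enough that every tolerance asserted is
dominated by sampling theory rather than luck.

## Known limitations

* Perfect-match counting under-counts in the presence of sequencing
  error, and the package makes no attempt to correct for it.
* Only the modal fragment family per snoRNA is called; a snoRNA producing
  both a 5′ and a 3′ sdRNA yields one call (the deeper family), and the
  runner-up cluster is visible only in the interval table.
* CPM is the only normalization offered — no TMM/median-of-ratios size
  factors — because cross-sample claims in this design are threshold
  screens, not differential-expression inference.
* The relatedness module reports one best local alignment per pair: no
  E-values, no multi-HSP chaining, no genome-scale search.
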