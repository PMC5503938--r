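test_that("the mimic sequence places on the sense strand of the inhibitor's revcomp", {
  catalog <- sno_catalog("sdRNA93_region",
                         reverse_complement("AAATCAGATTAGAGTTCTCATCCTTGGCT"))
  hits <- find_perfect_matches("GCCAAGGATGAGAACTCTAATCTGATTT", catalog,
                               match_policy(16, 28))
  expect_equal(nrow(hits), 1L)
  expect_equal(hits$start, 1L)
  expect_equal(hits$end, 29L)
  expect_equal(hits$match_length, 28L)
  expect_equal(hits$strand, "+")
})

test_that("policy length windows gate matches at both ends", {
  ref <- random_dna(80)
  catalog <- sno_catalog("ref", ref)
  r15 <- substr(ref, 11, 25)   # 15 nt, below the 16 nt floor
  expect_equal(nrow(find_perfect_matches(r15, catalog, match_policy(16, 28))), 0L)
  r30 <- substr(ref, 11, 40)   # 30 nt: rejected at <=28, accepted unbounded
  expect_equal(nrow(find_perfect_matches(r30, catalog, policy_cellline())), 0L)
  survey <- find_perfect_matches(r30, catalog, policy_sra_survey())
  expect_equal(nrow(survey), 1L)
  expect_equal(survey$start, 10L)
  # reads containing N can never be a 100% identity match
  rN <- paste0(substr(ref, 11, 29), "N")
  expect_equal(nrow(find_perfect_matches(rN, catalog, policy_sra_survey())), 0L)
})

test_that("matcher output equals a brute-force offset scan on random cases", {
  set.seed(101)
  for (case in 1:40) {
    catalog <- random_catalog(n_seq = sample(2:6, 1), max_len = 300)
    # half the reads sampled from a reference, half random
    if (case %% 2 == 0) {
      i <- sample(nrow(catalog), 1)
      len <- sample(16:30, 1)
      st <- sample(catalog$length[i] - len + 1, 1)
      read <- substr(catalog$sequence[i], st, st + len - 1)
    } else {
      read <- random_dna(sample(16:30, 1))
    }
    for (strands in c("sense", "both")) {
      got <- find_perfect_matches(read, catalog,
                                  match_policy(16, 28, strands = strands))
      want <- oracle_matches(read, catalog, 16, 28, strands)
      want <- want[order(want$snorna_id, want$start, want$strand), ]
      expect_equal(got$snorna_id, want$snorna_id)
      expect_equal(got$start, want$start)
      expect_equal(got$end, want$end)
      expect_equal(got$strand, want$strand)
    }
  }
})

test_that("tightening the policy window never adds alignments", {
  set.seed(55)
  catalog <- random_catalog(4, 200)
  reads <- c(vapply(sample(16:32, 10, replace = TRUE), random_dna, character(1)),
             substr(catalog$sequence[1], 5, 30),
             substr(catalog$sequence[2], 1, 20))
  for (read in reads) {
    wide <- nrow(find_perfect_matches(read, catalog, match_policy(16, Inf)))
    narrow <- nrow(find_perfect_matches(read, catalog, match_policy(18, 26)))
    expect_lte(narrow, wide)
  }
})

test_that("multi-placement reads contribute k alignments under 'all' and 1 under 'best'", {
  ref <- strrep("ACGT", 10)                 # 16-mer ACGTACGTACGTACGT at starts 0,4,...,24
  catalog <- sno_catalog("tandem", ref)
  read <- strrep("ACGT", 4)
  all_hits <- find_perfect_matches(read, catalog, match_policy(16, 28,
                                                               multi_reference = "all"))
  expect_equal(nrow(all_hits), 7L)
  expect_equal(all_hits$start, seq(0L, 24L, by = 4L))
  best <- find_perfect_matches(read, catalog, match_policy(16, 28,
                                                           multi_reference = "best"))
  expect_equal(nrow(best), 1L)
  expect_equal(best$start, 0L)
})

test_that("library alignment tallies total placement hits per snoRNA", {
  ref <- random_dna(120)
  catalog <- sno_catalog(c("hot", "cold"), c(ref, random_dna(90)))
  frag <- substr(ref, 21, 42)               # 22 nt
  n <- 1581
  lib <- sample_library("s", sprintf("r%04d", 1:n), rep(frag, n))
  res <- align_read_set(lib, catalog, policy_cellline())
  expect_equal(res$hits$hits[res$hits$snorna_id == "hot"], n)
  expect_equal(res$hits$hits[res$hits$snorna_id == "cold"], 0L)
  expect_equal(nrow(res$alignments), n)
  expect_true(all(res$alignments$start == 20L & res$alignments$end == 42L))
})

test_that("reads sampled at known offsets are recovered exactly", {
  set.seed(9)
  catalog <- random_catalog(5, 250)
  n <- 200
  idx <- sample(nrow(catalog), n, replace = TRUE)
  lens <- sample(17:28, n, replace = TRUE)
  starts <- vapply(seq_len(n), function(k) {
    sample(catalog$length[idx[k]] - lens[k] + 1, 1) - 1L
  }, integer(1))
  seqs <- vapply(seq_len(n), function(k) {
    substr(catalog$sequence[idx[k]], starts[k] + 1, starts[k] + lens[k])
  }, character(1))
  lib <- sample_library("s", sprintf("r%03d", 1:n), seqs)
  res <- align_read_set(lib, catalog, policy_cellline())
  for (k in seq_len(n)) {
    rows <- res$alignments[res$alignments$read_id == sprintf("r%03d", k), ]
    hit <- rows$snorna_id == catalog$id[idx[k]] & rows$start == starts[k] &
      rows$end == starts[k] + lens[k]
    expect_true(any(hit))
  }
})
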