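make_aln <- function(snorna_id, starts, ends) {
  data.frame(read_id = sprintf("r%05d", seq_along(starts)),
             snorna_id = rep(snorna_id, length(starts)),
             start = starts, end = ends,
             match_length = ends - starts,
             strand = rep("+", length(starts)),
             stringsAsFactors = FALSE)
}

test_that("interval tallies and the 1555-of-1581 style fixed fraction are exact", {
  set.seed(21)
  # 1555 reads at the modal interval, 26 scattered elsewhere
  starts <- c(rep(10L, 1555), sample(c(0:5, 40:60), 26, replace = TRUE))
  ends <- c(rep(32L, 1555), sample(70:90, 26, replace = TRUE))
  prof <- build_profile(make_aln("sno1b", starts, ends), delta5 = 0, delta3 = 0)
  expect_equal(prof$total_hits, 1581L)
  expect_equal(prof$modal_interval, c(10L, 32L))
  expect_equal(prof$modal_family_count, 1555L)
  expect_equal(prof$fixed_fraction, 1555 / 1581)
  expect_equal(sum(prof$interval_counts$count), prof$total_hits)
})

test_that("degenerate profiles behave: unanimity, uniformity, emptiness", {
  prof1 <- build_profile(make_aln("s", rep(5L, 40), rep(27L, 40)))
  expect_equal(prof1$fixed_fraction, 1)

  starts <- seq(0L, 49L)
  profu <- build_profile(make_aln("s", starts, starts + 20L),
                         delta5 = 0, delta3 = 0)
  expect_equal(profu$fixed_fraction, 1 / 50)
  expect_equal(profu$modal_interval, c(0L, 20L))  # tie broken 5'-most

  prof0 <- build_profile(make_aln("s", integer(0), integer(0)))
  expect_equal(prof0$total_hits, 0L)
  expect_true(is.na(prof0$fixed_fraction))
})

test_that("the 3' tolerance groups jittered ends into the modal family", {
  starts <- rep(4L, 10)
  ends <- c(rep(26L, 6), 29L, 23L, 30L, 22L)
  prof <- build_profile(make_aln("s", starts, ends), delta5 = 0, delta3 = 3)
  expect_equal(prof$modal_interval, c(4L, 26L))
  expect_equal(prof$modal_family_count, 8L)   # 26x6, 29, 23; not 30 or 22
  prof_strict <- build_profile(make_aln("s", starts, ends), delta5 = 0, delta3 = 0)
  expect_equal(prof_strict$modal_family_count, 6L)
})

test_that("fixed fraction is invariant under read duplication", {
  set.seed(22)
  aln <- make_aln("s", sample(0:5, 30, TRUE), sample(22:30, 30, TRUE))
  p1 <- build_profile(aln)
  p3 <- build_profile(aln[rep(seq_len(nrow(aln)), 3), ])
  expect_equal(p3$fixed_fraction, p1$fixed_fraction)
  expect_equal(p3$modal_interval, p1$modal_interval)
  expect_equal(p3$total_hits, 3L * p1$total_hits)
})

test_that("sdRNA calls compose the fraction threshold with the depth floor", {
  set.seed(23)
  sno <- sno_catalog("sno93", random_dna(100))
  aln_good <- make_aln("sno93", c(rep(0L, 1555), rep(40L, 26)),
                       c(rep(22L, 1555), rep(62L, 26)))
  call <- call_sdrna(build_profile(aln_good), sno)
  expect_true(call$is_fixed_position)
  expect_equal(call$sdrna_sequence, substr(sno$sequence, 1, 22))
  expect_equal(call$fragment_length, 22L)
  expect_equal(call$reason, "fixed-position excision")

  aln_half <- make_aln("sno93", rep(c(0L, 40L), each = 20),
                       rep(c(22L, 62L), each = 20))
  expect_false(call_sdrna(build_profile(aln_half), sno)$is_fixed_position)

  aln_thin <- make_aln("sno93", rep(0L, 5), rep(22L, 5))
  thin <- call_sdrna(build_profile(aln_thin), sno)
  expect_false(thin$is_fixed_position)
  expect_equal(thin$reason, "insufficient depth")

  empty <- call_sdrna(build_profile(make_aln("x", integer(0), integer(0))), sno)
  expect_false(empty$is_fixed_position)
  expect_equal(empty$reason, "no hits")
})

test_that("the fixed threshold is a strict inequality", {
  sno <- sno_catalog("s", random_dna(80))
  # exactly 90%: 90 of 100 at the modal interval
  aln <- make_aln("s", c(rep(0L, 90), rep(30L, 10)), c(rep(22L, 90), rep(52L, 10)))
  prof <- build_profile(aln, delta5 = 0, delta3 = 0)
  expect_equal(prof$fixed_fraction, 0.9)
  expect_false(call_sdrna(prof, sno, fixed_threshold = 0.90)$is_fixed_position)
})

test_that("called sdRNA sequences re-locate to their own interval", {
  cfg <- sim_config(seed = 31, n_snornas = 4, library_size = 8000L,
                    background_rate = 0.05)
  sim <- simulate_catalog(cfg)
  lib <- simulate_library(sim$catalog, sim$truth, cfg)
  res <- align_read_set(lib$library, sim$catalog, policy_sra_survey())
  for (s in sim$catalog$id) {
    aln_s <- res$alignments[res$alignments$snorna_id == s, ]
    if (nrow(aln_s) < 10) next
    call <- call_sdrna(build_profile(aln_s), sim$catalog[sim$catalog$id == s, ])
    if (!call$is_fixed_position) next
    relocated <- find_perfect_matches(call$sdrna_sequence,
                                      sim$catalog[sim$catalog$id == s, ],
                                      policy_sra_survey())
    expect_true(any(relocated$start == call$start & relocated$end == call$end))
  }
})

test_that("excision fidelity is recovered across its range under strict grouping", {
  for (f in c(0.5, 0.8, 0.95, 1.0)) {
    cfg <- sim_config(seed = 40 + round(100 * f), n_snornas = 1,
                      snorna_length_range = c(120L, 120L),
                      fidelity = f, background_rate = 0, offtarget_rate = 0,
                      library_size = 2000L)
    sim <- simulate_catalog(cfg)
    lib <- simulate_library(sim$catalog, sim$truth, cfg)
    res <- align_read_set(lib$library, sim$catalog, policy_sra_survey())
    prof <- build_profile(res$alignments, delta5 = 0, delta3 = 0)
    expect_equal(prof$fixed_fraction, f, tolerance = 0.03 / max(f, 0.5))
    expect_equal(prof$modal_interval,
                 c(sim$truth$sdrna_start, sim$truth$sdrna_end))
  }
})

test_that("fragment length summaries report range and the <=25 nt share", {
  calls <- data.frame(snorna_id = paste0("s", 1:4),
                      fragment_length = c(21L, 22L, 24L, 29L),
                      is_fixed_position = TRUE)
  s <- summarize_fragment_lengths(calls)
  expect_equal(s$min, 21L)
  expect_equal(s$max, 29L)
  expect_equal(s$share_le_25, 0.75)

  one <- data.frame(snorna_id = "s", fragment_length = 28L,
                    is_fixed_position = TRUE)
  s1 <- summarize_fragment_lengths(one)
  expect_equal(c(s1$min, s1$max, s1$share_le_25), c(28, 28, 0))
  expect_error(summarize_fragment_lengths(
    data.frame(fragment_length = 20L, is_fixed_position = FALSE)), "no called")
})
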