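test_that("CPM arithmetic is exact, including published-scale library sizes", {
  expect_equal(compute_cpm(0, 1e6), 0)
  expect_equal(compute_cpm(250, 1e6), 250)
  expect_true(flag_expressed(compute_cpm(250, 1e6)))
  # 1581 hits against a ~21M-read library
  expect_equal(compute_cpm(1581, 21092404), 74.9559, tolerance = 1e-6)
  expect_error(compute_cpm(5, 0), "total_reads")
  expect_error(compute_cpm(-1, 10), "raw_count")
})

test_that("CPM is invariant under joint scaling of count and library size", {
  set.seed(61)
  for (i in 1:20) {
    count <- sample(0:5000, 1)
    total <- sample(1e4:1e7, 1)
    k <- sample(2:50, 1)
    expect_equal(compute_cpm(count * k, total * k), compute_cpm(count, total))
  }
})

test_that("per-feature CPMs sum to 1e6 times the aligned fraction", {
  counts <- c(120, 0, 530, 88)
  total <- 5e4
  expect_equal(sum(compute_cpm(counts, total)), 1e6 * sum(counts) / total)
})

test_that("the expression flag is inclusive at 250 CPM", {
  expect_false(flag_expressed(249.999))
  expect_true(flag_expressed(250.0))
  expect_false(flag_expressed(0))
})

test_that("fold changes are pseudocount-stabilized and tiered at 5/7.5/75", {
  a <- data.frame(feature_id = c("f1", "f2", "f3"), cpm = c(750, 250, 300))
  b <- data.frame(feature_id = c("f1", "f2", "f3"), cpm = c(100, 250, 0))
  d <- differential_table(a, b)
  d <- d[match(c("f1", "f2", "f3"), d$feature_id), ]
  # pseudocount nudges 750/100 just below the 7.5 tier
  expect_equal(d$fold_change[1], 750.1 / 100.1)
  expect_equal(d$tier[1], ">=5x")
  expect_true(d$overexpressed[1])
  expect_equal(d$fold_change[2], 1)
  expect_false(d$overexpressed[2])
  expect_equal(d$tier[2], "none")
  # zero denominator: the near-absent-in-one-sample situation
  expect_equal(d$fold_change[3], 300.1 / 0.1)
  expect_equal(d$tier[3], ">=75x")
  expect_true(d$overexpressed[3])
})

test_that("overexpression requires expression in at least one sample", {
  a <- data.frame(feature_id = "low", cpm = 100)
  b <- data.frame(feature_id = "low", cpm = 2)
  d <- differential_table(a, b)
  expect_gte(d$fold_change, 5)
  expect_false(d$overexpressed)
})

test_that("features absent from one sample are zero-filled with a warning", {
  a <- data.frame(feature_id = c("x", "y"), cpm = c(300, 400))
  b <- data.frame(feature_id = "x", cpm = 10)
  expect_warning(d <- differential_table(a, b), "only one sample")
  expect_equal(d$cpm_b[d$feature_id == "y"], 0)
})

test_that("reciprocal fold changes multiply to one", {
  set.seed(62)
  for (i in 1:20) {
    cpm_a <- stats::runif(1, 0, 5000)
    cpm_b <- stats::runif(1, 0, 5000)
    a <- data.frame(feature_id = "f", cpm = cpm_a)
    b <- data.frame(feature_id = "f", cpm = cpm_b)
    fwd <- differential_table(a, b)$fold_change
    rev <- differential_table(b, a)$fold_change
    expect_equal(fwd * rev, 1)
  }
})

test_that("processing preference compares within-sample ratios at the 5.5 cutoff", {
  # ratios engineered to 3.0 vs 0.5 -> factor 6.0
  r <- processing_preference("s", sdrna_cpm_a = 5.9, snorna_cpm_a = 1.9,
                             sdrna_cpm_b = 0.9, snorna_cpm_b = 1.9)
  expect_equal(r$processing_ratio_a, 3.0)
  expect_equal(r$processing_ratio_b, 0.5)
  expect_equal(r$preference_factor, 6.0)
  expect_true(r$preferential)

  same <- processing_preference("s", 3.9, 7.9, 3.9, 7.9)
  expect_equal(same$preference_factor, 1.0)
  expect_false(same$preferential)

  # exactly 5.5 is preferential (inclusive)
  edge <- processing_preference("s", 10.9, 1.9, 1.9, 1.9)
  expect_equal(edge$preference_factor, 5.5)
  expect_true(edge$preferential)
})

test_that("planted CPM fold changes are recovered from simulated library pairs", {
  ids <- sprintf("sno%03d", 1:3)
  cpm_a <- c(sno001 = 40000, sno002 = 8000, sno003 = 8000)
  cpm_b <- c(sno001 = 8000, sno002 = 8000, sno003 = 40000)
  base <- sim_config(seed = 63, n_snornas = 3, background_rate = 0,
                     offtarget_rate = 0.2, library_size = 30000L,
                     sdrna_length_range = c(21L, 25L))
  sim <- simulate_catalog(base)
  cfg_a <- base; cfg_a$target_cpm <- cpm_a
  cfg_b <- base; cfg_b$seed <- 64L; cfg_b$target_cpm <- cpm_b
  lib_a <- simulate_library(sim$catalog, sim$truth, cfg_a)
  lib_b <- simulate_library(sim$catalog, sim$truth, cfg_b)
  hits_a <- align_read_set(lib_a$library, sim$catalog, policy_cellline())$hits
  hits_b <- align_read_set(lib_b$library, sim$catalog, policy_cellline())$hits
  d <- differential_table(
    data.frame(feature_id = ids, cpm = compute_cpm(hits_a$hits, 30000)),
    data.frame(feature_id = ids, cpm = compute_cpm(hits_b$hits, 30000)))
  expect_equal(d$cpm_a[1], 40000, tolerance = 0.02)
  expect_equal(d$fold_change[1], 5, tolerance = 0.05)
  expect_equal(d$fold_change[2], 1, tolerance = 0.05)
  expect_equal(d$fold_change[3], 1 / 5, tolerance = 0.05)
})
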