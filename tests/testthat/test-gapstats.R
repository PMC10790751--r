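test_that("expected_uniform is exact, linear, and additive over bins", {
  expect_equal(expected_uniform(4280133, 96, 100, 99.2, 99.3), 107003.325)
  expect_equal(expected_uniform(4280133, 96, 100, 99.2, 99.8), 642019.95)
  expect_equal(expected_uniform(0, 96, 100, 99, 99.5), 0)
  # linear in N and width; disjoint bins covering the range sum to N
  expect_equal(expected_uniform(2e6, 96, 100, 99, 99.2),
               2 * expected_uniform(1e6, 96, 100, 99, 99.2))
  bins <- seq(96, 100, by = 0.25)
  tot <- sum(vapply(seq_len(length(bins) - 1), function(i)
    expected_uniform(12345, 96, 100, bins[i], bins[i + 1]), numeric(1)))
  expect_equal(tot, 12345)
  expect_error(expected_uniform(10, 100, 96, 99, 99.5), "degenerate|interval")
  expect_error(expected_uniform(10, 96, 100, 99.5, 99.2), "interval")
})

test_that("deficit ratio is ~1 for uniform data and <1 for concentrated data", {
  for (s in 1:10) {
    set.seed(s)
    v <- runif(20000, 96, 100)
    r <- deficit_ratio(v, interval = c(99.2, 99.8), range = c(96, 100))
    expect_lt(abs(r$deficit_ratio - 1), 0.15)
  }
  # everything inside the interval: ratio below 1
  r <- deficit_ratio(runif(500, 99.3, 99.7))
  expect_lt(r$deficit_ratio, 1)
  # empty interval: flagged, not a number
  r0 <- deficit_ratio(runif(500, 96, 99))
  expect_true(r0$observed_zero)
  expect_true(is.na(r0$deficit_ratio))
})

test_that("deficit ratio reproduces the threefold-deficit situation", {
  # distribution with the gap interval holding one third of its uniform share
  set.seed(99)
  v <- c(runif(34000, 96, 99.2), runif(2000, 99.2, 99.8), runif(4000, 99.8, 100))
  r <- deficit_ratio(v)
  expect_equal(r$observed_in_interval, 2000)
  expect_gt(r$deficit_ratio, 2.5)
})

test_that("find_valleys localises a well-separated valley and ignores unimodal data", {
  set.seed(51)
  v <- c(rnorm(300, 99.0, 0.05), rnorm(300, 99.9, 0.02))
  fv <- find_valleys(v)
  expect_equal(nrow(fv), 1)
  expect_gt(fv$midpoint, 99.2)
  expect_lt(fv$midpoint, 99.8)
  for (s in 1:10) {
    set.seed(s)
    u <- rnorm(400, 98, 0.3)
    expect_equal(nrow(find_valleys(u)), 0)
  }
  expect_equal(nrow(find_valleys(numeric(0))), 0)
  expect_equal(nrow(find_valleys(rnorm(5, 98))), 0)   # below the n floor
})

test_that("classification rules are forced by their definitions", {
  expect_equal(classify_species(c(99.6, 99.9, 99.7), NULL, NA), "clonal")
  set.seed(52)
  v <- runif(100, 99.51, 100)
  expect_equal(classify_species(v, find_valleys(v), 0.001), "clonal")
  v2 <- c(rnorm(200, 98.0, 0.05), rnorm(200, 99.0, 0.05))
  fv2 <- find_valleys(v2)
  expect_equal(classify_species(v2, fv2, 0.001), "shifted_gap")
  expect_equal(classify_species(v2, fv2, 0.5), "no_gap")
  v3 <- c(rnorm(200, 99.0, 0.05), rnorm(200, 99.9, 0.02))
  expect_equal(classify_species(v3, find_valleys(v3), 0.001), "gap_99.2_99.8")
})

test_that("gap_scan end-to-end classifies a gapped simulation", {
  sim <- small_gapped()
  gr <- gap_scan(sim$pairs$ani, species_id = "toy", n_boot = 300, seed = 1)
  expect_s3_class(gr, "gap_report")
  expect_equal(gr$classification, "gap_99.2_99.8")
  expect_lt(gr$p_value, 0.05)
  expect_output(print(gr), "gap_99.2_99.8")
})

test_that("gap_mode pools valley midpoints with the stated tie-break", {
  expect_equal(gap_mode(c(99.45)), 99.5)   # 99.45 falls in the 99.5-centred bin
  expect_equal(gap_mode(c(99.41, 99.42, 99.51)), 99.4)
  # tie between the 99.4 and 99.5 bins resolves toward higher ANI
  expect_equal(gap_mode(c(99.41, 99.52)), 99.5)
  expect_error(gap_mode(list()), "no valleys")
})

test_that("subsampling preserves pair structure", {
  sim <- small_gapped()
  pt <- sim$pairs
  expect_equal(nrow(subsample_pairs(pt, k = 12, seed = 1)), nrow(pt))
  sub <- subsample_pairs(pt, k = 5, seed = 1)
  expect_equal(nrow(sub), choose(5, 2))
  expect_message(expect_null(subsample_pairs(pt, k = 50)), "skipping")
})

test_that("gapped species keep their classification under subsampling", {
  sim <- simulate_species(sim_config(seed = 31))
  ids <- rownames(sim$truth$identity)
  cmb <- t(combn(ids, 2))
  pt <- data.frame(query_id = cmb[, 1], ref_id = cmb[, 2],
                   ani = sim$truth$identity[cmb])
  hits <- 0
  for (s in 1:10) {
    sub <- subsample_pairs(pt, k = 10, seed = s)
    gr <- gap_scan(sub$ani, n_boot = 300, seed = s)
    hits <- hits + (gr$classification == "gap_99.2_99.8")
  }
  expect_gte(hits, 8)
})

test_that("divergence_time implements the closed form", {
  expect_equal(divergence_time(0), 0)
  expect_equal(divergence_time(0.005, mu = 4e-10, g = 100, k = 2), 62500)
  expect_equal(divergence_time(0.005, mu = 4e-10, g = 50, k = 2),
               2 * divergence_time(0.005, mu = 4e-10, g = 100, k = 2))
  expect_error(divergence_time(0.1, mu = 0), "positive")
  expect_error(divergence_time(0.1, k = 3), "k must be")
})
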