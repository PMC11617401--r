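test_that("rectification keeps only deviations of at least 0.1", {
  A <- rbind(c(0.75, 0.25, 0.5), c(0.62, 0.38, 0.5), c(0.55, 0.55, 0.55))
  R <- rectify(A, window = c(0, 800),
               bin_centers = c(100, 200, 300))
  expect_equal(unname(R[1, ]), c(0.25, 0.25, 0))
  expect_equal(unname(R[2, ]), c(0.12, 0.12, 0))
  expect_equal(unname(R[3, ]), c(0, 0, 0))
  # windows outside 0-800 ms are dropped
  R2 <- rectify(A, window = c(0, 800), bin_centers = c(-100, 200, 900))
  expect_equal(ncol(R2), 1)
})

test_that("peak entropy and temporal sparsity match hand computations", {
  # identity-like pattern: maximal entropy and sparsity
  I5 <- diag(5) * 0.3
  expect_equal(peak_entropy(I5), 1)
  expect_equal(temporal_sparsity(I5), 1)
  expect_equal(sequentiality_index(peak_entropy(I5), temporal_sparsity(I5)), 1)
  # all peaks in one bin
  one <- matrix(c(rep(0.4, 5), rep(0, 20)), 5, 5)
  expect_equal(peak_entropy(one), 0)
  # constant positive matrix: fully overlapped
  const <- matrix(0.2, 4, 6)
  expect_equal(temporal_sparsity(const), 0)
  expect_equal(sequentiality_index(peak_entropy(const),
                                   temporal_sparsity(const)), 0)
  # peaks (bin1, bin1, bin2) over B = 2
  m <- rbind(c(0.3, 0.1), c(0.2, 0.1), c(0.1, 0.3))
  expect_equal(peak_entropy(m),
               -(2 / 3 * log(2 / 3) + 1 / 3 * log(1 / 3)) / log(2))
  # single column (0.3, 0.1): H = entropy of (0.75, 0.25)
  col <- cbind(c(0.3, 0.1))
  H <- -(0.75 * log(0.75) + 0.25 * log(0.25))
  expect_equal(temporal_sparsity(col), 1 - H / log(2))
})

test_that("the printed index triples satisfy the combining rule", {
  # inputs are printed at 3 decimals, so the rule reproduces each printed
  # index to within one unit in the third decimal
  expect_equal(sequentiality_index(0.981, 0.571), 0.749, tolerance = 1e-3)
  expect_equal(sequentiality_index(0.939, 0.515), 0.695, tolerance = 1e-3)
  expect_equal(round(sequentiality_index(0.989, 0.284), 2), 0.53)
  expect_equal(round(sequentiality_index(0.983, 0.230), 3), 0.475)
  expect_equal(sequentiality_index(0.986, 0.221), 0.467, tolerance = 1e-3)
})

test_that("index components are bounded, scale-free and degenerate-safe", {
  set.seed(99)
  for (rep in 1:25) {
    R <- matrix(runif(30, 0, 0.4), 5, 6)
    R[R < 0.05] <- 0
    R <- R + 0.01 # keep rows nonzero
    s <- sequentiality(R)
    expect_true(all(c(s$PE, s$TS, s$SqI) >= 0 & c(s$PE, s$TS, s$SqI) <= 1))
    expect_equal(s$SqI, sqrt(s$PE * s$TS))
    s2 <- sequentiality(R * 7.3) # positive scaling changes nothing
    expect_equal(s2[, c("PE", "TS", "SqI")], s[, c("PE", "TS", "SqI")])
  }
  expect_error(peak_entropy(matrix(0, 2, 3)),
               class = "tastedyn_degenerate_error")
})

test_that("peak sorting agrees with a naive sort oracle", {
  set.seed(4)
  for (rep in 1:10) {
    R <- matrix(runif(25), 5, 5)
    ord <- sort_by_peak(R)
    peaks <- apply(R, 1, which.max)
    expect_equal(peaks[ord], sort(peaks))
  }
  rev_seq <- diag(4)[4:1, ]
  expect_equal(sort_by_peak(rev_seq), 4:1)
  expect_equal(sort_by_peak(diag(4)), 1:4)
})

test_that("split-half reproducibility detects planted sequences", {
  pop <- fx_perfect()
  s <- pop$session
  ep <- epoch_defaults("stimulus")
  rt <- sliding_rates(s, ep)
  tr <- usable_trials(s, ep$align_event)
  labels <- factor(tr$category, levels = c("water", "sucrose"))
  res <- split_half_reproducibility(rt, labels, n_perm = 10000, seed = 6)
  expect_lt(res$p, 0.001)
  expect_gte(res$mse, 0)
  # MSE with matched rows is invariant to relabeling both halves identically
  # (sorting for display is cosmetic): direct arithmetic property
  M1 <- matrix(runif(40), 8, 5)
  M2 <- matrix(runif(40), 8, 5)
  perm <- sample(8)
  expect_equal(mean((M1 - M2)^2), mean((M1[perm, ] - M2[perm, ])^2))
})

test_that("split-half p-values stay calibrated on unstructured populations", {
  pop <- fx_null_pop()
  s <- pop$session
  ep <- epoch_spec("short", "stimulus_delivery_t", 0, 400)
  rt <- sliding_rates(s, ep)
  tr <- usable_trials(s, ep$align_event)
  labels <- factor(tr$category, levels = c("water", "sucrose"))
  ps <- vapply(1:40, function(i) {
    split_half_reproducibility(rt, labels, n_perm = 400, seed = 100 + i)$p
  }, numeric(1))
  # unstructured rows are exchangeable: p should be far from systematically
  # small or large
  expect_gt(mean(ps), 0.25)
  expect_lt(mean(ps), 0.75)
})

test_that("latency comparisons behave at the extremes and detect offsets", {
  a <- c(100, 200, 300, 400)
  same <- latency_comparison(a, a)
  expect_equal(same$statistic, 0)
  expect_equal(same$p, 1)
  disjoint <- latency_comparison(c(10, 20, 30), c(500, 600, 700))
  expect_equal(disjoint$statistic, 1)
  # two populations offset by 200 ms at n = 40/40
  set.seed(12)
  pa <- rnorm(40, 300, 80)
  pb <- rnorm(40, 500, 80)
  expect_lt(latency_comparison(pa, pb)$p, 0.01)
  expect_equal(nrow(same$curves), 8)
})
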