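test_that("auroc matches exhaustive pair counting and its symmetries", {
  expect_equal(auroc(c(1, 2, 3), c(2, 3, 4)), 7 / 9)
  expect_equal(auroc(1:5, 1:5), 0.5)
  expect_equal(auroc(c(1, 2), c(5, 6)), 1)
  expect_error(auroc(numeric(0), 1), class = "tastedyn_contrast_error")
  set.seed(13)
  for (rep in 1:40) {
    n_a <- sample(1:12, 1)
    n_b <- sample(1:12, 1)
    x_a <- sample(0:6, n_a, replace = TRUE) # ties on purpose
    x_b <- sample(0:6, n_b, replace = TRUE)
    expect_equal(auroc(x_a, x_b), auroc_oracle(x_a, x_b))
    expect_equal(auroc(x_a, x_b) + auroc(x_b, x_a), 1)
    # invariance under a strictly increasing transform of the pooled rates
    expect_equal(auroc(exp(x_a / 2), exp(x_b / 2)), auroc(x_a, x_b))
  }
})

test_that("permutation p-values behave at the extremes and reproduce", {
  x <- c(3, 1, 4, 1, 5, 9, 2, 6)
  expect_gt(permutation_pvalue(x, x, n_perm = 500, seed = 1), 0.9)
  # full separation of 8 vs 8 distinct values: p near 2 * 8!8!/16!
  p <- permutation_pvalue(1:8, 101:108, n_perm = 10000, seed = 2)
  expect_lt(p, 0.001)
  expect_gt(p, 1 / 10001 - 1e-12)
  expect_identical(permutation_pvalue(1:6, 4:9, n_perm = 300, seed = 7),
                   permutation_pvalue(1:6, 4:9, n_perm = 300, seed = 7))
})

test_that("selectivity matrices flag planted bumps and stay calibrated", {
  scr <- fx_screens()
  pop <- fx_mixed()
  sm <- scr$stimulus$sm
  # a sucrose-preferring template neuron shows a contiguous A >= 0.6 block
  truth <- pop$ground_truth
  suc <- truth[truth$tuned_variable == "stimulus_category" &
                 truth$preferred == "sucrose", ]
  for (i in seq_len(nrow(suc))) {
    near <- abs(sm$bin_centers - suc$mu_ms[i]) <= 50
    expect_gte(max(sm$A[match(suc$neuron_id[i], sm$neuron_ids), near]), 0.6)
  }
  # untuned neurons: per-bin significance rate near the nominal level
  none_rows <- match(truth$neuron_id[truth$tuned_variable == "none"],
                     sm$neuron_ids)
  p_rate <- mean(sm$p[none_rows, ] <= 0.05)
  expect_lt(p_rate, 0.09)
  # class with < 2 trials -> invalid matrix
  rt <- sliding_rates(pop$session, epoch_spec("t", "stimulus_delivery_t",
                                              0, 200))
  lab <- factor(c("a", rep("b", nrow(pop$session$trials) - 1)))
  sm_bad <- selectivity_matrix(rt, lab, n_perm = 50, seed = 1)
  expect_true(all(is.na(sm_bad$A)))
  expect_false(any(sm_bad$sig))
})

test_that("the five-consecutive-bin rule gates encoder detection", {
  B <- 20
  mk_row <- function(bins_high) {
    a <- rep(0.5, B)
    a[bins_high] <- 0.75
    a
  }
  A <- rbind(mk_row(3:6), mk_row(3:7), mk_row(c(2:6, 10:16)))
  sm <- fake_selectivity(A)
  enc <- detect_encoders(sm)
  expect_equal(enc$is_encoder, c(FALSE, TRUE, TRUE)) # 4 bins miss, 5 make it
  # best bin: earliest maximal deviation inside a qualifying run
  expect_equal(enc$best_bin[2], 3)
  expect_equal(enc$best_bin_center[2], sm$bin_centers[3])

  # switching: qualifying runs on both sides of 0.5
  a_sw <- rep(0.5, B)
  a_sw[2:7] <- 0.8
  a_sw[12:18] <- 0.2
  enc_sw <- detect_encoders(fake_selectivity(rbind(a_sw)))
  expect_equal(enc_sw$preference, "switching")
  enc_hi <- detect_encoders(fake_selectivity(rbind(mk_row(3:9))))
  expect_equal(enc_hi$preference, "classB_preferring")

  # the stimulus disambiguation: auROC must beat the choice probability
  a <- rbind(mk_row(3:9), mk_row(3:9))
  C <- rbind(rep(0.5, B), rep(0.9, B)) # second neuron: choice index higher
  enc_c <- detect_encoders(fake_selectivity(a, C = C, contrast = "stimulus"))
  expect_equal(enc_c$is_encoder, c(TRUE, FALSE))
})

test_that("recovery on the mixed template separates tuned classes", {
  scr <- fx_screens()
  truth <- fx_mixed()$ground_truth
  ids <- function(v) truth$neuron_id[truth$tuned_variable == v]
  detected <- lapply(scr, function(x) x$enc$neuron_id[x$enc$is_encoder])
  # sensitivity per contrast
  expect_gte(mean(ids("stimulus_category") %in% detected$stimulus), 0.8)
  expect_gte(mean(ids("choice") %in% detected$choice), 0.8)
  expect_gte(mean(ids("outcome") %in% detected$outcome), 0.8)
  # the choice-probability rule keeps pure-choice neurons out of the
  # stimulus-encoder set even though stimulus and choice correlate
  expect_equal(sum(ids("choice") %in% detected$stimulus), 0)
  # untuned neurons essentially never enter the stimulus set
  expect_lte(mean(ids("none") %in% detected$stimulus), 0.05)
  # switching neurons are recovered with a switching preference
  sw <- truth$neuron_id[truth$switch]
  enc_ch <- scr$choice$enc
  expect_true(all(enc_ch$preference[match(sw, enc_ch$neuron_id)] ==
                    "switching"))
})

test_that("two-proportion z-tests match hand and printed computations", {
  expect_equal(proportion_ztest(45, 388, 60, 422)$z, -1.109, tolerance = 5e-4)
  expect_equal(proportion_ztest(10, 50, 10, 50)$z, 0)
  expect_equal(proportion_ztest(8, 10, 2, 10)$z, 0.6 / sqrt(0.25 * 0.2),
               tolerance = 1e-12)
  expect_warning(zt <- proportion_ztest(0, 10, 0, 12), "degenerate")
  expect_equal(zt$z, 0)
})

test_that("count reports produce rounded percentages and z-tests", {
  fake_enc <- function(k, n) {
    tibble::tibble(neuron_id = seq_len(n), is_encoder = seq_len(n) <= k)
  }
  rep <- neuron_counts_report(
    list(stimulus = fake_enc(45, 388), outcome = fake_enc(210, 388)),
    list(stimulus = fake_enc(60, 422), outcome = fake_enc(145, 422))
  )
  expect_equal(rep$pct_1[rep$contrast == "outcome"], 54.12)
  expect_equal(rep$pct_2[rep$contrast == "outcome"], 34.36)
  expect_equal(rep$z[rep$contrast == "stimulus"], -1.109, tolerance = 5e-4)
  expect_equal(neuron_counts_report(list(a = fake_enc(0, 100)),
                                    list(a = fake_enc(1, 100)))$pct_1, 0)
})
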