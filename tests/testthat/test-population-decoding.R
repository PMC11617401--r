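# synthetic rate tensor with controllable class separation
sep_tensor <- function(n_neur = 6, n_per_class = 30, B = 3, gap = 4,
                       n_class = 2, sd = 1, seed = 1) {
  set.seed(seed)
  n_tr <- n_per_class * n_class
  labels <- factor(rep(seq_len(n_class), each = n_per_class))
  X <- array(rnorm(n_neur * n_tr * B, sd = sd), dim = c(n_neur, n_tr, B))
  for (cl in seq_len(n_class)) {
    X[, labels == cl, ] <- X[, labels == cl, ] + (cl - 1) * gap
  }
  ep <- epoch_spec("fake", "x", 0, (B - 1) * 10 + 100)
  list(rates = new_rate_tensor(pmax(X, 0), seq_len(n_neur),
                               seq_len(n_tr), ep),
       labels = labels)
}

test_that("pseudo-trials resample real trials with the right shape", {
  d <- sep_tensor(n_neur = 1, n_per_class = 10)
  ps <- build_pseudo_trials(d$rates, d$labels, t_c = 8, seed = 3)
  expect_equal(dim(ps$features), c(16, 1, 3))
  expect_equal(as.vector(table(ps$labels)), c(8, 8))
  ps2 <- build_pseudo_trials(d$rates, d$labels, t_c = 8, seed = 3)
  expect_identical(ps$features, ps2$features)
  # every feature value is one of the source trial rates for that class
  for (cl in 1:2) {
    src <- d$rates$rates[1, d$labels == cl, 1]
    expect_true(all(ps$features[ps$labels == cl, 1, 1] %in% src))
  }
  # resampling distribution: each source trial drawn uniformly
  d2 <- sep_tensor(n_neur = 1, n_per_class = 8, B = 1, gap = 0, seed = 5)
  d2$rates$rates[1, , 1] <- 1:16
  draws <- unlist(lapply(1:700, function(sd) {
    ps <- build_pseudo_trials(d2$rates, d2$labels, t_c = 8, seed = sd)
    ps$features[ps$labels == 1, 1, 1]
  }))
  tab <- table(draws)
  n <- length(draws)
  expect_true(all(abs(tab / n - 1 / 8) < 3 * sqrt(1 / 8 * 7 / 8 / n) + 1 / n))
  # quota enforcement
  d3 <- sep_tensor(n_neur = 1, n_per_class = 4, B = 1, gap = 0, seed = 5)
  expect_error(build_pseudo_trials(d3$rates, d3$labels, t_c = 5),
               class = "tastedyn_quota_error")
})

small_cfg <- function(...) {
  decoding_config(n_neuron_resamples = 5, n_trial_resamples = 4, ...)
}

test_that("separable classes decode near perfectly, permuted labels at chance", {
  d <- sep_tensor(gap = 5)
  res <- decode_population(d$rates, d$labels, small_cfg(seed = 2))
  expect_true(all(res$accuracy$mean_acc >= 0.95))
  resp <- decode_population(d$rates, d$labels,
                            small_cfg(seed = 2, permute_labels = TRUE))
  expect_lt(abs(mean(resp$accuracy$mean_acc) - 0.5), 0.08)
  # determinism under a fixed master seed
  res2 <- decode_population(d$rates, d$labels, small_cfg(seed = 2))
  expect_identical(res$resample_acc, res2$resample_acc)
  expect_identical(res$confusion_counts, res2$confusion_counts)
})

test_that("a linear kernel is not outperformed on linearly separable data", {
  d <- sep_tensor(gap = 2.2, B = 1, seed = 4)
  accs <- vapply(c("linear", "gaussian", "poly3"), function(k) {
    mean(decode_population(d$rates, d$labels,
                           small_cfg(seed = 5, kernel = k))$accuracy$mean_acc)
  }, numeric(1))
  expect_gte(accs["linear"], max(accs) - 0.05)
})

test_that("confusion matrices are row-normalized with the diagonal as accuracy", {
  d <- sep_tensor(n_class = 6, n_per_class = 12, gap = 4, B = 2, seed = 6)
  cfg <- small_cfg(schema = "six_class", seed = 7)
  res <- decode_population(d$rates, d$labels, cfg)
  C <- confusion_matrix(res, window = range(res$bin_centers))
  expect_equal(rowSums(C), rep(1, 6), ignore_attr = TRUE)
  expect_equal(unname(per_class_accuracy(res, range(res$bin_centers))),
               unname(diag(C)))
  expect_true(mean(diag(C)) > 0.8) # well separated classes
})

test_that("pattern MSEs match the analytic values", {
  pat <- pattern_matrices()
  expect_equal(rowSums(pat$fine), rep(1, 6), ignore_attr = TRUE)
  expect_equal(rowSums(pat$gross), rep(1, 6), ignore_attr = TRUE)
  expect_equal(confusion_vs_patterns(pat$fine)$mse_fine, 0)
  expect_equal(confusion_vs_patterns(pat$gross)$mse_gross, 0)
  # MSE between the two patterns themselves: 5*(0.8^2 + 4*0.2^2)/36 = 1/9
  expect_equal(confusion_vs_patterns(pat$fine)$mse_gross,
               5 * (0.8^2 + 4 * 0.2^2) / 36)
  expect_equal(round(confusion_vs_patterns(pat$gross)$mse_fine, 4), 0.1111)
})

test_that("the extended population keeps stimulus neurons, drops choice ones", {
  pop <- fx_mixed_large()
  s <- pop$session
  truth <- pop$ground_truth
  ep <- epoch_spec("stim_sel", "stimulus_delivery_t", -100, 500)
  rt <- sliding_rates(s, ep, trial_filter = function(tr) tr$outcome == "correct")
  tr <- usable_trials(s, ep$align_event)
  tr <- tr[tr$outcome == "correct", ]
  sel <- select_extended_population(rt, tr$concentration,
                                    choice_encoders = NULL)
  stim_ids <- truth$neuron_id[truth$tuned_variable == "stimulus_category"]
  expect_gte(mean(stim_ids %in% sel), 0.8)
  # choice-flagged neurons are excluded when provided
  choice_ids <- truth$neuron_id[truth$tuned_variable == "choice"]
  fake_choice <- tibble::tibble(neuron_id = choice_ids, is_encoder = TRUE)
  sel2 <- select_extended_population(rt, tr$concentration,
                                     choice_encoders = fake_choice)
  expect_equal(sum(choice_ids %in% sel2), 0)
  # per-window false-selection rate of flat neurons near the nominal level
  none_ids <- truth$neuron_id[truth$tuned_variable == "none"]
  rt_none <- tensor_subset(rt, none_ids)
  g <- factor(tr$concentration)
  pvals <- c()
  for (i in seq_along(none_ids)) {
    for (b in seq(1, dim(rt_none$rates)[3], by = 10)) {
      pvals <- c(pvals, stats::oneway.test(rt_none$rates[i, , b] ~ g,
                                           var.equal = TRUE)$p.value)
    }
  }
  expect_lt(mean(pvals <= 0.05, na.rm = TRUE), 0.09)
})

test_that("warped outcome decoding dissociates neurons from licking", {
  pop <- fx_mixed()
  truth <- pop$ground_truth
  out_ids <- truth$neuron_id[truth$tuned_variable == "outcome"]
  cfg <- small_cfg(seed = 9, bin_stride = 30)
  ctl <- outcome_vs_licking_control(pop$session, out_ids, cfg, n_boot = 1000)
  post <- ctl$accuracy[ctl$accuracy$bin_center > 100, ]
  # outcome-tuned neurons beat the lick train after feedback
  expect_gt(mean(post$acc_neural), mean(post$acc_lick) + 0.1)
  expect_lt(min(post$p_boot), 0.01)
  # symmetric construction: untuned neurons, licking alone carries outcome
  pop0 <- fx_null_pop()
  ctl0 <- outcome_vs_licking_control(pop0$session,
                                     pop0$ground_truth$neuron_id[1:10],
                                     cfg, n_boot = 1000)
  late <- ctl0$accuracy[ctl0$accuracy$bin_center >= 400, ]
  expect_gt(max(late$acc_lick), max(late$acc_neural))
})
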