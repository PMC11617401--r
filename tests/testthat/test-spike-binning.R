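test_that("sliding windows count spikes with the half-open convention", {
  trials <- tibble::tibble(
    trial_id = 1L, concentration = 0, choice = "water", outcome = "correct",
    rewarded = TRUE, stimulus_delivery_t = 1000, last_central_lick_t = 1150,
    feedback_t = 1800
  )
  licks <- tibble::tibble(trial_id = 1L,
                          spout = c("central", "central", "left", "left"),
                          lick_t = c(1000, 1150, 1660, 1800))
  mk <- function(spike_ts) {
    taste_session(trials,
                  tibble::tibble(neuron_id = 1L, region = "aIC",
                                 spike_t = spike_ts),
                  licks)
  }
  ep1 <- epoch_spec("one", "stimulus_delivery_t", 0, 100, w = 100, s = 10)
  s <- mk(1000 + c(10, 55, 90))
  expect_equal(sliding_rates(s, ep1)$rates[1, 1, 1], 30) # 3 spikes / 100 ms

  # spike exactly on a window's right edge: out of [0,100), in [10,110)
  ep2 <- epoch_spec("two", "stimulus_delivery_t", 0, 210, w = 100, s = 10)
  s_edge <- mk(1000 + 100)
  r <- sliding_rates(s_edge, ep2)$rates[1, 1, ]
  expect_equal(r[1], 0)
  expect_equal(r[2], 10)

  # no spikes anywhere -> all-zero tensor
  s0 <- mk(numeric(0))
  expect_true(all(sliding_rates(s0, ep2)$rates == 0))
})

test_that("sliding_rates agrees with the naive counting oracle", {
  pop <- fx_null_pop()
  s <- pop$session
  ep <- epoch_spec("rand", "stimulus_delivery_t", -120, 340, w = 70, s = 30)
  rt <- sliding_rates(s, ep)
  by_neuron <- split(s$spikes$spike_t, s$spikes$neuron_id)
  set.seed(5)
  for (i in sample(length(rt$neuron_ids), 4)) {
    for (k in sample(nrow(s$trials), 4)) {
      expected <- sliding_oracle(by_neuron[[as.character(rt$neuron_ids[i])]],
                                 s$trials$stimulus_delivery_t[k], ep)
      expect_equal(rt$rates[i, k, ], expected)
    }
  }
})

test_that("lick rates share the sliding-rate contract", {
  pop <- fx_null_pop()
  s <- pop$session
  ep <- epoch_spec("lk", "feedback_t", -200, 400, w = 100, s = 50)
  lr <- lick_rates(s, ep)
  expect_equal(dim(lr)[1], 1L)
  # equivalence: feed the licks through sliding_rates as a spike train
  s2 <- s
  s2$spikes <- tibble::tibble(neuron_id = 1L, region = "aIC",
                              spike_t = sort(s$licks$lick_t))
  expect_equal(sliding_rates(s2, ep)$rates[1, , ], lr$rates[1, , ])
  # a hand-built window: 7 licks within 100 ms -> 70 "Hz"
  trials <- s$trials[1, ]
  licks7 <- tibble::tibble(trial_id = trials$trial_id, spout = "central",
                           lick_t = trials$feedback_t + seq(0, 90, by = 15))
  s3 <- s
  s3$trials <- trials
  s3$licks <- licks7
  ep1 <- epoch_spec("w", "feedback_t", 0, 100, w = 100, s = 10)
  expect_equal(lick_rates(s3, ep1, spout = "all")$rates[1, 1, 1], 70)
})

test_that("lick warping is exact, monotone and idempotent at 140 ms", {
  expect_equal(warp_to_licks(c(50, 150), c(0, 100, 200)), c(70, 210))
  # licks already on the 140 ms grid: identity
  licks <- c(0, 140, 280, 420)
  sp <- c(10, 150, 400)
  expect_equal(warp_to_licks(sp, licks), sp)
  # lick times map to exact multiples of the target interval
  licks2 <- c(0, 90, 310, 480)
  expect_equal(warp_to_licks(licks2, licks2), c(0, 140, 280, 420))
  # spikes outside [first, last] lick are discarded
  expect_equal(warp_to_licks(c(-5, 100, 500), licks2), warp_to_licks(100, licks2))
  # monotone and continuous on random inputs
  set.seed(8)
  for (rep in 1:20) {
    lk <- cumsum(runif(6, 50, 250))
    spk <- sort(runif(30, min(lk), max(lk)))
    w <- warp_to_licks(spk, lk)
    expect_true(all(diff(w) >= 0))
    expect_equal(length(w), 30)
  }
  expect_error(warp_to_licks(1, 5), class = "tastedyn_warp_error")
})

test_that("kernel smoothing conserves spike mass and averages trials", {
  trials <- tibble::tibble(
    trial_id = 1:2, concentration = c(20, 20), choice = "sucrose",
    outcome = "correct", rewarded = TRUE,
    stimulus_delivery_t = c(1000, 9000),
    last_central_lick_t = c(1140, 9140), feedback_t = c(1800, 9800)
  )
  licks <- dplyr::bind_rows(lapply(1:2, function(k) {
    tibble::tibble(trial_id = k, spout = c("central", "central", "right",
                                           "right"),
                   lick_t = trials$stimulus_delivery_t[k] +
                     c(0, 140, 660, 800))
  }))
  # identical spike pattern on both trials, single spike at t = 0
  spikes <- tibble::tibble(neuron_id = 1L, region = "aIC",
                           spike_t = c(1000, 9000))
  s <- taste_session(trials, spikes, licks)
  kr <- kernel_rates(s, "stimulus_delivery_t", c(-200, 200),
                     condition = category, min_trials = 2)
  rate <- kr$rates[1, 1, ]
  # Gaussian peak: 1000 / (20 * sqrt(2*pi)) Hz at the spike time
  expect_equal(max(rate), 1000 / (20 * sqrt(2 * pi)), tolerance = 1e-6)
  expect_equal(kr$grid[which.max(rate)], 0)
  # kernel mass: 1 ms grid integral within 1e-3 of one spike per trial
  expect_lt(abs(sum(rate) / 1000 - 1), 1e-3)
  # two identical trials: the mean equals either trial's curve, so rerunning
  # with one trial gives the same result
  s1 <- s
  s1$trials <- s$trials[1, ]
  s1$licks <- licks[licks$trial_id == 1, ]
  s1$spikes <- spikes[1, ]
  kr1 <- kernel_rates(s1, "stimulus_delivery_t", c(-200, 200),
                      condition = category, min_trials = 1)
  expect_equal(kr$rates[1, 1, ], kr1$rates[1, 1, ])
  # zero spikes -> identically zero
  s0 <- s
  s0$spikes <- spikes[0, ]
  expect_error(kernel_rates(s0, "stimulus_delivery_t", c(-200, 200),
                            condition = category),
               NA)
})
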