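# Shared fixtures, cached for the whole test run, plus independent oracles.

.fx <- new.env(parent = emptyenv())

fx_cached <- function(key, builder) {
  if (is.null(.fx[[key]])) .fx[[key]] <- builder()
  .fx[[key]]
}

# 200-trial mixed-encoder population (the template's default conditions)
fx_mixed <- function() {
  fx_cached("mixed", function() make_population("encoders_mixed", seed = 42))
}

# 400-trial session for analyses needing 8+ correct trials per concentration
fx_mixed_large <- function() {
  fx_cached("mixed_large", function() {
    make_population("encoders_mixed", seed = 43,
                    config = behavior_config(n_trials = 400))
  })
}

fx_null_pop <- function() {
  fx_cached("null_pop", function() make_population("null", seed = 44))
}

fx_perfect <- function() {
  fx_cached("perfect", function() make_population("perfect_sequence", seed = 45))
}

# encoding screens of the mixed population, all three contrasts
fx_screens <- function() {
  fx_cached("screens", function() {
    pop <- fx_mixed()
    lapply(stats::setNames(nm = c("stimulus", "choice", "outcome")),
           function(ct) {
             sm <- screen_session(pop$session, ct, n_perm = 1000, seed = 7)
             list(sm = sm, enc = detect_encoders(sm))
           })
  })
}

# tiny hand-built session: 3 trials, 2 neurons, fully known event times
fx_toy_session <- function() {
  trials <- tibble::tibble(
    trial_id = 1:3,
    concentration = c(0, 20, 0),
    choice = c("water", "sucrose", "sucrose"),
    outcome = c("correct", "correct", "incorrect"),
    rewarded = c(TRUE, TRUE, FALSE),
    stimulus_delivery_t = c(1000, 11000, 21000),
    last_central_lick_t = c(1140, 11150, 21160),
    feedback_t = c(1800, 11800, 21800)
  )
  licks <- dplyr::bind_rows(lapply(1:3, function(k) {
    t0 <- trials$stimulus_delivery_t[k]
    lat1 <- trials$feedback_t[k] - 140
    tibble::tibble(
      trial_id = k,
      spout = c("central", "central", rep(c("left", "right", "right")[k], 4)),
      lick_t = c(t0, trials$last_central_lick_t[k],
                 lat1, lat1 + 140, lat1 + 280, lat1 + 420)
    )
  }))
  spikes <- tibble::tibble(
    neuron_id = rep(1:2, each = 4),
    region = "aIC",
    spike_t = c(1010, 1055, 1090, 11020, 1100, 11100, 21100, 21500)
  )
  taste_session(trials, spikes, licks, session_id = "toy")
}

# independent auROC oracle: exhaustive pair counting
auroc_oracle <- function(x_a, x_b) {
  s <- 0
  for (a in x_a) for (b in x_b) s <- s + (b > a) + 0.5 * (b == a)
  s / (length(x_a) * length(x_b))
}

# independent sliding-window counting oracle (naive O(spikes x bins) loop)
sliding_oracle <- function(spikes, align, epoch) {
  B <- epoch$n_bins
  out <- numeric(B)
  for (b in seq_len(B)) {
    lo <- align + epoch$t_start + (b - 1) * epoch$s
    n <- 0
    for (sp in spikes) if (sp >= lo && sp < lo + epoch$w) n <- n + 1
    out[b] <- n * 1000 / epoch$w
  }
  out
}

# independent threshold-classifier oracle: try every cut and direction
threshold_oracle <- function(rates, labels) {
  high <- levels(factor(labels))[2]
  cand <- c(-Inf, sort(unique(rates)), Inf)
  best <- -1
  for (th in cand) {
    for (dir in c("high", "low")) {
      pred <- if (dir == "high") rates > th else rates < th
      best <- max(best, mean(pred == (labels == high)))
    }
  }
  best
}

# build a selectivity object by hand for rule-level tests
fake_selectivity <- function(A, p = NULL, C = NULL, alpha = 0.05,
                             contrast = "choice", t_start = 0, s = 10,
                             w = 100) {
  B <- ncol(A)
  p <- p %||% matrix(0.001, nrow(A), B)
  sig <- p <= alpha & abs(A - 0.5) >= 0.1 - 1e-12
  structure(
    list(A = A, p = p, sig = sig, C = C, contrast = contrast,
         epoch = epoch_spec(contrast, "x", t_start, t_start + (B - 1) * s + w,
                            w = w, s = s),
         neuron_ids = seq_len(nrow(A)),
         bin_centers = t_start + (seq_len(B) - 1) * s + w / 2,
         class_levels = c("water", "sucrose"),
         n_class = c(a = 10, b = 10), alpha = alpha, n_perm = 1000,
         valid = TRUE),
    class = "selectivity"
  )
}

`%||%` <- function(x, y) if (is.null(x)) y else x
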