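# Sliding-window rate tensors, Gaussian-kernel smoothing, and lick-based
# time warping.

new_rate_tensor <- function(rates, neuron_ids, trial_ids, epoch) {
  structure(list(rates = rates, neuron_ids = neuron_ids,
                 trial_ids = trial_ids, epoch = epoch),
            class = "rate_tensor")
}

#' @export
print.rate_tensor <- function(x, ...) {
  d <- dim(x$rates)
  cat(sprintf("<rate_tensor> %d neurons x %d trials x %d bins (%s epoch)\n",
              d[1], d[2], d[3], x$epoch$name))
  invisible(x)
}

#' @export
dim.rate_tensor <- function(x) dim(x$rates)

# counts of events in half-open sliding windows [L, L + w); exact at edges
window_counts <- function(rel, L, w) {
  if (length(rel) == 0) return(numeric(length(L)))
  colSums(outer(rel, L, ">=") & outer(rel, L + w, "<"))
}

build_tensor <- function(event_lists, trials, epoch) {
  B <- epoch$n_bins
  L <- epoch$t_start + (seq_len(B) - 1) * epoch$s
  align <- trials[[epoch$align_event]]
  n_neur <- length(event_lists)
  n_tr <- nrow(trials)
  rates <- array(0, dim = c(n_neur, n_tr, B))
  for (i in seq_len(n_neur)) {
    ev <- event_lists[[i]]
    for (k in seq_len(n_tr)) {
      rel <- ev[[k]] - align[k]
      rel <- rel[rel >= epoch$t_start & rel < epoch$t_end]
      rates[i, k, ] <- window_counts(rel, L, epoch$w) * 1000 / epoch$w
    }
  }
  rates
}

#' Sliding-window firing rates aligned to a trial event
#'
#' For every neuron, trial and window, the firing rate (Hz) is the spike
#' count in the half-open window `[align + t0, align + t0 + w)` scaled by
#' `1000 / w`. Windows follow the epoch's 100 ms / 10 ms default grid and
#' are timestamped at their centres. Trials whose alignment event is
#' undefined (e.g. aborted trials without feedback) are excluded.
#'
#' @param session A `taste_session`.
#' @param epoch An [epoch_spec()]; defaults to [epoch_defaults()] for its
#'   name when a character is given.
#' @param trial_filter Optional predicate `function(trials) -> logical`
#'   restricting the trials used (e.g. correct trials only).
#' @return A `rate_tensor`: neurons x trials x bins array plus ids and the
#'   epoch. Convert to a long tibble with [tidy()].
#' @export
sliding_rates <- function(session, epoch, trial_filter = NULL) {
  if (is.character(epoch)) epoch <- epoch_defaults(epoch)
  trials <- usable_trials(session, epoch$align_event)
  if (!is.null(trial_filter)) trials <- trials[trial_filter(trials), , drop = FALSE]
  abort_if(nrow(trials) == 0, "no usable trials for this epoch")
  neuron_ids <- sort(unique(session$spikes$neuron_id))
  by_neuron <- split(session$spikes$spike_t, session$spikes$neuron_id)
  # slice each neuron's spikes per trial so inner loops stay small
  event_lists <- lapply(neuron_ids, function(id) {
    sp <- by_neuron[[as.character(id)]] %||% numeric(0)
    lapply(seq_len(nrow(trials)), function(k) {
      a <- trials[[epoch$align_event]][k]
      sp[sp >= a + epoch$t_start & sp < a + epoch$t_end]
    })
  })
  rates <- build_tensor(event_lists, trials, epoch)
  new_rate_tensor(rates, neuron_ids, trials$trial_id, epoch)
}

#' Sliding-window lick rates
#'
#' Identical contract to [sliding_rates()] with the animal's licks as the
#' event train: one "unit" per session whose events are the trial's lick
#' times (optionally restricted by spout).
#'
#' @param session A `taste_session`.
#' @param epoch An [epoch_spec()] or epoch name.
#' @param spout `"all"`, `"central"`, or `"lateral"`.
#' @param trial_filter Optional predicate on the trials tibble.
#' @return A `rate_tensor` with a single row (`neuron_id = 0`).
#' @export
lick_rates <- function(session, epoch, spout = "all", trial_filter = NULL) {
  if (is.character(epoch)) epoch <- epoch_defaults(epoch)
  trials <- usable_trials(session, epoch$align_event)
  if (!is.null(trial_filter)) trials <- trials[trial_filter(trials), , drop = FALSE]
  abort_if(nrow(trials) == 0, "no usable trials for this epoch")
  lk <- session$licks
  lk <- switch(spout,
               all = lk,
               central = lk[lk$spout == "central", ],
               lateral = lk[lk$spout != "central", ])
  by_trial <- split(lk$lick_t, lk$trial_id)
  event_lists <- list(lapply(as.character(trials$trial_id),
                             function(id) by_trial[[id]] %||% numeric(0)))
  rates <- build_tensor(event_lists, trials, epoch)
  new_rate_tensor(rates, 0L, trials$trial_id, epoch)
}

#' Warp spike times onto a normalized lick clock
#'
#' Piecewise-linear map sending the k-th lick (k = 0, 1, ...) to
#' `k * target_ili` ms; a spike at fraction `f` through inter-lick interval
#' k maps to `(k + f) * target_ili`. Spikes before the first or after the
#' last lick have no behavioural correspondence and are discarded. The map
#' is monotone, continuous, exact at lick times, and the identity when all
#' intervals already equal `target_ili`.
#'
#' @param spike_ts Spike times, ms.
#' @param lick_ts Lick times, ms (at least two).
#' @param target_ili Normalized inter-lick interval, ms (140 by default).
#' @return Sorted warped spike times.
#' @export
warp_to_licks <- function(spike_ts, lick_ts, target_ili = 140) {
  lick_ts <- sort(lick_ts)
  abort_if(length(lick_ts) < 2, "warping needs at least two licks",
           class = "tastedyn_warp_error")
  nodes <- (seq_along(lick_ts) - 1) * target_ili
  w <- stats::approx(lick_ts, nodes, xout = spike_ts, rule = 1)$y
  sort(w[!is.na(w)])
}

# warped time of one lick within its own train
warp_event <- function(event_t, lick_ts, target_ili = 140) {
  lick_ts <- sort(lick_ts)
  idx <- which(abs(lick_ts - event_t) < 1e-9)
  abort_if(length(idx) == 0, "event is not a lick of this trial",
           class = "tastedyn_warp_error")
  (idx[1] - 1) * target_ili
}

#' Condition-averaged Gaussian-kernel firing rates
#'
#' Convolves each neuron's aligned spikes with a Gaussian kernel
#' (`sigma_k`, default 20 ms) on a 1 ms grid and averages over the trials
#' of each condition:
#' `rate(t) = mean over trials of sum_spikes 1000 * dnorm(t - t_spike, sigma_k)`.
#' No edge renormalization is applied (the kernel is truncated at the
#' epoch limits).
#'
#' @param session A `taste_session`.
#' @param align_event Trial column used as time zero.
#' @param t_range Length-2 numeric, ms relative to the event.
#' @param condition Tidy-evaluated expression on the trials tibble giving
#'   each trial's condition (e.g. `concentration` or
#'   `interaction(concentration, choice)`).
#' @param min_trials Minimum trials per condition; conditions below the
#'   threshold are dropped with a message.
#' @param trial_filter Optional predicate on the trials tibble.
#' @param sigma_k Kernel standard deviation, ms.
#' @return A `smoothed_rates` object: `rates` array (neurons x conditions x
#'   time), `grid` (ms), `neuron_ids`, `conditions`, `n_trials` per
#'   condition.
#' @export
kernel_rates <- function(session, align_event, t_range, condition,
                         min_trials = 2, trial_filter = NULL, sigma_k = 20) {
  trials <- usable_trials(session, align_event)
  if (!is.null(trial_filter)) trials <- trials[trial_filter(trials), , drop = FALSE]
  cond <- as.character(rlang::eval_tidy(rlang::enquo(condition), data = trials))
  counts <- table(cond)
  keep_conditions <- names(counts)[counts >= min_trials]
  dropped <- setdiff(names(counts), keep_conditions)
  if (length(dropped) > 0) {
    message("kernel_rates: dropping condition(s) below min_trials: ",
            paste(dropped, collapse = ", "))
  }
  abort_if(length(keep_conditions) == 0, "no condition meets min_trials")
  keep <- cond %in% keep_conditions
  trials <- trials[keep, , drop = FALSE]
  cond <- cond[keep]
  grid <- seq(t_range[1], t_range[2], by = 1)
  neuron_ids <- sort(unique(session$spikes$neuron_id))
  by_neuron <- split(session$spikes$spike_t, session$spikes$neuron_id)
  align <- trials[[align_event]]
  pad <- 4 * sigma_k
  rates <- array(0, dim = c(length(neuron_ids), length(keep_conditions),
                            length(grid)),
                 dimnames = list(NULL, keep_conditions, NULL))
  for (i in seq_along(neuron_ids)) {
    sp <- by_neuron[[as.character(neuron_ids[i])]] %||% numeric(0)
    for (j in seq_along(keep_conditions)) {
      tr_idx <- which(cond == keep_conditions[j])
      acc <- numeric(length(grid))
      for (k in tr_idx) {
        rel <- sp - align[k]
        rel <- rel[rel >= t_range[1] - pad & rel <= t_range[2] + pad]
        if (length(rel) > 0) {
          acc <- acc + 1000 *
            rowSums(stats::dnorm(outer(grid, rel, "-"), sd = sigma_k))
        }
      }
      rates[i, j, ] <- acc / length(tr_idx)
    }
  }
  structure(list(rates = rates, grid = grid, neuron_ids = neuron_ids,
                 conditions = keep_conditions,
                 n_trials = as.integer(counts[keep_conditions]),
                 align_event = align_event, sigma_k = sigma_k),
            class = "smoothed_rates")
}

#' @export
print.smoothed_rates <- function(x, ...) {
  cat(sprintf("<smoothed_rates> %d neurons x %d conditions x %d ms\n",
              length(x$neuron_ids), length(x$conditions), length(x$grid)))
  invisible(x)
}
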