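# Synthetic session generator: behaviour, lick trains, inhomogeneous-Poisson
# spike trains, and ground-truth population templates.

#' Behavioural generator configuration
#'
#' The synthetic rat reports "sucrose" with probability
#' `clip(a * c^b, lapse, 1 - lapse)` for concentration `c` (%w/v), and with
#' probability `lapse` on water trials (the false-alarm rate). Defaults give
#' an absolute threshold (`(0.5/a)^(1/b)`) of about 2.5 %w/v and an overall
#' accuracy near the 80%-correct training criterion, while keeping the
#' power law unclipped at every sucrose concentration so that psychometric
#' fitting can recover `a` and `b`.
#'
#' Lick trains use inter-lick intervals drawn from a Normal(`ili_mean`,
#' `ili_sd`) truncated at 60 ms; rats emit 2-3 dry licks at the central
#' spout (the stimulus drop arrives at the first), move to a lateral spout,
#' and lick it at least four times. Feedback (reward delivery or omission)
#' happens at the second lateral lick; rewarded rats keep licking to
#' consume the reward while unrewarded rats stop early.
#'
#' @param n_trials Number of trials.
#' @param water_fraction Probability that a trial's stimulus is water.
#' @param a,b Power-law psychometric parameters.
#' @param lapse Lapse/false-alarm rate, clipping the choice rule into
#'   `[lapse, 1 - lapse]`.
#' @param ili_mean,ili_sd Inter-lick interval mean and sd, ms.
#' @param movement_mean,movement_sd Central-to-lateral movement time, ms.
#' @return A `behavior_config` list.
#' @export
behavior_config <- function(n_trials = 200, water_fraction = 0.5,
                            a = 0.38, b = 0.30, lapse = 0.05,
                            ili_mean = 140, ili_sd = 15,
                            movement_mean = 400, movement_sd = 60) {
  abort_if(lapse < 0 || lapse >= 0.5, "lapse must be in [0, 0.5)")
  abort_if(a <= 0 || b <= 0, "power-law parameters a, b must be positive")
  abort_if(ili_sd < 0, "ili_sd must be non-negative")
  structure(list(n_trials = n_trials, water_fraction = water_fraction,
                 a = a, b = b, lapse = lapse,
                 ili_mean = ili_mean, ili_sd = ili_sd,
                 movement_mean = movement_mean, movement_sd = movement_sd),
            class = "behavior_config")
}

# truncated-normal inter-lick intervals (>= 60 ms)
r_ili <- function(n, mean, sd) pmax(stats::rnorm(n, mean, sd), 60)

#' Simulate the behaviour of one session
#'
#' Draws stimuli (water with probability `water_fraction`, otherwise
#' uniformly among the five sucrose concentrations), choices from the
#' clipped power-law rule, and builds every trial's event times from
#' simulated lick trains. Feedback is placed at the second lateral-spout
#' lick. Fully reproducible from `seed`.
#'
#' @param config A [behavior_config()].
#' @param seed Integer seed.
#' @return List with `trials` and `licks` tibbles (see [taste_session()]).
#' @export
simulate_behavior <- function(config = behavior_config(), seed = 1) {
  cfg <- config
  with_seed(derive_seed(seed, 101), {
    n <- cfg$n_trials
    is_water <- stats::runif(n) < cfg$water_fraction
    conc <- ifelse(is_water, 0,
                   sample(CONCENTRATIONS[-1], n, replace = TRUE))
    p_suc <- clip(cfg$a * conc^cfg$b, cfg$lapse, 1 - cfg$lapse)
    p_suc[conc == 0] <- cfg$lapse
    choice <- ifelse(stats::runif(n) < p_suc, "sucrose", "water")
    category <- ifelse(conc == 0, "water", "sucrose")
    correct <- choice == category

    trials <- vector("list", n)
    licks <- vector("list", n)
    t_base <- 1000 # leaves room for pre-stimulus analysis windows
    for (k in seq_len(n)) {
      n_central <- sample(2:3, 1)
      central <- t_base + c(0, cumsum(r_ili(n_central - 1, cfg$ili_mean, cfg$ili_sd)))
      stim_t <- central[1]
      last_central <- central[n_central]
      move <- max(stats::rnorm(1, cfg$movement_mean, cfg$movement_sd), 150)
      n_lat <- if (correct[k]) 10 + sample(0:4, 1) else 4 + sample(0:2, 1)
      lateral <- last_central + move +
        c(0, cumsum(r_ili(n_lat - 1, cfg$ili_mean, cfg$ili_sd)))
      feedback <- lateral[2]
      spout <- if (choice[k] == "water") "left" else "right"
      trials[[k]] <- tibble::tibble(
        trial_id = k, concentration = conc[k], choice = choice[k],
        outcome = if (correct[k]) "correct" else "incorrect",
        rewarded = correct[k],
        stimulus_delivery_t = stim_t, last_central_lick_t = last_central,
        feedback_t = feedback
      )
      licks[[k]] <- tibble::tibble(
        trial_id = k,
        spout = c(rep("central", n_central), rep(spout, n_lat)),
        lick_t = c(central, lateral)
      )
      t_base <- max(lateral) + 8000 # inter-trial interval keeps epochs apart
    }
    list(trials = dplyr::bind_rows(trials), licks = dplyr::bind_rows(licks))
  })
}

#' Neuron specification table for the spike simulator
#'
#' Each row describes one neuron: a baseline rate `lambda0` (Hz) plus, for
#' tuned neurons, a transient Gaussian rate bump of amplitude `delta` (Hz),
#' centre `mu` (ms relative to the tuned epoch's alignment event) and width
#' `sigma` (ms) added on trials matching the `preferred` condition.
#' "Switching" neurons carry a second bump (`mu2`, `sigma2`, `delta2`)
#' whose preferred condition is the opposite one, inverting the neuron's
#' selectivity mid-epoch.
#'
#' @param neuron_id Integer ids.
#' @param lambda0 Baseline rate, Hz.
#' @param tuned_variable One of `"stimulus_category"`, `"choice"`,
#'   `"outcome"`, `"none"`.
#' @param preferred Preferred condition (`water`/`sucrose` for stimulus and
#'   choice tuning, `correct`/`incorrect` for outcome tuning, `NA` for
#'   untuned neurons).
#' @param delta,mu,sigma First bump amplitude (Hz), centre and width (ms).
#' @param switch Logical; if `TRUE` the second bump is active.
#' @param mu2,sigma2,delta2 Second (opposite-preference) bump parameters.
#' @return Tibble of class `neuron_spec`.
#' @export
neuron_spec <- function(neuron_id, lambda0, tuned_variable = "none",
                        preferred = NA_character_, delta = 0, mu = NA_real_,
                        sigma = NA_real_, switch = FALSE, mu2 = NA_real_,
                        sigma2 = NA_real_, delta2 = 0) {
  out <- tibble::tibble(
    neuron_id = as.integer(neuron_id), lambda0 = lambda0,
    tuned_variable = tuned_variable, preferred = preferred,
    delta = delta, mu = mu, sigma = sigma,
    switch = switch, mu2 = mu2, sigma2 = sigma2, delta2 = delta2
  )
  abort_if(any(out$lambda0 < 0) || any(out$delta < 0) || any(out$delta2 < 0),
           "rates must be non-negative")
  abort_if(any(out$tuned_variable != "none" & (is.na(out$sigma) | out$sigma <= 0)),
           "tuned neurons need sigma > 0")
  class(out) <- c("neuron_spec", class(out))
  out
}

align_column <- function(tuned_variable) {
  switch(tuned_variable,
         stimulus_category = "stimulus_delivery_t",
         choice = "last_central_lick_t",
         outcome = "feedback_t",
         none = "stimulus_delivery_t")
}

trial_condition <- function(trials, tuned_variable) {
  switch(tuned_variable,
         stimulus_category = as.character(trials$category),
         choice = trials$choice,
         outcome = trials$outcome,
         none = rep(NA_character_, nrow(trials)))
}

opposite_condition <- function(x) {
  swap <- c(water = "sucrose", sucrose = "water",
            correct = "incorrect", incorrect = "correct")
  unname(swap[x])
}

#' Simulate spike trains for a trial set
#'
#' Spikes are drawn from an inhomogeneous Poisson process by thinning. The
#' rate on a trial is `lambda0` plus each bump's
#' `delta * exp(-(t - align - mu)^2 / (2 sigma^2))` when the trial matches
#' that bump's preferred condition. Spikes are generated in a window wide
#' enough to cover every analysis epoch of the trial; the quiet inter-trial
#' stretches carry no spikes (no analysis looks there).
#'
#' @param trials Trials tibble (with `category` column, as built by
#'   [taste_session()] or [simulate_behavior()]).
#' @param specs A [neuron_spec()] table.
#' @param seed Integer seed; each neuron gets an independent derived stream.
#' @param region Region label stamped on the spike table.
#' @return Tibble with `neuron_id`, `region`, `spike_t` (sorted per neuron).
#' @export
simulate_spikes <- function(trials, specs, seed = 1, region = "aIC") {
  if (!"category" %in% names(trials)) {
    trials$category <- stimulus_category(trials$concentration)
  }
  out <- vector("list", nrow(specs))
  for (i in seq_len(nrow(specs))) {
    sp <- specs[i, ]
    cond <- trial_condition(trials, sp$tuned_variable)
    align <- trials[[align_column(sp$tuned_variable)]]
    t_end_all <- pmax(trials$feedback_t, trials$last_central_lick_t,
                      na.rm = TRUE)
    spikes <- with_seed(derive_seed(seed, 1000 + sp$neuron_id), {
      res <- numeric(0)
      for (k in seq_len(nrow(trials))) {
        lo <- trials$stimulus_delivery_t[k] - 700
        hi <- t_end_all[k] + 1100
        lam_max <- sp$lambda0 + sp$delta + sp$delta2
        if (lam_max <= 0) next
        n_cand <- stats::rpois(1, lam_max * (hi - lo) / 1000)
        if (n_cand == 0) next
        tt <- sort(stats::runif(n_cand, lo, hi))
        lam <- rep(sp$lambda0, n_cand)
        if (sp$tuned_variable != "none" && !is.na(align[k])) {
          if (!is.na(cond[k]) && cond[k] == sp$preferred) {
            lam <- lam + sp$delta *
              exp(-(tt - align[k] - sp$mu)^2 / (2 * sp$sigma^2))
          }
          if (isTRUE(sp$switch) && !is.na(cond[k]) &&
              cond[k] == opposite_condition(sp$preferred)) {
            lam <- lam + sp$delta2 *
              exp(-(tt - align[k] - sp$mu2)^2 / (2 * sp$sigma2^2))
          }
        }
        keep <- stats::runif(n_cand) < lam / lam_max
        res <- c(res, tt[keep])
      }
      sort(res)
    })
    out[[i]] <- tibble::tibble(neuron_id = sp$neuron_id, region = region,
                               spike_t = spikes)
  }
  dplyr::bind_rows(out)
}

# ---- population templates ---------------------------------------------

template_specs <- function(template) {
  tile <- function(n, lo = 60, hi = 740) seq(lo, hi, length.out = n)
  switch(template,
    null = neuron_spec(
      neuron_id = 1:50,
      lambda0 = rep(c(2, 3, 4, 5, 6, 8), length.out = 50)
    ),
    perfect_sequence = neuron_spec(
      neuron_id = 1:20,
      lambda0 = 1,
      tuned_variable = "stimulus_category",
      preferred = "sucrose",
      delta = 30, mu = seq(20, 780, by = 40), sigma = 30
    ),
    encoders_mixed = dplyr::bind_rows(
      # 15 stimulus-tuned neurons tiling the stimulus epoch
      neuron_spec(1:15, lambda0 = rep(c(3, 4, 5), 5),
                  tuned_variable = "stimulus_category",
                  preferred = rep(c("sucrose", "water", "sucrose"), 5),
                  delta = 25, mu = tile(15), sigma = 60),
      # 16 plain choice-tuned neurons
      neuron_spec(16:31, lambda0 = rep(c(3, 5), 8),
                  tuned_variable = "choice",
                  preferred = rep(c("water", "sucrose"), 8),
                  delta = 25, mu = tile(16), sigma = 60),
      # 4 switching choice neurons: opposite preferences early vs late
      neuron_spec(32:35, lambda0 = 4,
                  tuned_variable = "choice",
                  preferred = c("water", "sucrose", "water", "sucrose"),
                  delta = 25, mu = c(120, 160, 200, 240), sigma = 50,
                  switch = TRUE, mu2 = c(520, 560, 600, 640), sigma2 = 50,
                  delta2 = 25),
      # 30 outcome-tuned neurons
      neuron_spec(36:65, lambda0 = rep(c(3, 4, 5), 10),
                  tuned_variable = "outcome",
                  preferred = rep(c("correct", "incorrect"), 15),
                  delta = 20, mu = tile(30), sigma = 70),
      # 35 untuned neurons
      neuron_spec(66:100, lambda0 = rep(c(2, 3, 4, 5, 6, 7, 8), 5))
    ),
    rlang::abort(sprintf("unknown template '%s'", template),
                 class = "tastedyn_argument_error")
  )
}

#' Generate a ground-truth population session
#'
#' Builds a full synthetic session from a named template plus the
#' per-neuron truth labels needed for recovery tests.
#'
#' Templates: `"encoders_mixed"` (100 neurons: 15 stimulus-tuned, 20
#' choice-tuned of which 4 switching, 30 outcome-tuned, 35 untuned, with
#' bump centres staggered across each epoch), `"null"` (50 untuned
#' neurons), `"perfect_sequence"` (20 neurons with non-overlapping bumps at
#' 20 distinct latencies uniformly spaced over 0-800 ms).
#'
#' @param template Template name.
#' @param seed Integer master seed; behaviour and every neuron's spikes
#'   derive their own streams from it, so the session is bit-reproducible.
#' @param config A [behavior_config()]; the default emulates a ~200-trial
#'   session at the trained rats' performance level.
#' @param region Region label for the session.
#' @return List with `session` (a [taste_session()]) and `ground_truth`
#'   (tibble: `neuron_id`, `tuned_variable`, `preferred`, `mu_ms`,
#'   `switch`).
#' @export
make_population <- function(template = c("encoders_mixed", "null",
                                         "perfect_sequence"),
                            seed = 1, config = behavior_config(),
                            region = "aIC") {
  template <- match.arg(template)
  specs <- template_specs(template)
  beh <- simulate_behavior(config, seed = seed)
  spikes <- simulate_spikes(beh$trials, specs, seed = seed, region = region)
  session <- taste_session(beh$trials, spikes, beh$licks,
                           session_id = paste0(template, "_", seed),
                           region = region, rat_id = "synthetic",
                           seed = seed)
  truth <- tibble::tibble(
    neuron_id = specs$neuron_id,
    tuned_variable = specs$tuned_variable,
    preferred = specs$preferred,
    mu_ms = specs$mu,
    switch = specs$switch
  )
  list(session = session, ground_truth = truth)
}
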