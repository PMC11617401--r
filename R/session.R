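#' Sucrose concentrations used in the categorization task
#'
#' The six stimulus concentrations (% w/v sucrose) delivered at the central
#' spout. Water (0%) is the stimulus on half of the trials; the five sucrose
#' concentrations share the other half.
#'
#' @export
CONCENTRATIONS <- c(0, 0.5, 1.3, 3.2, 7.9, 20)

#' Stimulus category implied by a concentration
#'
#' @param concentration Numeric vector of %w/v sucrose values, each one of
#'   `CONCENTRATIONS`.
#' @return Factor with levels `water`, `sucrose`; `water` iff the
#'   concentration is 0.
#' @export
stimulus_category <- function(concentration) {
  abort_if(!all(concentration %in% CONCENTRATIONS),
           "concentration must be one of 0, 0.5, 1.3, 3.2, 7.9, 20 %w/v",
           class = "tastedyn_validation_error")
  factor(ifelse(concentration == 0, "water", "sucrose"),
         levels = c("water", "sucrose"))
}

#' Construct a categorization session object
#'
#' Bundles the three tables that describe one recording session: a trials
#' table (stimulus, choice, outcome and event timestamps), a long table of
#' spike times, and a long table of lick times. All times are in
#' milliseconds on a shared session clock.
#'
#' @param trials Tibble with columns `trial_id`, `concentration`, `choice`,
#'   `outcome`, `rewarded`, `stimulus_delivery_t`, `last_central_lick_t`,
#'   `feedback_t`.
#' @param spikes Tibble with columns `neuron_id`, `region`, `spike_t`.
#' @param licks Tibble with columns `trial_id`, `spout` (one of `central`,
#'   `left`, `right`), `lick_t`.
#' @param session_id,region,rat_id,seed Session metadata. `region` is one of
#'   `"aIC"` (anterior insular cortex) or `"OFC"` (orbitofrontal cortex).
#' @param validate Run [validate_session()] on the result (default `TRUE`).
#' @return A `taste_session` object (a named list of tibbles plus metadata).
#' @export
taste_session <- function(trials, spikes, licks, session_id = "s1",
                          region = c("aIC", "OFC"), rat_id = "r1",
                          seed = NA_integer_, validate = TRUE) {
  region <- match.arg(region)
  s <- structure(
    list(
      session_id = session_id, region = region, rat_id = rat_id, seed = seed,
      trials = tibble::as_tibble(trials),
      spikes = tibble::as_tibble(spikes),
      licks = tibble::as_tibble(licks)
    ),
    class = "taste_session"
  )
  s$trials$category <- stimulus_category(s$trials$concentration)
  if (validate) validate_session(s)
  s
}

#' @export
print.taste_session <- function(x, ...) {
  cat(sprintf(
    "<taste_session %s> region %s, %d trials, %d neurons, %d licks\n",
    x$session_id, x$region, nrow(x$trials),
    dplyr::n_distinct(x$spikes$neuron_id), nrow(x$licks)
  ))
  invisible(x)
}

#' Validate the internal consistency of a session
#'
#' Enforces the task's structural invariants on every trial: the outcome is
#' `correct` iff the choice matches the stimulus category; a trial is
#' rewarded iff correct; event times are ordered
#' `stimulus_delivery_t < last_central_lick_t <= first lateral lick <
#' feedback_t`; and `last_central_lick_t` equals the last central-spout lick
#' recorded for the trial. Trials with fewer than two lateral licks (early
#' aborts) are tolerated but flagged: their `feedback_t` must be `NA` and
#' they are skipped by outcome-epoch analyses.
#'
#' @param session A `taste_session`.
#' @return The session, invisibly. Throws a
#'   `tastedyn_validation_error` naming the first offending trial and rule.
#' @export
validate_session <- function(session) {
  tr <- session$trials
  fail <- function(id, rule) {
    rlang::abort(sprintf("trial %s: %s", id, rule),
                 class = "tastedyn_validation_error")
  }
  abort_if(anyDuplicated(tr$trial_id) > 0, "duplicated trial_id",
           class = "tastedyn_validation_error")
  stimulus_category(tr$concentration) # validates the concentration set
  licks <- split(session$licks, session$licks$trial_id)
  for (i in seq_len(nrow(tr))) {
    t <- tr[i, ]
    cat_i <- if (t$concentration == 0) "water" else "sucrose"
    if ((t$outcome == "correct") != (t$choice == cat_i)) {
      fail(t$trial_id, "outcome inconsistent with choice and stimulus category")
    }
    if (t$rewarded != (t$outcome == "correct")) {
      fail(t$trial_id, "rewarded must equal (outcome == correct)")
    }
    lk <- licks[[as.character(t$trial_id)]]
    central <- lk$lick_t[lk$spout == "central"]
    lateral <- sort(lk$lick_t[lk$spout != "central"])
    if (length(central) > 0) {
      if (!isTRUE(all.equal(max(central), t$last_central_lick_t))) {
        fail(t$trial_id, "last_central_lick_t != max(central lick times)")
      }
      if (!(t$stimulus_delivery_t < t$last_central_lick_t)) {
        fail(t$trial_id, "stimulus_delivery_t must precede last_central_lick_t")
      }
    }
    if (length(lateral) >= 2) {
      if (!(t$last_central_lick_t <= lateral[1])) {
        fail(t$trial_id, "first lateral lick precedes last central lick")
      }
      if (!is.na(t$feedback_t)) {
        if (!isTRUE(all.equal(lateral[2], t$feedback_t))) {
          fail(t$trial_id, "feedback_t != second lateral lick")
        }
        if (!(lateral[1] < t$feedback_t)) {
          fail(t$trial_id, "feedback_t must follow the first lateral lick")
        }
      }
    } else if (!is.na(t$feedback_t)) {
      fail(t$trial_id, "feedback_t set but fewer than two lateral licks")
    }
  }
  sp <- session$spikes
  if (nrow(sp) > 0) {
    abort_if(any(sp$spike_t < 0), "negative spike times",
             class = "tastedyn_validation_error")
    if (is.unsorted(sp$spike_t[order(sp$neuron_id)], strictly = FALSE)) {
      # per-neuron ordering checked below instead
    }
    bad <- sp |>
      dplyr::group_by(.data$neuron_id) |>
      dplyr::summarise(unsorted = is.unsorted(.data$spike_t)) |>
      dplyr::filter(.data$unsorted)
    abort_if(nrow(bad) > 0,
             paste("spike times not sorted for neuron(s):",
                   paste(bad$neuron_id, collapse = ", ")),
             class = "tastedyn_validation_error")
  }
  invisible(session)
}

#' Trials usable for a given epoch
#'
#' @param session A `taste_session`.
#' @param align_event Name of the trial column holding the alignment event.
#' @return The trials tibble restricted to trials where the event is defined.
#' @export
usable_trials <- function(session, align_event) {
  tr <- session$trials
  tr[!is.na(tr[[align_event]]), , drop = FALSE]
}

# ---- epochs ------------------------------------------------------------

#' Define a sliding-window analysis epoch
#'
#' An epoch is a window of interest around a trial event, tiled with
#' overlapping firing-rate windows of size `w` moving in steps of `s`
#' (defaults 100 ms and 10 ms). Each window is half-open `[t0, t0 + w)` and
#' is timestamped at its centre.
#'
#' @param name Epoch label (`stimulus`, `choice`, `outcome`, or free text).
#' @param align_event Trial column used as time zero
#'   (`stimulus_delivery_t`, `last_central_lick_t`, or `feedback_t`).
#' @param t_start,t_end Epoch limits in ms relative to the align event.
#' @param w,s Window size and step in ms.
#' @return An `epoch_spec` with the bin count `n_bins` and `bin_centers`.
#' @export
epoch_spec <- function(name, align_event, t_start, t_end, w = 100, s = 10) {
  abort_if(!(t_start < t_end) || w <= 0 || s <= 0,
           "need t_start < t_end, w > 0, s > 0")
  B <- floor((t_end - t_start - w) / s) + 1
  abort_if(B < 1, "epoch too short for a single window")
  structure(
    list(name = name, align_event = align_event,
         t_start = t_start, t_end = t_end, w = w, s = s, n_bins = as.integer(B),
         bin_centers = t_start + (seq_len(B) - 1) * s + w / 2),
    class = "epoch_spec"
  )
}

#' Default epochs for the three task variables
#'
#' Stimulus: -400 to +800 ms around stimulus delivery. Choice: -300 to
#' +800 ms around the last lick to the central (stimulus) spout. Outcome:
#' -300 to +800 ms around feedback (the second lick to the chosen lateral
#' spout, when reward is delivered or omitted). All use 100 ms windows
#' moving in 10 ms steps.
#'
#' @param name One of `"stimulus"`, `"choice"`, `"outcome"`.
#' @return An [epoch_spec()].
#' @export
epoch_defaults <- function(name = c("stimulus", "choice", "outcome")) {
  name <- match.arg(name)
  switch(name,
    stimulus = epoch_spec("stimulus", "stimulus_delivery_t", -400, 800),
    choice   = epoch_spec("choice",   "last_central_lick_t", -300, 800),
    outcome  = epoch_spec("outcome",  "feedback_t",          -300, 800)
  )
}

#' @export
print.epoch_spec <- function(x, ...) {
  cat(sprintf("<epoch_spec %s> align %s, [%g, %g] ms, w=%g s=%g, %d bins\n",
              x$name, x$align_event, x$t_start, x$t_end, x$w, x$s, x$n_bins))
  invisible(x)
}

# ---- on-disk layout ----------------------------------------------------

#' Write a session to its on-disk TSV/JSON layout
#'
#' Produces `trials.tsv`, `spikes.tsv`, `licks.tsv` and `session.json` in
#' `path`. Files are tab-delimited with a header row, UTF-8, `.` decimal
#' separator; content is deterministic for a fixed session.
#'
#' @param session A `taste_session`.
#' @param path Directory (created if absent).
#' @return `path`, invisibly.
#' @export
write_session <- function(session, path) {
  dir.create(path, recursive = TRUE, showWarnings = FALSE)
  abort_if(!dir.exists(path), sprintf("cannot create directory '%s'", path),
           class = "tastedyn_io_error")
  tr <- session$trials[order(session$trials$trial_id),
                       c("trial_id", "concentration", "choice", "outcome",
                         "rewarded", "stimulus_delivery_t",
                         "last_central_lick_t", "feedback_t")]
  readr::write_tsv(tr, file.path(path, "trials.tsv"))
  sp <- session$spikes[order(session$spikes$neuron_id, session$spikes$spike_t),
                       c("neuron_id", "region", "spike_t")]
  readr::write_tsv(sp, file.path(path, "spikes.tsv"))
  lk <- session$licks[order(session$licks$trial_id, session$licks$lick_t),
                      c("trial_id", "spout", "lick_t")]
  readr::write_tsv(lk, file.path(path, "licks.tsv"))
  meta <- list(session_id = session$session_id, region = session$region,
               rat_id = session$rat_id, seed = session$seed)
  jsonlite::write_json(meta, file.path(path, "session.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' Load a session from its on-disk layout
#'
#' Reads the layout written by [write_session()] and validates every trial
#' invariant.
#'
#' @param path Directory containing `trials.tsv`, `spikes.tsv`, `licks.tsv`
#'   and `session.json`.
#' @return A validated `taste_session`.
#' @export
load_session <- function(path) {
  need <- c("trials.tsv", "spikes.tsv", "licks.tsv", "session.json")
  for (f in need) {
    abort_if(!file.exists(file.path(path, f)),
             sprintf("missing session file '%s' in '%s'", f, path),
             class = "tastedyn_io_error")
  }
  cols_tr <- readr::cols(
    trial_id = readr::col_integer(), concentration = readr::col_double(),
    choice = readr::col_character(), outcome = readr::col_character(),
    rewarded = readr::col_logical(), stimulus_delivery_t = readr::col_double(),
    last_central_lick_t = readr::col_double(), feedback_t = readr::col_double()
  )
  trials <- readr::read_tsv(file.path(path, "trials.tsv"),
                            col_types = cols_tr, progress = FALSE)
  spikes <- readr::read_tsv(file.path(path, "spikes.tsv"),
                            col_types = readr::cols(
                              neuron_id = readr::col_integer(),
                              region = readr::col_character(),
                              spike_t = readr::col_double()
                            ), progress = FALSE)
  licks <- readr::read_tsv(file.path(path, "licks.tsv"),
                           col_types = readr::cols(
                             trial_id = readr::col_integer(),
                             spout = readr::col_character(),
                             lick_t = readr::col_double()
                           ), progress = FALSE)
  meta <- jsonlite::read_json(file.path(path, "session.json"))
  taste_session(trials, spikes, licks,
                session_id = meta$session_id %||% basename(path),
                region = meta$region %||% "aIC",
                rat_id = meta$rat_id %||% NA_character_,
                seed = meta$seed %||% NA_integer_)
}
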