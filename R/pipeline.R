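# End-to-end orchestration: simulate/load -> bin -> screen -> sequences ->
# decode -> psychometrics -> PCA, with a JSON-serializable report.

#' Pipeline run configuration
#'
#' Every stage's seed derives deterministically from `seed`, so a run is
#' idempotent given its configuration.
#'
#' @param template Generator template for [make_population()], or `NULL`
#'   when `session` is supplied to [run_all()] directly.
#' @param seed Master seed.
#' @param behavior A [behavior_config()].
#' @param n_perm Label permutations per window for the encoding screen.
#' @param alpha Per-window significance level.
#' @param min_run Consecutive qualifying windows required of an encoder.
#' @param decoding A [decoding_config()] (`NULL` skips decoding);
#'   `decode_bin_stride` thins the decoded windows.
#' @param decode_bin_stride Decode every k-th window.
#' @param n_components Principal components for trajectories/distances.
#' @param do_pca,do_decoding Stage switches.
#' @param region Region label for simulated sessions.
#' @return A `run_config` list.
#' @export
run_config <- function(template = "encoders_mixed", seed = 1,
                       behavior = behavior_config(), n_perm = 1000,
                       alpha = 0.05, min_run = 5,
                       decoding = decoding_config(),
                       decode_bin_stride = 10, n_components = 3,
                       do_pca = TRUE, do_decoding = TRUE, region = "aIC") {
  structure(list(template = template, seed = seed, behavior = behavior,
                 n_perm = n_perm, alpha = alpha, min_run = min_run,
                 decoding = decoding, decode_bin_stride = decode_bin_stride,
                 n_components = n_components, do_pca = do_pca,
                 do_decoding = do_decoding, region = region),
            class = "run_config")
}

#' Run the full encoding-dynamics pipeline on one session
#'
#' Executes, per task variable (stimulus, choice, outcome): sliding-window
#' auROC screening with permutation significance, encoder detection,
#' sequentiality (PE/TS/SqI) of the rectified encoder matrix, and
#' split-half reproducibility. Adds the behavioural power-law psychometric
#' fit, binary and six-class stimulus decoding with a permuted-label
#' control (when enabled), and PCA trajectory variance/distances (when
#' enabled). All thresholds are echoed into the report.
#'
#' @param config A [run_config()].
#' @param session Optional pre-built `taste_session`; otherwise the
#'   configured template is simulated.
#' @param out_dir Optional directory; the report is written there as
#'   `report.json`.
#' @return A `taste_report` list; see the methods vignette for the schema.
#' @export
run_all <- function(config = run_config(), session = NULL, out_dir = NULL) {
  truth <- NULL
  if (is.null(session)) {
    pop <- make_population(config$template, seed = config$seed,
                           config = config$behavior, region = config$region)
    session <- pop$session
    truth <- pop$ground_truth
  }
  report <- list(
    session_id = session$session_id, region = session$region,
    n_trials = nrow(session$trials),
    n_neurons = dplyr::n_distinct(session$spikes$neuron_id),
    parameters = list(n_perm = config$n_perm, alpha = config$alpha,
                      min_run = config$min_run,
                      auroc_thresholds = c(0.4, 0.6),
                      class_orientation = "water/water-response/non-rewarded low; sucrose/sucrose-response/rewarded high",
                      seed = config$seed)
  )
  contrasts <- c("stimulus", "choice", "outcome")
  screens <- list()
  encoders <- list()
  for (ct in contrasts) {
    stage <- tryCatch({
      sm <- screen_session(session, ct, n_perm = config$n_perm,
                           alpha = config$alpha,
                           seed = derive_seed(config$seed, match(ct, contrasts)))
      enc <- detect_encoders(sm, min_run = config$min_run)
      enc_ids <- enc$neuron_id[enc$is_encoder]
      seqres <- NULL
      repres <- NULL
      if (length(enc_ids) >= 2) {
        R <- rectify(sm, neurons = enc_ids)
        if (all(rowSums(R) > 0)) {
          seqres <- sequentiality(R)
        }
        ep <- sm$epoch
        rt <- sliding_rates(session, ep)
        tr <- usable_trials(session, ep$align_event)
        labels <- switch(ct,
          stimulus = factor(tr$category, levels = c("water", "sucrose")),
          choice = factor(tr$choice, levels = c("water", "sucrose")),
          outcome = factor(ifelse(tr$rewarded, "rewarded", "non-rewarded"),
                           levels = c("non-rewarded", "rewarded")))
        repres <- tryCatch(
          split_half_reproducibility(rt, labels, n_perm = config$n_perm,
                                     seed = derive_seed(config$seed, 60 + match(ct, contrasts)),
                                     neurons = enc_ids),
          error = function(e) NULL)
      }
      list(sm = sm, enc = enc, seqres = seqres, repres = repres)
    }, error = function(e) {
      rlang::abort(sprintf("stage '%s screen' failed: %s", ct,
                           conditionMessage(e)), parent = e)
    })
    screens[[ct]] <- stage$sm
    encoders[[ct]] <- stage$enc
    n <- nrow(stage$enc)
    k <- sum(stage$enc$is_encoder)
    report$contrasts[[ct]] <- list(
      n_neurons = n, n_encoders = k, pct_encoders = round(100 * k / n, 2),
      sequentiality = if (!is.null(stage$seqres)) {
        as.list(stage$seqres[, c("PE", "TS", "SqI", "N", "B")])
      },
      reproducibility = if (!is.null(stage$repres)) {
        as.list(stage$repres[, c("mse", "p")])
      }
    )
  }

  report$psychometric <- tryCatch({
    fit <- fit_power_psychometric(session$trials)
    list(a = fit$a, b = fit$b, r2 = fit$r2, threshold = fit$threshold)
  }, error = function(e) list(error = conditionMessage(e)))

  if (config$do_decoding && !is.null(config$decoding)) {
    stim_epoch <- epoch_defaults("stimulus")
    rt <- sliding_rates(session, stim_epoch,
                        trial_filter = function(tr) tr$outcome == "correct")
    tr <- usable_trials(session, stim_epoch$align_event)
    tr <- tr[tr$outcome == "correct", , drop = FALSE]
    enc_ids <- encoders$stimulus$neuron_id[encoders$stimulus$is_encoder]
    report$decoding <- tryCatch({
      rt_enc <- tensor_subset(rt, enc_ids)
      run_schema <- function(schema, permute) {
        cfg <- config$decoding
        cfg$schema <- schema
        cfg$permute_labels <- permute
        cfg$bin_stride <- config$decode_bin_stride
        cfg$seed <- derive_seed(config$seed, 70 + permute)
        labels <- if (schema == "binary") {
          factor(tr$category, levels = c("water", "sucrose"))
        } else {
          factor(tr$concentration)
        }
        decode_population(rt_enc, labels, cfg)
      }
      bin_res <- run_schema("binary", FALSE)
      six_res <- run_schema("six_class", FALSE)
      six_perm <- run_schema("six_class", TRUE)
      conf <- confusion_matrix(six_res)
      pat <- confusion_vs_patterns(conf)
      list(
        n_neurons = length(enc_ids),
        binary_peak_accuracy = max(bin_res$accuracy$mean_acc),
        six_class_peak_accuracy = max(six_res$accuracy$mean_acc),
        six_class_chance_accuracy = mean(six_perm$accuracy$mean_acc),
        mse_fine = pat$mse_fine, mse_gross = pat$mse_gross
      )
    }, error = function(e) list(error = conditionMessage(e)))
  }

  if (config$do_pca) {
    report$pca <- tryCatch({
      sm_rates <- kernel_rates(session, "stimulus_delivery_t", c(-400, 800),
                               condition = concentration, min_trials = 5,
                               trial_filter = function(tr) tr$outcome == "correct")
      ts <- pca_trajectories(condition_matrix(sm_rates),
                             n_components = config$n_components)
      d_ws <- trajectory_distances(ts, "water_sucrose", config$n_components)
      d_all <- trajectory_distances(ts, "all", config$n_components)
      list(explained = ts$explained[seq_len(min(3, length(ts$explained)))],
           mean_water_sucrose_distance = mean(d_ws$mean_dist),
           mean_all_pairs_distance = mean(d_all$mean_dist))
    }, error = function(e) list(error = conditionMessage(e)))
  }

  out <- structure(list(report = report, session = session, truth = truth,
                        screens = screens, encoders = encoders,
                        config = config),
                   class = "taste_report")
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    jsonlite::write_json(report, file.path(out_dir, "report.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE,
                         null = "null")
  }
  out
}

#' @export
print.taste_report <- function(x, ...) {
  r <- x$report
  cat(sprintf("<taste_report %s> %d trials, %d neurons\n",
              r$session_id, r$n_trials, r$n_neurons))
  for (ct in names(r$contrasts)) {
    cc <- r$contrasts[[ct]]
    cat(sprintf("  %-8s %d/%d encoders (%.2f%%)\n", ct, cc$n_encoders,
                cc$n_neurons, cc$pct_encoders))
  }
  invisible(x)
}

#' Compare two regions' pipeline reports
#'
#' Cross-region table of encoder counts with pooled two-proportion
#' z-tests, plus Kolmogorov-Smirnov comparisons of the encoder peak-time
#' distributions per contrast.
#'
#' @param report_a,report_b `taste_report` objects.
#' @return Tibble: one row per shared contrast with counts, percentages,
#'   `z`, `p_z`, `ks_d`, `p_ks`.
#' @export
compare_regions <- function(report_a, report_b) {
  contrasts <- intersect(names(report_a$encoders), names(report_b$encoders))
  abort_if(length(contrasts) == 0, "reports share no contrasts")
  purrr::map_dfr(contrasts, function(ct) {
    ea <- report_a$encoders[[ct]]
    eb <- report_b$encoders[[ct]]
    zt <- proportion_ztest(sum(ea$is_encoder), nrow(ea),
                           sum(eb$is_encoder), nrow(eb))
    pa <- ea$best_bin_center[ea$is_encoder]
    pb <- eb$best_bin_center[eb$is_encoder]
    ks <- if (length(pa) >= 3 && length(pb) >= 3) {
      latency_comparison(pa, pb,
                         region_names = c(report_a$report$region,
                                          report_b$report$region))
    } else {
      list(statistic = NA_real_, p = NA_real_)
    }
    tibble::tibble(
      contrast = ct,
      k_1 = sum(ea$is_encoder), n_1 = nrow(ea),
      pct_1 = round(100 * mean(ea$is_encoder), 2),
      k_2 = sum(eb$is_encoder), n_2 = nrow(eb),
      pct_2 = round(100 * mean(eb$is_encoder), 2),
      z = zt$z, p_z = zt$p, ks_d = ks$statistic, p_ks = ks$p
    )
  })
}
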