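# Resampled, cross-validated pseudo-population SVM decoding, confusion
# patterns, and the lick-warped behavioural control.

#' Decoding configuration
#'
#' Defaults follow the resampling scheme used throughout the decoding
#' analyses: an 8-fold cross-validated one-vs-one SVM on pseudo-trials,
#' with 15 neuron resamples x 10 trial resamples = 150 resamples and 8
#' trials per decoded condition (16 pseudo-trials for the binary
#' water-vs-sucrose schema, 48 for the six-concentration schema).
#'
#' @param schema `"binary"` (water vs sucrose) or `"six_class"` (the six
#'   concentrations).
#' @param kernel `"linear"`, `"gaussian"` (radial basis) or `"poly3"`
#'   (third-order polynomial).
#' @param folds Cross-validation folds.
#' @param n_neuron_resamples,n_trial_resamples Resampling depth (15 x 10).
#' @param trials_per_condition Pseudo-trials per condition (8).
#' @param permute_labels Shuffle labels before each resample's CV (chance
#'   control).
#' @param n_neurons Pseudo-population size per neuron resample (defaults
#'   to the number of available neurons).
#' @param bin_stride Decode every `bin_stride`-th window of the tensor
#'   (1 = all windows).
#' @param seed Master seed.
#' @return A `decoding_config` list.
#' @export
decoding_config <- function(schema = c("binary", "six_class"),
                            kernel = c("linear", "gaussian", "poly3"),
                            folds = 8, n_neuron_resamples = 15,
                            n_trial_resamples = 10,
                            trials_per_condition = 8,
                            permute_labels = FALSE, n_neurons = NULL,
                            bin_stride = 1, seed = 1) {
  structure(list(schema = match.arg(schema), kernel = match.arg(kernel),
                 folds = folds, n_neuron_resamples = n_neuron_resamples,
                 n_trial_resamples = n_trial_resamples,
                 trials_per_condition = trials_per_condition,
                 permute_labels = permute_labels, n_neurons = n_neurons,
                 bin_stride = bin_stride, seed = seed),
            class = "decoding_config")
}

svm_fit_predict <- function(train_x, train_y, test_x, kernel) {
  args <- switch(kernel,
                 linear = list(kernel = "linear"),
                 gaussian = list(kernel = "radial"),
                 poly3 = list(kernel = "polynomial", degree = 3))
  fit <- do.call(e1071::svm,
                 c(list(x = train_x, y = train_y, scale = FALSE), args))
  stats::predict(fit, test_x)
}

#' Assemble pseudo-trials for one resample
#'
#' For each condition, builds `t_c` pseudo-trials whose feature for neuron
#' n is the rate of a trial sampled with replacement from n's trials of
#' that condition, independently across neurons and pseudo-trials. The
#' same trial pick is used at every time window, preserving within-trial
#' dynamics.
#'
#' @param rates A `rate_tensor` (already restricted to the wanted neurons
#'   and trials).
#' @param labels Condition factor over the tensor's trials.
#' @param t_c Pseudo-trials per condition.
#' @param seed Integer seed.
#' @param neuron_idx Optional row indices (with repeats) forming the
#'   pseudo-population.
#' @return List: `features` (pseudo-trials x neurons x bins array) and
#'   `labels` (factor).
#' @export
build_pseudo_trials <- function(rates, labels, t_c = 8, seed = 1,
                                neuron_idx = NULL) {
  labels <- droplevels(factor(labels))
  X <- rates$rates
  n_neur_all <- dim(X)[1]
  neuron_idx <- neuron_idx %||% seq_len(n_neur_all)
  n_neur <- length(neuron_idx)
  B <- dim(X)[3]
  conds <- levels(labels)
  by_cond <- split(seq_along(labels), labels)
  short <- conds[vapply(by_cond, length, 0L) < t_c]
  abort_if(length(short) > 0,
           paste("conditions below the trial quota:",
                 paste(short, collapse = ", ")),
           class = "tastedyn_quota_error")
  n_pseudo <- t_c * length(conds)
  feats <- array(NA_real_, dim = c(n_pseudo, n_neur, B))
  lab_out <- factor(rep(conds, each = t_c), levels = conds)
  with_seed(seed, {
    row <- 0
    for (cond in conds) {
      pool <- by_cond[[cond]]
      for (j in seq_len(t_c)) {
        row <- row + 1
        picks <- pool[sample.int(length(pool), n_neur, replace = TRUE)]
        for (b in seq_len(B)) {
          feats[row, , b] <- X[cbind(neuron_idx, picks, b)]
        }
      }
    }
  })
  list(features = feats, labels = lab_out)
}

#' Resampled cross-validated population decoding
#'
#' Decodes the trial's condition from pseudo-population activity at every
#' time window: for each of the 150 neuron x trial resamples, pseudo-trials
#' are rebuilt, split into stratified folds (each fold holds one
#' pseudo-trial per condition with the default 8 trials per condition and
#' 8 folds), and an SVM trained on the out-of-fold trials classifies the
#' in-fold trials. Accuracy is the mean out-of-fold correct fraction,
#' averaged over resamples; predictions are also pooled into per-window
#' confusion counts.
#'
#' @param rates A `rate_tensor` restricted to the decoded neurons.
#' @param labels Condition factor over the tensor's trials (2 or 6
#'   levels).
#' @param config A [decoding_config()].
#' @return A `decoding_result`: `accuracy` tibble (`bin_center`,
#'   `mean_acc`, `sem_acc`), `resample_acc` matrix (resamples x bins),
#'   `confusion_counts` (true x predicted x bins), `class_levels`,
#'   `bin_centers`, `config`.
#' @export
decode_population <- function(rates, labels, config = decoding_config()) {
  labels <- droplevels(factor(labels))
  conds <- levels(labels)
  n_class <- length(conds)
  abort_if(!(n_class %in% c(2, 6)),
           "decoding expects 2 or 6 condition classes")
  t_c <- config$trials_per_condition
  K <- config$folds
  bins <- seq(1, dim(rates$rates)[3], by = config$bin_stride)
  centers <- rates$epoch$bin_centers[bins]
  n_res <- config$n_neuron_resamples * config$n_trial_resamples
  n_avail <- dim(rates$rates)[1]
  n_use <- config$n_neurons %||% n_avail
  acc <- matrix(NA_real_, n_res, length(bins))
  conf <- array(0, dim = c(n_class, n_class, length(bins)),
                dimnames = list(true = conds, pred = conds, NULL))
  res <- 0
  for (rn in seq_len(config$n_neuron_resamples)) {
    neuron_idx <- with_seed(derive_seed(config$seed, 20000 + rn), {
      sample.int(n_avail, n_use, replace = TRUE)
    })
    for (rt in seq_len(config$n_trial_resamples)) {
      res <- res + 1
      ps <- build_pseudo_trials(rates, labels, t_c = t_c,
                                seed = derive_seed(config$seed, 30000 + res),
                                neuron_idx = neuron_idx)
      y <- ps$labels
      if (config$permute_labels) {
        y <- with_seed(derive_seed(config$seed, 40000 + res), sample(y))
      }
      # stratified folds on the decoded labels (the permuted ones for the
      # chance control, so folds stay balanced and CV is unbiased at null)
      folds <- with_seed(derive_seed(config$seed, 50000 + res), {
        f <- integer(length(y))
        for (cond in conds) {
          i <- which(y == cond)
          f[i] <- sample(rep_len(seq_len(K), length(i)))
        }
        f
      })
      for (bi in seq_along(bins)) {
        Fmat <- ps$features[, , bins[bi], drop = FALSE][, , 1, drop = TRUE]
        if (is.null(dim(Fmat))) Fmat <- matrix(Fmat, ncol = 1)
        correct <- 0
        for (k in seq_len(K)) {
          te <- folds == k
          pred <- svm_fit_predict(Fmat[!te, , drop = FALSE], y[!te],
                                  Fmat[te, , drop = FALSE], config$kernel)
          correct <- correct + sum(pred == y[te])
          tt <- table(factor(y[te], levels = conds),
                      factor(pred, levels = conds))
          conf[, , bi] <- conf[, , bi] + tt
        }
        acc[res, bi] <- correct / length(y)
      }
    }
  }
  structure(
    list(accuracy = tibble::tibble(bin_center = centers,
                                   mean_acc = colMeans(acc),
                                   sem_acc = apply(acc, 2, sem)),
         resample_acc = acc, confusion_counts = conf,
         class_levels = conds, bin_centers = centers, config = config),
    class = "decoding_result"
  )
}

#' @export
print.decoding_result <- function(x, ...) {
  cat(sprintf(
    "<decoding_result> %s schema, %s kernel, %d resamples x %d bins; peak accuracy %.3f\n",
    x$config$schema, x$config$kernel, nrow(x$resample_acc),
    length(x$bin_centers), max(x$accuracy$mean_acc)))
  invisible(x)
}

#' Row-normalized confusion matrix pooled over a time range
#'
#' @param result A `decoding_result` (six-class schema).
#' @param window Length-2 numeric: windows with centres inside are pooled
#'   (300-840 ms after stimulus delivery by default).
#' @return Square matrix, rows (true class) summing to 1.
#' @export
confusion_matrix <- function(result, window = c(300, 840)) {
  keep <- result$bin_centers >= window[1] & result$bin_centers <= window[2]
  abort_if(!any(keep), "no decoded windows inside the requested range")
  pooled <- apply(result$confusion_counts[, , keep, drop = FALSE], c(1, 2), sum)
  sweep(pooled, 1, rowSums(pooled), "/")
}

#' Per-class correct-classification proportions
#'
#' The fraction of pseudo-trials of each true class that were correctly
#' labeled, pooled over the stated window range and all resamples (the
#' diagonal of [confusion_matrix()]).
#'
#' @inheritParams confusion_matrix
#' @return Named numeric vector, one entry per class.
#' @export
per_class_accuracy <- function(result, window = c(300, 840)) {
  diag(confusion_matrix(result, window))
}

#' Theoretical fine and gross confusion patterns
#'
#' `fine` is the 6x6 identity (every concentration classified exactly).
#' `gross` keeps only the water/sucrose distinction: the water row is
#' (1, 0, ..., 0) and each sucrose row spreads 1/5 over the five sucrose
#' columns.
#'
#' @param class_levels Condition names, water first.
#' @return List with matrices `fine` and `gross`.
#' @export
pattern_matrices <- function(class_levels = as.character(CONCENTRATIONS)) {
  n <- length(class_levels)
  fine <- diag(n)
  gross <- matrix(0, n, n)
  gross[1, 1] <- 1
  gross[2:n, 2:n] <- 1 / (n - 1)
  dimnames(fine) <- dimnames(gross) <- list(class_levels, class_levels)
  list(fine = fine, gross = gross)
}

#' Compare a confusion matrix against the fine and gross patterns
#'
#' @param C Row-normalized confusion matrix.
#' @return Tibble with `mse_fine` and `mse_gross` (elementwise mean
#'   squared differences).
#' @export
confusion_vs_patterns <- function(C) {
  pat <- pattern_matrices(colnames(C) %||% as.character(CONCENTRATIONS))
  tibble::tibble(mse_fine = mean((C - pat$fine)^2),
                 mse_gross = mean((C - pat$gross)^2))
}

#' Extended stimulus-decoding population
#'
#' Identifies neurons whose firing differs across the six stimulus
#' concentrations (one-way six-level ANOVA, any window with `p <= alpha`)
#' and removes neurons flagged as choice-encoding, yielding the extended
#' population used for stimulus decoding.
#'
#' @param rates A `rate_tensor` over correct trials of the stimulus epoch.
#' @param concentrations Numeric concentration per trial of the tensor.
#' @param choice_encoders Optional [detect_encoders()] tibble from the
#'   choice contrast; its encoders are excluded.
#' @param alpha Per-window significance level.
#' @return Integer vector of selected neuron ids.
#' @export
select_extended_population <- function(rates, concentrations,
                                       choice_encoders = NULL,
                                       alpha = 0.05) {
  g <- factor(concentrations)
  abort_if(min(table(g)) < 2, "need >= 2 correct trials per concentration")
  X <- rates$rates
  selected <- logical(dim(X)[1])
  for (i in seq_len(dim(X)[1])) {
    for (b in seq_len(dim(X)[3])) {
      x <- X[i, , b]
      if (stats::var(x) == 0) next
      pv <- stats::oneway.test(x ~ g, var.equal = TRUE)$p.value
      if (!is.na(pv) && pv <= alpha) {
        selected[i] <- TRUE
        break
      }
    }
  }
  ids <- rates$neuron_ids[selected]
  if (!is.null(choice_encoders)) {
    drop_ids <- choice_encoders$neuron_id[choice_encoders$is_encoder]
    ids <- setdiff(ids, drop_ids)
  }
  ids
}

# subset a rate tensor by neuron ids
tensor_subset <- function(rates, neurons) {
  keep <- rates$neuron_ids %in% neurons
  abort_if(!any(keep), "no neurons left after subsetting")
  new_rate_tensor(rates$rates[keep, , , drop = FALSE],
                  rates$neuron_ids[keep], rates$trial_ids, rates$epoch)
}

#' Neural versus licking decoding of the trial outcome
#'
#' Tests whether outcome-encoding activity reflects reward delivery or
#' merely the licking movements around it. Every trial's inter-lick
#' intervals are normalized to 140 ms and spike times are warped onto the
#' normalized clock, aligning lick cycles across trials; reward delivery
#' versus omission is then decoded (linear-kernel SVM, same resampling
#' scheme) once from the warped population rates and once from the warped
#' lick rate, over -400 to +800 ms around (warped) feedback. Per-window
#' significance of the accuracy difference comes from a bootstrap over
#' the 150 resample accuracies.
#'
#' @param session A `taste_session`.
#' @param outcome_neurons Neuron ids (the outcome-encoder subset).
#' @param config A [decoding_config()] (schema forced to binary, linear
#'   kernel).
#' @param n_boot Bootstrap iterations for the per-window test.
#' @param target_ili Normalized inter-lick interval, ms.
#' @return List: `accuracy` tibble (`bin_center`, `acc_neural`,
#'   `sem_neural`, `acc_lick`, `sem_lick`, `p_boot`), plus the two
#'   `decoding_result`s.
#' @export
outcome_vs_licking_control <- function(session, outcome_neurons,
                                       config = decoding_config(),
                                       n_boot = 10000, target_ili = 140) {
  config$schema <- "binary"
  config$kernel <- "linear"
  epoch <- epoch_spec("outcome_warped", "warped_feedback_t", -400, 800)
  licks_by_trial <- split(session$licks$lick_t, session$licks$trial_id)
  tr <- usable_trials(session, "feedback_t")
  spikes_by_neuron <- split(session$spikes$spike_t, session$spikes$neuron_id)
  outcome_neurons <- intersect(outcome_neurons,
                               sort(unique(session$spikes$neuron_id)))
  abort_if(length(outcome_neurons) == 0, "no outcome neurons available")

  warped_spikes <- vector("list", length(outcome_neurons))
  names(warped_spikes) <- as.character(outcome_neurons)
  warped_licks <- vector("list", nrow(tr))
  warped_feedback <- rep(NA_real_, nrow(tr))
  keep_trial <- logical(nrow(tr))
  for (k in seq_len(nrow(tr))) {
    lks <- sort(licks_by_trial[[as.character(tr$trial_id[k])]] %||% numeric(0))
    if (length(lks) < 2) next
    keep_trial[k] <- TRUE
    warped_licks[[k]] <- warp_to_licks(lks, lks, target_ili)
    warped_feedback[k] <- warp_event(tr$feedback_t[k], lks, target_ili)
    for (id in as.character(outcome_neurons)) {
      sp <- spikes_by_neuron[[id]] %||% numeric(0)
      warped_spikes[[id]][[k]] <- warp_to_licks(sp, lks, target_ili)
    }
  }
  abort_if(sum(keep_trial) == 0, "no trials with enough licks to warp",
           class = "tastedyn_warp_error")
  tr <- tr[keep_trial, , drop = FALSE]
  tr$warped_feedback_t <- warped_feedback[keep_trial]
  warped_licks <- warped_licks[keep_trial]

  neural_lists <- lapply(as.character(outcome_neurons),
                         function(id) warped_spikes[[id]][keep_trial])
  neural <- new_rate_tensor(build_tensor(neural_lists, tr, epoch),
                            outcome_neurons, tr$trial_id, epoch)
  lick_tensor <- new_rate_tensor(build_tensor(list(warped_licks), tr, epoch),
                                 0L, tr$trial_id, epoch)
  labels <- factor(ifelse(tr$rewarded, "rewarded", "non-rewarded"),
                   levels = c("non-rewarded", "rewarded"))

  res_neural <- decode_population(neural, labels, config)
  cfg_lick <- config
  cfg_lick$n_neurons <- 1
  cfg_lick$seed <- derive_seed(config$seed, 777)
  res_lick <- decode_population(lick_tensor, labels, cfg_lick)

  p_boot <- with_seed(derive_seed(config$seed, 888), {
    vapply(seq_along(res_neural$bin_centers), function(bi) {
      an <- res_neural$resample_acc[, bi]
      al <- res_lick$resample_acc[, bi]
      n <- length(an)
      d <- vapply(seq_len(n_boot), function(j) {
        mean(an[sample.int(n, n, replace = TRUE)]) -
          mean(al[sample.int(n, n, replace = TRUE)])
      }, numeric(1))
      min(1, 2 * min(mean(d <= 0), mean(d >= 0)))
    }, numeric(1))
  })
  accuracy <- tibble::tibble(
    bin_center = res_neural$bin_centers,
    acc_neural = res_neural$accuracy$mean_acc,
    sem_neural = res_neural$accuracy$sem_acc,
    acc_lick = res_lick$accuracy$mean_acc,
    sem_lick = res_lick$accuracy$sem_acc,
    p_boot = p_boot
  )
  list(accuracy = accuracy, neural = res_neural, lick = res_lick)
}
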