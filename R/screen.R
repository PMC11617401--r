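# Signal-detection screening of single neurons: auROC per sliding window,
# permutation significance, choice-probability disambiguation, and encoder
# detection/classification.

#' Area under the ROC curve between two rate samples
#'
#' The overlap statistic between two firing-rate distributions:
#' `P(X_b > X_a) + 0.5 * P(X_b = X_a)`, i.e. the Mann-Whitney U statistic
#' divided by `n_a * n_b` with half credit for ties. 0.5 means complete
#' overlap; 0 or 1 mean fully segregated distributions. By convention the
#' second sample is the high-coded class, and
#' `auroc(a, b) == 1 - auroc(b, a)`.
#'
#' @param x_a,x_b Numeric samples (class A coded low, class B coded high).
#' @return A value in `[0, 1]`.
#' @export
auroc <- function(x_a, x_b) {
  abort_if(length(x_a) == 0 || length(x_b) == 0,
           "auroc needs two non-empty samples",
           class = "tastedyn_contrast_error")
  r <- rank(c(x_a, x_b))
  n_a <- length(x_a)
  n_b <- length(x_b)
  (sum(r[(n_a + 1):(n_a + n_b)]) - n_b * (n_b + 1) / 2) / (n_a * n_b)
}

#' Two-tailed permutation p-value for an auROC
#'
#' Permutes class labels `n_perm` times and compares `|auROC - 0.5|`
#' against the null distribution:
#' `p = (1 + #permutations at least as extreme) / (n_perm + 1)`.
#'
#' @param x_a,x_b Numeric samples.
#' @param n_perm Number of label permutations (10,000 by default).
#' @param seed Integer seed.
#' @return p-value in `[1/(n_perm + 1), 1]`.
#' @export
permutation_pvalue <- function(x_a, x_b, n_perm = 10000, seed = 1) {
  n_a <- length(x_a)
  n_b <- length(x_b)
  abort_if(n_a + n_b < 2 || n_a == 0 || n_b == 0,
           "need both classes present", class = "tastedyn_contrast_error")
  r <- rank(c(x_a, x_b))
  n <- n_a + n_b
  c0 <- n_b * (n_b + 1) / 2
  obs <- abs((sum(r[(n_a + 1):n]) - c0) / (n_a * n_b) - 0.5)
  with_seed(seed, {
    extreme <- 0L
    for (j in seq_len(n_perm)) {
      idx <- sample.int(n, n_b)
      stat <- abs((sum(r[idx]) - c0) / (n_a * n_b) - 0.5)
      if (stat >= obs - 1e-12) extreme <- extreme + 1L
    }
    (1 + extreme) / (n_perm + 1)
  })
}

# Observed auROC for every neuron at one bin: ranks matrix trick.
# M: trials x neurons rate matrix; grp_b: logical, TRUE = class B trials.
auroc_columns <- function(M, grp_b) {
  n_b <- sum(grp_b)
  n_a <- sum(!grp_b)
  R <- apply(M, 2, rank)
  if (is.null(dim(R))) R <- matrix(R, ncol = ncol(M))
  (colSums(R[grp_b, , drop = FALSE]) - n_b * (n_b + 1) / 2) / (n_a * n_b)
}

#' Sliding-window selectivity matrix with permutation significance
#'
#' Computes, for every neuron and window of a rate tensor, the auROC
#' between the two label classes plus a two-tailed permutation p-value
#' (labels shuffled per time bin; one shared shuffle set per bin across
#' neurons). A window is marked significant when `p <= alpha` and the
#' auROC deviates from 0.5 by at least 0.1 (the 0.4/0.6 rule).
#'
#' For the stimulus contrast (water vs sucrose on correct trials) a
#' companion choice-probability matrix `C` — the auROC of the same neurons
#' with trials arranged by the animal's response, over correct and error
#' trials — can be supplied via `companion` to support disambiguation in
#' [detect_encoders()]. Use [screen_session()] to assemble all of this
#' from a session in one call.
#'
#' @param rates A `rate_tensor`.
#' @param labels Factor over the tensor's trials with exactly two levels,
#'   the first coded low (class A), the second high (class B).
#' @param contrast Label for the contrast (`stimulus`, `choice`,
#'   `outcome`).
#' @param n_perm Number of label permutations per bin.
#' @param alpha Per-bin significance level.
#' @param seed Master seed; each bin derives its own stream.
#' @param companion Optional list `list(rates =, labels =)` from which the
#'   choice-probability matrix is computed (auROC only, no permutations).
#' @return A `selectivity` object with matrices `A`, `p`, `sig` (neurons x
#'   bins), optional `C`, the epoch, class levels and counts.
#' @export
selectivity_matrix <- function(rates, labels, contrast = "stimulus",
                               n_perm = 10000, alpha = 0.05, seed = 1,
                               companion = NULL) {
  labels <- factor(labels)
  abort_if(nlevels(labels) != 2, "labels must have exactly two levels")
  X <- rates$rates
  n_neur <- dim(X)[1]
  n_tr <- dim(X)[2]
  B <- dim(X)[3]
  abort_if(length(labels) != n_tr, "labels must match the tensor's trials")
  grp_b <- labels == levels(labels)[2]
  n_b <- sum(grp_b)
  n_a <- n_tr - n_b
  A <- matrix(NA_real_, n_neur, B)
  p <- matrix(NA_real_, n_neur, B)
  valid <- n_a >= 2 && n_b >= 2
  if (valid) {
    c0 <- n_b * (n_b + 1) / 2
    for (b in seq_len(B)) {
      M <- matrix(aperm(X[, , b, drop = FALSE], c(2, 1, 3)), ncol = n_neur)
      R <- apply(M, 2, rank)
      if (is.null(dim(R))) R <- matrix(R, ncol = n_neur)
      A[, b] <- (colSums(R[grp_b, , drop = FALSE]) - c0) / (n_a * n_b)
      # permutation null: shared label shuffles per bin, one matrix product
      W <- with_seed(derive_seed(seed, b), {
        idx <- replicate(n_perm, sample.int(n_tr, n_b))
        Wm <- matrix(0, n_perm, n_tr)
        Wm[cbind(rep(seq_len(n_perm), each = n_b), as.vector(idx))] <- 1
        Wm
      })
      null_stat <- abs((W %*% R - c0) / (n_a * n_b) - 0.5)
      obs_stat <- abs(A[, b] - 0.5)
      exceed <- colSums(null_stat >= rep(obs_stat, each = n_perm) - 1e-12)
      p[, b] <- (1 + exceed) / (n_perm + 1)
    }
  }
  sig <- !is.na(p) & p <= alpha & abs(A - 0.5) >= 0.1 - 1e-12
  C <- NULL
  if (!is.null(companion)) {
    C <- auroc_matrix(companion$rates, companion$labels)
  }
  structure(
    list(A = A, p = p, sig = sig, C = C, contrast = contrast,
         epoch = rates$epoch, neuron_ids = rates$neuron_ids,
         bin_centers = rates$epoch$bin_centers,
         class_levels = levels(labels), n_class = c(a = n_a, b = n_b),
         alpha = alpha, n_perm = n_perm, valid = valid),
    class = "selectivity"
  )
}

#' auROC matrix without permutation testing
#'
#' @param rates A `rate_tensor`.
#' @param labels Two-level factor over its trials.
#' @return Neurons x bins matrix of auROC values.
#' @export
auroc_matrix <- function(rates, labels) {
  labels <- factor(labels)
  abort_if(nlevels(labels) != 2, "labels must have exactly two levels")
  X <- rates$rates
  grp_b <- labels == levels(labels)[2]
  B <- dim(X)[3]
  n_neur <- dim(X)[1]
  A <- matrix(NA_real_, n_neur, B)
  if (sum(grp_b) >= 1 && sum(!grp_b) >= 1) {
    for (b in seq_len(B)) {
      M <- matrix(aperm(X[, , b, drop = FALSE], c(2, 1, 3)), ncol = n_neur)
      A[, b] <- auroc_columns(M, grp_b)
    }
  }
  A
}

#' @export
print.selectivity <- function(x, ...) {
  cat(sprintf(
    "<selectivity %s> %d neurons x %d bins, classes %s (low) vs %s (high), n = %d/%d\n",
    x$contrast, nrow(x$A), ncol(x$A), x$class_levels[1], x$class_levels[2],
    x$n_class["a"], x$n_class["b"]))
  invisible(x)
}

#' Screen one session for encoding neurons of a task variable
#'
#' Assembles the rate tensor, labels and (for the stimulus contrast) the
#' choice-probability companion, then runs [selectivity_matrix()].
#' Stimulus: water vs sucrose stimulus, with the choice-probability
#' companion computed from the same trials arranged by the animal's
#' response (correct and error trials enter both, so the two indices
#' decorrelate and the `A > C` rule can tell stimulus from choice
#' encoding). Choice: water-response vs sucrose-response on all trials.
#' Outcome: non-rewarded vs rewarded on all trials with defined feedback.
#'
#' @param session A `taste_session`.
#' @param contrast `"stimulus"`, `"choice"` or `"outcome"`.
#' @param epoch Optional [epoch_spec()]; defaults to the contrast's
#'   standard epoch.
#' @param n_perm,alpha,seed Passed to [selectivity_matrix()].
#' @return A `selectivity` object.
#' @export
screen_session <- function(session, contrast = c("stimulus", "choice",
                                                 "outcome"),
                           epoch = NULL, n_perm = 10000, alpha = 0.05,
                           seed = 1) {
  contrast <- match.arg(contrast)
  epoch <- epoch %||% epoch_defaults(contrast)
  if (contrast == "stimulus") {
    # both auROCs from the same trials: arranged by the delivered stimulus
    # (A) or by the reported choice (C); correct and error trials included
    # so that stimulus and choice decorrelate and A > C can disambiguate
    rates <- sliding_rates(session, epoch)
    tr <- usable_trials(session, epoch$align_event)
    labels <- factor(tr$category, levels = c("water", "sucrose"))
    companion <- list(rates = rates,
                      labels = factor(tr$choice,
                                      levels = c("water", "sucrose")))
    selectivity_matrix(rates, labels, contrast, n_perm, alpha, seed,
                       companion = companion)
  } else if (contrast == "choice") {
    rates <- sliding_rates(session, epoch)
    tr <- usable_trials(session, epoch$align_event)
    labels <- factor(tr$choice, levels = c("water", "sucrose"))
    selectivity_matrix(rates, labels, contrast, n_perm, alpha, seed)
  } else {
    rates <- sliding_rates(session, epoch)
    tr <- usable_trials(session, epoch$align_event)
    labels <- factor(ifelse(tr$rewarded, "rewarded", "non-rewarded"),
                     levels = c("non-rewarded", "rewarded"))
    selectivity_matrix(rates, labels, contrast, n_perm, alpha, seed)
  }
}

#' Detect encoding neurons from a selectivity matrix
#'
#' A window qualifies when it is significant (`p <= alpha` and auROC >=
#' 0.6 or <= 0.4) and — for the stimulus contrast — the stimulus auROC is
#' more extreme than the corresponding choice-probability value in the
#' matching direction (`A > C` when `A >= 0.6`, `A < C` when `A <= 0.4`).
#' A neuron is an encoder when at least `min_run` consecutive windows
#' qualify. The best window is the qualifying window with maximal
#' `|auROC - 0.5|` (earliest on ties). Preference follows the sign of the
#' qualifying runs: all above 0.5 = high-class preferring, all below =
#' low-class preferring, both = switching.
#'
#' @param sm A `selectivity` object.
#' @param min_run Minimum run length of qualifying windows (5).
#' @return Tibble with one row per neuron: `neuron_id`, `is_encoder`,
#'   `best_bin`, `best_bin_center`, `best_auroc`, `preference`, `runs`
#'   (list-column of run start/length).
#' @export
detect_encoders <- function(sm, min_run = 5) {
  n_neur <- nrow(sm$A)
  out <- vector("list", n_neur)
  for (i in seq_len(n_neur)) {
    A <- sm$A[i, ]
    qual <- sm$sig[i, ] & (A >= 0.6 - 1e-12 | A <= 0.4 + 1e-12)
    if (!is.null(sm$C)) {
      Ci <- sm$C[i, ]
      qual <- qual & ((A >= 0.6 - 1e-12 & A > Ci) |
                        (A <= 0.4 + 1e-12 & A < Ci))
    }
    qual[is.na(qual)] <- FALSE
    r <- rle(qual)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1
    keep <- r$values & r$lengths >= min_run
    runs <- tibble::tibble(start = starts[keep], length = r$lengths[keep])
    is_enc <- nrow(runs) > 0
    best_bin <- NA_integer_
    best_auroc <- NA_real_
    pref <- NA_character_
    if (is_enc) {
      in_run <- unlist(mapply(function(s, l) s:(s + l - 1),
                              runs$start, runs$length, SIMPLIFY = FALSE))
      best_bin <- in_run[which.max(abs(A[in_run] - 0.5))]
      best_auroc <- A[best_bin]
      hi <- any(A[in_run] > 0.5)
      lo <- any(A[in_run] < 0.5)
      pref <- if (hi && lo) "switching"
              else if (hi) "classB_preferring" else "classA_preferring"
    }
    out[[i]] <- tibble::tibble(
      neuron_id = sm$neuron_ids[i], is_encoder = is_enc,
      best_bin = best_bin,
      best_bin_center = if (is_enc) sm$bin_centers[best_bin] else NA_real_,
      best_auroc = best_auroc, preference = pref, runs = list(runs)
    )
  }
  res <- dplyr::bind_rows(out)
  attr(res, "contrast") <- sm$contrast
  attr(res, "class_levels") <- sm$class_levels
  res
}

#' Two-proportion z-test
#'
#' Pooled two-proportion z statistic
#' `z = (p1 - p2) / sqrt(phat (1 - phat) (1/n1 + 1/n2))` with
#' `phat = (k1 + k2)/(n1 + n2)`, and its two-tailed normal p-value.
#'
#' @param k1,n1 Successes and size of the first sample.
#' @param k2,n2 Successes and size of the second sample.
#' @return Tibble with `z`, `p`, and the two proportions.
#' @export
proportion_ztest <- function(k1, n1, k2, n2) {
  abort_if(any(c(k1, k2) < 0) || k1 > n1 || k2 > n2 || min(n1, n2) < 1,
           "need 0 <= k <= n and n >= 1")
  p1 <- k1 / n1
  p2 <- k2 / n2
  pooled <- (k1 + k2) / (n1 + n2)
  if (pooled %in% c(0, 1)) {
    warning("pooled proportion is degenerate; z set to 0")
    z <- 0
  } else {
    z <- (p1 - p2) / sqrt(pooled * (1 - pooled) * (1 / n1 + 1 / n2))
  }
  tibble::tibble(z = z, p = 2 * stats::pnorm(-abs(z)), p1 = p1, p2 = p2)
}

#' Encoder count report with cross-region z-tests
#'
#' @param region_a,region_b Named lists (by contrast) of
#'   [detect_encoders()] tibbles, one per region.
#' @param region_names Length-2 character, region labels.
#' @return Tibble with counts, percentages (2 decimals) and the pooled
#'   two-proportion z-test per contrast.
#' @export
neuron_counts_report <- function(region_a, region_b,
                                 region_names = c("aIC", "OFC")) {
  contrasts <- intersect(names(region_a), names(region_b))
  abort_if(length(contrasts) == 0, "no shared contrasts between regions")
  purrr::map_dfr(contrasts, function(ct) {
    ka <- sum(region_a[[ct]]$is_encoder)
    na <- nrow(region_a[[ct]])
    kb <- sum(region_b[[ct]]$is_encoder)
    nb <- nrow(region_b[[ct]])
    zt <- proportion_ztest(ka, na, kb, nb)
    tibble::tibble(
      contrast = ct,
      region_1 = region_names[1], k_1 = ka, n_1 = na,
      pct_1 = round(100 * ka / na, 2),
      region_2 = region_names[2], k_2 = kb, n_2 = nb,
      pct_2 = round(100 * kb / nb, 2),
      z = zt$z, p = zt$p
    )
  })
}
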