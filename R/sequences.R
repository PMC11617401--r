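# Sequentiality of encoding: rectified selectivity matrices, peak entropy,
# temporal sparsity, the sequentiality index, split-half reproducibility,
# and latency-distribution comparisons.

#' Rectify a selectivity matrix
#'
#' Keeps only the encoding-relevant deviation from chance: entries become
#' `|auROC - 0.5|` where the deviation reaches 0.1 (i.e. auROC above 0.6
#' or below 0.4) and 0 elsewhere, restricted to windows whose centres fall
#' in `window` (0-800 ms after the alignment event by default).
#'
#' @param sm A `selectivity` object, or a plain neurons x bins auROC
#'   matrix (then `bin_centers` must be given).
#' @param window Length-2 numeric, ms.
#' @param neurons Optional neuron ids to keep (e.g. the encoder subset).
#' @param bin_centers Window centres when `sm` is a plain matrix.
#' @return Non-negative neurons x bins matrix with attributes
#'   `bin_centers` and `neuron_ids`.
#' @export
rectify <- function(sm, window = c(0, 800), neurons = NULL,
                    bin_centers = NULL) {
  if (inherits(sm, "selectivity")) {
    A <- sm$A
    centers <- sm$bin_centers
    ids <- sm$neuron_ids
  } else {
    A <- sm
    centers <- bin_centers
    abort_if(is.null(centers), "bin_centers required for a plain matrix")
    ids <- seq_len(nrow(A))
  }
  if (!is.null(neurons)) {
    keep <- ids %in% neurons
    A <- A[keep, , drop = FALSE]
    ids <- ids[keep]
  }
  in_win <- centers >= window[1] & centers <= window[2]
  A <- A[, in_win, drop = FALSE]
  dev <- abs(A - 0.5)
  R <- ifelse(!is.na(dev) & dev >= 0.1 - 1e-12, dev, 0)
  structure(R, bin_centers = centers[in_win], neuron_ids = ids)
}

row_peaks <- function(R) {
  abort_if(any(rowSums(R) == 0),
           "rectified matrix has all-zero rows; restrict to encoding neurons",
           class = "tastedyn_degenerate_error")
  apply(R, 1, which.max) # earliest bin on ties
}

#' Peak entropy of an encoding sequence
#'
#' Entropy (natural log, normalized by `log(B)`) of the distribution of
#' per-neuron peak windows across the `B` windows: 1 when peaks tile the
#' epoch uniformly, 0 when every neuron peaks in the same window.
#'
#' @param R Rectified matrix from [rectify()]; every row must have a
#'   nonzero entry.
#' @return Peak entropy in `[0, 1]`.
#' @export
peak_entropy <- function(R) {
  B <- ncol(R)
  if (B == 1) return(0)
  peaks <- row_peaks(R)
  q <- tabulate(peaks, nbins = B) / length(peaks)
  entropy_nat(q) / log(B)
}

#' Temporal sparsity of an encoding sequence
#'
#' One minus the normalized mean entropy of each window's activity shares
#' across neurons (windows with zero total activity are excluded from the
#' average): 1 when each window's encoding is attributable to a single
#' neuron, 0 when all neurons contribute equally at every moment.
#'
#' @param R Rectified matrix from [rectify()].
#' @return Temporal sparsity in `[0, 1]`.
#' @export
temporal_sparsity <- function(R) {
  N <- nrow(R)
  if (N == 1) return(1)
  tot <- colSums(R)
  abort_if(all(tot == 0), "no window with positive activity",
           class = "tastedyn_degenerate_error")
  H <- vapply(which(tot > 0), function(b) entropy_nat(R[, b] / tot[b]),
              numeric(1))
  1 - mean(H) / log(N)
}

#' Sequentiality index
#'
#' Combines peak entropy and temporal sparsity as their geometric mean,
#' `SqI = sqrt(PE * TS)`: near 1 when encoding peaks homogeneously tile
#' the epoch with non-overlapping encoding periods.
#'
#' @param pe,ts Peak entropy and temporal sparsity, each in `[0, 1]`.
#' @return SqI in `[0, 1]`.
#' @export
sequentiality_index <- function(pe, ts) {
  tol <- 1e-9 # tolerate floating overshoot from the entropy normalizations
  abort_if(any(pe < -tol | pe > 1 + tol | ts < -tol | ts > 1 + tol),
           "PE and TS must lie in [0, 1]")
  sqrt(clip(pe, 0, 1) * clip(ts, 0, 1))
}

#' Sequentiality summary of a rectified selectivity matrix
#'
#' @param R Rectified matrix from [rectify()] (rows = encoding neurons).
#' @return One-row tibble: `PE`, `TS`, `SqI`, `N` neurons, `B` windows,
#'   plus `peak_bins` as a list-column.
#' @export
sequentiality <- function(R) {
  pe <- peak_entropy(R)
  ts <- temporal_sparsity(R)
  tibble::tibble(PE = pe, TS = ts, SqI = sequentiality_index(pe, ts),
                 N = nrow(R), B = ncol(R), peak_bins = list(row_peaks(R)))
}

#' Row order that sorts neurons by encoding peak time
#'
#' @param R Rectified matrix.
#' @return Integer permutation ordering rows by ascending peak window,
#'   ties broken by neuron id (row order).
#' @export
sort_by_peak <- function(R) {
  order(row_peaks(R), seq_len(nrow(R)))
}

#' Split-half reproducibility of an encoding sequence
#'
#' Randomly partitions trials into stratified halves (by label class; the
#' extra trial of an odd class goes to half 1), computes the auROC matrix
#' of each half, and measures their mean squared elementwise difference
#' with rows matched. The null keeps matrix 1 fixed and shuffles the row
#' (neuron) correspondence of matrix 2; small p means the sequence
#' reproduces across trial splits beyond chance.
#'
#' @param rates A `rate_tensor` (typically restricted to encoder neurons
#'   via `neurons`).
#' @param labels Two-level factor over the tensor's trials.
#' @param n_perm Row-index permutations (10,000 by default).
#' @param seed Integer seed (drives both the split and the shuffles).
#' @param neurons Optional neuron ids to keep.
#' @return One-row tibble: `mse`, `p`, `n_neurons`, `n_bins`.
#' @export
split_half_reproducibility <- function(rates, labels, n_perm = 10000,
                                       seed = 1, neurons = NULL) {
  labels <- factor(labels)
  abort_if(nlevels(labels) != 2, "labels must have exactly two levels")
  X <- rates$rates
  ids <- rates$neuron_ids
  if (!is.null(neurons)) {
    keep <- ids %in% neurons
    X <- X[keep, , , drop = FALSE]
    ids <- ids[keep]
  }
  n_tr <- dim(X)[2]
  idx_by_class <- split(seq_len(n_tr), labels)
  abort_if(any(lengths(idx_by_class) < 4),
           "each class needs at least 4 trials to split into valid halves")
  halves <- with_seed(derive_seed(seed, 7), {
    h1 <- integer(0)
    for (cl in idx_by_class) {
      cl <- sample(cl)
      h1 <- c(h1, cl[seq_len(ceiling(length(cl) / 2))])
    }
    h1
  })
  half1 <- sort(halves)
  half2 <- setdiff(seq_len(n_tr), half1)
  sub_tensor <- function(idx) {
    new_rate_tensor(X[, idx, , drop = FALSE], ids,
                    rates$trial_ids[idx], rates$epoch)
  }
  M1 <- auroc_matrix(sub_tensor(half1), labels[half1])
  M2 <- auroc_matrix(sub_tensor(half2), labels[half2])
  obs <- mean((M1 - M2)^2)
  # null MSEs via the cross-product trick:
  # mse(perm) = (sum M1^2 + sum M2^2 - 2 * sum_n <M1[n,], M2[perm[n],]>)/size
  G <- M1 %*% t(M2)
  c12 <- sum(M1^2) + sum(M2^2)
  size <- length(M1)
  N <- nrow(M1)
  null_mse <- with_seed(derive_seed(seed, 8), {
    vapply(seq_len(n_perm), function(j) {
      perm <- sample.int(N)
      (c12 - 2 * sum(G[cbind(seq_len(N), perm)])) / size
    }, numeric(1))
  })
  p <- (1 + sum(null_mse <= obs + 1e-15)) / (n_perm + 1)
  tibble::tibble(mse = obs, p = p, n_neurons = N, n_bins = ncol(M1))
}

#' Compare encoding-latency distributions between two populations
#'
#' Two-sample Kolmogorov-Smirnov test on the times at which the neurons of
#' two populations reach their peak selectivity, plus the cumulative
#' curves for plotting.
#'
#' @param peaks_a,peaks_b Numeric vectors of peak times (ms), e.g. the
#'   `best_bin_center` of each region's encoders or the peak times of
#'   rectified matrices.
#' @param region_names Labels for the two populations.
#' @return List with `statistic` (KS D), `p`, and `curves` (tibble:
#'   `region`, `t`, `cum_prop`).
#' @export
latency_comparison <- function(peaks_a, peaks_b,
                               region_names = c("aIC", "OFC")) {
  abort_if(length(peaks_a) < 3 || length(peaks_b) < 3,
           "need at least 3 peak times per population")
  ks <- suppressWarnings(stats::ks.test(peaks_a, peaks_b))
  grid <- sort(unique(c(peaks_a, peaks_b)))
  curves <- dplyr::bind_rows(
    tibble::tibble(region = region_names[1], t = grid,
                   cum_prop = stats::ecdf(peaks_a)(grid)),
    tibble::tibble(region = region_names[2], t = grid,
                   cum_prop = stats::ecdf(peaks_b)(grid))
  )
  list(statistic = unname(ks$statistic), p = ks$p.value, curves = curves)
}
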