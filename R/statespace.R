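# Condition-averaged PCA trajectories and pairwise trajectory distances.

#' Neurons x (time x condition) matrix from smoothed rates
#'
#' Concatenates each neuron's per-condition mean rate time courses
#' row-wise, condition-major (all time points of condition 1, then
#' condition 2, ...). This is the matrix whose neuron-space covariance
#' drives the population PCA.
#'
#' @param smoothed A `smoothed_rates` object from [kernel_rates()] (its
#'   `min_trials` argument implements the per-condition trial
#'   thresholds).
#' @return Matrix with attributes `conditions`, `grid`.
#' @export
condition_matrix <- function(smoothed) {
  r <- smoothed$rates
  n_neur <- dim(r)[1]
  n_cond <- dim(r)[2]
  n_t <- dim(r)[3]
  mat <- matrix(NA_real_, n_neur, n_cond * n_t)
  for (j in seq_len(n_cond)) {
    mat[, (j - 1) * n_t + seq_len(n_t)] <- r[, j, ]
  }
  structure(mat, conditions = smoothed$conditions, grid = smoothed$grid,
            neuron_ids = smoothed$neuron_ids)
}

#' PCA population trajectories
#'
#' Mean-centres each neuron across all columns, eigendecomposes the
#' neuron-space covariance matrix, and projects the condition-averaged
#' activity onto the principal components, giving one low-dimensional
#' trajectory per experimental condition. Each trajectory is smoothed
#' with locally weighted regression (`lowess`, span = fraction of the
#' epoch).
#'
#' @param mat A [condition_matrix()] (or any neurons x columns matrix
#'   with `conditions`/`grid` attributes).
#' @param n_components Components to retain in the trajectories.
#' @param span Smoothing span as a fraction of the epoch (0 disables
#'   smoothing).
#' @return A `trajectory_set`: `coefficients` (neurons x components),
#'   `explained` (variance fractions), `trajectories` (components x time
#'   x conditions array), `conditions`, `grid`.
#' @export
pca_trajectories <- function(mat, n_components = 3, span = 0.1) {
  conditions <- attr(mat, "conditions")
  grid <- attr(mat, "grid")
  abort_if(is.null(conditions) || is.null(grid),
           "mat must carry conditions and grid attributes")
  abort_if(nrow(mat) < 2 || ncol(mat) < 2, "need >= 2 neurons and columns")
  n_t <- length(grid)
  n_cond <- length(conditions)
  pc <- stats::prcomp(t(mat), center = TRUE, scale. = FALSE)
  var_frac <- pc$sdev^2 / sum(pc$sdev^2)
  k <- min(n_components, ncol(pc$rotation))
  scores <- pc$x[, seq_len(k), drop = FALSE] # (time*cond) x k
  traj <- array(NA_real_, dim = c(k, n_t, n_cond),
                dimnames = list(paste0("PC", seq_len(k)), NULL, conditions))
  for (j in seq_len(n_cond)) {
    block <- scores[(j - 1) * n_t + seq_len(n_t), , drop = FALSE]
    for (cmp in seq_len(k)) {
      y <- block[, cmp]
      if (span > 0 && n_t > 4) {
        y <- stats::lowess(grid, y, f = span)$y
      }
      traj[cmp, , j] <- y
    }
  }
  structure(
    list(coefficients = pc$rotation[, seq_len(k), drop = FALSE],
         explained = var_frac, trajectories = traj,
         conditions = conditions, grid = grid,
         full_scores = pc$x, center = pc$center),
    class = "trajectory_set"
  )
}

#' @export
print.trajectory_set <- function(x, ...) {
  cat(sprintf(
    "<trajectory_set> %d conditions x %d ms, PC1-%d explain %.1f%% of variance\n",
    length(x$conditions), length(x$grid), dim(x$trajectories)[1],
    100 * sum(x$explained[seq_len(dim(x$trajectories)[1])])))
  invisible(x)
}

#' Euclidean distances between condition trajectories
#'
#' Per time point, the Euclidean distance between two conditions'
#' trajectories in the leading-components subspace, averaged (mean and
#' SEM) over a set of condition pairs: all water-sucrose pairs (5 pairs
#' for the six stimulus conditions) or all pairs (15).
#'
#' @param ts A `trajectory_set` over the six stimulus conditions.
#' @param pair_set `"water_sucrose"`, `"all"`, or a 2-column character
#'   matrix of condition names.
#' @param n_components Subspace dimension (3 by default).
#' @return Tibble: `t`, `mean_dist`, `sem_dist`, `n_pairs`.
#' @export
trajectory_distances <- function(ts, pair_set = c("water_sucrose", "all"),
                                 n_components = 3) {
  if (is.character(pair_set) && length(pair_set) <= 2 && is.null(dim(pair_set))) {
    pair_set <- match.arg(pair_set)
    conc <- suppressWarnings(as.numeric(ts$conditions))
    water <- ts$conditions[!is.na(conc) & conc == 0]
    pairs <- t(utils::combn(ts$conditions, 2))
    if (pair_set == "water_sucrose") {
      abort_if(length(water) != 1, "no water (0) condition present")
      keep <- pairs[, 1] == water | pairs[, 2] == water
      pairs <- pairs[keep, , drop = FALSE]
    }
  } else {
    pairs <- pair_set
  }
  abort_if(!all(pairs %in% ts$conditions), "pair set names unknown conditions")
  k <- min(n_components, dim(ts$trajectories)[1])
  dist_one <- function(c1, c2) {
    d2 <- (ts$trajectories[seq_len(k), , c1, drop = FALSE] -
             ts$trajectories[seq_len(k), , c2, drop = FALSE])^2
    sqrt(colSums(matrix(d2, nrow = k)))
  }
  D <- vapply(seq_len(nrow(pairs)),
              function(i) dist_one(pairs[i, 1], pairs[i, 2]),
              numeric(length(ts$grid)))
  tibble::tibble(
    t = ts$grid,
    mean_dist = rowMeans(D),
    sem_dist = apply(D, 1, sem),
    n_pairs = nrow(pairs)
  )
}
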