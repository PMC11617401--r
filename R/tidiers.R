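# broom-style tidiers and re-exported generics.

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy a rate tensor into a long tibble
#'
#' @param x A `rate_tensor`.
#' @param ... Unused.
#' @return Tibble: `neuron_id`, `trial_id`, `bin_center`, `rate`.
#' @export
tidy.rate_tensor <- function(x, ...) {
  d <- dim(x$rates)
  tibble::tibble(
    neuron_id = rep(x$neuron_ids, times = d[2] * d[3]),
    trial_id = rep(rep(x$trial_ids, each = d[1]), times = d[3]),
    bin_center = rep(x$epoch$bin_centers, each = d[1] * d[2]),
    rate = as.vector(x$rates)
  )
}

#' Tidy a selectivity matrix into a long tibble
#'
#' @param x A `selectivity` object.
#' @param ... Unused.
#' @return Tibble: `neuron_id`, `bin_center`, `auroc`, `p`, `sig`, and
#'   `choice_prob` when the companion matrix is present.
#' @export
tidy.selectivity <- function(x, ...) {
  out <- tibble::tibble(
    neuron_id = rep(x$neuron_ids, times = ncol(x$A)),
    bin_center = rep(x$bin_centers, each = nrow(x$A)),
    auroc = as.vector(x$A),
    p = as.vector(x$p),
    sig = as.vector(x$sig)
  )
  if (!is.null(x$C)) out$choice_prob <- as.vector(x$C)
  out
}

#' @export
glance.selectivity <- function(x, ...) {
  tibble::tibble(
    contrast = x$contrast, n_neurons = nrow(x$A), n_bins = ncol(x$A),
    n_class_a = unname(x$n_class["a"]), n_class_b = unname(x$n_class["b"]),
    alpha = x$alpha, n_perm = x$n_perm,
    prop_sig_bins = mean(x$sig)
  )
}

#' @export
tidy.decoding_result <- function(x, ...) x$accuracy

#' @export
glance.decoding_result <- function(x, ...) {
  tibble::tibble(
    schema = x$config$schema, kernel = x$config$kernel,
    n_resamples = nrow(x$resample_acc), n_bins = length(x$bin_centers),
    peak_accuracy = max(x$accuracy$mean_acc),
    mean_accuracy = mean(x$accuracy$mean_acc),
    chance = 1 / length(x$class_levels)
  )
}

#' @export
tidy.psychometric_fit <- function(x, ...) {
  tibble::tibble(term = c("a", "b"), estimate = c(x$a, x$b))
}

#' @export
glance.psychometric_fit <- function(x, ...) {
  tibble::tibble(a = x$a, b = x$b, r2 = x$r2, threshold = x$threshold)
}

#' @export
tidy.trajectory_set <- function(x, ...) {
  d <- dim(x$trajectories)
  tibble::tibble(
    component = rep(dimnames(x$trajectories)[[1]], times = d[2] * d[3]),
    t = rep(rep(x$grid, each = d[1]), times = d[3]),
    condition = rep(x$conditions, each = d[1] * d[2]),
    value = as.vector(x$trajectories)
  )
}

#' @export
glance.trajectory_set <- function(x, ...) {
  tibble::tibble(
    n_conditions = length(x$conditions),
    n_components = dim(x$trajectories)[1],
    var_pc1 = x$explained[1],
    var_pc2 = if (length(x$explained) > 1) x$explained[2] else NA_real_,
    var_retained = sum(x$explained[seq_len(dim(x$trajectories)[1])])
  )
}
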