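# Power-law psychometric fitting and single-neuron neurometric curves.

#' Empirical psychometric points of a session
#'
#' @param trials Trials tibble.
#' @return Tibble with one row per concentration: `concentration`, `n`
#'   trials, `p_sucrose` (fraction of sucrose responses).
#' @export
psychometric_points <- function(trials) {
  trials |>
    dplyr::group_by(concentration = .data$concentration) |>
    dplyr::summarise(n = dplyr::n(),
                     p_sucrose = mean(.data$choice == "sucrose"),
                     .groups = "drop") |>
    dplyr::arrange(.data$concentration)
}

#' Fit a power-law psychometric function
#'
#' Fits `f(x) = a * x^b` to the probability of a "sucrose" response by
#' least squares in linear probability space, over the positive
#' concentrations only (`x = 0` is degenerate for a power law and is
#' excluded from the fit, though it is part of the behavioural curve).
#' The absolute threshold is the concentration at which the fitted curve
#' crosses 0.5: `x* = (0.5/a)^(1/b)`.
#'
#' @param points Tibble with columns `concentration` and `p_sucrose`
#'   (e.g. from [psychometric_points()]), or a trials tibble (detected by
#'   a `choice` column).
#' @return A `psychometric_fit` object: `a`, `b`, `r2`, `threshold`, and
#'   the fitted points. See [tidy()]/[glance()] methods.
#' @export
fit_power_psychometric <- function(points) {
  if ("choice" %in% names(points)) points <- psychometric_points(points)
  pts <- points[points$concentration > 0, , drop = FALSE]
  abort_if(nrow(pts) < 2,
           "need at least two positive concentrations with probabilities")
  x <- pts$concentration
  p <- pts$p_sucrose
  abort_if(stats::var(p) == 0,
           "all probabilities equal; exponent b is unidentifiable",
           class = "tastedyn_fit_error")
  # start values from the log-log regression on the positive-probability points
  pos <- p > 0
  abort_if(sum(pos) < 2, "need at least two positive probabilities",
           class = "tastedyn_fit_error")
  lm0 <- stats::lm(log(p[pos]) ~ log(x[pos]))
  a0 <- exp(stats::coef(lm0)[1])
  b0 <- stats::coef(lm0)[2]
  ss <- function(par) sum((p - par[1] * x^par[2])^2)
  if (ss(c(a0, b0)) > 1e-20) {
    opt <- stats::optim(c(a0, max(b0, 1e-3)), ss, method = "Nelder-Mead",
                        control = list(reltol = 1e-14, maxit = 5000))
    a_hat <- opt$par[1]
    b_hat <- opt$par[2]
  } else {
    a_hat <- unname(a0)
    b_hat <- unname(b0)
  }
  abort_if(a_hat <= 0, "fitted a must be positive",
           class = "tastedyn_fit_error")
  resid <- p - a_hat * x^b_hat
  r2 <- 1 - sum(resid^2) / sum((p - mean(p))^2)
  structure(
    list(a = unname(a_hat), b = unname(b_hat), r2 = r2,
         threshold = (0.5 / a_hat)^(1 / b_hat),
         points = points),
    class = "psychometric_fit"
  )
}

#' @export
print.psychometric_fit <- function(x, ...) {
  cat(sprintf(
    "<psychometric_fit> p(sucrose) = %.4g * c^%.4g, R^2 = %.3f, threshold = %.3g %%w/v\n",
    x$a, x$b, x$r2, x$threshold))
  invisible(x)
}

#' Optimal firing-rate classification threshold
#'
#' Exhaustive search for the rate threshold (and direction) that
#' maximizes the number of correctly classified trials when each trial is
#' labeled by whether its rate surpasses the threshold. Candidates are
#' the midpoints of adjacent sorted unique rates plus the two infinite
#' endpoints (so the one-class classifier is representable). Ties go to
#' the smallest threshold, then to the `high` direction (high rate means
#' the high-coded class).
#'
#' @param rates Per-trial firing rates in the window of interest.
#' @param labels Two-level factor; second level is the high-coded class
#'   (e.g. sucrose response).
#' @return List: `threshold`, `direction` (`"high"` or `"low"`),
#'   `accuracy`.
#' @export
optimal_threshold <- function(rates, labels) {
  labels <- factor(labels)
  abort_if(nlevels(labels) != 2 || min(table(labels)) < 1,
           "both classes must be present")
  high_class <- levels(labels)[2]
  u <- sort(unique(rates))
  cand <- c(-Inf, if (length(u) > 1) (u[-1] + u[-length(u)]) / 2, Inf)
  best <- list(threshold = NA_real_, direction = NA_character_, accuracy = -1)
  for (th in cand) {
    for (dir in c("high", "low")) {
      pred_high <- if (dir == "high") rates > th else rates < th
      acc <- mean((labels == high_class) == pred_high)
      better <- acc > best$accuracy + 1e-12
      tie <- abs(acc - best$accuracy) <= 1e-12 &&
        (th < best$threshold ||
           (th == best$threshold && dir == "high" && best$direction == "low"))
      if (better || tie) {
        best <- list(threshold = th, direction = dir, accuracy = acc)
      }
    }
  }
  best
}

#' Neurometric curve of a single neuron
#'
#' Classifies each trial as a water or sucrose response according to the
#' neuron's optimal firing-rate threshold (fitted on the choice labels)
#' and reports, per stimulus concentration, the fraction of trials
#' classified "sucrose", paired with the behavioural probability of a
#' sucrose response on the same trials.
#'
#' @param trial_rates Tibble with one row per trial: `concentration`,
#'   `choice`, and `rate` (the neuron's firing rate in its best encoding
#'   window).
#' @return A `neurometric_curve`: tibble with `concentration`, `n`,
#'   `p_neurometric`, `p_psychometric`, plus the threshold fit as
#'   attributes `threshold`, `direction`, `accuracy`.
#' @export
neurometric_curve <- function(trial_rates) {
  stopifnot(all(c("concentration", "choice", "rate") %in% names(trial_rates)))
  labels <- factor(trial_rates$choice, levels = c("water", "sucrose"))
  th <- optimal_threshold(trial_rates$rate, labels)
  pred_sucrose <- if (th$direction == "high") {
    trial_rates$rate > th$threshold
  } else {
    trial_rates$rate < th$threshold
  }
  out <- trial_rates |>
    dplyr::mutate(.pred = pred_sucrose) |>
    dplyr::group_by(concentration = .data$concentration) |>
    dplyr::summarise(n = dplyr::n(),
                     p_neurometric = mean(.pred),
                     p_psychometric = mean(.data$choice == "sucrose"),
                     .groups = "drop") |>
    dplyr::arrange(.data$concentration)
  attr(out, "threshold") <- th$threshold
  attr(out, "direction") <- th$direction
  attr(out, "accuracy") <- th$accuracy
  class(out) <- c("neurometric_curve", class(out))
  out
}
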