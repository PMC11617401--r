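# ggplot2 visualizations of the main result types.

#' @export
autoplot.selectivity <- function(object, rectified = TRUE,
                                 window = c(0, 800), ...) {
  if (rectified) {
    R <- rectify(object, window = window)
    keep <- rowSums(R) > 0
    R <- R[keep, , drop = FALSE]
    ids <- attr(R, "neuron_ids")[keep]
    ord <- sort_by_peak(R)
    df <- tibble::tibble(
      neuron = rep(seq_along(ord), times = ncol(R)),
      bin_center = rep(attr(R, "bin_centers"), each = nrow(R)),
      value = as.vector(R[ord, , drop = FALSE])
    )
    lab <- "|auROC - 0.5| (rectified)"
  } else {
    df <- tidy(object) |>
      dplyr::mutate(neuron = match(.data$neuron_id, object$neuron_ids),
                    value = .data$auroc)
    lab <- "auROC"
  }
  ggplot2::ggplot(df, ggplot2::aes(x = .data$bin_center, y = .data$neuron,
                                   fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c(name = lab) +
    ggplot2::labs(x = sprintf("time from %s (ms)", object$epoch$align_event),
                  y = "neuron (sorted by peak)",
                  title = sprintf("%s selectivity", object$contrast)) +
    ggplot2::theme_minimal()
}

#' @export
autoplot.decoding_result <- function(object, ...) {
  df <- object$accuracy
  chance <- 1 / length(object$class_levels)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$bin_center, y = .data$mean_acc)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$mean_acc - .data$sem_acc,
                                      ymax = .data$mean_acc + .data$sem_acc),
                         alpha = 0.3) +
    ggplot2::geom_line() +
    ggplot2::geom_hline(yintercept = chance, linetype = "dashed") +
    ggplot2::labs(x = "time (ms)", y = "decoding accuracy",
                  title = sprintf("%s decoding (%s kernel)",
                                  object$config$schema,
                                  object$config$kernel)) +
    ggplot2::theme_minimal()
}

#' @export
autoplot.psychometric_fit <- function(object, ...) {
  pts <- object$points
  xs <- seq(min(pts$concentration[pts$concentration > 0]) / 2,
            max(pts$concentration), length.out = 200)
  curve <- tibble::tibble(concentration = xs,
                          p_sucrose = object$a * xs^object$b)
  ggplot2::ggplot(pts, ggplot2::aes(x = .data$concentration,
                                    y = .data$p_sucrose)) +
    ggplot2::geom_point(size = 2) +
    ggplot2::geom_line(data = curve) +
    ggplot2::geom_hline(yintercept = 0.5, linetype = "dotted") +
    ggplot2::geom_vline(xintercept = object$threshold, linetype = "dotted") +
    ggplot2::labs(x = "sucrose concentration (%w/v)",
                  y = "p('sucrose' response)",
                  title = sprintf("psychometric fit: %.3g x^%.3g (R2 = %.2f)",
                                  object$a, object$b, object$r2)) +
    ggplot2::theme_minimal()
}

#' @export
autoplot.trajectory_set <- function(object, components = c(1, 2), ...) {
  k <- dim(object$trajectories)[1]
  abort_if(max(components) > k, "component not retained in trajectories")
  df <- purrr::map_dfr(object$conditions, function(cond) {
    tibble::tibble(
      condition = cond, t = object$grid,
      x = object$trajectories[components[1], , cond],
      y = object$trajectories[components[2], , cond]
    )
  })
  ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$y,
                                   colour = .data$condition)) +
    ggplot2::geom_path() +
    ggplot2::labs(x = sprintf("PC%d", components[1]),
                  y = sprintf("PC%d", components[2]),
                  title = "population trajectories") +
    ggplot2::theme_minimal()
}

#' Plot a neurometric curve against its psychometric curve
#'
#' @param curve A [neurometric_curve()].
#' @return A ggplot.
#' @export
plot_neurometric <- function(curve) {
  df <- tidyr::pivot_longer(curve, c("p_neurometric", "p_psychometric"),
                            names_to = "source", values_to = "p")
  df$source <- sub("p_", "", df$source)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$concentration, y = .data$p,
                                   colour = .data$source)) +
    ggplot2::geom_point() +
    ggplot2::geom_line() +
    ggplot2::scale_colour_manual(values = c(neurometric = "red",
                                            psychometric = "black")) +
    ggplot2::labs(x = "sucrose concentration (%w/v)",
                  y = "p('sucrose')", colour = NULL) +
    ggplot2::theme_minimal()
}
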