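#' Plot hand and cursor traces of a few trials
#'
#' @param object A `cst_trialset`.
#' @param n_trials Number of trials to show.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot cst_trialset
#' @export
autoplot.cst_trialset <- function(object, n_trials = 6, ...) {
  take <- utils::head(seq_len(nrow(object)), n_trials)
  long <- tidyr::unnest(
    dplyr::select(tibble::as_tibble(object)[take, ], "trial_id", "lam", "data"),
    "data")
  long <- tidyr::pivot_longer(
    dplyr::select(long, "trial_id", "lam", "t", "x", "p"),
    c("x", "p"), names_to = "series", values_to = "cm")
  ggplot2::ggplot(long, ggplot2::aes(.data$t, .data$cm, colour = .data$series)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~trial_id) +
    ggplot2::scale_colour_manual(values = c(x = "#2166ac", p = "#b2182b"),
                                 labels = c(x = "cursor", p = "hand")) +
    ggplot2::labs(x = "time (s)", y = "position (cm)", colour = NULL)
}

#' Plot a binned success curve with its psychometric fit
#'
#' @param object A `cst_psychfit`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot cst_psychfit
#' @export
autoplot.cst_psychfit <- function(object, ...) {
  grid <- tibble::tibble(lam = seq(min(object$table$bin_center),
                                   max(object$table$bin_center),
                                   length.out = 200))
  grid$rate <- predict(object, grid$lam)
  ggplot2::ggplot(object$table,
                  ggplot2::aes(.data$bin_center, .data$rate)) +
    ggplot2::geom_point(ggplot2::aes(size = .data$n), alpha = 0.7) +
    ggplot2::geom_line(data = grid, ggplot2::aes(.data$lam, .data$rate)) +
    ggplot2::geom_vline(xintercept = object$lam_c, linetype = 2) +
    ggplot2::geom_hline(yintercept = 50, linetype = 3) +
    ggplot2::labs(x = expression(lambda), y = "% success", size = "trials")
}

#' RMS-space scatter of trials, optionally with classifier labels
#'
#' @param features A feature table ([trial_features()] output), optionally
#'   after [classify_trials()] (then points are coloured by label, otherwise
#'   by generating objective when present).
#' @return A ggplot object.
#' @export
plot_rms_space <- function(features) {
  colour_var <- if ("label" %in% names(features)) "label" else
    if ("objective" %in% names(features)) "objective" else NULL
  gg <- ggplot2::ggplot(features,
                        ggplot2::aes(.data$rms_x, .data$rms_xdot))
  if (!is.null(colour_var)) {
    gg <- gg + ggplot2::aes(colour = .data[[colour_var]])
  }
  gg + ggplot2::geom_point(alpha = 0.4, size = 0.8) +
    ggplot2::labs(x = "RMS cursor position (cm)",
                  y = "RMS cursor velocity (cm/s)")
}

#' Mean-state scatter (mean cursor velocity against mean cursor position)
#'
#' @param features A feature table.
#' @return A ggplot object.
#' @export
plot_state_space <- function(features) {
  gg <- ggplot2::ggplot(features,
                        ggplot2::aes(.data$mean_x, .data$mean_xdot))
  if ("objective" %in% names(features)) {
    gg <- gg + ggplot2::aes(colour = .data$objective)
  }
  gg + ggplot2::geom_point(alpha = 0.4, size = 0.8) +
    ggplot2::geom_hline(yintercept = 0, linetype = 3) +
    ggplot2::geom_vline(xintercept = 0, linetype = 3) +
    ggplot2::labs(x = "mean cursor position (cm)",
                  y = "mean cursor velocity (cm/s)")
}
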