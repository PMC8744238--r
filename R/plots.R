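#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot an age schedule
#'
#' Cumulative probability of dying against the age cut points, log scale on
#' the vertical axis (zeros dropped).
#'
#' @param object An `age_schedule`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.age_schedule <- function(object, ...) {
  df <- object[object$q > 0, , drop = FALSE]
  ggplot2::ggplot(df, ggplot2::aes(x = .data$days, y = .data$q)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::scale_x_log10(breaks = object$days, labels = object$label) +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "age cut point", y = "cumulative probability of dying",
                  title = paste0("cause: ", attr(object, "cause"),
                                 ", q5 = ", signif(attr(object, "q5"), 3))) +
    ggplot2::theme_minimal()
}

#' Plot fitted age-specific curves over a range of under-five mortality
#'
#' Shows the `k = 0` fitted relation between under-five mortality and each
#' age group's cumulative probability, with the training records overlaid
#' when a [lifetable_set] is supplied.
#'
#' @param object A `logquad_fit`.
#' @param set Optional [lifetable_set] of training records to overlay.
#' @param n Number of curve evaluation points.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.logquad_fit <- function(object, set = NULL, n = 60, ...) {
  rng <- if (!is.null(set)) range(set$q5[set$cause == object$cause & set$q5 > 0])
         else c(0.002, 0.05)
  q5_grid <- exp(seq(log(rng[1]), log(rng[2]), length.out = n))
  curves <- purrr::map_dfr(q5_grid, function(q5) {
    tibble::tibble(q5 = q5, label = object$coeffs$label,
                   q = exp(lnq_pattern(object, q5, 0)))
  })
  curves$label <- factor(curves$label, levels = grid_labels(object$grid))
  p <- ggplot2::ggplot(curves, ggplot2::aes(x = .data$q5, y = .data$q,
                                            colour = .data$label)) +
    ggplot2::geom_line() +
    ggplot2::scale_x_log10() + ggplot2::scale_y_log10() +
    ggplot2::labs(x = "under-five mortality (q5)",
                  y = "cumulative probability of dying",
                  colour = "age group",
                  title = paste0("log quadratic fit, cause: ", object$cause)) +
    ggplot2::theme_minimal()
  if (!is.null(set)) {
    pts <- lifetable_long(subset(set, causes = object$cause))
    pts <- pts[pts$q > 0, , drop = FALSE]
    pts$label <- factor(pts$label, levels = grid_labels(object$grid))
    p <- p + ggplot2::geom_point(data = pts, alpha = 0.3, size = 0.8)
  }
  p
}

#' Plot pooled cross-validation errors by age and method
#'
#' @param object A `cv_report`.
#' @param metric `"abs"` (deaths per 1000 livebirths) or `"rel"` (percent).
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.cv_report <- function(object, metric = c("abs", "rel"), ...) {
  metric <- match.arg(metric)
  df <- object$pooled
  df$label <- factor(df$label, levels = grid_labels(object$grid))
  if (metric == "abs") {
    df$value <- df$mean_abs_error * 1000
    ylab <- "mean |error| (per 1000 livebirths)"
  } else {
    df$value <- df$mean_rel_error * 100
    ylab <- "mean relative error (%)"
  }
  ggplot2::ggplot(df, ggplot2::aes(x = .data$label, y = .data$value,
                                   fill = .data$method)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::labs(x = "age group", y = ylab,
                  title = paste0("hold-out error, cause: ", object$cause)) +
    ggplot2::theme_minimal()
}

#' Plot simulation-study prediction error by scenario and age
#'
#' @param object A `sim_report`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.sim_report <- function(object, ...) {
  df <- object$summary
  df$label <- factor(df$label,
                     levels = grid_labels(object$config$base_fit$grid))
  df$scenario <- paste0("q5=", signif(df$scenario_q5, 3), ", k=",
                        signif(df$scenario_k, 3))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$label,
                                   y = .data$mean_abs_error * 1000,
                                   colour = .data$method,
                                   group = .data$method)) +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::facet_wrap(~scenario) +
    ggplot2::labs(x = "age group",
                  y = "mean |error| (per 1000 livebirths)") +
    ggplot2::theme_minimal()
}
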