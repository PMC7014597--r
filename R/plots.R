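#' Plot an intraspecific divergence screen
#'
#' CLR-CLR scatter of the tested toxins with the fitted nontoxin line (solid)
#' and null band (dashed), outliers coloured by over-expressing sample —
#' the standard way these screens are read.
#'
#' @param object A `divergence_calls` tibble from [divergence_outliers()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.divergence_calls <- function(object, ...) {
  fit <- attr(object, "fit")
  band <- attr(object, "band")
  pair <- attr(object, "pair")
  offset <- sqrt(1 + fit$slope^2)
  ggplot2::ggplot(object, ggplot2::aes(x = .data$clr_x, y = .data$clr_y)) +
    ggplot2::geom_abline(slope = fit$slope, intercept = fit$intercept, colour = "red") +
    ggplot2::geom_abline(slope = fit$slope, intercept = fit$intercept + band$lower * offset,
                         linetype = "dashed") +
    ggplot2::geom_abline(slope = fit$slope, intercept = fit$intercept + band$upper * offset,
                         linetype = "dashed") +
    ggplot2::geom_point(ggplot2::aes(colour = .data$direction, shape = .data$outlier)) +
    ggplot2::labs(x = sprintf("CLR expression, %s", pair[1]),
                  y = sprintf("CLR expression, %s", pair[2]),
                  colour = "over-expressed in", shape = "outlier") +
    ggplot2::theme_minimal()
}

#' Plot per-treatment module expression profiles
#'
#' One panel per module; grey lines are individual transcripts (z-scored),
#' the coloured line the module mean.
#'
#' @param object A `coexpression_modules` object.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.coexpression_modules <- function(object, ...) {
  lines <- attr(object$profiles, "lines")
  means <- lines |>
    group_by(.data$module, .data$venom_type) |>
    summarise(z = mean(.data$z), .groups = "drop")
  ggplot2::ggplot(lines, ggplot2::aes(x = .data$venom_type, y = .data$z)) +
    ggplot2::geom_line(ggplot2::aes(group = .data$transcript_id), colour = "grey70") +
    ggplot2::geom_line(data = means, ggplot2::aes(group = 1), colour = "steelblue",
                       linewidth = 1) +
    ggplot2::facet_wrap(~module, labeller = ggplot2::label_both) +
    ggplot2::labs(x = "venom type", y = "z-scored expression") +
    ggplot2::theme_minimal()
}

#' Plot a per-base coverage profile
#'
#' @param object A `coverage_profile` tibble from [depth_profile()].
#' @param min_depth Depth floor drawn as a dashed line (default 5).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.coverage_profile <- function(object, min_depth = 5, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$pos, y = .data$depth)) +
    ggplot2::geom_area(fill = "grey80") +
    ggplot2::geom_hline(yintercept = min_depth, linetype = "dashed", colour = "red") +
    ggplot2::facet_wrap(~transcript_id, scales = "free_x") +
    ggplot2::labs(x = "position (0-based)", y = "read depth") +
    ggplot2::theme_minimal()
}
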