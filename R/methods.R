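#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' @export
tidy.loss_projection <- function(x, ...) {
  tibble::as_tibble(unclass(x))
}

#' @export
glance.loss_projection <- function(x, ...) {
  p <- attr(x, "params")
  tibble::tibble(
    S = p$S,
    D = p$D,
    V = p$V,
    n = p$n,
    per_day_loss = per_day_loss_fraction(p$D, p$V),
    final_count = x$count[nrow(x)],
    total_loss = x$count[1] - x$count[nrow(x)],
    mean_daily_loss = attr(x, "mean_daily_loss")
  )
}

#' @export
print.loss_projection <- function(x, ...) {
  p <- attr(x, "params")
  cat(sprintf(
    "Death-window projection: S = %s, D = %g, V = %.3g h, n = %g d\n",
    format(p$S, big.mark = ","), p$D, p$V, p$n
  ))
  cat(sprintf("Mean daily loss: %.1f cells/day\n",
              attr(x, "mean_daily_loss")))
  print(tibble::as_tibble(unclass(x)), ...)
  invisible(x)
}

#' @export
autoplot.loss_projection <- function(object, ...) {
  ggplot2::ggplot(tibble::as_tibble(unclass(object)),
                  ggplot2::aes(x = .data$day, y = .data$count)) +
    ggplot2::geom_line(colour = "steelblue") +
    ggplot2::geom_point() +
    ggplot2::labs(x = "Day of death window", y = "Expected cell count") +
    ggplot2::theme_minimal()
}

#' @export
tidy.visible_fraction_estimate <- function(x, ...) {
  tibble::tibble(
    label = x$label %||% NA_character_,
    n_samples = length(x$per_sample_fractions %||% numeric()),
    mean = x$mean,
    ci_low = x$ci_low,
    ci_high = x$ci_high,
    confidence = x$confidence
  )
}

#' @export
print.visible_fraction_estimate <- function(x, ...) {
  cat("Visible-dying fraction estimate")
  if (!is.null(x$label)) cat(" (", x$label, ")", sep = "")
  cat("\n")
  cat(sprintf("  mean = %.6g  [%.6g, %.6g]", x$mean, x$ci_low, x$ci_high))
  if (!is.na(x$confidence)) {
    cat(sprintf("  (%g%% t-interval, n = %d)", 100 * x$confidence,
                length(x$per_sample_fractions)))
  }
  cat("\n")
  invisible(x)
}

#' @export
glance.mosaic_analysis <- function(x, ...) {
  tibble::tibble(
    n_points = x$n_points,
    n_interior = x$n_interior,
    mean_area = x$mean_area,
    sd_area = x$sd_area,
    regularity_index = x$regularity_index,
    degenerate = x$degenerate
  )
}

#' @export
tidy.mosaic_analysis <- function(x, ...) {
  tibble::tibble(area = x$interior_areas)
}

#' @export
print.mosaic_analysis <- function(x, ...) {
  cat(sprintf(
    "Voronoi mosaic analysis: %d points, %d interior domains\n",
    x$n_points, x$n_interior
  ))
  if (x$degenerate) {
    cat("Degenerate mosaic: all interior domain areas identical ",
        "(perfect lattice); regularity index undefined.\n", sep = "")
  } else {
    cat(sprintf("Regularity index (mean/SD of areas): %.3f\n",
                x$regularity_index))
  }
  invisible(x)
}

#' @export
autoplot.snapshot_series <- function(object, ...) {
  long <- tidyr::pivot_longer(
    tibble::as_tibble(unclass(object)),
    cols = c("live", "visible", "cleared"),
    names_to = "compartment", values_to = "cells"
  )
  ggplot2::ggplot(long, ggplot2::aes(x = .data$day, y = .data$cells,
                                     colour = .data$compartment)) +
    ggplot2::geom_line() +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "Day", y = "Cells (log scale)") +
    ggplot2::theme_minimal()
}

#' @export
autoplot.retina_pattern <- function(object, ...) {
  r <- attr(object, "radius")
  circ <- tibble::tibble(
    x = r * cos(seq(0, 2 * pi, length.out = 200)),
    y = r * sin(seq(0, 2 * pi, length.out = 200))
  )
  ggplot2::ggplot(tibble::as_tibble(unclass(object)),
                  ggplot2::aes(x = .data$x, y = .data$y)) +
    ggplot2::geom_path(data = circ, colour = "grey50") +
    ggplot2::geom_point(size = 0.4) +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "x (mm)", y = "y (mm)") +
    ggplot2::theme_minimal()
}

`%||%` <- function(a, b) if (is.null(a)) b else a
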