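#' Linear regression of working distance on maximum distortion ratio
#'
#' Ordinary least squares relating the maximum distortion ratio of a view
#' to the working distance (a proxy for the angle of view: at fixed sensor
#' geometry the view widens linearly with distance). The printed direction
#' regresses working distance on the distortion ratio; the natural
#' predictive direction (ratio on distance) is also available. The slope is
#' tested with a two-sided t-test on n - 2 degrees of freedom.
#'
#' @param data A data frame with one row per working distance.
#' @param ratio,distance Column names (strings) of the maximum distortion
#'   ratio and working distance (defaults `"max_ratio_mm"`,
#'   `"working_distance_mm"`).
#' @param direction `"distance_on_ratio"` (default, the printed form) or
#'   `"ratio_on_distance"`.
#' @return A `distortion_trend` object with `slope`, `intercept`,
#'   `r_squared`, `p_value`, `n`, the underlying [stats::lm] fit and the
#'   data; see [tidy()] and [glance()].
#' @examples
#' tab <- tibble::tibble(
#'   working_distance_mm = c(60, 65, 70, 75, 80),
#'   max_ratio_mm = c(0.24, 0.27, 0.32, 0.34, 0.38)
#' )
#' fit <- fit_linear(tab)
#' glance(fit)
#' @export
fit_linear <- function(data, ratio = "max_ratio_mm",
                       distance = "working_distance_mm",
                       direction = c("distance_on_ratio", "ratio_on_distance")) {
  direction <- match.arg(direction)
  if (!all(c(ratio, distance) %in% names(data))) {
    abort("`data` must contain the ratio and distance columns.")
  }
  if (direction == "distance_on_ratio") {
    x <- data[[ratio]]
    y <- data[[distance]]
    xlab <- ratio
    ylab <- distance
  } else {
    x <- data[[distance]]
    y <- data[[ratio]]
    xlab <- distance
    ylab <- ratio
  }
  if (length(x) < 3) abort("Need at least 3 points for a regression.")
  if (var(x) == 0) abort("The predictor is constant; the slope is undefined.")

  fit <- lm(y ~ x)
  slope <- unname(coef(fit)[2])
  intercept <- unname(coef(fit)[1])
  n <- length(x)
  ssr <- sum(fit$residuals^2)
  sst <- sum((y - mean(y))^2)
  r_squared <- if (sst > 0) 1 - ssr / sst else 1
  se_slope <- sqrt((ssr / (n - 2)) / sum((x - mean(x))^2))
  t_stat <- if (se_slope > 0) slope / se_slope else Inf
  p_value <- max(2 * pt(-abs(t_stat), df = n - 2), .Machine$double.xmin)

  structure(
    list(
      slope = slope, intercept = intercept, r_squared = r_squared,
      p_value = p_value, n = n, direction = direction,
      xlab = xlab, ylab = ylab, fit = fit,
      data = tibble(x = x, y = y)
    ),
    class = "distortion_trend"
  )
}

#' @export
print.distortion_trend <- function(x, ...) {
  cat(sprintf(
    "<distortion_trend> %s = %.4g * %s + %.4g  (R^2 = %.4f, p = %.3g, n = %d)\n",
    x$ylab, x$slope, x$xlab, x$intercept, x$r_squared, x$p_value, x$n
  ))
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.distortion_trend <- function(x, ...) {
  s <- unname(summary(x$fit)$coefficients)
  tibble(
    term = c("(Intercept)", x$xlab),
    estimate = s[, 1], std.error = s[, 2],
    statistic = s[, 3], p.value = s[, 4]
  )
}

#' @exportS3Method generics::glance
glance.distortion_trend <- function(x, ...) {
  tibble(
    slope = x$slope, intercept = x$intercept,
    r.squared = x$r_squared, p.value = x$p_value, n = x$n
  )
}

#' Plot a fitted distortion trend
#'
#' @param object A `distortion_trend`.
#' @param ... Unused.
#' @return A ggplot scatter of the data with the fitted line.
#' @exportS3Method ggplot2::autoplot
autoplot.distortion_trend <- function(object, ...) {
  ggplot2::ggplot(object$data, ggplot2::aes(.data$x, .data$y)) +
    ggplot2::geom_point(size = 2) +
    ggplot2::geom_abline(
      slope = object$slope, intercept = object$intercept, colour = "steelblue"
    ) +
    ggplot2::labs(
      x = object$xlab, y = object$ylab,
      subtitle = sprintf("R² = %.4f, p = %.3g", object$r_squared, object$p_value)
    )
}
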