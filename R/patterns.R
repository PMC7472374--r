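#' Ideal vertical-line calibration pattern
#'
#' Builds the undistorted calibration target: equally spaced dark vertical
#' lines on a light background, rendered with an anti-aliased Gaussian
#' cross-section so that subpixel centroid detection is meaningful. Line
#' positions are expressed in object-plane millimetres, symmetric about the
#' pattern centre, and the rendered line count is always odd so that one
#' line sits exactly on the midline.
#'
#' @param width_px,height_px Image size in pixels.
#' @param spacing_mm Centre-to-centre line spacing in mm (default 1).
#' @param px_per_mm Object-plane sampling density of the rendered raster.
#' @param line_sigma_px Gaussian cross-section scale of a line, in px.
#' @return A `line_pattern`: list with `image` ([gray_image()]),
#'   `line_positions_mm` (increasing, symmetric about 0) and `spacing_mm`.
#' @examples
#' pat <- make_vertical_line_pattern(800, 600, spacing_mm = 1, px_per_mm = 20)
#' length(pat$line_positions_mm) # 39
#' @export
make_vertical_line_pattern <- function(width_px, height_px, spacing_mm = 1,
                                       px_per_mm = 20, line_sigma_px = 1.2) {
  if (width_px <= 0 || height_px <= 0) abort("Image dimensions must be positive.")
  if (spacing_mm <= 0) abort("`spacing_mm` must be positive.")
  if (px_per_mm <= 0) abort("`px_per_mm` must be positive.")
  if (spacing_mm * px_per_mm < 4 * line_sigma_px) {
    abort("Lines are not separable: need spacing_mm * px_per_mm >= 4 * line_sigma_px.")
  }
  width_mm <- width_px / px_per_mm
  # keep every line at least half a spacing away from the raster edge
  k <- floor((width_mm / 2 - spacing_mm / 2) / spacing_mm)
  if (k < 1) abort("Pattern would hold fewer than 2 lines; enlarge the raster.")
  positions_mm <- seq(-k, k) * spacing_mm

  row <- render_line_profile(width_px, positions_mm * px_per_mm, line_sigma_px)
  img <- gray_image(
    matrix(row, nrow = height_px, ncol = width_px, byrow = TRUE),
    px_per_mm = px_per_mm
  )
  structure(
    list(image = img, line_positions_mm = positions_mm, spacing_mm = spacing_mm,
         line_sigma_px = line_sigma_px),
    class = "line_pattern"
  )
}

# Intensity profile of dark Gaussian lines on unit background, evaluated at
# the 0-based pixel centres of a raster `width_px` wide. `offsets_px` are
# line centres relative to the image centre (width/2).
render_line_profile <- function(width_px, offsets_px, sigma_px) {
  x <- seq_len(width_px) - 1 - width_px / 2
  dips <- rowSums(vapply(
    offsets_px,
    function(o) exp(-((x - o)^2) / (2 * sigma_px^2)),
    numeric(length(x))
  ))
  pmin(pmax(1 - dips, 0), 1)
}

#' Standard scalar bar: a line pattern with per-line depth steps
#'
#' The scalar bar is a vertical-line target whose successive lines are
#' raised toward the camera in equal depth increments, so that a corrected
#' stereo pair resolves one disparity step per line. Line `i` (1-based)
#' carries depth offset `(i - 1) * depth_step_mm`; with 20 lines and a
#' 0.05 mm step the total depth span is 1 mm.
#'
#' @inheritParams make_vertical_line_pattern
#' @param n_lines Number of lines (>= 2).
#' @param depth_step_mm Depth increment per line in mm (>= 0; 0 degenerates
#'   to a flat pattern).
#' @return A `scalar_bar` (also a `line_pattern`) with `line_depths_mm`,
#'   `depth_step_mm` and `n_lines`.
#' @examples
#' bar <- make_scalar_bar(n_lines = 20, depth_step_mm = 0.05,
#'                        width_px = 800, height_px = 600, px_per_mm = 20)
#' max(bar$line_depths_mm) # 0.95; total span 20 * 0.05 = 1 mm
#' @export
make_scalar_bar <- function(n_lines = 20, spacing_mm = 1, depth_step_mm = 0.05,
                            width_px = 800, height_px = 600, px_per_mm = 20,
                            line_sigma_px = 1.2) {
  if (n_lines < 2) abort("A scalar bar needs at least 2 lines.")
  if (depth_step_mm < 0) abort("`depth_step_mm` must be non-negative.")
  if (spacing_mm <= 0) abort("`spacing_mm` must be positive.")
  positions_mm <- (seq_len(n_lines) - (n_lines + 1) / 2) * spacing_mm
  need_mm <- 2 * (max(abs(positions_mm)) + spacing_mm / 2)
  if (width_px / px_per_mm < need_mm) {
    abort("Raster too narrow for the requested lines; enlarge `width_px`.")
  }
  row <- render_line_profile(width_px, positions_mm * px_per_mm, line_sigma_px)
  img <- gray_image(
    matrix(row, nrow = height_px, ncol = width_px, byrow = TRUE),
    px_per_mm = px_per_mm
  )
  structure(
    list(
      image = img, line_positions_mm = positions_mm, spacing_mm = spacing_mm,
      line_sigma_px = line_sigma_px,
      line_depths_mm = (seq_len(n_lines) - 1) * depth_step_mm,
      depth_step_mm = depth_step_mm, n_lines = as.integer(n_lines)
    ),
    class = c("scalar_bar", "line_pattern")
  )
}

#' @export
print.line_pattern <- function(x, ...) {
  cat(sprintf(
    "<%s> %d lines, %.3g mm spacing, raster %d x %d px @ %.4g px/mm\n",
    class(x)[1], length(x$line_positions_mm), x$spacing_mm,
    x$image$width_px, x$image$height_px, x$image$px_per_mm
  ))
  if (!is.null(x$line_depths_mm)) {
    cat(sprintf(
      "  depth step %.3g mm, total span %.3g mm\n",
      x$depth_step_mm, length(x$line_depths_mm) * x$depth_step_mm
    ))
  }
  invisible(x)
}

#' Write a pattern to PNG with a JSON sidecar
#'
#' @param pattern A `line_pattern` or `scalar_bar`.
#' @param path Output PNG path; metadata goes to `<path>.json`.
#' @return `path`, invisibly.
#' @export
write_pattern_png <- function(pattern, path) {
  meta <- list(
    line_positions_mm = pattern$line_positions_mm,
    spacing_mm = pattern$spacing_mm
  )
  if (!is.null(pattern$line_depths_mm)) {
    meta$line_depths_mm <- pattern$line_depths_mm
    meta$depth_step_mm <- pattern$depth_step_mm
  }
  write_gray_png(pattern$image, path, meta = meta)
}
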