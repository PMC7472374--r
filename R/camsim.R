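#' Non-convergence stereo rig configuration
#'
#' Describes the close-up stereo geometry: a pinhole camera at working
#' distance `z` from a fronto-parallel object plane, translated laterally by
#' the baseline between the reference and shift exposures. The object-plane
#' sampling density follows from the pinhole model,
#' `px_per_mm = f / (z * pitch)`, so the field of view widens as the working
#' distance grows. The default pixel pitch is chosen so that the zoomed
#' close-up view spans 32 mm across an 800 px frame at z = 60 mm.
#'
#' @param working_distance_mm Camera-to-object distance z (mm), > 0.
#' @param baseline_mm Lateral translation b between the two views (mm), >= 0.
#' @param focal_mm Focal length f (mm), > 0.
#' @param pixel_pitch_mm Sensor pixel pitch (mm/px), > 0.
#' @param width_px,height_px Image size in pixels (4:3 by default).
#' @return A `stereo_config` list; see [px_per_mm_at_object()] and
#'   [angle_of_view()] for derived quantities.
#' @examples
#' cfg <- stereo_config(60)
#' px_per_mm_at_object(cfg) # 25 px/mm: the view spans 32 mm
#' @export
stereo_config <- function(working_distance_mm,
                          baseline_mm = 10,
                          focal_mm = 5.6,
                          pixel_pitch_mm = 5.6 * 32 / (60 * 800),
                          width_px = 800, height_px = 600) {
  if (working_distance_mm <= 0) abort("`working_distance_mm` must be > 0.")
  if (baseline_mm < 0) abort("`baseline_mm` must be >= 0.")
  if (focal_mm <= 0 || pixel_pitch_mm <= 0) abort("Focal length and pixel pitch must be > 0.")
  if (width_px <= 0 || height_px <= 0) abort("Image dimensions must be positive.")
  structure(
    list(
      working_distance_mm = working_distance_mm,
      baseline_mm = baseline_mm,
      focal_mm = focal_mm,
      pixel_pitch_mm = pixel_pitch_mm,
      width_px = as.integer(width_px),
      height_px = as.integer(height_px)
    ),
    class = "stereo_config"
  )
}

#' @export
print.stereo_config <- function(x, ...) {
  cat(sprintf(
    "<stereo_config> z = %g mm, b = %g mm, f = %g mm, %d x %d px, %.4g px/mm at object\n",
    x$working_distance_mm, x$baseline_mm, x$focal_mm,
    x$width_px, x$height_px, px_per_mm_at_object(x)
  ))
  invisible(x)
}

#' Object-plane sampling density of a stereo configuration
#'
#' @param config A [stereo_config()].
#' @param depth_mm Optional depth offset toward the camera (mm); lines raised
#'   by `depth_mm` are magnified as if at distance `z - depth_mm`.
#' @return Pixels per object-plane millimetre.
#' @export
px_per_mm_at_object <- function(config, depth_mm = 0) {
  z <- config$working_distance_mm - depth_mm
  if (any(z <= 0)) abort("Depth offsets must stay short of the camera.")
  config$focal_mm / (z * config$pixel_pitch_mm)
}

#' Diagonal-free horizontal angle of view
#'
#' Returns `2 * atan(half_width / z)` in degrees, where `half_width` is the
#' object-plane half-width seen by the sensor at the working distance.
#'
#' @param config A [stereo_config()].
#' @return Angle of view in degrees.
#' @examples
#' # half-width 15 mm at z = 60 mm -> 2 * atan(0.25) = 28.07 degrees
#' @export
angle_of_view <- function(config) {
  half_mm <- config$width_px / (2 * px_per_mm_at_object(config))
  2 * atan2(half_mm, config$working_distance_mm) * 180 / pi
}

#' Division-model pincushion distortion with independent half-image strength
#'
#' Ground-truth forward model of the simulator. In centre-relative pixel
#' coordinates the ideal point is the distorted point divided by
#' `1 + lambda1 * rd^2 + lambda2 * rd^4` (the two-parameter division model),
#' with separate coefficients for the left (`x <= 0`) and right (`x > 0`)
#' halves of the image. Negative coefficients displace observed points
#' toward the centre: the positive-displacement pincushion studied here.
#' Defaults are tuned so that the maximum border line displacement of the
#' simulated views spans roughly 0.24 mm (z = 60 mm) to 0.37 mm (z = 80 mm)
#' at the default close-up geometry, with the right half distorted more
#' strongly than the left.
#'
#' @param lambda1_left,lambda2_left Division-model coefficients (px^-2,
#'   px^-4) for the left half-image.
#' @param lambda1_right,lambda2_right Same for the right half-image.
#' @return A `distortion_spec` list.
#' @export
distortion_spec <- function(lambda1_left = -0.74e-7, lambda2_left = -1e-15,
                            lambda1_right = -1.11e-7, lambda2_right = -2e-15) {
  structure(
    list(
      lambda1_left = lambda1_left, lambda2_left = lambda2_left,
      lambda1_right = lambda1_right, lambda2_right = lambda2_right
    ),
    class = "distortion_spec"
  )
}

#' Identity (zero-distortion) specification
#' @return A `distortion_spec` with all coefficients zero.
#' @export
identity_spec <- function() distortion_spec(0, 0, 0, 0)

#' @export
print.distortion_spec <- function(x, ...) {
  cat(sprintf(
    "<distortion_spec> left: l1 = %g, l2 = %g | right: l1 = %g, l2 = %g\n",
    x$lambda1_left, x$lambda2_left, x$lambda1_right, x$lambda2_right
  ))
  invisible(x)
}

as_points_matrix <- function(points) {
  if (is.data.frame(points)) points <- as.matrix(points[, 1:2])
  if (is.null(dim(points))) points <- matrix(points, ncol = 2)
  if (ncol(points) != 2 || !is.numeric(points) || anyNA(points) || any(!is.finite(points))) {
    abort("`points` must be finite centre-relative (x, y) coordinates.")
  }
  unname(points)
}

# Per-point division-model denominator 1 + l1 rd^2 + l2 rd^4, using the
# left-half coefficients where x <= 0 (tie at the centre column -> left).
division_denominator <- function(points, spec) {
  rd2 <- points[, 1]^2 + points[, 2]^2
  left <- points[, 1] <= 0
  l1 <- ifelse(left, spec$lambda1_left, spec$lambda1_right)
  l2 <- ifelse(left, spec$lambda2_left, spec$lambda2_right)
  1 + l1 * rd2 + l2 * rd2^2
}

#' Map distorted points to their ideal positions (closed form)
#'
#' Applies the division model directly: `ideal = distorted / (1 + lambda1 *
#' rd^2 + lambda2 * rd^4)` in centre-relative pixel coordinates, per
#' half-image.
#'
#' @param points n x 2 matrix (or data frame) of centre-relative distorted
#'   coordinates in px.
#' @param spec A [distortion_spec()].
#' @return n x 2 matrix of ideal centre-relative coordinates.
#' @export
undistort_points <- function(points, spec) {
  pts <- as_points_matrix(points)
  pts / division_denominator(pts, spec)
}

#' Map ideal points to their distorted positions (numerical inverse)
#'
#' Inverts the division model ideal -> distorted by bisection on the
#' distorted radius: the model is stated distorted -> ideal, but the
#' renderer and ground-truth line sets need the inverse. The radial map is
#' monotone over the operating range, so bisection is robust and
#' tolerance-controlled.
#'
#' @inheritParams undistort_points
#' @param points n x 2 matrix of centre-relative ideal coordinates in px.
#' @param tol Radial residual tolerance in px (default 1e-10).
#' @return n x 2 matrix of distorted centre-relative coordinates.
#' @export
distort_points <- function(points, spec, tol = 1e-10) {
  pts <- as_points_matrix(points)
  ru <- sqrt(pts[, 1]^2 + pts[, 2]^2)
  left <- pts[, 1] <= 0
  l1 <- ifelse(left, spec$lambda1_left, spec$lambda1_right)
  l2 <- ifelse(left, spec$lambda2_left, spec$lambda2_right)

  g <- function(rd) rd / (1 + l1 * rd^2 + l2 * rd^4) # distorted radius -> ideal radius

  lo <- rep(0, length(ru))
  hi <- ru
  # widen the bracket for barrel-signed coefficients (g(ru) < ru)
  for (i in seq_len(80)) {
    short <- g(hi) < ru
    if (!any(short)) break
    hi[short] <- hi[short] * 1.5 + 1e-12
  }
  for (i in seq_len(120)) {
    mid <- (lo + hi) / 2
    below <- g(mid) < ru
    lo[below] <- mid[below]
    hi[!below] <- mid[!below]
  }
  rd <- (lo + hi) / 2
  if (any(abs(g(rd) - ru) > pmax(tol, 1e-12 * ru))) {
    abort("Division-model inversion did not converge to tolerance.")
  }
  scale <- ifelse(ru > 0, rd / ru, 1)
  pts * scale
}

#' Project a pattern through the pinhole model
#'
#' Places the camera at `lateral_offset_mm` along the object-plane x axis
#' and projects every pattern line: a line at lateral position `X` mm raised
#' by `depth` mm lands at pixel
#' `x = width/2 + (X - offset) * f / ((z - depth) * pitch)`. For a flat
#' pattern the offset is a pure translation of `offset * px_per_mm` pixels.
#' The rendered image is the ideal (undistorted) view.
#'
#' @param pattern A `line_pattern` or `scalar_bar`.
#' @param config A [stereo_config()].
#' @param lateral_offset_mm Camera position along x (mm); the shift view of
#'   a stereo pair uses the baseline.
#' @param require_full_field Must the pattern cover the whole field of
#'   view? Defaults to `TRUE` for flat calibration patterns (a calibration
#'   view with blank margins would starve the border of correspondences)
#'   and `FALSE` for scalar bars, which are scene objects that may sit
#'   inside a wider view.
#' @return List with `image` (ideal [gray_image()]) and `lines`, a tibble of
#'   `line`, `X_mm`, `depth_mm`, `x_px` (absolute, 0-based) restricted to
#'   lines landing inside the raster.
#' @export
project_pattern <- function(pattern, config, lateral_offset_mm = 0,
                            require_full_field = !inherits(pattern, "scalar_bar")) {
  q <- px_per_mm_at_object(config)
  half_mm <- config$width_px / (2 * q)
  span <- range(pattern$line_positions_mm)
  pad <- pattern$spacing_mm / 2
  if (require_full_field &&
      (lateral_offset_mm - half_mm < span[1] - pad ||
       lateral_offset_mm + half_mm > span[2] + pad)) {
    abort("Pattern is narrower than the field of view at this configuration.")
  }
  depths <- pattern$line_depths_mm %||% rep(0, length(pattern$line_positions_mm))
  q_line <- px_per_mm_at_object(config, depth_mm = depths)
  x_px <- config$width_px / 2 +
    (pattern$line_positions_mm - lateral_offset_mm) * q_line
  lines <- tibble(
    line = seq_along(x_px),
    X_mm = pattern$line_positions_mm,
    depth_mm = depths,
    x_px = x_px
  )
  inside <- lines$x_px > -6 * pattern$line_sigma_px &
    lines$x_px < config$width_px - 1 + 6 * pattern$line_sigma_px
  lines <- lines[inside, ]
  row <- render_line_profile(
    config$width_px, lines$x_px - config$width_px / 2, pattern$line_sigma_px
  )
  img <- gray_image(
    matrix(row, config$height_px, config$width_px, byrow = TRUE),
    px_per_mm = q
  )
  list(image = img, lines = lines)
}

# Evaluate the ideal line-profile intensity at arbitrary (possibly
# non-integer) absolute x coordinates; only the two nearest lines contribute
# (line spacing is always many sigma).
profile_at <- function(x_abs, centres_abs, sigma) {
  centres <- sort(centres_abs)
  idx <- findInterval(x_abs, centres)
  dip <- numeric(length(x_abs))
  lo <- idx >= 1L
  dip[lo] <- exp(-((x_abs[lo] - centres[idx[lo]])^2) / (2 * sigma^2))
  hi <- idx < length(centres)
  dip[hi] <- dip[hi] + exp(-((x_abs[hi] - centres[idx[hi] + 1L])^2) / (2 * sigma^2))
  pmin(pmax(1 - dip, 0), 1)
}

#' Render a distorted stereo pair with known ground truth
#'
#' Renders the reference view (camera at 0) and the shift view (camera
#' translated by the baseline), each carrying the ground-truth division
#' -model pincushion distortion of `spec`. Images are rendered analytically:
#' every pixel is mapped to its ideal coordinate in closed form and the
#' ideal line profile is evaluated there, so there is no resampling blur.
#' Ground-truth ideal and distorted line positions (at the central image
#' row) are stored for both views.
#'
#' @param pattern A `line_pattern` or `scalar_bar`.
#' @param config A [stereo_config()].
#' @param spec A [distortion_spec()]; `identity_spec()` gives an
#'   undistorted pair.
#' @param noise_sd Optional additive Gaussian intensity noise (default 0).
#' @param seed Optional seed used only when `noise_sd > 0`.
#' @param rig_center_mm Lateral position of the reference camera (mm);
#'   the shift camera sits at `rig_center_mm + baseline`. Setting it to
#'   `-baseline/2` frames a narrow object (such as a scalar bar at the
#'   origin) symmetrically in both views.
#' @return A `stereo_pair`: distorted `reference` and `shift` images, their
#'   ideal counterparts, per-view line tibbles with `x_ideal_px` and
#'   `x_distorted_px`, plus `config` and `spec`.
#' @export
render_distorted_stereo <- function(pattern, config, spec = distortion_spec(),
                                    noise_sd = 0, seed = NULL,
                                    rig_center_mm = 0) {
  views <- list(reference = rig_center_mm,
                shift = rig_center_mm + config$baseline_mm)
  out <- list(config = config, spec = spec)
  for (v in names(views)) {
    proj <- project_pattern(pattern, config, lateral_offset_mm = views[[v]])
    lines <- proj$lines
    cx <- config$width_px / 2
    # ground-truth distorted line positions at the central row (y = yc)
    ideal_rel <- cbind(lines$x_px - cx, 0)
    dist_rel <- distort_points(ideal_rel, spec)
    lines$x_ideal_px <- lines$x_px
    lines$x_distorted_px <- dist_rel[, 1] + cx
    lines$x_px <- NULL

    img <- render_distorted_image(lines$x_ideal_px, pattern$line_sigma_px, config, spec)
    if (noise_sd > 0) {
      if (!is.null(seed)) set.seed(seed + match(v, names(views)))
      img$pixels <- pmin(pmax(
        img$pixels + matrix(
          stats::rnorm(length(img$pixels), 0, noise_sd),
          nrow(img$pixels)
        ), 0), 1)
    }
    out[[v]] <- img
    out[[paste0("lines_", v)]] <- as_tibble(lines)
    out[[paste0("ideal_", v)]] <- proj$image
  }
  structure(out, class = "stereo_pair")
}

# Distorted view of a set of ideal vertical lines: each pixel (a distorted
# coordinate) is sent to its ideal position in closed form and the ideal
# profile is sampled there.
render_distorted_image <- function(centres_abs_px, sigma, config, spec) {
  w <- config$width_px
  h <- config$height_px
  cx <- w / 2
  cy <- h / 2
  xr <- matrix(rep(seq_len(w) - 1 - cx, each = h), h, w)
  yr <- matrix(rep(seq_len(h) - 1 - cy, times = w), h, w)
  rd2 <- xr^2 + yr^2
  l1 <- ifelse(xr <= 0, spec$lambda1_left, spec$lambda1_right)
  l2 <- ifelse(xr <= 0, spec$lambda2_left, spec$lambda2_right)
  ux <- xr / (1 + l1 * rd2 + l2 * rd2^2) + cx
  vals <- profile_at(as.vector(ux), centres_abs_px, sigma)
  gray_image(matrix(vals, h, w), px_per_mm = px_per_mm_at_object(config))
}

#' @export
print.stereo_pair <- function(x, ...) {
  cat(sprintf(
    "<stereo_pair> z = %g mm, b = %g mm, %d + %d ground-truth lines\n",
    x$config$working_distance_mm, x$config$baseline_mm,
    nrow(x$lines_reference), nrow(x$lines_shift)
  ))
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
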