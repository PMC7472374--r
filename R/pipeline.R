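#' Simulate the five-distance stereo acquisition grid
#'
#' Renders one distorted stereo pair per working distance over a shared
#' wide calibration pattern, reproducing the close-up acquisition design:
#' baseline 10 mm, working distances 60 to 80 mm in 5 mm steps by default.
#' The pattern is sized automatically so that every camera position at the
#' largest distance still sees a full field of lines.
#'
#' @param working_distances_mm Numeric vector of working distances.
#' @param spec A [distortion_spec()] (ground truth).
#' @param baseline_mm Stereo baseline (mm).
#' @param width_px,height_px Image size.
#' @param spacing_mm Pattern line spacing (mm).
#' @param noise_sd,seed Optional intensity noise (off by default).
#' @param ... Passed to [stereo_config()].
#' @return A list with `pairs` (named list of `stereo_pair`s), `pattern`,
#'   and `manifest` (tibble of per-distance geometry).
#' @export
simulate_stereo_grid <- function(working_distances_mm = seq(60, 80, by = 5),
                                 spec = distortion_spec(),
                                 baseline_mm = 10,
                                 width_px = 800, height_px = 600,
                                 spacing_mm = 1,
                                 noise_sd = 0, seed = NULL, ...) {
  configs <- lapply(working_distances_mm, function(z) {
    stereo_config(z, baseline_mm = baseline_mm,
                  width_px = width_px, height_px = height_px, ...)
  })
  half_mm <- max(vapply(
    configs, function(cf) cf$width_px / (2 * px_per_mm_at_object(cf)), numeric(1)
  ))
  half_pattern <- baseline_mm + half_mm + 2 * spacing_mm
  pattern <- make_vertical_line_pattern(
    width_px = ceiling(2 * half_pattern * 20), height_px = 8,
    spacing_mm = spacing_mm, px_per_mm = 20
  )
  pairs <- lapply(configs, function(cf) {
    render_distorted_stereo(pattern, cf, spec, noise_sd = noise_sd, seed = seed)
  })
  names(pairs) <- paste0("z", working_distances_mm)
  manifest <- tibble(
    working_distance_mm = working_distances_mm,
    baseline_mm = baseline_mm,
    px_per_mm = vapply(configs, px_per_mm_at_object, numeric(1)),
    angle_of_view_deg = vapply(configs, angle_of_view, numeric(1)),
    n_lines_reference = vapply(pairs, function(p) nrow(p$lines_reference), numeric(1)),
    n_lines_shift = vapply(pairs, function(p) nrow(p$lines_shift), numeric(1))
  )
  list(pairs = pairs, pattern = pattern, manifest = manifest)
}

#' Calibrate a DCM from a distorted/ideal image pair
#'
#' Detects the vertical lines of the distorted view and of its ideal
#' (undistorted) rendering in a narrow band around the image midline,
#' pairs them in order, re-expresses both sets about the image centre and
#' fits the per-half distortion-ratio field, from which the per-pixel DCM
#' is built. The midline band keeps the correspondences close to the
#' horizontal axis, where the unknown vertical component of the distortion
#' is second-order, so the radial field is sampled cleanly along `rd`.
#'
#' @param distorted,ideal [gray_image()]s of the same scene with and
#'   without distortion.
#' @param degree Ratio-field polynomial degree (default 2).
#' @param band_frac Central row fraction used for detection (default 0.1).
#' @param min_lines Minimum line count required in each view (default 9).
#' @param min_radius_px Pairs closer to the centre than this are dropped
#'   (default 2% of the image width): the ratio of two near-zero radii is
#'   dominated by detection noise and carries no information about the
#'   radial field.
#' @return A `dcm` sized to the images.
#' @export
calibrate_dcm <- function(distorted, ideal, degree = 2, band_frac = 0.1,
                          min_lines = 9,
                          min_radius_px = 0.02 * distorted$width_px) {
  stopifnot_same_dims(distorted, ideal, "distorted and ideal images")
  det_d <- detect_lines(distorted, min_lines, band_frac = band_frac, keep_all = TRUE)
  det_i <- detect_lines(ideal, min_lines, band_frac = band_frac, keep_all = TRUE)
  # pair each ideal line with the distorted line nearest to it; the inward
  # pincushion pull can drag lines from just outside the ideal frame into
  # the distorted view, so the distorted set may be the larger one
  spacing <- stats::median(diff(sort(det_i$x_px)))
  nearest <- vapply(det_i$x_px, function(x) {
    j <- which.min(abs(det_d$x_px - x))
    if (abs(det_d$x_px[j] - x) > spacing / 2) NA_integer_ else j
  }, integer(1))
  ok <- !is.na(nearest)
  if (sum(ok) < min_lines || anyDuplicated(nearest[ok])) {
    abort(sprintf(
      "Cannot pair the line sets: %d lines in the distorted view, %d in the ideal.",
      nrow(det_d), nrow(det_i)
    ))
  }
  yc <- distorted$height_px / 2
  # the band is centred on the midline, so the points sit at y ~= yc
  corr <- correspondences(
    ideal = cbind(det_i$x_px[ok], yc),
    distorted = cbind(det_d$x_px[nearest[ok]], yc),
    center = c(distorted$width_px / 2, yc)
  )
  corr <- corr[corr$rd >= min_radius_px, ]
  field <- fit_ratio_field(corr, degree = degree)
  build_dcm(field, distorted$width_px, distorted$height_px)
}

#' Correct an image and fill the resulting holes
#'
#' Runs the full warp pipeline: forward-map the image through the DCM,
#' fill the hole region from nearest neighbours, and form the subtraction
#' image between input and filled output.
#'
#' @param image A [gray_image()].
#' @param dcm A `dcm` of matching size.
#' @return List with `corrected` (raw splat), `filled`, `mask`,
#'   `subtraction` and a one-row `metrics` tibble (`hole_fraction`,
#'   `rms_difference`).
#' @export
correct_and_fill <- function(image, dcm) {
  res <- correct_image(image, dcm)
  filled <- fill_holes_nearest(res$corrected, res$mask)
  sub <- subtract_images(image, filled)
  list(
    corrected = res$corrected, filled = filled, mask = res$mask,
    subtraction = sub,
    metrics = tibble(
      hole_fraction = res$mask$hole_fraction,
      rms_difference = sqrt(mean(sub$pixels^2))
    )
  )
}

#' Match corresponding lines of a stereo pair
#'
#' Detects lines in both views over a central row band and matches `n`
#' corresponding lines spread across the shared field, using the known
#' stereo geometry to resolve the alignment (the baseline is close to a
#' multiple of the line spacing).
#'
#' @param reference,shift [gray_image()]s of the two views.
#' @param config The pair's [stereo_config()].
#' @param n Number of corresponding lines (default 20).
#' @param band_frac Central row fraction for detection (default 0.8; the
#'   wide band averages down the positional quantisation left by the
#'   forward splat).
#' @param min_lines Minimum detections required per view (default `n`).
#' @return A `match_result` tibble (distances in px and object-plane mm).
#' @export
match_pair <- function(reference, shift, config, n = 20, band_frac = 0.8,
                       min_lines = n) {
  q <- px_per_mm_at_object(config)
  det_l <- detect_lines(reference, min_lines, band_frac = band_frac, keep_all = TRUE)
  det_r <- detect_lines(shift, min_lines, band_frac = band_frac, keep_all = TRUE)
  match_lines(det_l, det_r, n = n,
              px_per_mm = q,
              expected_offset_px = config$baseline_mm * q)
}

# Re-measure the lines of a before-correction match in the corrected pair.
# Each matched line's corrected position is predicted with the DCM point
# map and paired to the nearest detection in the corrected image, so the
# before and after distance series describe the same physical lines. Lines
# whose corrected position falls outside the detectable frame in either
# view are dropped (their indices are recorded in the "kept" attribute),
# and the anchored distances are re-based on the first kept line.
track_lines_after_correction <- function(before, ref_corrected, shf_corrected,
                                         dcm, config, band_frac = 0.8) {
  q <- px_per_mm_at_object(config)
  yc <- config$height_px / 2
  det_l <- detect_lines(ref_corrected, 2, band_frac = band_frac, keep_all = TRUE)
  det_r <- detect_lines(shf_corrected, 2, band_frac = band_frac, keep_all = TRUE)
  exp_l <- map_point(dcm, cbind(before$xL, yc))[, 1]
  exp_r <- map_point(dcm, cbind(before$xR, yc))[, 1]
  tol <- q * 0.4 # well under half the line spacing
  snap <- function(det, expected) {
    vapply(expected, function(e) {
      j <- which.min(abs(det$x_px - e))
      if (abs(det$x_px[j] - e) <= tol) det$x_px[j] else NA_real_
    }, numeric(1))
  }
  xL <- snap(det_l, exp_l)
  xR <- snap(det_r, exp_r)
  keep <- which(!is.na(xL) & !is.na(xR))
  if (length(keep) < 2) abort("Corrected pair lost nearly all matched lines.")
  d_raw <- xL[keep] - xR[keep]
  d <- d_raw - d_raw[1]
  out <- tibble(
    line = before$line[keep],
    xL = xL[keep], xR = xR[keep],
    d_raw_px = d_raw, d_px = d, d_mm = d / q
  )
  attr(out, "anchor_index") <- 1L
  attr(out, "px_per_mm") <- q
  attr(out, "kept") <- keep
  class(out) <- c("match_result", class(out))
  out
}

#' End-to-end correction experiment over the working-distance grid
#'
#' The package's core validation: simulate the five-distance stereo grid
#' with ground-truth pincushion distortion, calibrate a single DCM from
#' the widest-angle reference view against its ideal rendering (one lens,
#' one DCM), correct every image, and compare corresponding-line matches
#' before and after correction. Produces the per-distance summary table:
#' average correction rate and maximum corresponding-line distance before
#' and after, in object-plane mm.
#'
#' @inheritParams simulate_stereo_grid
#' @param n Number of corresponding lines matched per distance (default 20).
#' @param band_frac Central row fraction for line detection (default 0.8).
#' @param exclude_below_mm Lines whose before-correction distance is
#'   smaller than this (default 0.01 mm, about the subpixel measurement
#'   resolution on splatted images) are excluded from the average
#'   correction rate: a relative improvement over a starting distance
#'   within measurement noise of zero is meaningless.
#' @return A list:
#'   * `summary` — tibble with `working_distance_mm`,
#'     `avg_correction_rate_pct`, `max_before_mm`, `max_after_mm`,
#'     `hole_fraction_reference`;
#'   * `matches_before`, `matches_after` — named lists of `match_result`s;
#'   * `dcm`, `grid` — the calibrated DCM and the simulation.
#' @export
run_correction_experiment <- function(working_distances_mm = seq(60, 80, by = 5),
                                      spec = distortion_spec(),
                                      baseline_mm = 10,
                                      width_px = 800, height_px = 600,
                                      n = 20, band_frac = 0.8,
                                      exclude_below_mm = 0.01,
                                      noise_sd = 0, seed = NULL, ...) {
  grid <- simulate_stereo_grid(
    working_distances_mm, spec = spec, baseline_mm = baseline_mm,
    width_px = width_px, height_px = height_px,
    noise_sd = noise_sd, seed = seed, ...
  )
  widest <- which.max(working_distances_mm)
  cal_pair <- grid$pairs[[widest]]
  dcm <- calibrate_dcm(cal_pair$reference, cal_pair$ideal_reference)

  matches_before <- list()
  matches_after <- list()
  rows <- list()
  for (i in seq_along(working_distances_mm)) {
    z <- working_distances_mm[i]
    pair <- grid$pairs[[i]]
    cfg <- pair$config
    before <- match_pair(pair$reference, pair$shift, cfg,
                         n = n, band_frac = band_frac)
    ref_c <- correct_and_fill(pair$reference, dcm)
    shf_c <- correct_and_fill(pair$shift, dcm)
    after <- track_lines_after_correction(
      before, ref_c$filled, shf_c$filled, dcm, cfg, band_frac = band_frac
    )
    # Eq.-style comparison needs the same physical lines in both series: a
    # border line whose corrected position leaves the detectable frame is
    # dropped from both, and both are re-anchored on the first kept line
    keep <- attr(after, "kept")
    dd <- before$d_raw_px[keep]
    dd <- (dd - dd[1]) / px_per_mm_at_object(cfg)
    key <- names(grid$pairs)[i]
    matches_before[[key]] <- before
    matches_after[[key]] <- after
    rows[[key]] <- tibble(
      working_distance_mm = z,
      avg_correction_rate_pct = correction_rate(dd, after$d_mm,
                                                eps = exclude_below_mm),
      max_before_mm = max_distortion_ratio(before),
      max_after_mm = max_distortion_ratio(after),
      hole_fraction_reference = ref_c$metrics$hole_fraction
    )
  }
  list(
    summary = dplyr::bind_rows(rows),
    matches_before = matches_before,
    matches_after = matches_after,
    dcm = dcm, grid = grid
  )
}

#' Scalar-bar depth-recovery experiment
#'
#' Simulates a stereo pair of the depth-stepped scalar bar, corrects it
#' with a DCM calibrated from a flat line pattern under the same
#' configuration, and recovers each line's depth from its raw stereo
#' disparity via `d = b f / z`. In a successful correction the per-line
#' disparity rises monotonically with depth, the mean recovered increment
#' matches the configured depth step, and the recovered total span matches
#' `n_lines * depth_step`.
#'
#' @param working_distance_mm Working distance (default 60).
#' @param spec Ground-truth [distortion_spec()].
#' @param n_lines,depth_step_mm,spacing_mm Scalar-bar geometry (defaults
#'   20 lines, 0.05 mm step, 1 mm spacing).
#' @param width_px,height_px Image size.
#' @param method `"points"` (default) detects lines on the distorted
#'   images over a narrow midline band and relocates the detected centres
#'   with the DCM point map — the precise measurement, free of the
#'   positional quantisation that forward splatting imprints on a warped
#'   image. `"images"` corrects the full images first and detects lines on
#'   the filled results, as in routine image correction.
#' @param band_frac Detection band fraction; defaults to 0.1 for the
#'   point method (keeping the band where line bending is second-order)
#'   and 0.8 for the image method (averaging down splat quantisation).
#' @param ... Passed to [stereo_config()].
#' @return A list with `depths` (match tibble + recovered depths),
#'   `step_estimate_mm` (regression slope of recovered depth on line
#'   index), `span_estimate_mm`, `dcm` and the simulated `pair`.
#' @export
run_scalar_bar_experiment <- function(working_distance_mm = 60,
                                      spec = distortion_spec(),
                                      n_lines = 20, depth_step_mm = 0.05,
                                      spacing_mm = 1,
                                      width_px = 800, height_px = 600,
                                      method = c("points", "images"),
                                      band_frac = NULL, ...) {
  method <- match.arg(method)
  if (is.null(band_frac)) band_frac <- if (method == "points") 0.1 else 0.8
  cfg <- stereo_config(working_distance_mm,
                       width_px = width_px, height_px = height_px, ...)
  q <- px_per_mm_at_object(cfg)
  half_mm <- cfg$width_px / (2 * q)
  half_pattern <- cfg$baseline_mm + half_mm + 2 * spacing_mm
  flat <- make_vertical_line_pattern(
    width_px = ceiling(2 * half_pattern * 20), height_px = 8,
    spacing_mm = spacing_mm, px_per_mm = 20
  )
  cal_pair <- render_distorted_stereo(flat, cfg, spec)
  dcm <- calibrate_dcm(cal_pair$reference, cal_pair$ideal_reference)

  bar <- make_scalar_bar(
    n_lines = n_lines, spacing_mm = spacing_mm, depth_step_mm = depth_step_mm,
    width_px = ceiling((n_lines + 2) * spacing_mm * 20), height_px = 8,
    px_per_mm = 20
  )
  # frame the bar midway between the two camera positions so every line is
  # visible in both views
  pair <- render_distorted_stereo(bar, cfg, spec,
                                  rig_center_mm = -cfg$baseline_mm / 2)
  if (method == "images") {
    ref_c <- correct_and_fill(pair$reference, dcm)
    shf_c <- correct_and_fill(pair$shift, dcm)
    m <- match_pair(ref_c$filled, shf_c$filled, cfg,
                    n = n_lines, band_frac = band_frac)
  } else {
    yc <- cfg$height_px / 2
    correct_set <- function(img) {
      det <- detect_lines(img, n_lines, band_frac = band_frac, keep_all = TRUE)
      det$x_px <- map_point(dcm, cbind(det$x_px, yc))[, 1]
      det
    }
    m <- match_lines(
      correct_set(pair$reference), correct_set(pair$shift), n = n_lines,
      px_per_mm = q, expected_offset_px = cfg$baseline_mm * q
    )
  }
  depths <- recover_depths(m, cfg)
  idx <- depths$line - 1
  step_fit <- lm(depths$depth_rel_mm ~ idx)
  list(
    depths = depths,
    step_estimate_mm = unname(coef(step_fit)[2]),
    span_estimate_mm = depths$depth_rel_mm[n_lines] - depths$depth_rel_mm[1],
    dcm = dcm, pair = pair
  )
}

#' Per-distance summary table of a correction experiment
#'
#' @param experiment Result of [run_correction_experiment()].
#' @return The per-distance summary tibble, with the average correction
#'   rate and the max corresponding-line distances before/after (mm).
#' @export
summary_table <- function(experiment) experiment$summary

#' Fit the working distance versus maximum distortion ratio trend
#'
#' Convenience wrapper running [fit_linear()] on an experiment summary.
#'
#' @param experiment Result of [run_correction_experiment()].
#' @return A `distortion_trend`.
#' @export
fit_experiment_trend <- function(experiment) {
  fit_linear(
    dplyr::rename(experiment$summary, max_ratio_mm = "max_before_mm"),
    ratio = "max_ratio_mm", distance = "working_distance_mm"
  )
}
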