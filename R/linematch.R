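#' Detect vertical lines at subpixel precision
#'
#' Averages image rows into a single intensity profile (optionally only a
#' central band of rows, which tightens localisation when distortion bends
#' the lines away from vertical), finds local minima that are prominent
#' against the background, and refines each to subpixel precision with an
#' intensity-weighted centroid of the dip in a window around the minimum.
#'
#' @param image A [gray_image()].
#' @param expected_count Minimum number of lines that must be found; when
#'   more are found, the `expected_count` lines nearest the image midline
#'   are returned (set `keep_all = TRUE` to keep every detection).
#' @param band_frac Fraction of central rows averaged into the profile
#'   (default 1 = whole image).
#' @param prominence Minimum dip depth relative to the strongest dip for a
#'   minimum to count as a line (default 0.5).
#' @param window_px Half-width of the centroid window (default 4).
#' @param keep_all Keep all detections instead of the most central ones?
#' @return A tibble of class `line_set` with `line`, `x_px` (strictly
#'   increasing subpixel centres, 0-based) and `score` (dip depth).
#' @export
detect_lines <- function(image, expected_count, band_frac = 1,
                         prominence = 0.5, window_px = 4, keep_all = FALSE) {
  stopifnot(is_gray_image(image))
  h <- image$height_px
  n_band <- max(1L, round(h * band_frac))
  r0 <- floor((h - n_band) / 2) + 1L
  profile <- colMeans(image$pixels[r0:(r0 + n_band - 1L), , drop = FALSE])

  bg <- max(profile)
  dip <- bg - profile
  if (max(dip) < 1e-6) {
    abort("No lines found: the intensity profile is flat.")
  }
  n <- length(profile)
  cand <- which(
    dip >= prominence * max(dip) &
      dip >= c(-Inf, dip[-n]) & dip > c(dip[-1], -Inf)
  )
  # keep candidates whose centroid window fits inside the profile
  cand <- cand[cand > window_px & cand <= n - window_px]
  # collapse plateaus/near-duplicates closer than the window
  if (length(cand) > 1) {
    cand <- cand[c(TRUE, diff(cand) > window_px)]
  }
  if (length(cand) < expected_count) {
    abort(sprintf(
      "Expected at least %d lines but found %d prominent minima.",
      expected_count, length(cand)
    ))
  }
  centres <- vapply(cand, function(i) {
    idx <- (i - window_px):(i + window_px)
    wgt <- pmax(bg - profile[idx], 0)
    sum(wgt * (idx - 1)) / sum(wgt) # 0-based x
  }, numeric(1))
  score <- dip[cand]

  out <- tibble(line = seq_along(centres), x_px = centres, score = score)
  if (!keep_all && nrow(out) > expected_count) {
    mid <- (image$width_px - 1) / 2
    keep <- order(abs(out$x_px - mid))[seq_len(expected_count)]
    out <- out[sort(keep), ]
    out$line <- seq_len(nrow(out))
  }
  class(out) <- c("line_set", class(out))
  out
}

#' Match corresponding lines across a stereo pair
#'
#' Aligns the two detected line sets by the integer index offset that
#' minimises the variance of the per-line position differences (correct
#' alignment leaves only the smooth distortion signal; a misalignment by
#' one line shifts every difference by a full line spacing). From the
#' shared lines, `n` are selected spread evenly across the shared span, so
#' matched lines sit at fixed fractional image positions regardless of the
#' field of view. Distances are then anchored on the first matched line:
#' `d_i = (xL_i - xR_i) - (xL_1 - xR_1)`, so `d_1 = 0` by construction and
#' any anchor error propagates to the following lines. The raw
#' (un-anchored) differences are kept for disparity work.
#'
#' @param left,right `line_set` tibbles from [detect_lines()] (reference
#'   and shift view).
#' @param n Number of corresponding lines to match.
#' @param px_per_mm Object-plane scale used to express distances in mm
#'   (optional; `d_mm` is `NA` when not given).
#' @param expected_offset_px Expected mean `xL - xR` (for a stereo pair,
#'   `baseline_mm * px_per_mm`). When the baseline is a near-multiple of
#'   the line spacing several alignments are self-consistent, and the one
#'   whose mean difference is closest to this value is the physical match.
#'   When `NULL`, the alignment with the smallest difference variance is
#'   used, ties going to the smallest mean difference.
#' @return A tibble of class `match_result` with `line`, `xL`, `xR`,
#'   `d_raw_px` (`xL - xR`), `d_px` (anchored) and `d_mm`; attributes
#'   `anchor_index` and `px_per_mm`.
#' @export
match_lines <- function(left, right, n, px_per_mm = NULL,
                        expected_offset_px = NULL) {
  xl <- sort(left$x_px)
  xr <- sort(right$x_px)
  nl <- length(xl)
  nr <- length(xr)
  if (nl < 2 || nr < 2) abort("Each view needs at least 2 detected lines.")

  # candidate integer index offsets; positive k matches xl[i + k] to xr[i]
  cands <- list()
  for (k in seq(-(nr - 2), nl - 2)) {
    i_r <- seq_len(nr)
    i_l <- i_r + k
    ok <- i_l >= 1 & i_l <= nl
    if (sum(ok) < 2) next
    d <- xl[i_l[ok]] - xr[i_r[ok]]
    cands[[length(cands) + 1]] <- list(
      k = k, v = var(d), mu = mean(d), i_l = i_l[ok], i_r = i_r[ok]
    )
  }
  if (length(cands) == 0) abort("The line sets do not overlap.")
  if (!is.null(expected_offset_px)) {
    cost <- vapply(cands, function(a) abs(a$mu - expected_offset_px), numeric(1))
  } else {
    v <- vapply(cands, `[[`, numeric(1), "v")
    mu <- vapply(cands, `[[`, numeric(1), "mu")
    cost <- round(v / (max(v) + 1e-12), 6) * 1e6 + abs(mu) / (max(abs(mu)) + 1e-12)
  }
  best <- cands[[which.min(cost)]]
  m <- length(best$i_l)
  if (m < n) {
    abort(sprintf("Only %d corresponding lines overlap; %d requested.", m, n))
  }
  sel <- unique(round(seq(1, m, length.out = n)))
  if (length(sel) < n) sel <- seq_len(n) # degenerate guard, m == n
  i_l <- best$i_l[sel]
  i_r <- best$i_r[sel]

  d_raw <- xl[i_l] - xr[i_r]
  d <- d_raw - d_raw[1]
  out <- tibble(
    line = seq_along(sel),
    xL = xl[i_l], xR = xr[i_r],
    d_raw_px = d_raw, d_px = d,
    d_mm = if (is.null(px_per_mm)) NA_real_ else d / px_per_mm
  )
  attr(out, "anchor_index") <- 1L
  attr(out, "px_per_mm") <- px_per_mm
  class(out) <- c("match_result", class(out))
  out
}

#' Maximum corresponding-line distance, in object-plane mm
#'
#' The maximum absolute anchored distance over the matched lines of one
#' working distance: the working definition of the maximum distortion
#' ratio of a view.
#'
#' @param result A `match_result`.
#' @param px_per_mm Object-plane scale; taken from the result's attribute
#'   when omitted.
#' @return Maximum `|d|` in mm.
#' @export
max_distortion_ratio <- function(result, px_per_mm = NULL) {
  if (nrow(result) == 0) abort("Empty match result.")
  px_per_mm <- px_per_mm %||% attr(result, "px_per_mm")
  if (is.null(px_per_mm)) abort("Need `px_per_mm` to express the distance in mm.")
  max(abs(result$d_px)) / px_per_mm
}

#' Average correction rate (percent)
#'
#' Mean relative reduction of the corresponding-line distances achieved by
#' the correction: `mean((dd_i - dc_i) / dd_i) * 100` over the matched
#' lines, where `dd` are the distances before and `dc` after correction.
#' Lines whose before-distance is below `eps` (notably the anchor line,
#' which is 0 by construction) are excluded: the rate is undefined at
#' `dd_i = 0`. The rate is invariant to uniform rescaling of both series,
#' so px and mm distances give the same value.
#'
#' @param dd,dc Equal-length numeric vectors of distances before and after
#'   correction (signed or absolute; magnitudes are compared).
#' @param eps Exclusion threshold on `|dd_i|` (default 1e-6).
#' @return The average correction rate in percent.
#' @examples
#' correction_rate(c(0.2, 0.4), c(0.02, 0.08)) # 85
#' @export
correction_rate <- function(dd, dc, eps = 1e-6) {
  if (length(dd) != length(dc)) abort("`dd` and `dc` must have equal length.")
  if (length(dd) < 1) abort("Need at least one line.")
  keep <- abs(dd) > eps
  if (!any(keep)) abort("All before-correction distances are ~0; rate undefined.")
  mean((abs(dd[keep]) - abs(dc[keep])) / abs(dd[keep])) * 100
}

#' Disparity/depth conversion for a non-convergence stereo pair
#'
#' For rectified stereo, disparity `d`, depth `z`, baseline `b` and focal
#' length `f` satisfy `d = b * f / z` (all in mm, with `d` measured on the
#' sensor). `disparity_to_depth()` inverts the relation; `depth_to_disparity()`
#' evaluates it.
#'
#' @param d Disparity in sensor mm, > 0.
#' @param b Baseline in mm.
#' @param f Focal length in mm.
#' @return Depth `z` in mm.
#' @examples
#' depth_to_disparity(60, b = 10, f = 5.6) # 0.9333 mm
#' disparity_to_depth(0.93333333, b = 10, f = 5.6) # 60 mm
#' @export
disparity_to_depth <- function(d, b, f) {
  if (any(d <= 0)) abort("Disparity must be > 0 to recover a depth.")
  b * f / d
}

#' @rdname disparity_to_depth
#' @param z Depth in mm, > 0.
#' @export
depth_to_disparity <- function(z, b, f) {
  if (any(z <= 0)) abort("Depth must be > 0.")
  b * f / z
}

#' Recover per-line depths from raw scalar-bar disparities
#'
#' Converts the raw per-line stereo differences of a matched scalar-bar
#' pair into sensor-plane disparities (`d_raw_px * pixel_pitch`), inverts
#' `d = b f / z` per line and reports each line's depth relative to the
#' first line.
#'
#' @param result A `match_result` built from a scalar-bar pair (raw
#'   disparities must be positive).
#' @param config The [stereo_config()] of the pair.
#' @return The result tibble with `disparity_mm`, `z_mm` and
#'   `depth_rel_mm` columns added.
#' @export
recover_depths <- function(result, config) {
  disp_mm <- result$d_raw_px * config$pixel_pitch_mm
  if (any(disp_mm <= 0)) abort("Raw disparities must be positive; is this a stereo pair?")
  z <- disparity_to_depth(disp_mm, config$baseline_mm, config$focal_mm)
  result$disparity_mm <- disp_mm
  result$z_mm <- z
  result$depth_rel_mm <- z[1] - z
  result
}

#' Plot a corresponding-line distance series
#'
#' @param object A `match_result`.
#' @param ... Unused.
#' @return A ggplot of anchored distance versus line index.
#' @exportS3Method ggplot2::autoplot
autoplot.match_result <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(.data$line, .data$d_px)) +
    ggplot2::geom_hline(yintercept = 0, linetype = 2, colour = "grey50") +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::labs(
      x = "corresponding line",
      y = "distance xL - xR (px, anchored)"
    )
}
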