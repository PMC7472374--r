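#' Ideal/distorted point correspondences
#'
#' Pairs each ideal calibration point with its observed (distorted)
#' counterpart, re-expressed relative to the image centre
#' `(xc, yc) = (width/2, height/2)`. The centre-relative radii `ru`
#' (ideal) and `rd` (distorted) drive all downstream distortion-ratio
#' computations. Pairs at exactly zero distorted radius carry no ratio
#' information and are dropped.
#'
#' @param ideal,distorted n x 2 matrices (or data frames) of absolute pixel
#'   coordinates (0-based), row-aligned pairs.
#' @param center Length-2 vector `(xc, yc)` in absolute px.
#' @return A tibble of class `correspondences` with columns `xu`, `yu`,
#'   `xd`, `yd` (centre-relative px), `ru`, `rd` and `half` (`"left"` when
#'   `xd <= 0`, the centre column counting as left).
#' @export
correspondences <- function(ideal, distorted, center) {
  iu <- as_points_matrix(ideal)
  id <- as_points_matrix(distorted)
  if (nrow(iu) != nrow(id)) abort("`ideal` and `distorted` must pair row by row.")
  if (length(center) != 2L) abort("`center` must be (xc, yc).")
  xu <- iu[, 1] - center[1]
  yu <- iu[, 2] - center[2]
  xd <- id[, 1] - center[1]
  yd <- id[, 2] - center[2]
  out <- tibble(
    xu = xu, yu = yu, xd = xd, yd = yd,
    ru = sqrt(xu^2 + yu^2), rd = sqrt(xd^2 + yd^2),
    half = ifelse(xd <= 0, "left", "right")
  )
  out <- out[out$rd > 0, ]
  attr(out, "center") <- as.numeric(center)
  class(out) <- c("correspondences", class(out))
  out
}

#' Per-pair distortion ratio R = ru / rd
#'
#' The distortion ratio of a correspondence is the ideal radius divided by
#' the distorted radius. For the positive-displacement pincushion studied
#' here, observed points sit closer to the centre than their ideal
#' positions, so R >= 1 everywhere and grows with the distortion; pairs
#' with R < 1 (barrel-like) are flagged with a warning rather than
#' silently accepted.
#'
#' @param corr A [correspondences()] tibble.
#' @return The same tibble with a new column `R`.
#' @examples
#' # ru = 1, rd = 0.9 -> R = 1.1111...
#' @export
distortion_ratio <- function(corr) {
  if (any(corr$rd <= 0)) abort("All pairs must have distorted radius rd > 0.")
  corr$R <- corr$ru / corr$rd
  if (any(corr$R < 1 - 1e-9)) {
    warn(sprintf(
      "%d pair(s) have R < 1 (barrel-like displacement) in pincushion input.",
      sum(corr$R < 1 - 1e-9)
    ))
  }
  corr
}

#' Smooth per-half distortion-ratio field
#'
#' Fits `R - 1` as an even polynomial in the distorted radius with zero
#' constant term (radial distortion vanishes at the centre, so `R(0) = 1`),
#' separately for the left and right half-images, by ordinary least
#' squares. The default degree 2 fits a single `rd^2` coefficient per
#' half, the dominant term of fine radial distortion.
#'
#' @param corr A [correspondences()] tibble (the `R` column is computed if
#'   absent).
#' @param degree Even polynomial degree (2 or 4).
#' @return A `ratio_field`: per-half coefficients (one per even power),
#'   fitted radius ranges and residual standard deviations.
#' @export
fit_ratio_field <- function(corr, degree = 2) {
  if (degree %% 2 != 0 || degree < 2) abort("`degree` must be a positive even integer.")
  if (!("R" %in% names(corr))) corr <- distortion_ratio(corr)
  n_coef <- degree / 2
  halves <- list()
  for (h in c("left", "right")) {
    sub <- corr[corr$half == h, ]
    if (nrow(sub) < degree + 1) {
      abort(sprintf(
        "Underdetermined fit: %d pair(s) in the %s half, need >= %d.",
        nrow(sub), h, degree + 1
      ))
    }
    basis <- vapply(seq_len(n_coef), function(j) sub$rd^(2 * j),
                    numeric(nrow(sub)))
    fit <- lm.fit(as.matrix(basis), sub$R - 1)
    halves[[h]] <- list(
      coef = unname(fit$coefficients),
      rmax = max(sub$rd),
      sigma = sqrt(mean(fit$residuals^2))
    )
  }
  structure(
    list(left = halves$left, right = halves$right, degree = degree,
         n = nrow(corr)),
    class = "ratio_field"
  )
}

#' Construct a ratio field from known coefficients
#'
#' Mostly used to build analytic or identity fields (e.g. all-zero
#' coefficients give the identity correction).
#'
#' @param left_coef,right_coef Numeric vectors of even-power coefficients
#'   (`rd^2`, `rd^4`, ...) for `R - 1` in each half.
#' @param rmax Radius (px) up to which the field is considered fitted;
#'   evaluation clamps beyond it.
#' @return A `ratio_field`.
#' @export
ratio_field <- function(left_coef, right_coef, rmax) {
  if (length(left_coef) != length(right_coef)) {
    abort("Both halves must have the same polynomial degree.")
  }
  structure(
    list(
      left = list(coef = left_coef, rmax = rmax, sigma = 0),
      right = list(coef = right_coef, rmax = rmax, sigma = 0),
      degree = 2 * length(left_coef), n = 0L
    ),
    class = "ratio_field"
  )
}

#' @export
print.ratio_field <- function(x, ...) {
  cat(sprintf(
    "<ratio_field> degree %d | left: %s | right: %s (rmax %.1f / %.1f px)\n",
    x$degree,
    paste(signif(x$left$coef, 4), collapse = ", "),
    paste(signif(x$right$coef, 4), collapse = ", "),
    x$left$rmax, x$right$rmax
  ))
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.ratio_field <- function(x, ...) {
  n_coef <- x$degree / 2
  tibble(
    half = rep(c("left", "right"), each = n_coef),
    term = rep(paste0("rd^", 2 * seq_len(n_coef)), 2),
    estimate = c(x$left$coef, x$right$coef)
  )
}

#' Evaluate a ratio field
#'
#' Returns `R(rd)` per point, using the half-specific coefficients;
#' evaluation is clamped to the fitted radius range (a warning notes any
#' extrapolation).
#'
#' @param field A `ratio_field`.
#' @param rd Distorted radii (px).
#' @param half Character vector `"left"`/`"right"`, recycled.
#' @param warn_extrapolation Warn when `rd` exceeds the fitted range?
#' @return Numeric vector of distortion ratios, `>= 1` at the origin by
#'   construction (`R(0) = 1`).
#' @export
eval_ratio_field <- function(field, rd, half, warn_extrapolation = TRUE) {
  half <- rep_len(half, length(rd))
  rmax <- ifelse(half == "left", field$left$rmax, field$right$rmax)
  if (warn_extrapolation && any(rd > rmax + 1e-9)) {
    warn(sprintf(
      "Clamping %d radii beyond the fitted range (max fitted rd = %.1f px).",
      sum(rd > rmax + 1e-9), max(rmax)
    ))
  }
  r <- pmin(rd, rmax)
  out <- rep(1, length(rd))
  n_coef <- field$degree / 2
  for (j in seq_len(n_coef)) {
    cj <- ifelse(half == "left", field$left$coef[j], field$right$coef[j])
    out <- out + cj * r^(2 * j)
  }
  out
}

# Distortion coefficient implied by the field, k = (1 - R) / rd^2, written
# as the even polynomial -(c1 + c2 rd^2 + ...) so the rd -> 0 limit (-c1)
# is exact. Uses the clamped radius, consistent with eval_ratio_field().
field_coefficient_k <- function(field, rd, half) {
  half <- rep_len(half, length(rd))
  rmax <- ifelse(half == "left", field$left$rmax, field$right$rmax)
  r <- pmin(rd, rmax)
  out <- rep(0, length(rd))
  n_coef <- field$degree / 2
  for (j in seq_len(n_coef)) {
    cj <- ifelse(half == "left", field$left$coef[j], field$right$coef[j])
    out <- out - cj * r^(2 * j - 2)
  }
  out
}

#' Distortion coefficient k = (1 - R) / rd^2
#'
#' Reduces the division model to its second-order term: `k` is negative for
#' pincushion pairs (R > 1) and zero exactly when the pair is undistorted.
#'
#' @param R Distortion ratio(s).
#' @param rd Distorted radius/radii in px, > 0.
#' @return Numeric vector of coefficients.
#' @examples
#' coefficient_k(1.25, 2) # -0.0625
#' @export
coefficient_k <- function(R, rd) {
  if (any(rd <= 0)) abort("`rd` must be > 0 (k is undefined at the centre).")
  (1 - R) / rd^2
}

#' Correction coefficient lambda
#'
#' Solves the second-order division model for the per-pixel correction
#' coefficient: `lambda = (-1 + sqrt(1 + 4 k ru^2)) / (2 k ru^2)`,
#' equivalently the root of `k ru^2 lambda^2 + lambda - 1 = 0` that tends
#' to 1 as the distortion vanishes. The product `k * ru^2` is formed once
#' and the numerically stable form `2 / (1 + sqrt(1 + 4 q))` is used, with
#' the exact limit `lambda = 1` returned when `|k ru^2| < 1e-12`.
#'
#' @param k Distortion coefficient(s) from [coefficient_k()].
#' @param ru Ideal radius/radii in px.
#' @return Numeric vector of correction coefficients; `lambda > 1` for
#'   pincushion input (points are pushed back outward).
#' @examples
#' lambda_coefficient(-0.137174, 1) # 1.19639...
#' @export
lambda_coefficient <- function(k, ru) {
  lambda_from_q(k * ru^2)
}

# lambda from the scale-invariant product q = k * ru^2; with ru = R * rd
# and k = (1 - R) / rd^2 this is (1 - R) * R^2, free of any radius division
lambda_from_q <- function(q) {
  disc <- 1 + 4 * q
  if (any(disc < 0)) {
    abort("1 + 4 k ru^2 < 0: distortion too strong for the second-order model.")
  }
  out <- 2 / (1 + sqrt(disc))
  out[abs(q) < 1e-12] <- 1
  out
}

#' Build the per-pixel Distortion Correction Matrix
#'
#' Evaluates, at every pixel of the image grid, the distorted radius `rd`
#' (distance to the centre), the field ratio `R`, the implied ideal radius
#' `ru = R * rd` (the ideal radius is unknown at correction time, so it is
#' reconstructed from the fitted field), the coefficient `k` and the
#' correction coefficient `lambda`. The left and right halves use their own
#' field coefficients; a pixel exactly on the centre column counts as left.
#'
#' @param field A `ratio_field`.
#' @param width_px,height_px Image grid size.
#' @return A `dcm` object holding the `R`, `k` and `lambda` matrices
#'   (height x width), the centre and the generating field.
#' @export
build_dcm <- function(field, width_px, height_px) {
  w <- as.integer(width_px)
  h <- as.integer(height_px)
  if (w <= 0 || h <= 0) abort("Image dimensions must be positive.")
  cx <- w / 2
  cy <- h / 2
  xr <- rep(seq_len(w) - 1 - cx, each = h)
  yr <- rep(seq_len(h) - 1 - cy, times = w)
  rd <- sqrt(xr^2 + yr^2)
  half <- ifelse(xr <= 0, "left", "right")
  R <- eval_ratio_field(field, rd, half, warn_extrapolation = FALSE)
  # k = (1 - R) / rd^2; at the centre the exact polynomial limit applies
  k <- ifelse(rd > 0, (1 - R) / pmax(rd, .Machine$double.eps)^2,
              field_coefficient_k(field, rd, half))
  # lambda from the scale-invariant product k * ru^2 = (1 - R) * R^2
  lam <- lambda_from_q((1 - R) * R^2)
  structure(
    list(
      R = matrix(R, h, w), k = matrix(k, h, w), lambda = matrix(lam, h, w),
      center = c(cx, cy), width_px = w, height_px = h, field = field
    ),
    class = "dcm"
  )
}

#' Identity DCM (no correction)
#'
#' @inheritParams build_dcm
#' @return A `dcm` with `lambda` identically 1.
#' @export
identity_dcm <- function(width_px, height_px) {
  rmax <- sqrt((width_px / 2)^2 + (height_px / 2)^2)
  build_dcm(ratio_field(0, 0, rmax), width_px, height_px)
}

#' @export
print.dcm <- function(x, ...) {
  cat(sprintf(
    "<dcm> %d x %d px, centre (%g, %g), lambda in [%.6f, %.6f]\n",
    x$width_px, x$height_px, x$center[1], x$center[2],
    min(x$lambda), max(x$lambda)
  ))
  invisible(x)
}

#' @exportS3Method generics::glance
glance.dcm <- function(x, ...) {
  tibble(
    width_px = x$width_px, height_px = x$height_px,
    lambda_min = min(x$lambda), lambda_max = max(x$lambda),
    lambda_max_left = max(x$lambda[, seq_len(floor(x$width_px / 2))]),
    lambda_max_right = max(x$lambda[, -seq_len(floor(x$width_px / 2))]),
    degree = x$field$degree
  )
}

#' Plot the per-pixel correction coefficient of a DCM
#'
#' @param object A `dcm`.
#' @param ... Unused.
#' @return A ggplot heat map of `lambda`.
#' @exportS3Method ggplot2::autoplot
autoplot.dcm <- function(object, ...) {
  df <- tibble(
    x = rep(seq_len(object$width_px) - 1L, each = object$height_px),
    y = rep(seq_len(object$height_px) - 1L, times = object$width_px),
    lambda = as.vector(object$lambda)
  )
  ggplot2::ggplot(df, ggplot2::aes(.data$x, .data$y, fill = .data$lambda)) +
    ggplot2::geom_raster() +
    ggplot2::scale_y_reverse() +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "x (px)", y = "y (px)", fill = expression(lambda))
}

#' Relocate points with a DCM
#'
#' Applies the forward correction `(xn, yn) = lambda * (xd - xc, yd - yc) +
#' (xc, yc)`: each distorted point is pushed radially outward to (an
#' approximation of) its ideal position. `lambda` is evaluated from the
#' generating field at the exact point radius, which agrees with the stored
#' per-pixel matrix at integer pixel centres.
#'
#' @param dcm A `dcm`.
#' @param points n x 2 matrix (or data frame) of absolute pixel
#'   coordinates inside the image.
#' @return n x 2 matrix of corrected absolute coordinates.
#' @export
map_point <- function(dcm, points) {
  pts <- as_points_matrix(points)
  if (any(pts[, 1] < -0.5 | pts[, 1] > dcm$width_px - 0.5 |
          pts[, 2] < -0.5 | pts[, 2] > dcm$height_px - 0.5)) {
    abort("Points must lie inside the image.")
  }
  xr <- pts[, 1] - dcm$center[1]
  yr <- pts[, 2] - dcm$center[2]
  rd <- sqrt(xr^2 + yr^2)
  half <- ifelse(xr <= 0, "left", "right")
  R <- eval_ratio_field(dcm$field, rd, half, warn_extrapolation = FALSE)
  lam <- lambda_from_q((1 - R) * R^2)
  cbind(lam * xr + dcm$center[1], lam * yr + dcm$center[2])
}

#' Serialize a DCM to JSON
#'
#' Stores the generating field (per-half coefficients, fitted ranges),
#' centre and grid size; the per-pixel matrices are rebuilt on read, so the
#' file stays small and text-based.
#'
#' @param dcm A `dcm`.
#' @param path Output JSON path.
#' @return `path`, invisibly.
#' @export
write_dcm <- function(dcm, path) {
  jsonlite::write_json(
    list(
      width_px = dcm$width_px, height_px = dcm$height_px,
      center = dcm$center, degree = dcm$field$degree,
      left = dcm$field$left[c("coef", "rmax")],
      right = dcm$field$right[c("coef", "rmax")]
    ),
    path, auto_unbox = TRUE, digits = NA
  )
  invisible(path)
}

#' @rdname write_dcm
#' @export
read_dcm <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  need <- c("width_px", "height_px", "degree", "left", "right")
  if (!all(need %in% names(j))) abort("Not a valid DCM file (missing fields).")
  field <- structure(
    list(
      left = list(coef = as.numeric(j$left$coef), rmax = j$left$rmax, sigma = NA_real_),
      right = list(coef = as.numeric(j$right$coef), rmax = j$right$rmax, sigma = NA_real_),
      degree = j$degree, n = 0L
    ),
    class = "ratio_field"
  )
  build_dcm(field, j$width_px, j$height_px)
}
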