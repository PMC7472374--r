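#' Grayscale raster image with object-plane sampling density
#'
#' The universal image carrier of the package: a numeric matrix of
#' intensities in \[0, 1\] (rows are image rows, i.e. the y axis pointing
#' down; columns are x) plus the object-plane sampling density in pixels
#' per millimetre. Pixel coordinates are 0-based throughout: the pixel
#' stored at row `r`, column `c` has centre `(x, y) = (c - 1, r - 1)`.
#' The distortion centre used by the correction is `(width/2, height/2)`.
#'
#' @param pixels Numeric matrix of intensities in \[0, 1\].
#' @param px_per_mm Positive scalar, object-plane pixels per millimetre.
#' @return A `gray_image` object.
#' @examples
#' img <- gray_image(matrix(runif(12), 3, 4), px_per_mm = 10)
#' dim(img$pixels)
#' @export
gray_image <- function(pixels, px_per_mm) {
  if (!is.matrix(pixels) || !is.numeric(pixels)) {
    abort("`pixels` must be a numeric matrix.")
  }
  if (anyNA(pixels) || min(pixels) < -1e-9 || max(pixels) > 1 + 1e-9) {
    abort("Image intensities must lie in [0, 1] and contain no NA.")
  }
  if (!is.numeric(px_per_mm) || length(px_per_mm) != 1L || px_per_mm <= 0) {
    abort("`px_per_mm` must be a positive scalar.")
  }
  structure(
    list(
      pixels = pmin(pmax(pixels, 0), 1),
      width_px = ncol(pixels),
      height_px = nrow(pixels),
      px_per_mm = px_per_mm
    ),
    class = "gray_image"
  )
}

#' @export
print.gray_image <- function(x, ...) {
  cat(sprintf(
    "<gray_image> %d x %d px, %.4g px/mm (%.3g x %.3g mm), intensity [%.3f, %.3f]\n",
    x$width_px, x$height_px, x$px_per_mm,
    x$width_px / x$px_per_mm, x$height_px / x$px_per_mm,
    min(x$pixels), max(x$pixels)
  ))
  invisible(x)
}

#' @export
dim.gray_image <- function(x) c(x$height_px, x$width_px)

is_gray_image <- function(x) inherits(x, "gray_image")

stopifnot_same_dims <- function(a, b, what = "images") {
  if (a$width_px != b$width_px || a$height_px != b$height_px) {
    abort(sprintf(
      "Dimension mismatch between %s: %dx%d vs %dx%d.",
      what, a$width_px, a$height_px, b$width_px, b$height_px
    ))
  }
}

#' Convert a grayscale image to a long tibble of pixel intensities
#'
#' @param x A [gray_image()].
#' @param ... Unused.
#' @return A tibble with 0-based `x`, `y` pixel coordinates and `intensity`.
#' @exportS3Method tibble::as_tibble
as_tibble.gray_image <- function(x, ...) {
  tibble(
    x = rep(seq_len(x$width_px) - 1L, each = x$height_px),
    y = rep(seq_len(x$height_px) - 1L, times = x$width_px),
    intensity = as.vector(x$pixels)
  )
}

#' Plot a grayscale image
#'
#' @param object A [gray_image()].
#' @param ... Unused.
#' @return A ggplot object (reversed y axis so the image reads as displayed).
#' @exportS3Method ggplot2::autoplot
autoplot.gray_image <- function(object, ...) {
  df <- as_tibble(object)
  ggplot2::ggplot(df, ggplot2::aes(.data$x, .data$y, fill = .data$intensity)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_gradient(low = "black", high = "white", limits = c(0, 1)) +
    ggplot2::scale_y_reverse() +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "x (px)", y = "y (px)", fill = "intensity")
}

#' @export
plot.gray_image <- function(x, ...) print(autoplot(x, ...))

#' Read and write grayscale PNG images
#'
#' `write_gray_png()` stores a [gray_image()] as an 8-bit grayscale PNG and,
#' optionally, a JSON sidecar holding `px_per_mm` and any extra metadata.
#' `read_gray_png()` reads a PNG back (converting colour input to grayscale
#' with the Rec. 601 luma weights 0.299, 0.587, 0.114), picking `px_per_mm`
#' from the sidecar when present.
#'
#' @param image A [gray_image()].
#' @param path PNG file path.
#' @param meta Named list of extra metadata for the sidecar (optional).
#' @param sidecar Write `<path>.json` with metadata? Default `TRUE`.
#' @return `write_gray_png()` returns `path` invisibly; `read_gray_png()`
#'   returns a `gray_image`.
#' @export
write_gray_png <- function(image, path, meta = list(), sidecar = TRUE) {
  stopifnot(is_gray_image(image))
  png::writePNG(image$pixels, target = path, dpi = NULL)
  if (isTRUE(sidecar)) {
    meta$px_per_mm <- image$px_per_mm
    jsonlite::write_json(meta, paste0(path, ".json"),
      auto_unbox = TRUE, digits = NA
    )
  }
  invisible(path)
}

#' @rdname write_gray_png
#' @param px_per_mm Sampling density to use when no sidecar is found.
#' @export
read_gray_png <- function(path, px_per_mm = NULL) {
  px <- png::readPNG(path)
  if (length(dim(px)) == 3L) {
    nc <- dim(px)[3]
    px <- if (nc >= 3L) {
      0.299 * px[, , 1] + 0.587 * px[, , 2] + 0.114 * px[, , 3]
    } else {
      px[, , 1]
    }
  }
  side <- paste0(path, ".json")
  if (is.null(px_per_mm)) {
    if (file.exists(side)) {
      px_per_mm <- jsonlite::read_json(side)$px_per_mm
    } else {
      abort("No `px_per_mm` given and no JSON sidecar found.")
    }
  }
  gray_image(px, px_per_mm = as.numeric(px_per_mm))
}
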