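#' Correct a full image with a DCM by forward mapping
#'
#' Relocates every source pixel through the per-pixel correction (see
#' [map_point()]) and splats it onto the nearest integer target cell.
#' Because the pincushion correction pushes content outward, some in-bounds
#' target cells receive no source pixel: these form the hole mask. Targets
#' falling outside the image are dropped. When two sources land on the same
#' cell the source with the smaller distorted radius wins (it carries the
#' less-distorted information); remaining ties go to the first source in
#' row-major order, so the splat is fully deterministic.
#'
#' @param image A [gray_image()].
#' @param dcm A `dcm` with the same dimensions.
#' @return List with `corrected` (a `gray_image`) and `mask` (a
#'   `hole_mask`: logical matrix plus its `hole_fraction`). Hole cells are
#'   left at intensity 0 until filled.
#' @export
correct_image <- function(image, dcm) {
  stopifnot(is_gray_image(image))
  if (image$width_px != dcm$width_px || image$height_px != dcm$height_px) {
    abort(sprintf(
      "DCM (%dx%d) and image (%dx%d) dimensions differ.",
      dcm$width_px, dcm$height_px, image$width_px, image$height_px
    ))
  }
  w <- image$width_px
  h <- image$height_px
  cx <- dcm$center[1]
  cy <- dcm$center[2]
  xr <- rep(seq_len(w) - 1 - cx, each = h)
  yr <- rep(seq_len(h) - 1 - cy, times = w)
  lam <- as.vector(dcm$lambda)
  tx <- round(lam * xr + cx)
  ty <- round(lam * yr + cy)
  rd <- sqrt(xr^2 + yr^2)

  inb <- tx >= 0 & tx <= w - 1 & ty >= 0 & ty <= h - 1
  src <- which(inb)
  tgt <- ty[inb] + 1 + tx[inb] * h # column-major index of target cell
  # winners first: smaller rd, then row-major source order as tie-break
  ord <- order(rd[inb], src)
  tgt <- tgt[ord]
  src <- src[ord]
  keep <- !duplicated(tgt)

  out <- matrix(0, h, w)
  out[tgt[keep]] <- image$pixels[src[keep]]
  hit <- matrix(FALSE, h, w)
  hit[tgt[keep]] <- TRUE
  mask <- !hit
  structure_mask <- structure(
    list(mask = mask, hole_fraction = sum(mask) / length(mask)),
    class = "hole_mask"
  )
  list(
    corrected = gray_image(out, px_per_mm = image$px_per_mm),
    mask = structure_mask
  )
}

#' @export
print.hole_mask <- function(x, ...) {
  cat(sprintf(
    "<hole_mask> %d x %d, %d holes (%.4f%%)\n",
    ncol(x$mask), nrow(x$mask), sum(x$mask), 100 * x$hole_fraction
  ))
  invisible(x)
}

#' Fraction of cells that are holes
#'
#' @param mask A `hole_mask`.
#' @return `count(holes) / count(cells)`, in \[0, 1\].
#' @export
hole_fraction <- function(mask) {
  if (!inherits(mask, "hole_mask")) abort("`mask` must be a hole_mask.")
  sum(mask$mask) / length(mask$mask)
}

#' Fill hole cells from their nearest non-hole neighbours
#'
#' Every hole cell takes the intensity of its Euclidean-nearest non-hole
#' cell (donors are always original non-hole cells, so the fill is
#' idempotent). Among equidistant donors the one with the smallest row
#' index, then smallest column index, wins — a fixed tie-break that makes
#' the fill deterministic. Suited to the thin hole arcs left by fine
#' pincushion correction, where the neighbouring pixels continue the same
#' image structure.
#'
#' @param image A [gray_image()] (typically the `corrected` output of
#'   [correct_image()]).
#' @param mask The matching `hole_mask`.
#' @return A filled `gray_image`.
#' @export
fill_holes_nearest <- function(image, mask) {
  stopifnot(is_gray_image(image), inherits(mask, "hole_mask"))
  m <- mask$mask
  if (nrow(m) != image$height_px || ncol(m) != image$width_px) {
    abort("Mask and image dimensions differ.")
  }
  if (all(m)) abort("The mask covers the entire image: nothing to fill from.")
  if (!any(m)) return(image)

  h <- nrow(m)
  w <- ncol(m)
  px <- image$pixels
  holes <- which(m) # column-major indices
  hr <- ((holes - 1) %% h) + 1
  hc <- ((holes - 1) %/% h) + 1
  unfilled <- rep(TRUE, length(holes))

  # Donor offsets are visited in strictly increasing Euclidean distance;
  # equidistant offsets are visited in (drow, dcol) order so the donor with
  # the smallest row index, then column index, wins. Euclidean distance
  # interleaves across Chebyshev rings, so ring-r offsets with distance > r
  # wait in a pending pool until every nearer offset has been generated.
  max_cheb <- max(h, w)
  pending <- data.frame(dr = integer(), dc = integer(), dist = numeric())
  r <- 1
  while (any(unfilled) && r <= max_cheb) {
    ring <- expand.grid(dr = -r:r, dc = -r:r)
    ring <- ring[pmax(abs(ring$dr), abs(ring$dc)) == r, ]
    ring$dist <- sqrt(ring$dr^2 + ring$dc^2)
    pending <- rbind(pending, ring)
    ready <- pending$dist <= r + 1e-12
    batch <- pending[ready, ]
    pending <- pending[!ready, ]
    batch <- batch[order(batch$dist, batch$dr, batch$dc), ]
    for (k in seq_len(nrow(batch))) {
      idx <- which(unfilled)
      if (length(idx) == 0) break
      rr <- hr[idx] + batch$dr[k]
      cc <- hc[idx] + batch$dc[k]
      ok <- rr >= 1 & rr <= h & cc >= 1 & cc <= w
      if (!any(ok)) next
      donor <- (cc[ok] - 1) * h + rr[ok]
      good <- !m[donor] # donor must be an original non-hole cell
      if (!any(good)) next
      tgt_idx <- idx[ok][good]
      px[holes[tgt_idx]] <- image$pixels[donor[good]]
      unfilled[tgt_idx] <- FALSE
    }
    r <- r + 1
  }
  if (any(unfilled)) abort("Could not find donors for all holes.")
  gray_image(px, px_per_mm = image$px_per_mm)
}

#' Absolute difference image
#'
#' Per-pixel absolute difference `|a - b|`, clipped to \[0, 1\]. Used to
#' visualise where a correction moved image content: for radial distortion
#' the differences concentrate toward the left/right borders and vanish at
#' the centre.
#'
#' @param a,b [gray_image()]s of equal dimensions.
#' @return A `gray_image` of absolute differences.
#' @export
subtract_images <- function(a, b) {
  stopifnot(is_gray_image(a), is_gray_image(b))
  stopifnot_same_dims(a, b)
  gray_image(pmin(pmax(abs(a$pixels - b$pixels), 0), 1), px_per_mm = a$px_per_mm)
}
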