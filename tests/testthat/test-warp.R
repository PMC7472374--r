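make_test_image <- function(w = 120, h = 90, seed = 7) {
  set.seed(seed)
  gray_image(matrix(runif(w * h), h, w), px_per_mm = 20)
}

test_that("identity DCM leaves the image untouched with zero holes", {
  img <- make_test_image()
  res <- correct_image(img, identity_dcm(120, 90))
  expect_identical(res$corrected$pixels, img$pixels)
  expect_equal(hole_fraction(res$mask), 0)
  expect_identical(fill_holes_nearest(res$corrected, res$mask)$pixels,
                   img$pixels)
})

test_that("splatting never invents intensity values", {
  img <- make_test_image()
  dcm <- build_dcm(ratio_field(1e-6, 2e-6, rmax = 100), 120, 90)
  res <- correct_image(img, dcm)
  vals <- res$corrected$pixels[!res$mask$mask]
  expect_true(all(vals %in% img$pixels))
  expect_error(correct_image(img, identity_dcm(60, 60)), "differ")
})

test_that("forward splat is deterministic", {
  img <- make_test_image()
  dcm <- build_dcm(ratio_field(1e-6, 2e-6, rmax = 100), 120, 90)
  a <- correct_image(img, dcm)
  b <- correct_image(img, dcm)
  expect_identical(a$corrected$pixels, b$corrected$pixels)
  expect_identical(a$mask$mask, b$mask$mask)
})

test_that("hole fraction counts holes and grows with distortion strength", {
  m <- matrix(FALSE, 20, 50)
  m[1, 1] <- m[5, 7] <- TRUE
  hm <- structure(list(mask = m, hole_fraction = 2 / 1000), class = "hole_mask")
  expect_equal(hole_fraction(hm), 0.002)
  empty <- structure(list(mask = matrix(FALSE, 5, 5), hole_fraction = 0),
                     class = "hole_mask")
  expect_equal(hole_fraction(empty), 0)

  img <- make_test_image(160, 120)
  fracs <- vapply(c(5e-7, 1e-6, 2e-6), function(cc) {
    dcm <- build_dcm(ratio_field(cc, cc, rmax = 120), 160, 120)
    hole_fraction(correct_image(img, dcm)$mask)
  }, numeric(1))
  expect_true(all(diff(fracs) >= 0))
  expect_gt(fracs[3], 0)
})

test_that("nearest-neighbour fill takes the closest donor, deterministically", {
  px <- matrix(0.5, 9, 9)
  px[5, 6] <- 0.9
  img <- gray_image(px, 10)
  m <- matrix(FALSE, 9, 9)
  m[5, 5] <- TRUE
  img$pixels[5, 5] <- 0
  mask <- structure(list(mask = m, hole_fraction = sum(m) / 81),
                    class = "hole_mask")
  # equidistant donors at (4,5), (5,4), (5,6), (6,5): smallest row wins
  filled <- fill_holes_nearest(img, mask)
  expect_equal(filled$pixels[5, 5], 0.5)
  expect_equal(filled$pixels[-5, ], img$pixels[-5, ]) # non-holes unchanged

  # unique nearest donor is used even when farther cells differ
  px2 <- matrix(0.2, 7, 7)
  img2 <- gray_image(px2, 10)
  m2 <- matrix(FALSE, 7, 7)
  m2[5, 5] <- m2[4, 5] <- m2[6, 5] <- m2[5, 4] <- TRUE
  img2$pixels[3, 5] <- 0.8 # nearest original non-hole above the hole column
  mask2 <- structure(list(mask = m2, hole_fraction = sum(m2) / 49),
                     class = "hole_mask")
  filled2 <- fill_holes_nearest(img2, mask2)
  expect_equal(filled2$pixels[4, 5], 0.8)

  # empty mask: unchanged; full mask: error
  none <- structure(list(mask = matrix(FALSE, 7, 7), hole_fraction = 0),
                    class = "hole_mask")
  expect_identical(fill_holes_nearest(img2, none)$pixels, img2$pixels)
  full <- structure(list(mask = matrix(TRUE, 7, 7), hole_fraction = 1),
                    class = "hole_mask")
  expect_error(fill_holes_nearest(img2, full), "entire image")
})

test_that("hole filling is idempotent", {
  img <- make_test_image(160, 120)
  dcm <- build_dcm(ratio_field(1.5e-6, 1.5e-6, rmax = 120), 160, 120)
  res <- correct_image(img, dcm)
  once <- fill_holes_nearest(res$corrected, res$mask)
  twice <- fill_holes_nearest(once, res$mask)
  expect_identical(once$pixels, twice$pixels)
  expect_false(any(res$mask$mask & once$pixels != twice$pixels))
})

test_that("subtraction images are absolute clipped differences", {
  a <- gray_image(matrix(0.7, 10, 10), 5)
  b <- gray_image(matrix(0.2, 10, 10), 5)
  expect_equal(max(abs(subtract_images(a, b)$pixels - 0.5)), 0, tolerance = 1e-12)
  expect_equal(max(abs(subtract_images(b, a)$pixels - 0.5)), 0, tolerance = 1e-12)
  expect_true(all(subtract_images(a, a)$pixels == 0))
  expect_error(subtract_images(a, gray_image(matrix(0, 5, 5), 5)), "mismatch")
})

test_that("distort-correct-fill closes the loop on a rendered pattern", {
  pat <- make_vertical_line_pattern(1500, 8, 1, 20)
  cfg <- stereo_config(60, width_px = 400, height_px = 120)
  pair <- render_distorted_stereo(pat, cfg, distortion_spec())
  dcm <- calibrate_dcm(pair$reference, pair$ideal_reference)
  out <- correct_and_fill(pair$reference, dcm)
  diff <- abs(out$filled$pixels - pair$ideal_reference$pixels)
  # mask a 2 px band around ideal line centres: residual subpixel shifts
  # concentrate intensity error at the steep line edges
  centres <- round(pair$lines_reference$x_ideal_px) + 1
  edge_cols <- unique(pmax(1, pmin(400, c(outer(centres, -4:4, `+`)))))
  rms_flat <- sqrt(mean(diff[, -edge_cols]^2))
  expect_lt(rms_flat, 0.05)
  # differences against the distorted input concentrate toward the borders
  sub <- out$subtraction$pixels
  border_energy <- mean(sub[, c(1:80, 321:400)])
  centre_energy <- mean(sub[, 161:240])
  expect_gt(border_energy, centre_energy)
})
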