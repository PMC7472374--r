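# independent oracle: lambda as the root of k*ru^2 * L^2 + L - 1 = 0
# nearest 1, found by polyroot
lambda_oracle <- function(k, ru) {
  q <- k * ru^2
  if (abs(q) < 1e-300) return(1)
  rts <- Re(polyroot(c(-1, 1, q)))
  rts[which.min(abs(rts - 1))]
}

test_that("distortion ratio is the quotient of radii", {
  corr <- correspondences(
    ideal = cbind(c(101, 102, 100), c(100, 100, 102)),
    distorted = cbind(c(100.9, 101.6, 100), c(100, 100, 101.8)),
    center = c(100, 100)
  )
  corr <- distortion_ratio(corr)
  expect_equal(corr$R, c(1 / 0.9, 2 / 1.6, 2 / 1.8))
  expect_equal(corr$R[1], 1.111111, tolerance = 1e-6)
  expect_equal(corr$R[2], 1.25)

  same <- distortion_ratio(correspondences(
    cbind(105, 100), cbind(105, 100), center = c(100, 100)
  ))
  expect_equal(same$R, 1)
})

test_that("zero-radius pairs are rejected or dropped", {
  corr <- correspondences(cbind(c(100, 103), c(100, 100)),
                          cbind(c(100, 102.5), c(100, 100)),
                          center = c(100, 100))
  expect_equal(nrow(corr), 1) # centre pair dropped on construction
  expect_error(coefficient_k(1.1, 0), "undefined at the centre")
})

test_that("coefficient k reduces the division model to second order", {
  expect_equal(coefficient_k(1 / 0.9, 0.9), (1 - 1 / 0.9) / 0.81)
  expect_equal(coefficient_k(1 / 0.9, 0.9), -0.137174, tolerance = 1e-5)
  expect_equal(coefficient_k(1, 5), 0)
  expect_equal(coefficient_k(1.25, 2), -0.0625)
  expect_true(all(coefficient_k(c(1.01, 1.1), c(1, 2)) < 0))
})

test_that("lambda solves its defining quadratic", {
  expect_equal(lambda_coefficient(-0.137174, 1), lambda_oracle(-0.137174, 1),
               tolerance = 1e-12)
  expect_equal(lambda_coefficient(-0.137174, 1), 1.196321, tolerance = 1e-6)
  l2 <- lambda_coefficient(-0.0102010, 1)
  expect_equal(l2, lambda_oracle(-0.0102010, 1), tolerance = 1e-12)
  expect_equal(l2, 1.0104146, tolerance = 1e-7)
  # Eq. (4) is approximate: lambda * rd ~ ru, close to but not exactly 1
  expect_equal(l2 * 0.990099, 1.0004105, tolerance = 1e-7)

  expect_equal(lambda_coefficient(0, 10), 1)
  expect_equal(lambda_coefficient(-1e-15, 1), 1) # below the limit threshold
  expect_error(lambda_coefficient(-0.3, 1), "too strong")

  # vectorised agreement with the oracle over a grid
  k <- -seq(0.001, 0.05, length.out = 25)
  ru <- seq(0.3, 1.5, length.out = 25)
  lam <- lambda_coefficient(k, ru)
  orc <- mapply(lambda_oracle, k, ru)
  expect_equal(lam, orc, tolerance = 1e-12)
  expect_true(all(abs(k * ru^2 * lam^2 + lam - 1) < 1e-12))
})

test_that("ratio-field fitting recovers generating coefficients within 1%", {
  corr <- synthetic_correspondences(c_left = 2e-7, c_right = 2e-7)
  field <- fit_ratio_field(corr, degree = 2)
  expect_lt(abs(field$left$coef[1] - 2e-7) / 2e-7, 0.01)
  expect_lt(abs(field$right$coef[1] - 2e-7) / 2e-7, 0.01)

  # asymmetric halves are recovered separately
  corr2 <- synthetic_correspondences(c_left = 1e-7, c_right = 2e-7)
  field2 <- fit_ratio_field(corr2, degree = 2)
  expect_lt(abs(field2$left$coef[1] - 1e-7) / 1e-7, 0.01)
  expect_lt(abs(field2$right$coef[1] - 2e-7) / 2e-7, 0.01)
})

test_that("undistorted correspondences give a null field and unit lambda", {
  corr <- synthetic_correspondences(c_left = 0, c_right = 0)
  field <- fit_ratio_field(corr)
  expect_equal(field$left$coef, 0, tolerance = 1e-15)
  expect_equal(field$right$coef, 0, tolerance = 1e-15)
  dcm <- build_dcm(field, 80, 60)
  expect_true(all(dcm$lambda == 1))
})

test_that("underdetermined fits are rejected", {
  corr <- synthetic_correspondences()
  left_only <- corr[corr$half == "left", ][1:2, ]
  expect_error(fit_ratio_field(left_only, degree = 2), "Underdetermined")
})

test_that("built DCM satisfies the quadratic-root identity at every pixel", {
  dcm <- build_dcm(analytic_test_field(), 160, 120)
  cx <- 80
  cy <- 60
  xr <- rep(seq_len(160) - 1 - cx, each = 120)
  yr <- rep(seq_len(120) - 1 - cy, times = 160)
  rd <- matrix(sqrt(xr^2 + yr^2), 120, 160)
  ru <- dcm$R * rd
  resid <- dcm$k * ru^2 * dcm$lambda^2 + dcm$lambda - 1
  expect_lt(max(abs(resid)), 1e-9)
  # structural invariants
  expect_true(all(is.finite(dcm$lambda)))
  expect_equal(dcm$lambda[dcm$R == 1], rep(1, sum(dcm$R == 1)))
  # asymmetric field: mirrored pixels differ
  expect_false(isTRUE(all.equal(dcm$lambda[, 40], dcm$lambda[, 122])))
})

test_that("pincushion lambda is >= 1 and non-decreasing in radius", {
  dcm <- build_dcm(analytic_test_field(), 200, 2)
  expect_true(all(dcm$lambda >= 1))
  mid_row <- dcm$lambda[1, ]
  right <- mid_row[101:200]
  left <- rev(mid_row[1:100])
  expect_true(all(diff(right) >= -1e-15))
  expect_true(all(diff(left) >= -1e-15))
})

test_that("map_point applies lambda about the centre", {
  field <- ratio_field(0, 0, rmax = 300)
  dcm <- build_dcm(field, 200, 200)
  pts <- cbind(c(100, 30, 170), c(100, 50, 120))
  expect_equal(map_point(dcm, pts), pts) # identity field
  expect_equal(map_point(dcm, cbind(100, 100)), cbind(100, 100))

  # worked example: R(9) = 10/9 at rd = 9 -> lambda from the oracle,
  # xn = 100 - 9 * lambda
  c1 <- (10 / 9 - 1) / 81
  dcm2 <- build_dcm(ratio_field(c1, c1, rmax = 9), 200, 200)
  k <- (1 - 10 / 9) / 81
  lam <- lambda_oracle(k, 10 / 9 * 9)
  got <- map_point(dcm2, cbind(91, 100))
  expect_equal(got[1, 1], 100 - 9 * lam, tolerance = 1e-9)
  expect_equal(got[1, 1], 89.2331, tolerance = 1e-4)
  expect_error(map_point(dcm2, cbind(500, 10)), "inside the image")
})

test_that("lambda approximation error is second order in (R - 1)", {
  # |lambda * rd - ru| <= C (R-1)^2 ru with a modest constant
  rd <- 350
  for (eps in c(1e-4, 1e-3, 5e-3, 1e-2)) {
    R <- 1 + eps
    ru <- R * rd
    lam <- lambda_coefficient(coefficient_k(R, rd), ru)
    err <- abs(lam * rd - ru)
    expect_lt(err, 6 * eps^2 * ru)
    expect_gt(err, 0.5 * eps^2 * ru) # genuinely quadratic, not smaller order
  }
})

test_that("point correction recovers ideal positions on weak distortion", {
  # magnitude chosen inside the second-order error budget for 0.05 px
  spec <- distortion_spec(-2e-8, 0, -3e-8, 0)
  pat <- make_vertical_line_pattern(1500, 8, 1, 20)
  cfg <- stereo_config(60, width_px = 800, height_px = 60)
  pair <- render_distorted_stereo(pat, cfg, spec)
  dcm <- calibrate_dcm(pair$reference, pair$ideal_reference)
  gt <- pair$lines_reference
  # stay inside the fitted radius range: evaluation clamps beyond it
  rmax <- min(dcm$field$left$rmax, dcm$field$right$rmax)
  gt <- gt[abs(gt$x_distorted_px - 400) <= rmax, ]
  corrected <- map_point(dcm, cbind(gt$x_distorted_px, 30))[, 1]
  expect_lt(max(abs(corrected - gt$x_ideal_px)), 0.05)
})

test_that("DCM serialises to JSON and back", {
  dcm <- build_dcm(analytic_test_field(), 120, 90)
  path <- withr::local_tempfile(fileext = ".json")
  write_dcm(dcm, path)
  back <- read_dcm(path)
  expect_equal(back$lambda, dcm$lambda)
  expect_equal(back$center, dcm$center)
  bad <- withr::local_tempfile(fileext = ".json")
  jsonlite::write_json(list(a = 1), bad, auto_unbox = TRUE)
  expect_error(read_dcm(bad), "valid DCM")
})
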