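test_that("pinhole geometry scales with working distance", {
  cfg60 <- stereo_config(60)
  cfg120 <- stereo_config(120)
  # doubling z at fixed focal length doubles the object-plane field of view
  expect_equal(
    cfg120$width_px / px_per_mm_at_object(cfg120),
    2 * cfg60$width_px / px_per_mm_at_object(cfg60)
  )
  expect_equal(px_per_mm_at_object(cfg60), 25)
})

test_that("angle of view follows 2*atan(half-width / z)", {
  # same half-width/z ratio gives the same angle: 2*atan(0.25) = 28.07 deg
  cfg <- stereo_config(60, pixel_pitch_mm = 5.6 * 30 / (60 * 800))
  expect_equal(angle_of_view(cfg), 2 * atan(0.25) * 180 / pi, tolerance = 1e-12)
  expect_equal(angle_of_view(cfg), 28.0725, tolerance = 1e-4)
  cfg80 <- stereo_config(80, pixel_pitch_mm = 5.6 * 40 / (80 * 800))
  expect_equal(angle_of_view(cfg80), angle_of_view(cfg), tolerance = 1e-12)
})

test_that("division model fixes the centre and is invertible", {
  spec <- distortion_spec()
  expect_equal(distort_points(cbind(0, 0), spec), cbind(0, 0))
  expect_equal(undistort_points(cbind(0, 0), spec), cbind(0, 0))

  id <- identity_spec()
  pts <- cbind(c(-300, -10, 5, 250), c(40, -200, 0, 100))
  expect_equal(distort_points(pts, id), pts)
  expect_equal(undistort_points(pts, id), pts)

  # round trip distort -> undistort over seeded random points
  set.seed(42)
  rnd <- cbind(runif(200, -390, 390), runif(200, -290, 290))
  back <- undistort_points(distort_points(rnd, spec), spec)
  expect_lt(max(abs(back - rnd)), 1e-8)
})

test_that("pincushion pulls points inward, asymmetrically per half", {
  spec <- distortion_spec()
  pts <- cbind(c(-350, -150, 150, 350), c(50, -80, 80, -50))
  dst <- distort_points(pts, spec)
  r_ideal <- sqrt(rowSums(pts^2))
  r_dist <- sqrt(rowSums(dst^2))
  expect_true(all(r_dist < r_ideal))

  # mirrored points displace by different amounts: right half is stronger
  d_left <- 300 - abs(distort_points(cbind(-300, 0), spec)[1, 1])
  d_right <- abs(distort_points(cbind(300, 0), spec)[1, 1]) - 300
  expect_gt(abs(d_right), abs(d_left))
  # direct evaluation of the forward model on both halves agrees
  expect_equal(
    undistort_points(cbind(-300, 0), spec)[1, 1],
    -300 / (1 + spec$lambda1_left * 9e4 + spec$lambda2_left * 8.1e9)
  )
})

test_that("projection translates the flat pattern by the lateral offset", {
  pat <- make_vertical_line_pattern(1400, 8, 1, 20)
  cfg <- stereo_config(60, pixel_pitch_mm = 5.6 * 30 / (60 * 800),
                       width_px = 800, height_px = 8)
  p0 <- project_pattern(pat, cfg, 0)
  p10 <- project_pattern(pat, cfg, 10)
  shared <- intersect(p0$lines$line, p10$lines$line)
  q <- px_per_mm_at_object(cfg)
  expect_equal(
    p0$lines$x_px[match(shared, p0$lines$line)] -
      p10$lines$x_px[match(shared, p10$lines$line)],
    rep(10 * q, length(shared))
  )
  narrow <- make_vertical_line_pattern(200, 8, 1, 20)
  expect_error(project_pattern(narrow, cfg), "narrower than the field")
})

test_that("scalar-bar depth adds the closed-form pinhole disparity excess", {
  bar <- make_scalar_bar(n_lines = 3, spacing_mm = 1, depth_step_mm = 0.05,
                         width_px = 300, height_px = 8, px_per_mm = 20)
  cfg <- stereo_config(60, baseline_mm = 10, width_px = 800, height_px = 8)
  ref <- project_pattern(bar, cfg, 0)$lines
  shf <- project_pattern(bar, cfg, 10)$lines
  disp_px <- ref$x_px - shf$x_px
  # line with depth d: sensor disparity b*f/(z - d); depth 0.05 mm exceeds
  # the flat-plane disparity by 10*5.6/59.95 - 10*5.6/60 (sensor mm)
  disp_sensor_mm <- disp_px * cfg$pixel_pitch_mm
  expected <- 10 * 5.6 / (60 - bar$line_depths_mm)
  expect_equal(disp_sensor_mm, expected, tolerance = 1e-12)
  expect_equal(disp_sensor_mm[2] - disp_sensor_mm[1],
               10 * 5.6 / 59.95 - 10 * 5.6 / 60, tolerance = 1e-12)
})

test_that("rendered stereo pairs carry consistent ground truth", {
  pat <- make_vertical_line_pattern(1500, 8, 1, 20)
  cfg <- stereo_config(60, width_px = 400, height_px = 60)
  pair <- render_distorted_stereo(pat, cfg, identity_spec())
  q <- px_per_mm_at_object(cfg)
  shared <- intersect(pair$lines_reference$line, pair$lines_shift$line)
  dl <- pair$lines_reference
  dr <- pair$lines_shift
  expect_equal(
    dl$x_distorted_px[match(shared, dl$line)] -
      dr$x_distorted_px[match(shared, dr$line)],
    rep(10 * q, length(shared))
  )
  # identity spec: distorted positions equal ideal positions
  expect_equal(dl$x_distorted_px, dl$x_ideal_px)

  dist_pair <- render_distorted_stereo(pat, cfg, distortion_spec())
  cx <- cfg$width_px / 2
  expect_true(all(
    abs(dist_pair$lines_reference$x_distorted_px - cx) <=
      abs(dist_pair$lines_reference$x_ideal_px - cx) + 1e-9
  ))
})

test_that("border displacement in object mm grows with working distance", {
  # fixed pixel-space distortion observed at a fixed fractional image
  # radius: the mm-valued displacement scales with the field of view
  spec <- distortion_spec()
  disp_mm <- vapply(seq(60, 80, by = 5), function(z) {
    cfg <- stereo_config(z)
    q <- px_per_mm_at_object(cfg)
    x <- 0.48 * cfg$width_px # fractional position, right half
    d <- distort_points(cbind(x, 0), spec)
    (x - d[1, 1]) / q
  }, numeric(1))
  expect_true(all(diff(disp_mm) > 0))
  # defaults are tuned to the 0.24-0.38 mm border-displacement band
  expect_gt(disp_mm[1], 0.2)
  expect_lt(disp_mm[5], 0.42)
})
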