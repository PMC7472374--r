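# Shared fixtures, computed once per test run. The full-scale experiment is
# the expensive piece (five 800x600 stereo pairs, calibration, warping);
# several test files interrogate different aspects of the same run.

.fixture_cache <- new.env(parent = emptyenv())

cached_fixture <- function(name, expr) {
  if (!exists(name, envir = .fixture_cache)) {
    assign(name, force(expr), envir = .fixture_cache)
  }
  get(name, envir = .fixture_cache)
}

# full-scale five-distance run at the generator's default conditions
full_experiment <- function() {
  cached_fixture("full_experiment", run_correction_experiment())
}

scalar_bar_run <- function() {
  cached_fixture("scalar_bar_run", run_scalar_bar_experiment())
}

# a small asymmetric analytic field used by several DCM tests
analytic_test_field <- function() {
  ratio_field(left_coef = 1e-7, right_coef = 2e-7, rmax = 500)
}

# noise-free synthetic correspondences drawn from a known radial ratio law
# R(rd) = 1 + c * rd^2, per half; the generating constants are the oracle
synthetic_correspondences <- function(c_left = 1e-7, c_right = 2e-7,
                                      width = 800, height = 600) {
  cx <- width / 2
  cy <- height / 2
  xs <- seq(-0.45, 0.45, length.out = 25) * width
  ys <- seq(-0.4, 0.4, length.out = 7) * height
  pts <- expand.grid(x = xs, y = ys)
  rd <- sqrt(pts$x^2 + pts$y^2)
  keep <- rd > 1
  pts <- pts[keep, ]
  rd <- rd[keep]
  cc <- ifelse(pts$x <= 0, c_left, c_right)
  R <- 1 + cc * rd^2
  correspondences(
    ideal = cbind(pts$x * R + cx, pts$y * R + cy),
    distorted = cbind(pts$x + cx, pts$y + cy),
    center = c(cx, cy)
  )
}
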