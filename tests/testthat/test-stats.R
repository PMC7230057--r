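test_that("displacement statistics match simple hand values", {
  s <- displacement_stats(c(0.5, 1.0, 1.5, 2.0))
  expect_equal(s$max, 2.0)
  expect_equal(s$mean, 1.25)
  expect_equal(s$median, 1.25)
  z <- displacement_stats(rep(0, 10))
  expect_equal(c(z$max, z$mean, z$median, z$q1, z$q3), rep(0, 5))
  expect_error(displacement_stats(numeric(0)), "empty-input")
})

test_that("quantiles match a sort-based oracle on random draws", {
  set.seed(51)
  mag <- rexp(1000, rate = 2)
  s <- displacement_stats(mag)
  # linear interpolation between order statistics, computed directly
  oracle <- function(p) {
    x <- sort(mag)
    h <- (length(x) - 1) * p + 1
    lo <- floor(h)
    x[lo] + (h - lo) * (x[pmin(lo + 1, length(x))] - x[lo])
  }
  expect_equal(s$q1, oracle(0.25), tolerance = 1e-12)
  expect_equal(s$median, oracle(0.5), tolerance = 1e-12)
  expect_equal(s$q3, oracle(0.75), tolerance = 1e-12)
  expect_equal(s$max, max(mag))
  expect_equal(s$mean, mean(mag))
})

test_that("quantile ordering invariant holds for random inputs", {
  set.seed(53)
  for (rep in 1:25) {
    mag <- abs(rnorm(sample(2:200, 1), sd = runif(1, 0.1, 5)))
    s <- displacement_stats(mag)
    expect_true(0 <= s$q1 && s$q1 <= s$median && s$median <= s$q3 &&
                s$q3 <= s$max)
    expect_true(s$mean >= min(mag) && s$mean <= s$max)
    expect_equal(s$n, length(mag))
  }
})

test_that("max location points at the largest displacement", {
  locs <- rbind(c(0, 0, 0), c(10, 0, 0), c(0, 20, 0))
  s <- displacement_stats(c(0.1, 0.9, 0.4), locations = locs)
  expect_equal(s$max_location, c(10, 0, 0), ignore_attr = TRUE)
})

test_that("method comparison applies the half-pixel rule", {
  a <- displacement_stats(c(0.5, 1.0, 1.5, 2.0))
  expect_error(compare_methods(a, a, 0), "positive")
  same <- compare_methods(a, a, 1.0)
  expect_true(all(same$differences == 0))
  expect_false(any(same$significant))
  b <- displacement_stats(c(0.5, 1.0, 1.5, 2.0) + 0.4)  # mean differs by 0.4
  mc <- compare_methods(b, a, 1.0)
  expect_false(mc$significant[["mean"]])   # 0.4 < 0.5: non-significant
  c2 <- displacement_stats(c(0.5, 1.0, 1.5, 2.6))       # max differs by 0.6
  mc2 <- compare_methods(c2, a, 1.0)
  expect_true(mc2$significant[["max"]])    # 0.6 >= 0.5: significant
})

test_that("method comparison is antisymmetric in its arguments", {
  set.seed(57)
  a <- displacement_stats(abs(rnorm(50)))
  b <- displacement_stats(abs(rnorm(50, sd = 1.3)))
  ab <- compare_methods(a, b, 0.8)
  ba <- compare_methods(b, a, 0.8)
  expect_equal(ab$differences, -ba$differences)
  expect_equal(ab$significant, ba$significant)
})

test_that("midpoint error is zero for coincident sets and catches mismatches", {
  g <- small_geometry()
  mids <- cell_midpoints(g)
  s <- midpoint_error(g, NULL, mids, mids)
  expect_equal(s$max, 0)
  expect_error(midpoint_error(g, NULL, mids, mids[-1, , drop = FALSE]),
               "alignment error")
})

test_that("midpoint error under an affine field matches the CP error", {
  # affine fields are exactly linear between vertices: a B-spline transform
  # whose coefficients sample the affine displacement reproduces it, so a
  # fit that is exact at vertices is exact at midpoints too
  g <- small_geometry()
  aff <- make_distortion_field("polynomial",
                               list(constant = c(0.4, 0.1, -0.3),
                                    linear = diag(c(0.01, -0.008, 0.005))), 40)
  shape <- c(8, 8, 8)
  h <- 12
  orig <- -42
  nodes <- as.matrix(expand.grid(x = orig + (0:7) * h, y = orig + (0:7) * h,
                                 z = orig + (0:7) * h))
  coef <- array(evaluate_distortion(aff, nodes), dim = c(shape, 3))
  tr <- bspline_transform(rep(orig, 3), h, shape, coef)
  mids <- cell_midpoints(g)
  obs_mids <- mids + evaluate_distortion(aff, mids)
  verts <- true_cp_positions(g)
  obs_verts <- verts + evaluate_distortion(aff, verts)
  s_mid <- midpoint_error(g, tr, mids, obs_mids)
  s_cp <- displacement_stats(transform_points(tr, verts) - obs_verts)
  expect_lt(abs(s_mid$mean - s_cp$mean), 0.05)
  expect_lt(s_mid$max, 1e-6)
})

test_that("distance profile reports radius and magnitude per CP", {
  ref <- cps_from_matrix(rbind(c(30, 0, 0)))
  det <- cps_from_matrix(rbind(c(30, 0, 1)), "detected")
  pr <- pair_control_points(ref, det, 7.5)
  prof <- distance_profile(pr, isocenter = c(0, 0, 0))
  expect_equal(prof$points$radius_mm, 30)
  expect_equal(prof$points$magnitude_mm, 1)
  prof2 <- distance_profile(pr, isocenter = c(30, 0, 0))
  expect_equal(prof2$points$radius_mm, 0)
})

test_that("binned profile means are monotone for a radial quadratic field", {
  g <- build_grid_geometry(15, 3, c(60, 60, 60))
  f <- make_distortion_field("radial", c(r2 = 2 / 60^2), 60)
  v <- true_cp_positions(g)
  w <- true_cp_positions(g, f)
  pr <- pair_control_points(cps_from_matrix(v), cps_from_matrix(w, "detected"), 7.5)
  prof <- distance_profile(pr)
  expect_true(all(diff(prof$bins$mean_magnitude_mm) >= 0))
})

test_that("performance classification applies both thresholds", {
  mk <- function(mx) displacement_stats(c(0.1, mx))
  r1 <- classify_performance(mk(0.9))
  expect_true(r1$high_performing)
  expect_true(r1$acr_pass)
  r2 <- classify_performance(mk(2.1))
  expect_false(r2$acr_pass)
  r3 <- classify_performance(mk(1.5))
  expect_true(r3$acr_pass)
  expect_false(r3$high_performing)
  # boundaries: exactly 1.0 is not sub-millimetre; exactly 2.0 still passes
  expect_false(classify_performance(mk(1.0))$high_performing)
  expect_true(classify_performance(mk(2.0))$acr_pass)
})
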