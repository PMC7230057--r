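test_that("zero coefficients give the identity mapping", {
  tr <- bspline_transform(c(-30, -30, -30), 15, c(6, 6, 6))
  set.seed(3)
  pts <- matrix(runif(60, -25, 25), ncol = 3)
  expect_equal(transform_points(tr, pts), pts)
  dd <- dense_displacement(tr, image_volume(array(0, dim = c(8, 8, 8)), 5))
  expect_true(all(dd == 0))
})

test_that("point transformation equals direct tensor-product summation", {
  set.seed(13)
  shape <- c(6, 5, 7)
  h <- c(11, 13, 9)
  orig <- c(-20, -10, -30)
  coef <- array(rnorm(prod(shape) * 3), dim = c(shape, 3))
  tr <- bspline_transform(orig, h, shape, coef)
  pts <- cbind(runif(100, orig[1] + h[1], orig[1] + (shape[1] - 2) * h[1]),
               runif(100, orig[2] + h[2], orig[2] + (shape[2] - 2) * h[2]),
               runif(100, orig[3] + h[3], orig[3] + (shape[3] - 2) * h[3]))
  got <- transform_points(tr, pts, displacement_only = TRUE)
  want <- matrix(0, 100, 3)
  for (i in seq_len(shape[1]))
    for (j in seq_len(shape[2]))
      for (k in seq_len(shape[3])) {
        w <- b3_ref((pts[, 1] - orig[1]) / h[1] - (i - 1)) *
             b3_ref((pts[, 2] - orig[2]) / h[2] - (j - 1)) *
             b3_ref((pts[, 3] - orig[3]) / h[3] - (k - 1))
        want <- want + outer(w, coef[i, j, k, ])
      }
  expect_equal(got, want, tolerance = 1e-9)
})

test_that("points far outside the support get finite smooth extrapolation", {
  set.seed(17)
  tr <- bspline_transform(c(-20, -20, -20), 10, c(6, 6, 6),
                          array(rnorm(6^3 * 3), dim = c(6, 6, 6, 3)))
  far <- rbind(c(500, 0, 0), c(-300, 200, -400), c(0, 0, 1e4))
  d <- transform_points(tr, far, displacement_only = TRUE)
  expect_true(all(is.finite(d)))
  # continuous across the support boundary
  near <- transform_points(tr, rbind(c(19.99, 0, 0)), displacement_only = TRUE)
  just <- transform_points(tr, rbind(c(20.01, 0, 0)), displacement_only = TRUE)
  expect_equal(near, just, tolerance = 1e-2)
})

test_that("dense displacement agrees with pointwise transformation", {
  set.seed(19)
  tr <- bspline_transform(c(-25, -25, -25), 12, c(6, 6, 6),
                          array(rnorm(6^3 * 3, sd = 0.5), dim = c(6, 6, 6, 3)))
  grid <- image_volume(array(0, dim = c(11, 12, 13)), c(2, 2, 2))
  dd <- dense_displacement(tr, grid)
  idx <- as.matrix(expand.grid(i = seq(1, 11, by = 5), j = seq(1, 12, by = 5),
                               k = seq(1, 13, by = 5)))
  pts <- sweep(sweep(idx - 1, 2, grid$spacing, "*"), 2, grid$origin, "+")
  want <- transform_points(tr, pts, displacement_only = TRUE)
  for (r in seq_len(nrow(idx)))
    expect_equal(dd[idx[r, 1], idx[r, 2], idx[r, 3], ], want[r, ],
                 tolerance = 1e-9, ignore_attr = TRUE)
  expect_true(all(sqrt(apply(dd^2, 1:3, sum)) >= 0))
})

test_that("dyadic refinement reproduces the coarse field exactly", {
  set.seed(23)
  lo_c <- c(-3, -2, -4)
  shape_c <- c(8, 7, 9)
  cf <- array(rnorm(prod(shape_c) * 3), dim = c(shape_c, 3))
  lo_f <- 2 * lo_c
  shape_f <- 2 * (shape_c - 1) + 1
  ff <- gridwarp:::refine_coefficients(cf, lo_c, lo_f, shape_f)
  hc <- 10
  tc <- bspline_transform(lo_c * 2 * hc, 2 * hc, shape_c, cf)
  tf <- bspline_transform(lo_f * hc, hc, shape_f, ff)
  pts <- matrix(runif(150, -15, 15), ncol = 3)
  expect_equal(transform_points(tc, pts), transform_points(tf, pts),
               tolerance = 1e-9)
})

test_that("transforms round-trip through JSON", {
  tr <- bspline_transform(c(-20, -20, -20), 10, c(6, 6, 6),
                          array(rnorm(6^3 * 3), dim = c(6, 6, 6, 3)))
  path <- tempfile(fileext = ".json")
  write_transform(tr, path, extra = list(seed = 3))
  back <- read_transform(path)
  expect_equal(back$coefficients, tr$coefficients)
  expect_equal(back$origin, tr$origin)
})

test_that("metric gradients agree with finite differences on smooth images", {
  g <- small_geometry()
  ref <- small_reference()
  obs <- warp_volume(small_observed(), small_field(), 0, 5)
  smooth <- function(v) {
    v$data <- array(gridwarp:::cpp_gauss3(as.double(v$data), dim(v$data),
                                          rep(1.2, 3)), dim(v$data))
    v
  }
  refs <- smooth(ref)
  obss <- smooth(obs)
  msk <- auto_grid_mask(ref)
  mvox <- which(msk, arr.ind = TRUE)
  set.seed(1)
  rows <- sample(nrow(mvox), 600)
  pts <- gridwarp:::voxel_to_world(ref, mvox[rows, ] - 1) +
    (matrix(runif(1800), ncol = 3) - 0.5) * 1.5
  shape <- c(6L, 6L, 6L)
  coef <- array(rnorm(prod(shape) * 3) * 0.4, dim = c(shape, 3))
  grads <- gridwarp:::gradient_volumes(obss)
  evalm <- function(coef, metric) gridwarp:::cpp_metric_grad(
    as.double(coef), shape, rep(-30, 3), rep(12, 3), pts,
    as.double(refs$data), dim(refs$data), refs$spacing, refs$origin,
    as.double(obss$data), as.double(grads[[1]]), as.double(grads[[2]]),
    as.double(grads[[3]]), dim(obss$data), obss$spacing, obss$origin,
    metric, 32L, range(refs$data), range(obss$data))
  for (metric in c(0L, 1L)) {
    r0 <- evalm(coef, metric)
    ids <- order(-abs(r0$grad))[c(1, 5, 20, 60, 150)]
    for (id in ids) {
      eps <- 1e-3
      cp <- coef
      cp[id] <- cp[id] + eps
      cm <- coef
      cm[id] <- cm[id] - eps
      fd <- (evalm(cp, metric)$value - evalm(cm, metric)$value) / (2 * eps)
      expect_equal(r0$grad[id], fd, tolerance = 0.15)
    }
  }
})

test_that("registering a volume to itself recovers the identity", {
  ref <- small_reference()
  p <- registration_params(fgs = 15, nr = 2, nss = 1000, mni = 150,
                           metric = "mean-squares", seed = 4)
  tr <- bspline_register(ref, ref, p)
  verts <- true_cp_positions(small_geometry())
  d <- sqrt(rowSums(transform_points(tr, verts, displacement_only = TRUE)^2))
  expect_lte(mean(d), 0.1)
  expect_lte(max(d), 0.5)
})

test_that("a known smooth field is recovered by both metrics", {
  g <- small_geometry()
  fld <- small_field()
  verts <- true_cp_positions(g)
  truth <- evaluate_distortion(fld, verts)
  # mean squares, same contrast
  ref <- small_reference()
  refw <- warp_volume(small_reference(), fld, 3, 6)
  p <- registration_params(fgs = 15, nr = 3, nss = 2000, mni = 300,
                           metric = "mean-squares", seed = 5)
  tr <- bspline_register(ref, refw, p)
  rec <- transform_points(tr, verts, displacement_only = TRUE)
  expect_lt(sqrt(mean(rowSums((rec - truth)^2))), 0.25)
  # mutual information, inverted contrast plus noise
  obsw <- warp_volume(small_observed(), fld, 15, 7)
  p$metric <- "mutual-information"
  tr2 <- bspline_register(ref, obsw, p)
  rec2 <- transform_points(tr2, verts, displacement_only = TRUE)
  expect_lt(sqrt(mean(rowSums((rec2 - truth)^2))), 0.25)
})

test_that("registration is bit-reproducible for identical seeds", {
  ref <- small_reference()
  obsw <- warp_volume(small_observed(), small_field(), 15, 7)
  p <- registration_params(fgs = 20, nr = 2, nss = 1000, mni = 100, seed = 8)
  t1 <- bspline_register(ref, obsw, p)
  t2 <- bspline_register(ref, obsw, p)
  expect_identical(t1$coefficients, t2$coefficients)
  p2 <- p
  p2$seed <- 9L
  t3 <- bspline_register(ref, obsw, p2)
  expect_false(identical(t1$coefficients, t3$coefficients))
})

test_that("best-so-far metric value per level is non-increasing", {
  ref <- small_reference()
  obsw <- warp_volume(small_observed(), small_field(), 15, 7)
  p <- registration_params(fgs = 20, nr = 2, nss = 1000, mni = 100, seed = 8)
  tr <- bspline_register(ref, obsw, p)
  trace <- attr(tr, "trace")
  for (lv in unique(trace$level)) {
    b <- trace$best[trace$level == lv]
    expect_true(all(diff(b) <= 0))
  }
})

test_that("disjoint volumes fail registration with a clear error", {
  ref <- small_reference()
  other <- small_observed()
  other$origin <- other$origin + 500
  expect_error(bspline_register(ref, other), "common grid")
})

test_that("parameter values outside the standard ranges warn", {
  expect_warning(registration_params(fgs = 80), "FGS")
  expect_warning(registration_params(nr = 8), "NR")
  expect_warning(registration_params(nss = 100), "NSS")
  expect_warning(registration_params(mni = 50), "MNI")
})
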