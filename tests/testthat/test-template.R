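test_that("vertex template has the documented size and symmetries", {
  tpl <- build_vertex_template(3, 7.5, 0.5, "grid-bright")
  expect_equal(dim(tpl), c(15, 15, 15))
  # invariant under axis permutations and flips
  expect_equal(unclass(tpl), aperm(tpl, c(2, 1, 3)), ignore_attr = TRUE)
  expect_equal(unclass(tpl), aperm(tpl, c(3, 2, 1)), ignore_attr = TRUE)
  expect_equal(unclass(tpl), tpl[15:1, , ], ignore_attr = TRUE)
  expect_equal(unclass(tpl), tpl[, , 15:1], ignore_attr = TRUE)
  # polarity inversion complements the foreground
  dark <- build_vertex_template(3, 7.5, 0.5, "grid-dark")
  expect_equal(unclass(dark), 1 - unclass(tpl), ignore_attr = TRUE)
})

test_that("template foreground fraction matches the inclusion-exclusion form", {
  # three orthogonal square bars: volume 3 a^2 s - 2 a^3 over s^3
  # voxel size in general position (bar faces between voxel-center planes)
  a <- 3
  sp <- 3 / 7
  tpl <- suppressMessages(build_vertex_template(a, 7.5, sp, "grid-bright"))
  s <- dim(tpl)[1] * sp  # realized (odd-count) template edge length
  expected <- (3 * a^2 * s - 2 * a^3) / s^3
  expect_lt(abs(mean(tpl) - expected) / expected, 0.02)
})

test_that("even voxel counts are adjusted up to odd", {
  expect_message(tpl <- build_vertex_template(3, 8, 1), "odd")
  expect_equal(dim(tpl), c(9, 9, 9))
})

test_that("NCC is exactly 1 on a noise-free copy of the template", {
  tpl <- build_vertex_template(3, 7.5, 1.5, "grid-bright")
  n <- 31
  vol <- array(0, dim = c(n, n, n))
  at <- 12:(12 + dim(tpl)[1] - 1)
  vol[at, at, at] <- tpl
  iv <- image_volume(vol, 1.5)
  corr <- ncc_match(iv, tpl)
  ctr <- 12 + (dim(tpl)[1] - 1) / 2
  expect_equal(corr$data[ctr, ctr, ctr], 1, tolerance = 1e-9)
  expect_true(all(corr$data >= -1 & corr$data <= 1))
})

test_that("NCC equals a brute-force sliding-window computation", {
  set.seed(31)
  vol <- array(rnorm(16^3), dim = c(16, 16, 16))
  tpl <- array(as.numeric(array(runif(5^3), dim = c(5, 5, 5)) > 0.6),
               dim = c(5, 5, 5))
  iv <- image_volume(vol, 1)
  got <- ncc_match(iv, structure(tpl, spacing = c(1, 1, 1)))
  expect_equal(got$data, zncc_oracle(vol, tpl), tolerance = 1e-6)
})

test_that("NCC is invariant to affine intensity rescaling", {
  vol <- small_reference()
  tpl <- build_vertex_template(3, 7.5, 1.5, "grid-bright")
  c1 <- ncc_match(vol, tpl)
  vol2 <- vol
  vol2$data <- 3.7 * vol$data + 250
  c2 <- ncc_match(vol2, tpl)
  expect_equal(c1$data, c2$data, tolerance = 1e-6)
})

test_that("degenerate templates are rejected", {
  vol <- small_reference()
  expect_error(ncc_match(vol, structure(array(1, dim = c(3, 3, 3)),
                                        spacing = rep(1.5, 3))), "degenerate")
  expect_error(ncc_match(vol, structure(array(0, dim = c(3, 3, 3)),
                                        spacing = rep(1.5, 3))), "degenerate")
})

test_that("candidate extraction localizes symmetric blobs exactly", {
  corr <- array(-1, dim = c(21, 21, 21))
  # one symmetric blob centred on voxel (11, 11, 11)
  offs <- as.matrix(expand.grid(dx = -2:2, dy = -2:2, dz = -2:2))
  w <- 0.9 - 0.15 * sqrt(rowSums(offs^2))
  for (r in seq_len(nrow(offs))) {
    p <- c(11, 11, 11) + offs[r, ]
    corr[p[1], p[2], p[3]] <- max(corr[p[1], p[2], p[3]], w[r])
  }
  iv <- image_volume(corr, 1, origin = c(0, 0, 0))
  cps <- extract_cp_candidates(iv, 0.5)
  expect_equal(nrow(cps$points), 1)
  expect_equal(as.numeric(cps$points[1, c("x", "y", "z")]), c(10, 10, 10))
  # two well-separated blobs -> two CPs
  corr2 <- array(-1, dim = c(21, 21, 21))
  corr2[5:7, 5:7, 5:7] <- 0.8
  corr2[15:17, 15:17, 15:17] <- 0.8
  cps2 <- extract_cp_candidates(image_volume(corr2, 1), 0.5)
  expect_equal(nrow(cps2$points), 2)
  # empty suprathreshold set warns and returns an empty set
  expect_warning(cps3 <- extract_cp_candidates(image_volume(corr2 * 0 - 1, 1), 0.5),
                 "no voxels")
  expect_equal(nrow(cps3$points), 0)
})

test_that("detection on a noise-free phantom is sub-voxel accurate for every CP", {
  g <- mid_geometry()
  vol <- voxelize_phantom(g, 1, "reference", margin = 8)
  tpl <- suppressMessages(build_vertex_template(3, 7.5, 1, "grid-bright"))
  cps <- extract_cp_candidates(ncc_match(vol, tpl), 0.5)
  truth <- cps_from_matrix(true_cp_positions(g))
  pr <- pair_control_points(truth, cps, 7.5)
  expect_equal(nrow(pr$pairs), 64)
  expect_lt(max(pr$pairs$distance), 0.5 * max(vol$spacing))
})

test_that("detection at 0.5 mm voxels is within 0.25 mm for every CP", {
  g <- small_geometry()
  vol <- voxelize_phantom(g, 0.5, "reference", margin = 8)
  cps <- extract_cp_candidates(ncc_match(vol, build_vertex_template(3, 7.5, 0.5,
                                                                    "grid-bright")),
                               0.5)
  pr <- pair_control_points(cps_from_matrix(true_cp_positions(g)), cps, 7.5)
  expect_equal(nrow(pr$pairs), 27)
  expect_lt(max(pr$pairs$distance), 0.25)
})

test_that("pairing matches identical and shifted sets as expected", {
  set.seed(41)
  ref <- cps_from_matrix(matrix(runif(60, -30, 30), ncol = 3))
  same <- ref
  same$source_tag <- "detected"
  pr <- pair_control_points(ref, same, 7.5)
  expect_equal(nrow(pr$pairs), 20)
  expect_equal(max(pr$pairs$distance), 0)
  shifted <- cps_from_matrix(cp_matrix(ref) + rep(c(1, 0, 0), each = 20), "detected")
  pr2 <- pair_control_points(ref, shifted, 7.5)
  expect_equal(pr2$pairs$distance, rep(1, 20))
  expect_equal(pr2$pairs$dx, rep(1, 20))
})

test_that("points beyond the pairing radius stay unmatched", {
  ref <- cps_from_matrix(rbind(c(0, 0, 0), c(20, 0, 0)))
  det <- cps_from_matrix(rbind(c(0, 0, 9), c(20, 1, 0)), "detected")
  pr <- pair_control_points(ref, det, 7.5)
  expect_equal(nrow(pr$pairs), 1)
  expect_equal(pr$unmatched_reference_ids, 1)
  expect_equal(pr$unmatched_detected_ids, 1)
})

test_that("pairing is symmetric up to displacement sign", {
  set.seed(43)
  a <- cps_from_matrix(matrix(runif(90, -30, 30), ncol = 3))
  bm <- cp_matrix(a) + matrix(rnorm(90, sd = 1), ncol = 3)
  b <- cps_from_matrix(bm[sample(30), ], "detected")
  p1 <- pair_control_points(a, b, 7.5)
  p2 <- pair_control_points(b, a, 7.5)
  k1 <- p1$pairs[order(p1$pairs$reference_id), ]
  k2 <- p2$pairs[order(p2$pairs$detected_id), ]
  expect_equal(k1$reference_id, k2$detected_id)
  expect_equal(k1$detected_id, k2$reference_id)
  expect_equal(k1$dx, -k2$dx)
  expect_equal(k1$distance, k2$distance)
})

test_that("control-point sets round-trip through TSV", {
  cps <- cps_from_matrix(matrix(runif(30, -20, 20), ncol = 3), "detected")
  cps$points$flag[3] <- TRUE
  path <- tempfile(fileext = ".tsv")
  write_cps(cps, path)
  back <- read_cps(path, "detected")
  expect_equal(back$points$x, cps$points$x)
  expect_equal(back$points$flag, cps$points$flag)
})
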