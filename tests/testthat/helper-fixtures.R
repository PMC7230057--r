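# Shared fixtures, built lazily and cached for the session so expensive
# simulations run once.

.fixture_cache <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (!exists(name, envir = .fixture_cache))
    assign(name, builder(), envir = .fixture_cache)
  get(name, envir = .fixture_cache)
}

# small 3x3x3-vertex grid (27 CPs), fast to voxelize
small_geometry <- function() fixture("small_geometry", function() {
  build_grid_geometry(15, 3, c(30, 30, 30))
})

# 4x4x4-vertex grid (64 CPs)
mid_geometry <- function() fixture("mid_geometry", function() {
  build_grid_geometry(15, 3, c(45, 45, 45))
})

cp_matrix <- function(cps) as.matrix(cps$points[, c("x", "y", "z")])

# piecewise cubic cardinal B-spline, independent of the compiled kernels
b3_ref <- function(s) {
  s <- abs(s)
  ifelse(s < 1, (4 - 6 * s^2 + 3 * s^3) / 6,
         ifelse(s < 2, (2 - s)^3 / 6, 0))
}

# direct sliding-window zero-normalized cross-correlation oracle
zncc_oracle <- function(vol, tpl) {
  vd <- dim(vol)
  td <- dim(tpl)
  out <- array(-1, dim = vd)
  tv <- as.numeric(tpl)
  ctr <- (td - 1) %/% 2
  for (z in 1:(vd[3] - td[3] + 1))
    for (y in 1:(vd[2] - td[2] + 1))
      for (x in 1:(vd[1] - td[1] + 1)) {
        win <- as.numeric(vol[x:(x + td[1] - 1), y:(y + td[2] - 1),
                              z:(z + td[3] - 1)])
        num <- sum(win * tv) - sum(win) * sum(tv) / length(tv)
        den <- sqrt((sum(win^2) - sum(win)^2 / length(tv)) *
                    (sum(tv^2) - sum(tv)^2 / length(tv)))
        out[x + ctr[1], y + ctr[2], z + ctr[3]] <-
          if (den > 1e-12) max(-1, min(1, num / den)) else 0
      }
  out
}

cps_from_matrix <- function(m, tag = "reference") {
  control_points(data.frame(id = seq_len(nrow(m)), x = m[, 1], y = m[, 2],
                            z = m[, 3]), tag)
}

# reference volume of the small grid at 1.5 mm voxels
small_reference <- function() fixture("small_reference", function() {
  voxelize_phantom(small_geometry(), 1.5, "reference", margin = 9)
})

small_observed <- function() fixture("small_observed", function() {
  voxelize_phantom(small_geometry(), 1.5, "observed", margin = 9)
})

# a gentle smooth field for the small grid
small_field <- function() fixture("small_field", function() {
  random_smooth_field(1.5, 26, seed = 19)
})
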