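#' Analytic distortion fields
#'
#' Smooth ground-truth displacement fields d(x) used to warp synthetic
#' volumes and to score recovery. Two bases are available:
#'
#' * `"polynomial"`: `d(x) = constant + linear %*% x + quadratic terms`,
#'   where `coefficients` is a list with `constant` (length 3, mm),
#'   `linear` (3 x 3, dimensionless) and optional `quadratic` (3 x 6 matrix
#'   over the monomials x^2, y^2, z^2, xy, xz, yz, in 1/mm).
#' * `"radial"`: `d(x) = (c1 r + c2 r^2 + c3 r^3) * rhat`, with
#'   `coefficients = c(r = c1, r2 = c2, r3 = c3)` — the classic
#'   gradient-nonlinearity-like radially growing pattern.
#'
#' The maximum magnitude over a dense sample of the spherical domain is
#' computed on construction and stored as `max_magnitude`.
#'
#' @param basis `"polynomial"` or `"radial"`.
#' @param coefficients see Details.
#' @param domain_radius radius (mm) of the sphere on which the field is
#'   intended to act (the phantom extent).
#' @return An object of class `analytic_distortion`.
#' @export
make_distortion_field <- function(basis = c("polynomial", "radial"),
                                  coefficients, domain_radius = 110) {
  basis <- match.arg(basis)
  if (basis == "polynomial") {
    co <- list(constant = rep_len(as.numeric(coefficients$constant %||% 0), 3),
               linear = matrix(as.numeric(coefficients$linear %||% 0), 3, 3),
               quadratic = if (is.null(coefficients$quadratic)) NULL
                           else matrix(as.numeric(coefficients$quadratic), 3, 6))
  } else {
    co <- c(r = 0, r2 = 0, r3 = 0)
    nm <- names(coefficients)
    if (is.null(nm)) nm <- c("r", "r2", "r3")[seq_along(coefficients)]
    co[nm] <- as.numeric(coefficients)
  }
  if (!all(is.finite(unlist(co)))) stop("coefficients must be finite")
  field <- structure(list(basis = basis, coefficients = co,
                          domain_radius = domain_radius, max_magnitude = NA_real_),
                     class = "analytic_distortion")
  field$max_magnitude <- max_field_magnitude(field)
  field
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Evaluate a distortion field at world points
#'
#' @param field an [make_distortion_field()] object.
#' @param pts N x 3 matrix of world coordinates (mm).
#' @return N x 3 matrix of displacement vectors (mm).
#' @export
evaluate_distortion <- function(field, pts) {
  pts <- as_points(pts)
  if (field$basis == "polynomial") {
    co <- field$coefficients
    d <- matrix(co$constant, nrow(pts), 3, byrow = TRUE) + pts %*% t(co$linear)
    if (!is.null(co$quadratic)) {
      q <- cbind(pts[, 1]^2, pts[, 2]^2, pts[, 3]^2,
                 pts[, 1] * pts[, 2], pts[, 1] * pts[, 3], pts[, 2] * pts[, 3])
      d <- d + q %*% t(co$quadratic)
    }
    d
  } else {
    r <- sqrt(rowSums(pts^2))
    co <- field$coefficients
    scale <- co[["r"]] + co[["r2"]] * r + co[["r3"]] * r^2  # = |d|/r
    pts * scale
  }
}

# dense-sample estimate of max |d| inside the domain sphere
max_field_magnitude <- function(field, n_per_axis = 21) {
  g <- seq(-field$domain_radius, field$domain_radius, length.out = n_per_axis)
  pts <- as.matrix(expand.grid(x = g, y = g, z = g))
  pts <- pts[rowSums(pts^2) <= field$domain_radius^2, , drop = FALSE]
  max(sqrt(rowSums(evaluate_distortion(field, pts)^2)))
}

#' @export
print.analytic_distortion <- function(x, ...) {
  cat(sprintf("<analytic_distortion> %s basis, max |d| = %.3f mm within r = %.0f mm\n",
              x$basis, x$max_magnitude, x$domain_radius))
  invisible(x)
}

#' Random smooth distortion field with a prescribed peak magnitude
#'
#' Draws a second-order polynomial field with seeded random coefficients and
#' rescales it (the field is linear in its coefficients) so that the maximum
#' magnitude over the domain equals `max_magnitude`. Emulates the smooth
#' system-related distortion patterns (field inhomogeneity plus gradient
#' nonlinearity) seen inside a head-sized volume.
#'
#' @param max_magnitude peak displacement magnitude in mm (default 2).
#' @param domain_radius sphere radius in mm over which the peak is enforced.
#' @param seed integer seed; the field is a deterministic function of it.
#' @return An [make_distortion_field()] object (`polynomial` basis).
#' @export
random_smooth_field <- function(max_magnitude = 2, domain_radius = 110, seed = 1) {
  co <- with_seed(seed, list(
    constant = rnorm(3, sd = 0.3),
    linear = matrix(rnorm(9), 3, 3) / domain_radius,
    quadratic = matrix(rnorm(18), 3, 6) / domain_radius^2))
  f <- make_distortion_field("polynomial", co, domain_radius)
  scale <- max_magnitude / f$max_magnitude
  co$constant <- co$constant * scale
  co$linear <- co$linear * scale
  co$quadratic <- co$quadratic * scale
  make_distortion_field("polynomial", co, domain_radius)
}

#' Warp a volume by an analytic distortion field
#'
#' The forward mapping is `T(x) = x + d(x)`: a structure at x in the input
#' appears at T(x) in the output. The output intensity at world point x is
#' the input sampled at `T^-1(x)`, computed per voxel by fixed-point
#' iteration (`y <- x - d(y)`) to below 0.01 mm residual. Optional additive
#' Gaussian intensity noise is seeded and reproducible.
#'
#' @param volume an [image_volume].
#' @param distortion an [make_distortion_field()] object; its peak magnitude
#'   must stay below `max_allowed` for the inversion to converge.
#' @param noise_sigma standard deviation of additive Gaussian noise
#'   (intensity units).
#' @param seed integer seed for the noise.
#' @param max_allowed convergence guard on the field magnitude (mm); default
#'   7.5 (half the standard vertex spacing).
#' @param fill intensity for voxels mapped outside the input field of view
#'   (default: the input's corner voxel, i.e. background/air).
#' @return A warped [image_volume] on the same grid.
#' @export
warp_volume <- function(volume, distortion, noise_sigma = 0, seed = 0,
                        max_allowed = 7.5, fill = NULL) {
  if (distortion$max_magnitude >= max_allowed)
    stop("distortion-too-large: max |d| = ",
         signif(distortion$max_magnitude, 4), " mm >= ", max_allowed, " mm")
  if (is.null(fill)) fill <- volume$data[1, 1, 1]
  nv <- dim(volume$data)
  cx <- lapply(1:3, function(a) axis_coords(volume, a))
  x <- cbind(rep(cx[[1]], times = nv[2] * nv[3]),
             rep(rep(cx[[2]], each = nv[1]), times = nv[3]),
             rep(cx[[3]], each = nv[1] * nv[2]))
  y <- x
  converged <- FALSE
  for (it in 1:50) {
    d <- evaluate_distortion(distortion, y)
    resid <- y + d - x
    if (max(abs(resid)) < 0.005) {  # per-component; comfortably < 0.01 mm
      converged <- TRUE
      break
    }
    y <- x - d
  }
  if (!converged) stop("distortion-too-large: fixed-point inversion did not converge")
  vals <- cpp_sample_trilinear(as.double(volume$data), nv,
                               world_to_voxel(volume, y), fill)
  if (noise_sigma > 0)
    vals <- vals + with_seed(seed, rnorm(length(vals), sd = noise_sigma))
  out <- volume
  out$data <- array(vals, dim = nv)
  out
}

#' Ground-truth control-point positions under a distortion field
#'
#' Returns `v + d(v)` for every grid vertex (or cell midpoint) — the
#' positions where the phantom structures appear in a warped acquisition.
#'
#' @param geometry a [build_grid_geometry()] object.
#' @param distortion an [make_distortion_field()] object (or `NULL` for the
#'   identity).
#' @param what `"vertices"` or `"midpoints"`.
#' @return N x 3 matrix of world coordinates (mm).
#' @export
true_cp_positions <- function(geometry, distortion = NULL,
                              what = c("vertices", "midpoints")) {
  what <- match.arg(what)
  pts <- if (what == "vertices") vertex_matrix(geometry) else cell_midpoints(geometry)
  if (is.null(pts)) stop("geometry has no ", what)
  if (is.null(distortion)) return(pts)
  pts + evaluate_distortion(distortion, pts)
}
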