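#' Cubic B-spline free-form deformation transforms
#'
#' A deformation parameterized by 3-vector displacements on a regular
#' control-point lattice, interpolated with cubic tensor-product B-splines:
#' `T(x) = x + sum_ijk c_ijk B((x - x_i)/h)`. Zero coefficients give the
#' identity; the mapping is C2 inside the support, and outside it the
#' boundary cells' polynomial pieces are extended naturally (finite, smooth
#' extrapolation — flagged in the serialized metadata).
#'
#' @param origin world coordinate (mm) of control point (1,1,1).
#' @param spacing control-grid spacing in mm (scalar or length 3); equals
#'   the final grid spacing (FGS) for a fitted transform.
#' @param shape integer length-3 lattice shape (at least 4 per axis).
#' @param coefficients numeric array `shape x 3` of control-point
#'   displacements in mm (default all zero).
#' @return An object of class `bspline_transform`.
#' @export
bspline_transform <- function(origin, spacing, shape, coefficients = NULL) {
  shape <- as.integer(rep_len(shape, 3L))
  spacing <- rep_len(as.numeric(spacing), 3L)
  if (any(shape < 4L)) stop("control lattice needs at least 4 points per axis")
  if (is.null(coefficients)) coefficients <- array(0, dim = c(shape, 3L))
  if (!identical(dim(coefficients), c(shape, 3L)))
    stop("coefficients must have dim c(shape, 3)")
  structure(list(origin = rep_len(as.numeric(origin), 3L), spacing = spacing,
                 shape = shape, coefficients = coefficients),
            class = "bspline_transform")
}

#' @export
print.bspline_transform <- function(x, ...) {
  cat(sprintf("<bspline_transform> %s control points, spacing %s mm, max |c| = %.3f mm\n",
              paste(x$shape, collapse = " x "),
              paste(signif(x$spacing, 4), collapse = " x "),
              max(abs(x$coefficients))))
  invisible(x)
}

#' Apply a B-spline transform to points
#'
#' @param transform a [bspline_transform()].
#' @param pts N x 3 matrix of world points (mm).
#' @param displacement_only return only the displacement vectors.
#' @return N x 3 matrix of transformed points (or displacements).
#' @export
transform_points <- function(transform, pts, displacement_only = FALSE) {
  pts <- as_points(pts)
  d <- cpp_bspline_disp(as.double(transform$coefficients), transform$shape,
                        transform$origin, transform$spacing, pts)
  if (displacement_only) d else pts + d
}

#' Dense displacement field on an image grid
#'
#' Evaluates the transform's displacement at every voxel center of the
#' requested grid; suitable for NIfTI export (4D, three components) and
#' slice rendering.
#'
#' @param transform a [bspline_transform()].
#' @param grid an [image_volume] supplying the output grid.
#' @return 4D array `nx x ny x nz x 3` of displacements in mm, with the
#'   grid's `spacing` and `origin` as attributes.
#' @export
dense_displacement <- function(transform, grid) {
  nv <- dim(grid$data)
  cx <- lapply(1:3, function(a) axis_coords(grid, a))
  pts <- cbind(rep(cx[[1]], times = nv[2] * nv[3]),
               rep(rep(cx[[2]], each = nv[1]), times = nv[3]),
               rep(cx[[3]], each = nv[1] * nv[2]))
  d <- transform_points(transform, pts, displacement_only = TRUE)
  structure(array(d, dim = c(nv, 3L)), spacing = grid$spacing,
            origin = grid$origin)
}

#' Serialize / deserialize a B-spline transform as JSON
#'
#' @param transform a [bspline_transform()].
#' @param path JSON file path.
#' @param extra named list of provenance fields to embed (seed, config hash).
#' @export
write_transform <- function(transform, path, extra = list()) {
  obj <- c(list(type = "bspline", origin = transform$origin,
                spacing = transform$spacing, shape = transform$shape,
                extrapolation = "natural-polynomial",
                coefficients = as.numeric(transform$coefficients)),
           extra)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_transform
#' @export
read_transform <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  bspline_transform(obj$origin, obj$spacing, obj$shape,
                    array(obj$coefficients, dim = c(obj$shape, 3L)))
}

# Dyadic refinement of a cubic B-spline coefficient lattice. Grids are
# indexed in absolute units of their own spacing relative to a common
# anchor; the coarse grid has spacing 2h and absolute index range
# lo_c..(lo_c + n_c - 1), the fine grid spacing h and range lo_f..  The
# returned fine coefficients reproduce the coarse field exactly (standard
# knot-insertion weights 1/8, 6/8, 1/8 and 1/2, 1/2), with coefficients
# outside the coarse range treated as zero.
refine_axis_matrix <- function(lo_c, n_c, lo_f, n_f) {
  W <- matrix(0, n_f, n_c)
  for (r in seq_len(n_f)) {
    m <- lo_f + r - 1L
    if (m %% 2L == 0L) {
      j <- m %/% 2L
      for (off in -1:1) {
        col <- j + off - lo_c + 1L
        if (col >= 1 && col <= n_c)
          W[r, col] <- W[r, col] + c(1, 6, 1)[off + 2] / 8
      }
    } else {
      j <- (m - 1L) %/% 2L
      for (off in 0:1) {
        col <- j + off - lo_c + 1L
        if (col >= 1 && col <= n_c)
          W[r, col] <- W[r, col] + 0.5
      }
    }
  }
  W
}

refine_coefficients <- function(coef, lo_coarse, lo_fine, shape_fine) {
  for (ax in 1:3) {
    dm <- dim(coef)
    W <- refine_axis_matrix(lo_coarse[ax], dm[ax], lo_fine[ax], shape_fine[ax])
    perm <- c(ax, setdiff(1:4, ax))
    a <- aperm(coef, perm)
    flat <- matrix(a, nrow = dm[ax])
    out <- W %*% flat
    newdim <- dim(a)
    newdim[1] <- shape_fine[ax]
    coef <- aperm(array(out, dim = newdim), order(perm))
  }
  coef
}
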