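#' Rigid transforms
#'
#' Six-parameter rigid transform `T(x) = R (x - center) + center + translation`
#' with `R = Rz(rz) Ry(ry) Rx(rx)` (intrinsic rotations about the world axes,
#' radians). The transform maps fixed-frame points to moving-frame points, so
#' it can be used directly to resample the moving volume on the fixed grid.
#'
#' @param angles rotations `c(rx, ry, rz)` in radians.
#' @param translation length-3 translation in mm.
#' @param center rotation center in mm.
#' @return An object of class `rigid_transform`.
#' @export
rigid_transform <- function(angles = c(0, 0, 0), translation = c(0, 0, 0),
                            center = c(0, 0, 0)) {
  structure(list(angles = as.numeric(angles),
                 translation = as.numeric(translation),
                 center = as.numeric(center)),
            class = "rigid_transform")
}

rotation_matrix <- function(angles) {
  ca <- cos(angles)
  sa <- sin(angles)
  rx <- rbind(c(1, 0, 0), c(0, ca[1], -sa[1]), c(0, sa[1], ca[1]))
  ry <- rbind(c(ca[2], 0, sa[2]), c(0, 1, 0), c(-sa[2], 0, ca[2]))
  rz <- rbind(c(ca[3], -sa[3], 0), c(sa[3], ca[3], 0), c(0, 0, 1))
  rz %*% ry %*% rx
}

# decompose R = Rz(g) Ry(b) Rx(a) back to angles c(a, b, g)
euler_from_matrix <- function(R) {
  b <- asin(max(-1, min(1, -R[3, 1])))
  a <- atan2(R[3, 2], R[3, 3])
  g <- atan2(R[2, 1], R[1, 1])
  c(a, b, g)
}

#' Apply / invert rigid transforms
#'
#' @param transform a [rigid_transform()].
#' @param pts N x 3 matrix of world points (mm).
#' @return `apply_rigid` returns the transformed N x 3 matrix;
#'   `invert_rigid` returns the inverse `rigid_transform`.
#' @export
apply_rigid <- function(transform, pts) {
  pts <- as_points(pts)
  R <- rotation_matrix(transform$angles)
  shift <- transform$center + transform$translation
  sweep(sweep(pts, 2, transform$center, "-") %*% t(R), 2, shift, "+")
}

#' @rdname apply_rigid
#' @export
invert_rigid <- function(transform) {
  R <- rotation_matrix(transform$angles)
  rigid_transform(angles = euler_from_matrix(t(R)),
                  translation = as.numeric(-t(R) %*% transform$translation),
                  center = transform$center)
}

#' @export
print.rigid_transform <- function(x, ...) {
  cat(sprintf("<rigid_transform> angles (%s) deg, translation (%s) mm\n",
              paste(signif(x$angles * 180 / pi, 4), collapse = ", "),
              paste(signif(x$translation, 4), collapse = ", ")))
  invisible(x)
}

#' Masked rigid pre-alignment
#'
#' Recovers the 6-parameter rigid transform aligning a moving volume to a
#' fixed volume using only voxels inside a small sphere around the phantom
#' center (default radius 27 mm), where the effect of geometric distortion
#' on the angular alignment is negligible. The metric (mutual information by
#' default, mean squares for same-contrast pairs) is optimized by
#' Nelder-Mead in two stages (translation only, then all six parameters).
#'
#' @param moving,fixed [image_volume]s overlapping the ROI sphere.
#' @param roi_radius sphere radius in mm (default 27).
#' @param roi_center sphere center in world mm (default the isocenter).
#' @param metric `"mutual-information"` or `"mean-squares"`.
#' @param max_points deterministic cap on the number of ROI voxels used.
#' @param nbins histogram bins for mutual information.
#' @return A [rigid_transform()] mapping fixed coordinates to moving
#'   coordinates, with the final metric value in attribute `metric_value`.
#' @export
rigid_register <- function(moving, fixed, roi_radius = 27,
                           roi_center = c(0, 0, 0),
                           metric = c("mutual-information", "mean-squares"),
                           max_points = 30000, nbins = 64) {
  metric <- match.arg(metric)
  cx <- lapply(1:3, function(a) axis_coords(fixed, a) - roi_center[a])
  nv <- dim(fixed$data)
  in1 <- which(abs(cx[[1]]) <= roi_radius)
  in2 <- which(abs(cx[[2]]) <= roi_radius)
  in3 <- which(abs(cx[[3]]) <= roi_radius)
  idx <- as.matrix(expand.grid(i = in1, j = in2, k = in3))
  pts <- cbind(cx[[1]][idx[, 1]], cx[[2]][idx[, 2]], cx[[3]][idx[, 3]])
  inside <- rowSums(pts^2) <= roi_radius^2
  idx <- idx[inside, , drop = FALSE]
  if (nrow(idx) < 1000)
    stop("insufficient-ROI error: only ", nrow(idx), " voxels inside the sphere")
  if (nrow(idx) > max_points) {
    sel <- round(seq(1, nrow(idx), length.out = max_points))
    idx <- idx[sel, , drop = FALSE]
  }
  # Sample positions are jittered within their voxel (fixed, seeded draw) to
  # break the voxel-grid lock of interpolation-based metrics; fixed values
  # are interpolated at the jittered positions.
  jitter <- with_seed(60421L,
                      matrix(runif(length(idx)) - 0.5, ncol = 3))
  pts_world <- voxel_to_world(fixed, idx - 1L + jitter)
  # the smoothed stages only steer into the basin; subsample them harder
  coarse_sel <- if (nrow(idx) > 15000)
    round(seq(1, nrow(idx), length.out = 15000)) else seq_len(nrow(idx))

  smooth_vol <- function(vol, sigma_mm) {
    if (sigma_mm <= 0) return(vol)
    out <- vol
    out$data <- array(cpp_gauss3(as.double(vol$data), dim(vol$data),
                                 sigma_mm / vol$spacing), dim(vol$data))
    out
  }

  make_objective <- function(mov_s, fvals_s, rows) {
    pw <- pts_world[rows, , drop = FALSE]
    fv <- fvals_s[rows]
    function(par) {
      tr <- rigid_transform(par[1:3], par[4:6], roi_center)
      mv <- sample_volume(mov_s, apply_rigid(tr, pw), fill = NA_real_)
      okv <- !is.na(mv) & !is.na(fv)
      if (sum(okv) < 100) return(1e6)
      if (metric == "mean-squares") mean((mv[okv] - fv[okv])^2)
      else -cpp_mi_pair(fv[okv], mv[okv], nbins)
    }
  }

  # Coarse-to-fine: heavy smoothing first so the capture range exceeds the
  # bar thickness (the sharp grid gives the unsmoothed metric a narrow
  # basin), then refine on the original images.
  par <- rep(0, 6)
  value <- NA_real_
  for (sigma_mm in c(4, 1.5, 0)) {
    mov_s <- smooth_vol(moving, sigma_mm)
    fix_s <- smooth_vol(fixed, sigma_mm)
    fvals_s <- sample_volume(fix_s, pts_world, fill = NA_real_)
    objective <- make_objective(mov_s, fvals_s,
                                if (sigma_mm > 0) coarse_sel else seq_len(nrow(idx)))
    if (sigma_mm == 4) {  # translation only at the coarsest scale
      o <- optim(par[4:6], function(p) objective(c(par[1:3], p)),
                 method = "Nelder-Mead",
                 control = list(maxit = 500, reltol = 1e-10,
                                parscale = c(2, 2, 2)))
      par[4:6] <- o$par
    }
    o <- optim(par, objective, method = "Nelder-Mead",
               control = list(maxit = 600, reltol = 1e-10,
                              parscale = c(0.02, 0.02, 0.02, 1, 1, 1)))
    o <- optim(o$par, objective, method = "Nelder-Mead",
               control = list(maxit = 400, reltol = 1e-11,
                              parscale = c(0.005, 0.005, 0.005, 0.25, 0.25, 0.25)))
    par <- o$par
    value <- o$value
  }
  out <- rigid_transform(par[1:3], par[4:6], roi_center)
  attr(out, "metric_value") <- value
  out
}

#' Resample a volume onto a reference grid
#'
#' Output voxel at reference-grid world point x takes the input volume's
#' value at `T(x)` (linear interpolation); voxels mapped outside the input
#' field of view take `fill`.
#'
#' @param volume input [image_volume].
#' @param reference [image_volume] providing the output grid.
#' @param transform a [rigid_transform()] (or `NULL` for the identity).
#' @param fill out-of-field value (default: the input's corner voxel).
#' @return An [image_volume] on the reference grid.
#' @export
resample_to_reference <- function(volume, reference, transform = NULL,
                                  fill = NULL) {
  if (is.null(fill)) fill <- volume$data[1, 1, 1]
  nv <- dim(reference$data)
  cx <- lapply(1:3, function(a) axis_coords(reference, a))
  pts <- cbind(rep(cx[[1]], times = nv[2] * nv[3]),
               rep(rep(cx[[2]], each = nv[1]), times = nv[3]),
               rep(cx[[3]], each = nv[1] * nv[2]))
  if (!is.null(transform)) pts <- apply_rigid(transform, pts)
  vals <- sample_volume(volume, pts, fill = fill)
  out <- volume
  out$data <- array(vals, dim = nv)
  out$spacing <- reference$spacing
  out$origin <- reference$origin
  out
}
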