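#' Create an image volume
#'
#' A 3D scalar image in an axis-aligned world frame. The world coordinate of
#' voxel `(i, j, k)` (1-based) is `origin + (c(i, j, k) - 1) * spacing`, all
#' in millimetres. By convention the world origin sits at the phantom
#' isocenter, so a volume built with the default origin is centred on it.
#'
#' @param data 3D numeric array of intensities (finite).
#' @param spacing voxel spacing in mm; scalar or length-3, strictly positive.
#' @param origin world coordinate (mm) of the first voxel center; default
#'   centres the volume on the world origin.
#' @param modality `"reference"` (CT-like geometric ground truth) or
#'   `"observed"` (MR-like distorted acquisition).
#' @return An object of class `image_volume`.
#' @export
image_volume <- function(data, spacing, origin = NULL,
                         modality = c("observed", "reference")) {
  modality <- match.arg(modality)
  if (length(dim(data)) != 3L) stop("`data` must be a 3D array")
  spacing <- rep_len(as.numeric(spacing), 3L)
  if (any(!is.finite(spacing)) || any(spacing <= 0))
    stop("voxel spacing must be strictly positive on all axes")
  if (!all(is.finite(data))) stop("all intensities must be finite")
  if (is.null(origin)) origin <- -(dim(data) - 1) / 2 * spacing
  origin <- rep_len(as.numeric(origin), 3L)
  structure(list(data = data, spacing = spacing, origin = origin,
                 modality = modality),
            class = "image_volume")
}

#' @export
print.image_volume <- function(x, ...) {
  cat(sprintf("<image_volume> %s, %d x %d x %d voxels, spacing %s mm\n",
              x$modality, dim(x$data)[1], dim(x$data)[2], dim(x$data)[3],
              paste(signif(x$spacing, 4), collapse = " x ")))
  cat(sprintf("  origin (%s) mm, intensity range [%.4g, %.4g]\n",
              paste(signif(x$origin, 5), collapse = ", "),
              min(x$data), max(x$data)))
  invisible(x)
}

#' @export
dim.image_volume <- function(x) dim(x$data)

# world (mm, N x 3) -> continuous 0-based voxel coordinates (N x 3)
world_to_voxel <- function(volume, pts) {
  pts <- as_points(pts)
  sweep(sweep(pts, 2, volume$origin, "-"), 2, volume$spacing, "/")
}

voxel_to_world <- function(volume, idx) {
  sweep(sweep(as_points(idx), 2, volume$spacing, "*"), 2, volume$origin, "+")
}

as_points <- function(pts) {
  if (is.null(dim(pts))) pts <- matrix(pts, ncol = 3)
  storage.mode(pts) <- "double"
  pts
}

# 1D world coordinates of voxel centers along one axis
axis_coords <- function(volume, axis) {
  volume$origin[axis] + (seq_len(dim(volume$data)[axis]) - 1) * volume$spacing[axis]
}

#' Sample a volume at world points by trilinear interpolation
#'
#' @param volume an [image_volume].
#' @param pts N x 3 matrix of world coordinates (mm).
#' @param fill value assigned outside the field of view.
#' @return numeric vector of length N.
#' @export
sample_volume <- function(volume, pts, fill = NA_real_) {
  vox <- world_to_voxel(volume, pts)
  cpp_sample_trilinear(as.double(volume$data), dim(volume$data), vox, fill)
}

#' Read / write volumes as NIfTI
#'
#' Volumes are stored with an axis-aligned scaling+translation sform; reading
#' a NIfTI whose transform is not axis-aligned is refused.
#'
#' @param volume an [image_volume].
#' @param path file path (`.nii` or `.nii.gz`).
#' @param modality modality tag to assign on read.
#' @return `write_volume` returns `path` invisibly; `read_volume` returns an
#'   [image_volume].
#' @export
write_volume <- function(volume, path) {
  img <- RNifti::asNifti(volume$data)
  RNifti::pixdim(img) <- volume$spacing
  xfm <- rbind(cbind(diag(volume$spacing), volume$origin), c(0, 0, 0, 1))
  img <- RNifti::`sform<-`(img, structure(xfm, code = 2L))
  img <- RNifti::`qform<-`(img, structure(xfm, code = 2L))
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' @rdname write_volume
#' @export
read_volume <- function(path, modality = c("observed", "reference")) {
  modality <- match.arg(modality)
  img <- RNifti::readNifti(path)
  xfm <- RNifti::xform(img)
  rot <- xfm[1:3, 1:3]
  if (max(abs(rot - diag(diag(rot)))) > 1e-4)
    stop("only axis-aligned NIfTI volumes are supported")
  image_volume(array(as.numeric(img), dim = dim(img)[1:3]),
               spacing = abs(diag(rot)), origin = xfm[1:3, 4],
               modality = modality)
}
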