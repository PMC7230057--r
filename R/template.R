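#' Binary vertex template for NCC matching
#'
#' A small binary volume enclosing one grid vertex: three orthogonal
#' square-cross-section bars crossing at the template center. With
#' `polarity = "grid-bright"` the bars are foreground (reference/CT-like
#' contrast); with `"grid-dark"` the background phase is foreground, which
#' makes the correlation peak positive on MR-like images where the grid is
#' hyposignal. Voxel counts are forced odd per axis (unambiguous center);
#' an even rounding is adjusted upward with a message.
#'
#' @param bar_thickness bar thickness in mm (default 3).
#' @param template_size cube edge length in mm (default 7.5).
#' @param voxel_spacing voxel size in mm, scalar or length 3.
#' @param polarity `"grid-bright"` or `"grid-dark"`.
#' @return 3D 0/1 array with attributes `spacing` and `polarity`.
#' @export
build_vertex_template <- function(bar_thickness = 3, template_size = 7.5,
                                  voxel_spacing = 1,
                                  polarity = c("grid-bright", "grid-dark")) {
  polarity <- match.arg(polarity)
  sp <- rep_len(as.numeric(voxel_spacing), 3L)
  if (template_size < bar_thickness)
    stop("template_size must be at least bar_thickness")
  n <- round(template_size / sp)
  even <- n %% 2 == 0
  if (any(even)) {
    n[even] <- n[even] + 1L
    message("template voxel count adjusted up to odd: ",
            paste(n, collapse = " x "))
  }
  coords <- lapply(1:3, function(a) (seq_len(n[a]) - (n[a] + 1) / 2) * sp[a])
  ht <- bar_thickness / 2
  near <- lapply(coords, function(co) abs(co) <= ht + 1e-9)
  nx <- array(near[[1]], dim = n)
  ny <- aperm(array(near[[2]], dim = n[c(2, 1, 3)]), c(2, 1, 3))
  nz <- aperm(array(near[[3]], dim = n[c(3, 1, 2)]), c(2, 3, 1))
  grid <- (ny & nz) | (nx & nz) | (nx & ny)
  fg <- if (polarity == "grid-bright") grid else !grid
  structure(array(as.numeric(fg), dim = n), spacing = sp, polarity = polarity)
}

#' 3D normalized cross-correlation template matching
#'
#' Zero-normalized cross-correlation of a binary template over a volume.
#' The correlation is computed only where the template fully fits inside the
#' volume; the outer margin is assigned -1.
#'
#' @param volume an [image_volume].
#' @param template binary 3D array from [build_vertex_template()].
#' @return An [image_volume] of correlation coefficients in `[-1, 1]` on the
#'   input grid.
#' @export
ncc_match <- function(volume, template) {
  td <- dim(template)
  if (any(td > dim(volume$data)))
    stop("template does not fit within the volume")
  nf <- sum(template > 0.5)
  if (nf == 0 || nf == prod(td))
    stop("degenerate-template error: template has zero variance")
  corr <- cpp_zncc(as.double(volume$data), dim(volume$data),
                   as.double(template), td)
  out <- volume
  out$data <- array(corr, dim = dim(volume$data))
  out
}

#' Control-point sets
#'
#' @param points data frame with columns `id`, `x`, `y`, `z` (mm) and
#'   logical `flag` (review flag for low-confidence detections).
#' @param source_tag `"reference"`, `"detected"` or `"transformed"`.
#' @return An object of class `control_points`.
#' @export
control_points <- function(points, source_tag = c("detected", "reference",
                                                  "transformed")) {
  source_tag <- match.arg(source_tag)
  if (!all(c("id", "x", "y", "z") %in% names(points)))
    stop("points must have columns id, x, y, z")
  if (anyDuplicated(points$id)) stop("control-point ids must be unique")
  if (!all(is.finite(as.matrix(points[, c("x", "y", "z")]))))
    stop("control-point coordinates must be finite")
  if (is.null(points$flag)) points$flag <- FALSE
  structure(list(points = points, source_tag = source_tag),
            class = "control_points")
}

#' @export
print.control_points <- function(x, ...) {
  cat(sprintf("<control_points> %d %s points (%d flagged for review)\n",
              nrow(x$points), x$source_tag, sum(x$points$flag)))
  invisible(x)
}

cp_matrix <- function(cps) as.matrix(cps$points[, c("x", "y", "z")])

#' Extract control-point candidates from a correlation volume
#'
#' Thresholds the correlation map and labels connected components
#' (26-connectivity); components below a minimum voxel count are dropped.
#' Each surviving component yields one candidate, localized either by
#' separable three-point parabolic interpolation of the correlation peak
#' (`localization = "peak"`, the default — unbiased for truncated boundary
#' vertices whose correlation blobs are asymmetric) or by the component's
#' correlation-weighted center of mass (`"com"`; `weighted = FALSE` gives
#' the binary center of mass). Components that look merged (much larger
#' than typical) or weak (peak barely above threshold) are flagged for
#' review rather than corrected interactively. With `expected_count` given,
#' an automatic mode picks the largest threshold whose component count
#' equals it.
#'
#' @param correlation correlation [image_volume] from [ncc_match()].
#' @param threshold correlation threshold in (0, 1); default 0.5.
#' @param min_voxels minimum component size in voxels (default 3).
#' @param expected_count optional expected number of vertices for the
#'   automatic threshold mode.
#' @param localization `"peak"` (subvoxel parabolic peak) or `"com"`.
#' @param weighted for `"com"`: correlation-weighted (default) or binary.
#' @param max_elongation reject components whose bounding-box axis ratio
#'   exceeds this (default 2.5): suprathreshold ridges running along a bar
#'   between vertices are elongated, while true vertex blobs are compact.
#' @param source_tag tag for the resulting set.
#' @return A [control_points] set (possibly empty, with a warning); the
#'   number of components rejected as ridges is in attribute `n_rejected`.
#' @export
extract_cp_candidates <- function(correlation, threshold = 0.5, min_voxels = 3,
                                  expected_count = NULL,
                                  localization = c("peak", "com"),
                                  weighted = TRUE, max_elongation = 2.5,
                                  source_tag = "detected") {
  localization <- match.arg(localization)
  if (!is.null(expected_count)) {
    for (thr in seq(0.9, 0.2, by = -0.05)) {
      n <- nrow(extract_cp_candidates(correlation, thr, min_voxels,
                                      localization = localization,
                                      weighted = weighted)$points)
      if (n == expected_count) {
        threshold <- thr
        break
      }
    }
  }
  if (!(threshold > 0 && threshold < 1)) stop("threshold must be in (0, 1)")
  empty <- function(msg) {
    warning(msg)
    control_points(data.frame(id = integer(), x = numeric(), y = numeric(),
                              z = numeric(), flag = logical()), source_tag)
  }
  mask <- correlation$data >= threshold
  if (!any(mask))
    return(empty(paste("no voxels above correlation threshold", threshold)))
  dimv <- dim(correlation$data)
  lab <- cpp_label26(as.logical(mask), dimv)
  sel <- which(lab > 0L)
  labs <- lab[sel]
  size <- tabulate(labs)
  keep <- which(size >= min_voxels)
  if (length(keep) == 0) return(empty("all components below the minimum size"))

  vox <- matrix(NA_real_, length(keep), 3)
  peak <- numeric(length(keep))
  ridge <- logical(length(keep))
  for (m in seq_along(keep)) {
    vk <- sel[labs == keep[m]]
    cvals <- correlation$data[vk]
    pk <- vk[which.max(cvals)]
    peak[m] <- max(cvals)
    # bounding-box extents (mm): reject bar-ridge components
    kk0 <- (vk - 1) %/% (dimv[1] * dimv[2])
    rem0 <- (vk - 1) %% (dimv[1] * dimv[2])
    ext <- (c(diff(range(rem0 %% dimv[1])), diff(range(rem0 %/% dimv[1])),
              diff(range(kk0))) + 1) * correlation$spacing
    ridge[m] <- max(ext) / min(ext) > max_elongation
    if (localization == "peak") {
      # 0-based integer position of the peak voxel
      kk <- (pk - 1) %/% (dimv[1] * dimv[2])
      rem <- (pk - 1) %% (dimv[1] * dimv[2])
      ipk <- c(rem %% dimv[1], rem %/% dimv[1], kk)
      est <- as.numeric(ipk)
      p <- ipk + 1L  # 1-based integer peak, used for all three axis fits
      for (ax in 1:3) {
        if (p[ax] > 1 && p[ax] < dimv[ax]) {
          pm <- p
          pm[ax] <- pm[ax] - 1L
          pp <- p
          pp[ax] <- pp[ax] + 1L
          ym <- correlation$data[matrix(pm, 1)]
          y0 <- correlation$data[matrix(p, 1)]
          yp <- correlation$data[matrix(pp, 1)]
          den <- ym - 2 * y0 + yp
          if (den < 0) {
            shift <- 0.5 * (ym - yp) / den
            if (abs(shift) <= 1) est[ax] <- est[ax] + shift
          }
        }
      }
      vox[m, ] <- est
    } else {
      kk <- (vk - 1) %/% (dimv[1] * dimv[2])
      rem <- (vk - 1) %% (dimv[1] * dimv[2])
      idx <- cbind(rem %% dimv[1], rem %/% dimv[1], kk)
      w <- if (weighted) cvals else rep(1, length(vk))
      vox[m, ] <- colSums(idx * w) / sum(w)
    }
  }
  if (all(ridge)) return(empty("all components rejected as ridges"))
  vox <- vox[!ridge, , drop = FALSE]
  peak <- peak[!ridge]
  keep <- keep[!ridge]
  world <- voxel_to_world(correlation, vox)
  med_size <- median(size[keep])
  flag <- size[keep] > 3 * med_size | peak < threshold + 0.1
  out <- control_points(data.frame(id = seq_along(keep),
                                   x = world[, 1], y = world[, 2], z = world[, 3],
                                   flag = flag),
                        source_tag)
  attr(out, "n_rejected") <- sum(ridge)
  out
}

#' Pair detected control points with reference control points
#'
#' Greedy mutual-nearest-neighbour matching in ascending distance order:
#' candidate pairs within `max_distance` are accepted closest-first, each
#' point used at most once. Displacements are `detected - reference`.
#'
#' @param reference,detected [control_points] sets (non-empty).
#' @param max_distance pairing radius in mm (default 7.5, half the standard
#'   vertex spacing).
#' @return An object of class `cp_pairs`: data frame `pairs` (reference and
#'   detected ids and coordinates, displacement components, distance) plus
#'   `unmatched_reference_ids` and `unmatched_detected_ids`.
#' @export
pair_control_points <- function(reference, detected, max_distance = 7.5) {
  rp <- cp_matrix(reference)
  dp <- cp_matrix(detected)
  if (nrow(rp) == 0 || nrow(dp) == 0) stop("both point sets must be non-empty")
  d2 <- outer(rowSums(rp^2), rowSums(dp^2), "+") - 2 * rp %*% t(dp)
  d2[d2 < 0] <- 0
  dist <- sqrt(d2)
  cand <- which(dist <= max_distance, arr.ind = TRUE)
  ord <- order(dist[cand], cand[, 1], cand[, 2])
  cand <- cand[ord, , drop = FALSE]
  used_r <- logical(nrow(rp))
  used_d <- logical(nrow(dp))
  ri <- integer(0)
  di <- integer(0)
  for (m in seq_len(nrow(cand))) {
    i <- cand[m, 1]
    j <- cand[m, 2]
    if (used_r[i] || used_d[j]) next
    used_r[i] <- TRUE
    used_d[j] <- TRUE
    ri <- c(ri, i)
    di <- c(di, j)
  }
  disp <- dp[di, , drop = FALSE] - rp[ri, , drop = FALSE]
  pairs <- data.frame(reference_id = reference$points$id[ri],
                      detected_id = detected$points$id[di],
                      ref_x = rp[ri, 1], ref_y = rp[ri, 2], ref_z = rp[ri, 3],
                      dx = disp[, 1], dy = disp[, 2], dz = disp[, 3],
                      distance = sqrt(rowSums(disp^2)))
  structure(list(pairs = pairs,
                 unmatched_reference_ids = reference$points$id[!used_r],
                 unmatched_detected_ids = detected$points$id[!used_d],
                 max_distance = max_distance),
            class = "cp_pairs")
}

#' @export
print.cp_pairs <- function(x, ...) {
  cat(sprintf("<cp_pairs> %d pairs (%d reference / %d detected unmatched), max pairing distance %.2f mm\n",
              nrow(x$pairs), length(x$unmatched_reference_ids),
              length(x$unmatched_detected_ids), x$max_distance))
  invisible(x)
}

displacement_matrix <- function(pairs) {
  as.matrix(pairs$pairs[, c("dx", "dy", "dz")])
}

#' Serialize control points as TSV
#'
#' Columns: id, x_mm, y_mm, z_mm, flag.
#'
#' @param cps a [control_points] set.
#' @param path output TSV path.
#' @export
write_cps <- function(cps, path) {
  df <- cps$points
  names(df) <- c("id", "x_mm", "y_mm", "z_mm", "flag")
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_cps
#' @param source_tag tag to assign on read.
#' @export
read_cps <- function(path, source_tag = "detected") {
  df <- read.delim(path)
  names(df) <- c("id", "x", "y", "z", "flag")
  control_points(df, source_tag)
}
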