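#' Displacement-distribution statistics
#'
#' Summarizes the Euclidean magnitudes of control-point displacement
#' vectors: maximum, mean, median and first/third quartiles (quantiles by
#' linear interpolation between order statistics, R type 7), plus the world
#' location of the maximum.
#'
#' @param pairs a [pair_control_points()] result, or a numeric vector of
#'   displacement magnitudes (mm), or an N x 3 matrix of displacement
#'   vectors (mm); matrix/pairs input also records the max location.
#' @param locations optional N x 3 matrix of the points the magnitudes
#'   belong to (used for `max_location` with vector input).
#' @return An object of class `distortion_stats` with fields `n`, `max`,
#'   `mean`, `median`, `q1`, `q3`, `magnitudes`, `max_location`.
#' @export
displacement_stats <- function(pairs, locations = NULL) {
  if (inherits(pairs, "cp_pairs")) {
    locations <- as.matrix(pairs$pairs[, c("ref_x", "ref_y", "ref_z")])
    mag <- pairs$pairs$distance
  } else if (!is.null(dim(pairs))) {
    mag <- sqrt(rowSums(as_points(pairs)^2))
  } else {
    mag <- as.numeric(pairs)
  }
  if (length(mag) < 1) stop("empty-input error: need at least one displacement")
  q <- quantile(mag, c(0.25, 0.5, 0.75), names = FALSE, type = 7)
  maxloc <- if (!is.null(locations)) locations[which.max(mag), ] else NULL
  structure(list(n = length(mag), max = max(mag), mean = mean(mag),
                 median = q[2], q1 = q[1], q3 = q[3], magnitudes = mag,
                 max_location = maxloc),
            class = "distortion_stats")
}

#' @export
print.distortion_stats <- function(x, ...) {
  cat(sprintf(paste0("<distortion_stats> n = %d: max %.3f, mean %.3f, ",
                     "median %.3f, Q1 %.3f, Q3 %.3f mm\n"),
              x$n, x$max, x$mean, x$median, x$q1, x$q3))
  invisible(x)
}

stats_vector <- function(stats) {
  c(max = stats$max, mean = stats$mean, median = stats$median,
    q1 = stats$q1, q3 = stats$q3)
}

#' Midpoint overfitting diagnostic
#'
#' Distances between nonrigidly transformed reference cell midpoints and
#' their observed counterparts. Distortions are assumed smooth and nearly
#' linear between neighbouring vertices, so when the registration does not
#' overfit, midpoint errors behave like control-point errors; a B-spline
#' lattice much finer than the vertex spacing can "ripple" in the uniform
#' background between bars, which shows up here first.
#'
#' @param geometry a [build_grid_geometry()] object (supplies cell count).
#' @param transform a [bspline_transform()] (or `NULL` for identity).
#' @param reference_midpoints N x 3 matrix of midpoints in the reference
#'   frame (defaults to the geometry's cell midpoints).
#' @param observed_midpoints N x 3 matrix of the corresponding midpoints in
#'   the observed frame (e.g. means of 8 detected neighbouring CPs, or
#'   ground truth).
#' @return A [displacement_stats()] summary of the per-midpoint distances.
#' @export
midpoint_error <- function(geometry, transform, reference_midpoints = NULL,
                           observed_midpoints = NULL) {
  if (is.null(reference_midpoints)) reference_midpoints <- cell_midpoints(geometry)
  reference_midpoints <- as_points(reference_midpoints)
  observed_midpoints <- as_points(observed_midpoints)
  if (nrow(reference_midpoints) != nrow(observed_midpoints))
    stop("alignment error: midpoint counts differ (",
         nrow(reference_midpoints), " vs ", nrow(observed_midpoints), ")")
  moved <- if (is.null(transform)) reference_midpoints
           else transform_points(transform, reference_midpoints)
  displacement_stats(moved - observed_midpoints, locations = reference_midpoints)
}

#' Compare two methods' displacement statistics under the half-pixel rule
#'
#' Differences in the five summary statistics between two methods; a
#' difference is flagged significant iff its absolute value is at least half
#' the image pixel size. "Pixel size" is taken as the maximum voxel
#' dimension of the observed volume.
#'
#' @param stats_a,stats_b [displacement_stats()] objects.
#' @param pixel_size observed-image pixel size in mm (> 0).
#' @return An object of class `method_comparison` with `differences`
#'   (signed, a - b), `half_pixel` and logical `significant` flags.
#' @export
compare_methods <- function(stats_a, stats_b, pixel_size) {
  if (!(pixel_size > 0)) stop("pixel_size must be positive")
  diffs <- stats_vector(stats_a) - stats_vector(stats_b)
  half <- pixel_size / 2
  structure(list(differences = diffs, half_pixel = half,
                 significant = abs(diffs) >= half),
            class = "method_comparison")
}

#' @export
print.method_comparison <- function(x, ...) {
  cat(sprintf("<method_comparison> half-pixel = %.3f mm\n", x$half_pixel))
  for (nm in names(x$differences))
    cat(sprintf("  %-6s %+0.4f mm %s\n", nm, x$differences[nm],
                if (x$significant[nm]) "(significant)" else ""))
  invisible(x)
}

#' Distortion magnitude versus distance from the isocenter
#'
#' The one-dimensional QA profile: per control point, distance of its
#' reference position from the isocenter against its displacement
#' magnitude, plus binned means.
#'
#' @param pairs a [pair_control_points()] result.
#' @param isocenter world point (mm), default the origin.
#' @param bin_width radial bin width in mm (default 10).
#' @return list with `points` (data frame: radius_mm, magnitude_mm) and
#'   `bins` (data frame: radius bin center, mean magnitude, n).
#' @export
distance_profile <- function(pairs, isocenter = c(0, 0, 0), bin_width = 10) {
  ref <- as.matrix(pairs$pairs[, c("ref_x", "ref_y", "ref_z")])
  r <- sqrt(rowSums(sweep(ref, 2, isocenter, "-")^2))
  mag <- pairs$pairs$distance
  pts <- data.frame(radius_mm = r, magnitude_mm = mag)
  bin <- floor(r / bin_width)
  bins <- data.frame(radius_mm = (sort(unique(bin)) + 0.5) * bin_width,
                     mean_magnitude_mm = as.numeric(tapply(mag, bin, mean)),
                     n = as.integer(table(bin)))
  list(points = pts, bins = bins)
}

#' Classify scanner performance from a distortion summary
#'
#' Sub-millimetre maximum distortion (`max < 1.0` mm) is regarded as
#' high-performing; the accreditation criterion allows a maximum deviation
#' of 2.0 mm (`max <= 2.0` mm passes). Boundary behaviour: a maximum of
#' exactly 1.0 mm is not sub-millimetre (not high-performing); a maximum of
#' exactly 2.0 mm is within the allowed deviation (pass).
#'
#' @param stats a [displacement_stats()] object.
#' @return list with `high_performing`, `acr_pass`, `max_mm`, `mean_mm`.
#' @export
classify_performance <- function(stats) {
  list(high_performing = stats$max < 1.0,
       acr_pass = stats$max <= 2.0,
       max_mm = stats$max, mean_mm = stats$mean)
}

#' Write a displacement table as TSV
#'
#' Columns: id, x, y, z (reference position), dx, dy, dz, r_mm (distance
#' from isocenter) and displacement magnitude.
#'
#' @param pairs a [pair_control_points()] result.
#' @param path output TSV path.
#' @param isocenter world point for the radius column.
#' @export
write_displacements <- function(pairs, path, isocenter = c(0, 0, 0)) {
  p <- pairs$pairs
  r <- sqrt((p$ref_x - isocenter[1])^2 + (p$ref_y - isocenter[2])^2 +
            (p$ref_z - isocenter[3])^2)
  df <- data.frame(id = p$reference_id, x = p$ref_x, y = p$ref_y, z = p$ref_z,
                   dx = p$dx, dy = p$dy, dz = p$dz, r_mm = r,
                   magnitude_mm = p$distance)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' QA plots
#'
#' `plot_distance_profile` renders the isocenter-distance scatter with
#' binned means; `plot_displacement_box` renders a box summary of one or
#' more displacement distributions.
#'
#' @param profile a [distance_profile()] result.
#' @param file optional PNG path; when given, the plot is written there.
#' @export
plot_distance_profile <- function(profile, file = NULL) {
  if (!is.null(file)) {
    grDevices::png(file, width = 900, height = 600)
    on.exit(grDevices::dev.off())
  }
  plot(profile$points$radius_mm, profile$points$magnitude_mm,
       pch = 16, col = "#00000055", xlab = "distance from isocenter (mm)",
       ylab = "distortion magnitude (mm)")
  graphics::lines(profile$bins$radius_mm, profile$bins$mean_magnitude_mm,
                  col = "red", lwd = 2, type = "b", pch = 15)
  invisible(NULL)
}

#' @rdname plot_distance_profile
#' @param stats_list named list of [displacement_stats()] objects.
#' @export
plot_displacement_box <- function(stats_list, file = NULL) {
  if (!is.null(file)) {
    grDevices::png(file, width = 900, height = 600)
    on.exit(grDevices::dev.off())
  }
  graphics::boxplot(lapply(stats_list, `[[`, "magnitudes"),
                    ylab = "CP displacement (mm)", las = 2)
  invisible(NULL)
}
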