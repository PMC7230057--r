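#' Build the grid-phantom geometry
#'
#' Constructs the regular cubic lattice of grid vertices (the control points,
#' CPs), the bars connecting adjacent vertices, and the elementary cells
#' (cubes of 8 neighbouring vertices) whose centers serve as the midpoint
#' overfitting diagnostic. The lattice is the maximal one fitting inside the
#' extent box, centred on the world origin (the phantom isocenter). When a
#' container radius is given, vertices are trimmed to the cylinder about the
#' first (height) axis: a vertex is kept iff its radial distance from the
#' axis is at most `container_inner_radius - bar_thickness/2`, so that the
#' whole bar cross-section fits inside the container wall.
#'
#' @param vertex_spacing lattice spacing in mm (default 15).
#' @param bar_thickness thickness of the square-cross-section bars in mm
#'   (default 3).
#' @param grid_extent length-3 extent of the grid box in mm, height first
#'   (default `c(120, 150, 150)`).
#' @param container_inner_radius optional cylindrical trim radius in mm.
#' @return An object of class `phantom_geometry` with elements `vertices`
#'   (data frame: id, lattice indices i/j/k, world x/y/z), `cells` (matrix of
#'   8 vertex ids per elementary cube), `midpoints` (cell centers, mm) and
#'   `bars` (one row per bar: axis and endpoint vertex ids).
#' @export
build_grid_geometry <- function(vertex_spacing = 15, bar_thickness = 3,
                                grid_extent = c(120, 150, 150),
                                container_inner_radius = NULL) {
  s <- as.numeric(vertex_spacing)
  bt <- as.numeric(bar_thickness)
  ext <- rep_len(as.numeric(grid_extent), 3L)
  if (!(s > bt && bt > 0))
    stop("invalid-geometry: need vertex_spacing > bar_thickness > 0")
  if (any(ext < s))
    stop("empty-grid: extent smaller than one vertex spacing on some axis")

  n <- floor(ext / s) + 1L
  coords <- lapply(1:3, function(a) (seq_len(n[a]) - (n[a] + 1) / 2) * s)

  idx <- as.matrix(expand.grid(i = seq_len(n[1]), j = seq_len(n[2]),
                               k = seq_len(n[3])))
  xyz <- cbind(coords[[1]][idx[, 1]], coords[[2]][idx[, 2]],
               coords[[3]][idx[, 3]])
  keep <- rep(TRUE, nrow(idx))
  if (!is.null(container_inner_radius)) {
    r_allowed <- container_inner_radius - bt / 2
    keep <- sqrt(xyz[, 2]^2 + xyz[, 3]^2) <= r_allowed + 1e-9
    if (!any(keep)) stop("empty-grid: trimming removed every vertex")
  }
  idx <- idx[keep, , drop = FALSE]
  xyz <- xyz[keep, , drop = FALSE]
  vertices <- data.frame(id = seq_len(nrow(idx)),
                         i = idx[, 1], j = idx[, 2], k = idx[, 3],
                         x = xyz[, 1], y = xyz[, 2], z = xyz[, 3])

  # id lookup on the full lattice (0 = absent)
  lut <- array(0L, dim = n)
  lut[cbind(vertices$i, vertices$j, vertices$k)] <- vertices$id

  # bars between adjacent surviving vertices
  bars <- list()
  for (ax in 1:3) {
    shift <- c(0L, 0L, 0L)
    shift[ax] <- 1L
    a <- vertices[vertices[[c("i", "j", "k")[ax]]] < n[ax], , drop = FALSE]
    nb <- lut[cbind(a$i + shift[1], a$j + shift[2], a$k + shift[3])]
    sel <- nb > 0L
    if (any(sel))
      bars[[ax]] <- data.frame(axis = ax, from = a$id[sel], to = nb[sel])
  }
  bars <- do.call(rbind, bars)
  rownames(bars) <- NULL

  # elementary cells: all 8 corners present
  cells <- NULL
  mids <- NULL
  base <- idx[idx[, 1] < n[1] & idx[, 2] < n[2] & idx[, 3] < n[3], , drop = FALSE]
  if (nrow(base) > 0) {
    corner_off <- as.matrix(expand.grid(0:1, 0:1, 0:1))
    ids <- sapply(seq_len(nrow(corner_off)), function(c8) {
      lut[cbind(base[, 1] + corner_off[c8, 1],
                base[, 2] + corner_off[c8, 2],
                base[, 3] + corner_off[c8, 3])]
    })
    ids <- matrix(ids, nrow = nrow(base))
    full <- rowSums(ids > 0L) == 8L
    if (any(full)) {
      cells <- ids[full, , drop = FALSE]
      mids <- cbind(coords[[1]][base[full, 1]] + s / 2,
                    coords[[2]][base[full, 2]] + s / 2,
                    coords[[3]][base[full, 3]] + s / 2)
      colnames(mids) <- c("x", "y", "z")
    }
  }

  structure(list(vertex_spacing = s, bar_thickness = bt, grid_extent = ext,
                 container_inner_radius = container_inner_radius,
                 lattice_shape = n, vertices = vertices, bars = bars,
                 cells = cells, midpoints = mids),
            class = "phantom_geometry")
}

#' @export
print.phantom_geometry <- function(x, ...) {
  cat(sprintf(paste0("<phantom_geometry> %.0f mm spacing, %.0f mm bars, ",
                     "extent %s mm\n  %d vertices, %d bars, %d cells%s\n"),
              x$vertex_spacing, x$bar_thickness,
              paste(x$grid_extent, collapse = " x "),
              nrow(x$vertices), nrow(x$bars),
              if (is.null(x$cells)) 0L else nrow(x$cells),
              if (is.null(x$container_inner_radius)) "" else
                sprintf(", trimmed to r = %.0f mm", x$container_inner_radius)))
  invisible(x)
}

vertex_matrix <- function(geometry) {
  as.matrix(geometry$vertices[, c("x", "y", "z")])
}

#' Cell midpoints of a phantom geometry
#'
#' Centers of the elementary cubes of 8 neighbouring vertices.
#'
#' @param geometry a [build_grid_geometry()] object.
#' @return N x 3 matrix of world coordinates (mm).
#' @export
cell_midpoints <- function(geometry) {
  if (is.null(geometry$midpoints)) stop("geometry has no complete cells")
  geometry$midpoints
}

#' Voxelize the phantom geometry into an image volume
#'
#' A voxel takes the grid intensity iff its center lies within
#' `bar_thickness/2` (Chebyshev slab distance) of a bar axis, where each bar
#' axis is the segment between two adjacent vertices extended by half a bar
#' thickness at both ends so that vertices are solid cubes. The observed
#' (MR-like) contrast is a hyposignal grid in a signal-producing background;
#' the reference (CT-like) contrast is a hyperdense grid in a low-density
#' background. With a container radius present, voxels outside the cylinder
#' are set to `air_level`.
#'
#' @param geometry a [build_grid_geometry()] object.
#' @param voxel_spacing voxel size in mm (scalar or length 3); must not
#'   exceed the bar thickness.
#' @param contrast `"observed"` or `"reference"`.
#' @param intensity_levels `c(background, grid)`; defaults are
#'   `c(1000, 50)` (observed, oil vs polylactide) and `c(-100, 120)`
#'   (reference) — only the relative contrast matters downstream.
#' @param margin field-of-view padding beyond the grid extent, mm.
#' @param air_level intensity outside the container (defaults 0 observed,
#'   -1000 reference); only used when the geometry is trimmed.
#' @return An [image_volume] centred on the isocenter.
#' @export
voxelize_phantom <- function(geometry, voxel_spacing = 1,
                             contrast = c("observed", "reference"),
                             intensity_levels = NULL, margin = 12,
                             air_level = NULL) {
  contrast <- match.arg(contrast)
  sp <- rep_len(as.numeric(voxel_spacing), 3L)
  if (any(sp > geometry$bar_thickness))
    stop("resolution error: voxel_spacing must not exceed bar_thickness")
  if (is.null(intensity_levels))
    intensity_levels <- if (contrast == "observed") c(1000, 50) else c(-100, 120)
  if (is.null(air_level))
    air_level <- if (contrast == "observed") 0 else -1000

  half <- geometry$grid_extent / 2 + margin
  nvox <- 2L * floor(half / sp) + 1L
  origin <- -(nvox - 1) / 2 * sp
  coords <- lapply(1:3, function(a) origin[a] + (seq_len(nvox[a]) - 1) * sp[a])

  mask <- array(FALSE, dim = nvox)
  ht <- geometry$bar_thickness / 2
  v <- geometry$vertices
  for (b in seq_len(nrow(geometry$bars))) {
    ax <- geometry$bars$axis[b]
    p1 <- as.numeric(v[geometry$bars$from[b], c("x", "y", "z")])
    p2 <- as.numeric(v[geometry$bars$to[b], c("x", "y", "z")])
    lo <- pmin(p1, p2)
    hi <- pmax(p1, p2)
    lo[ax] <- lo[ax] - ht
    hi[ax] <- hi[ax] + ht
    perp <- setdiff(1:3, ax)
    lo[perp] <- lo[perp] - ht
    hi[perp] <- hi[perp] + ht
    rng <- lapply(1:3, function(a)
      which(coords[[a]] >= lo[a] - 1e-9 & coords[[a]] <= hi[a] + 1e-9))
    if (any(lengths(rng) == 0)) next
    mask[rng[[1]], rng[[2]], rng[[3]]] <- TRUE
  }

  vol <- array(intensity_levels[1], dim = nvox)
  vol[mask] <- intensity_levels[2]
  if (!is.null(geometry$container_inner_radius)) {
    r2 <- outer(coords[[2]]^2, coords[[3]]^2, "+")
    outside <- r2 > geometry$container_inner_radius^2
    if (any(outside)) {
      out3 <- aperm(array(outside, dim = c(nvox[2], nvox[3], nvox[1])),
                    c(3, 1, 2))
      vol[out3] <- air_level
    }
  }
  image_volume(vol, spacing = sp, origin = origin,
               modality = if (contrast == "observed") "observed" else "reference")
}

#' Write / read a geometry manifest
#'
#' JSON serialization of the lattice: parameters, realized vertex count,
#' vertex list, cells and bars.
#'
#' @param geometry a [build_grid_geometry()] object.
#' @param path JSON file path.
#' @export
write_geometry <- function(geometry, path) {
  obj <- list(vertex_spacing = geometry$vertex_spacing,
              bar_thickness = geometry$bar_thickness,
              grid_extent = geometry$grid_extent,
              container_inner_radius = geometry$container_inner_radius,
              n_vertices = nrow(geometry$vertices),
              n_cells = if (is.null(geometry$cells)) 0L else nrow(geometry$cells),
              vertices = geometry$vertices)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_geometry
#' @export
read_geometry <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  build_grid_geometry(obj$vertex_spacing, obj$bar_thickness, obj$grid_extent,
                      obj$container_inner_radius)
}
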