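#' Registration parameters
#'
#' The four swept parameters of the nonrigid registration plus metric and
#' seed. Defaults are the optimized values found for grid-phantom QA:
#' FGS = 30 mm, NR = 3, NSS = 3000, MNI = 500. Values outside the standard
#' search ranges (FGS 5-60 mm, NR 1-6, NSS 1000-7000, MNI 100-1000) are
#' allowed with a warning.
#'
#' @param fgs final grid spacing of the B-spline control lattice, mm.
#' @param nr number of multiresolution levels.
#' @param nss number of random spatial samples drawn per iteration.
#' @param mni maximum number of optimizer iterations per level.
#' @param metric `"mutual-information"` (cross-modality default) or
#'   `"mean-squares"` (same-contrast pairs).
#' @param seed integer seed; a run is fully deterministic given it.
#' @param bending_weight weight of the discrete bending-energy penalty on
#'   the coefficient lattice (default 0 — no regularization).
#' @param nbins histogram bins for mutual information.
#' @return An object of class `registration_params`.
#' @export
registration_params <- function(fgs = 30, nr = 3, nss = 3000, mni = 500,
                                metric = c("mutual-information", "mean-squares"),
                                seed = 1, bending_weight = 0, nbins = 32) {
  metric <- match.arg(metric)
  if (fgs < 5 || fgs > 60)
    warning("FGS outside the standard search range [5, 60] mm")
  if (nr < 1 || nr > 6)
    warning("NR outside the standard search range [1, 6]")
  if (nss < 1000 || nss > 7000)
    warning("NSS outside the standard search range [1000, 7000]")
  if (mni < 100 || mni > 1000)
    warning("MNI outside the standard search range [100, 1000]")
  structure(list(fgs = fgs, nr = as.integer(nr), nss = as.integer(nss),
                 mni = as.integer(mni), metric = metric,
                 seed = as.integer(seed), bending_weight = bending_weight,
                 nbins = as.integer(nbins)),
            class = "registration_params")
}

#' @export
print.registration_params <- function(x, ...) {
  cat(sprintf("<registration_params> FGS %g mm, NR %d, NSS %d, MNI %d, %s, seed %d\n",
              x$fgs, x$nr, x$nss, x$mni, x$metric, x$seed))
  invisible(x)
}

#' Read / write a flat parameter configuration file
#'
#' JSON with keys `final_grid_spacing_mm`, `num_resolutions`,
#' `num_spatial_samples`, `max_iterations`, `metric`, `seed`.
#'
#' @param params a [registration_params()] object.
#' @param path JSON file path.
#' @export
write_params <- function(params, path) {
  jsonlite::write_json(list(final_grid_spacing_mm = params$fgs,
                            num_resolutions = params$nr,
                            num_spatial_samples = params$nss,
                            max_iterations = params$mni,
                            metric = params$metric, seed = params$seed,
                            bending_weight = params$bending_weight),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_params
#' @export
read_params <- function(path) {
  p <- jsonlite::read_json(path, simplifyVector = TRUE)
  registration_params(p$final_grid_spacing_mm, p$num_resolutions,
                      p$num_spatial_samples, p$max_iterations,
                      metric = p$metric, seed = p$seed,
                      bending_weight = p$bending_weight %||% 0)
}

#' Automatic grid mask from a reference volume
#'
#' Segments the grid phase (the minority intensity tail) of a phantom
#' volume and dilates it by one bar thickness, yielding the sampling mask
#' for the nonrigid registration.
#'
#' @param volume an [image_volume] (typically the reference/CT).
#' @param dilate_mm dilation radius in mm (default 3, one bar thickness).
#' @return logical 3D array on the volume grid.
#' @export
auto_grid_mask <- function(volume, dilate_mm = 3) {
  v <- volume$data
  med <- median(v)
  qs <- quantile(v, c(0.001, 0.999), names = FALSE)
  grid_high <- (qs[2] - med) >= (med - qs[1])
  extreme <- if (grid_high) qs[2] else qs[1]
  thr <- med + 0.5 * (extreme - med)
  mask <- if (grid_high) v >= thr else v <= thr
  rad <- pmax(1L, as.integer(round(dilate_mm / volume$spacing)))
  out <- cpp_dilate3(as.logical(mask), dim(v), rad)
  array(out, dim = dim(v))
}

# Gaussian-smooth + stride-downsample a volume by an integer factor
downsample_volume <- function(volume, factor) {
  if (factor == 1) return(volume)
  sm <- cpp_gauss3(as.double(volume$data), dim(volume$data),
                   rep(factor / 2, 3))
  sm <- array(sm, dim = dim(volume$data))
  sel <- lapply(dim(volume$data), function(n) seq(1L, n, by = factor))
  out <- volume
  out$data <- sm[sel[[1]], sel[[2]], sel[[3]], drop = FALSE]
  out$spacing <- volume$spacing * factor
  out
}

# central-difference gradient volumes in intensity per mm
gradient_volumes <- function(volume) {
  v <- volume$data
  n <- dim(v)
  g <- vector("list", 3)
  for (ax in 1:3) {
    ip <- pmin(seq_len(n[ax]) + 1L, n[ax])
    im <- pmax(seq_len(n[ax]) - 1L, 1L)
    denom <- (ip - im) * volume$spacing[ax]
    if (ax == 1) g[[ax]] <- (v[ip, , , drop = FALSE] - v[im, , , drop = FALSE]) / denom
    if (ax == 2) g[[ax]] <- (v[, ip, , drop = FALSE] - v[, im, , drop = FALSE]) /
        rep(denom, each = n[1])
    if (ax == 3) g[[ax]] <- (v[, , ip, drop = FALSE] - v[, , im, drop = FALSE]) /
        rep(denom, each = n[1] * n[2])
  }
  g
}

# discrete bending-energy penalty gradient: second differences along each
# lattice axis, normalized by control spacing^2
bending_gradient <- function(coef, spacing) {
  g <- array(0, dim = dim(coef))
  for (ax in 1:3) {
    n <- dim(coef)[ax]
    if (n < 3) next
    perm <- c(ax, setdiff(1:4, ax))
    a <- aperm(coef, perm)
    d2 <- a
    d2[] <- 0
    core <- 2:(n - 1)
    lap <- a[core - 1, , , , drop = FALSE] - 2 * a[core, , , , drop = FALSE] +
      a[core + 1, , , , drop = FALSE]
    # gradient of sum(lap^2) w.r.t. the three stencil positions
    d2[core - 1, , , ] <- d2[core - 1, , , , drop = FALSE] + 2 * lap
    d2[core, , , ] <- d2[core, , , , drop = FALSE] - 4 * lap
    d2[core + 1, , , ] <- d2[core + 1, , , , drop = FALSE] + 2 * lap
    g <- g + aperm(d2, order(perm)) / spacing[ax]^2
  }
  g
}

#' Nonrigid B-spline registration
#'
#' Registers the reference (domain) volume onto an observed (target) volume
#' with a multiresolution stochastic-gradient-descent optimization of a
#' cubic B-spline free-form deformation. The returned transform maps domain
#' coordinates to target coordinates, so it applies directly to reference
#' control points.
#'
#' At level `l` (counting down from `nr - 1` to 0) both images are smoothed
#' and downsampled by `2^l` and the control-grid spacing is `fgs * 2^l`;
#' between levels the coefficient lattice is refined exactly by dyadic
#' B-spline subdivision. Each iteration draws `nss` fresh uniformly random
#' points inside the mask (seeded — runs are bit-reproducible) and takes an
#' adaptive stochastic gradient step. The step scale is calibrated per level
#' so the first update moves no control point by more than half a voxel;
#' two independent calibration batches must agree in direction (gradient
#' cosine above 0.05) or the level is skipped — a noise-only gradient, as
#' for already-aligned images, produces no movement. During iterations a
#' `1/(A + t)` decay clock advances when successive gradients
#' anti-correlate (overshoot/noise) and rewinds when they agree, and each
#' update is clipped to half a voxel.
#'
#' @param domain_volume reference [image_volume] (defines the transform's
#'   domain).
#' @param target_volume observed [image_volume] on the same grid.
#' @param params a [registration_params()] object.
#' @param mask optional logical array on the domain grid restricting the
#'   metric samples; default [auto_grid_mask()] of the domain volume.
#' @param verbose print per-level progress.
#' @return A [bspline_transform()] with attributes `trace` (per-level data
#'   frames of iteration, batch metric value and best-so-far value) and
#'   `params`.
#' @export
bspline_register <- function(domain_volume, target_volume, params = registration_params(),
                             mask = NULL, verbose = FALSE) {
  if (!isTRUE(all.equal(domain_volume$spacing, target_volume$spacing)) ||
      !identical(dim(domain_volume$data), dim(target_volume$data)) ||
      max(abs(domain_volume$origin - target_volume$origin)) > 1e-6)
    stop("volumes must be pre-aligned on a common grid (see resample_to_reference)")
  if (is.null(mask)) mask <- auto_grid_mask(domain_volume)
  if (!any(mask)) stop("registration mask is empty")

  with_seed(params$seed, {
    anchor <- domain_volume$origin + (dim(domain_volume$data) - 1) / 2 *
      domain_volume$spacing
    # mask bounding box in world coordinates
    midx <- which(mask, arr.ind = TRUE)
    bb_lo <- domain_volume$origin + (apply(midx, 2, min) - 1) * domain_volume$spacing
    bb_hi <- domain_volume$origin + (apply(midx, 2, max) - 1) * domain_volume$spacing

    coef <- NULL
    prev_lo <- NULL
    trace <- list()

    for (level in seq(params$nr - 1, 0)) {
      f <- 2L^level
      h <- params$fgs * f
      dom_l <- downsample_volume(domain_volume, f)
      tgt_l <- downsample_volume(target_volume, f)
      sel <- lapply(dim(mask), function(n) seq(1L, n, by = f))
      mask_l <- mask[sel[[1]], sel[[2]], sel[[3]], drop = FALSE]
      mvox <- which(mask_l, arr.ind = TRUE)
      if (nrow(mvox) < 10) stop("registration mask too small at level ", level)

      lo <- as.integer(floor((bb_lo - anchor) / h)) - 2L
      hi <- as.integer(ceiling((bb_hi - anchor) / h)) + 2L
      shape <- hi - lo + 1L
      origin <- anchor + lo * h
      coef <- if (is.null(coef)) array(0, dim = c(shape, 3L))
              else refine_coefficients(coef, prev_lo, lo, shape)
      prev_lo <- lo

      grads <- gradient_volumes(tgt_l)
      frange <- range(dom_l$data)
      mrange <- range(tgt_l$data)
      metric_code <- if (params$metric == "mean-squares") 0L else 1L

      draw_batch <- function() {
        rows <- sample.int(nrow(mvox), params$nss, replace = TRUE)
        jitter <- matrix(runif(params$nss * 3) - 0.5, ncol = 3)
        voxel_to_world(dom_l, mvox[rows, , drop = FALSE] - 1L + jitter)
      }
      eval_grad <- function(pts) {
        cpp_metric_grad(as.double(coef), shape, origin, rep(h, 3), pts,
                        as.double(dom_l$data), dim(dom_l$data), dom_l$spacing,
                        dom_l$origin,
                        as.double(tgt_l$data), as.double(grads[[1]]),
                        as.double(grads[[2]]), as.double(grads[[3]]),
                        dim(tgt_l$data), tgt_l$spacing, tgt_l$origin,
                        metric_code, params$nbins, frange, mrange)
      }

      # Step-size calibration: two independent batches must agree in
      # direction (noise-dominated gradients on already-aligned images do
      # not), and the first step moves no control point by more than half
      # a voxel.
      delta <- 0.5 * mean(dom_l$spacing)
      b1 <- eval_grad(draw_batch())
      b2 <- eval_grad(draw_batch())
      n1 <- sqrt(sum(b1$grad^2))
      n2 <- sqrt(sum(b2$grad^2))
      cosv <- if (n1 > 0 && n2 > 0) sum(b1$grad * b2$grad) / (n1 * n2) else 0
      gmax <- max(abs(b1$grad), abs(b2$grad))
      A <- 20
      a <- if (gmax > 0 && cosv > 0.05) delta * (A + 1) / gmax else 0

      vals <- numeric(params$mni)
      best <- numeric(params$mni)
      bestv <- Inf
      if (a > 0) {
        # adaptive time: anti-correlated successive gradients (overshoot or
        # noise) advance the decay clock, correlated ones rewind it
        t_ad <- 0
        g_prev <- NULL
        np <- 0
        for (t in seq_len(params$mni)) {
          res <- eval_grad(draw_batch())
          g <- res$grad
          if (params$bending_weight > 0)
            g <- g + params$bending_weight *
              as.double(bending_gradient(coef, rep(h, 3)))
          gn <- sqrt(sum(g^2))
          if (!is.null(g_prev) && gn > 0 && np > 0) {
            x <- -sum(g * g_prev) / (gn * np)
            t_ad <- max(0, t_ad + 2 / (1 + exp(-4 * x)) - 1)
          }
          step <- (a / (A + t_ad + 1)) * g
          smax <- max(abs(step))
          if (smax > delta) step <- step * (delta / smax)
          coef <- coef - array(step, dim = dim(coef))
          g_prev <- g
          np <- gn
          vals[t] <- res$value
          bestv <- min(bestv, res$value)
          best[t] <- bestv
          if (!is.finite(res$value))
            stop("registration-failure: non-finite metric at level ", level,
                 ", iteration ", t)
        }
      }
      trace[[length(trace) + 1]] <-
        data.frame(level = level, iteration = seq_len(params$mni),
                   value = vals, best = best)
      if (verbose)
        message(sprintf("level %d (factor %d): metric %.6g -> %.6g",
                        level, f, g0$value, if (params$mni > 0) bestv else g0$value))
    }

    out <- bspline_transform(origin, rep(params$fgs, 3), dim(coef)[1:3], coef)
    attr(out, "trace") <- do.call(rbind, trace)
    attr(out, "params") <- params
    out
  })
}
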