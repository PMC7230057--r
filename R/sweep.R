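#' Evaluate registration parameters over a set of acquisitions
#'
#' Runs the nonrigid registration on each acquisition with the given
#' parameters, applies the recovered transform to the reference control
#' points, and returns the grand mean distance between the transformed
#' reference CPs and the observed CPs (the error measure of the parameter
#' search), weighted by CP count across acquisitions.
#'
#' Each acquisition is a list with elements `reference` and `observed`
#' (pre-aligned [image_volume]s on a common grid), `reference_cps` and
#' `observed_cps` ([control_points] sets whose shared ids define the
#' correspondence). Per-acquisition seeds are derived deterministically from
#' the parameter seed and the acquisition index. A failed registration is
#' recorded and excluded with a warning rather than aborting the sweep.
#'
#' @param acquisitions list of acquisition lists (see Details).
#' @param params a [registration_params()] object.
#' @return grand mean error in mm, with attributes `per_acquisition` (mean
#'   error per acquisition), `n_cps` and `failed` (indices).
#' @export
evaluate_params <- function(acquisitions, params) {
  if (length(acquisitions) < 1) stop("need at least one acquisition")
  per <- rep(NA_real_, length(acquisitions))
  ncp <- rep(0L, length(acquisitions))
  failed <- integer(0)
  for (i in seq_along(acquisitions)) {
    acq <- acquisitions[[i]]
    p <- params
    p$seed <- as.integer((as.numeric(params$seed) * 131 + i) %% 2147483647)
    res <- tryCatch({
      tr <- bspline_register(acq$reference, acq$observed, p,
                             mask = acq$mask %||% NULL)
      ids <- intersect(acq$reference_cps$points$id, acq$observed_cps$points$id)
      rp <- cp_matrix(acq$reference_cps)[match(ids, acq$reference_cps$points$id), ,
                                         drop = FALSE]
      op <- cp_matrix(acq$observed_cps)[match(ids, acq$observed_cps$points$id), ,
                                        drop = FALSE]
      moved <- transform_points(tr, rp)
      sqrt(rowSums((moved - op)^2))
    }, error = function(e) e)
    if (inherits(res, "error")) {
      warning("acquisition ", i, " excluded: ", conditionMessage(res))
      failed <- c(failed, i)
    } else {
      per[i] <- mean(res)
      ncp[i] <- length(res)
    }
  }
  okv <- !is.na(per)
  if (!any(okv)) stop("all acquisitions failed")
  grand <- sum(per[okv] * ncp[okv]) / sum(ncp[okv])
  structure(grand, per_acquisition = per, n_cps = ncp, failed = failed)
}

#' Sequential coordinate-wise registration-parameter optimization
#'
#' Sweeps the registration parameters one at a time in the given order,
#' fixing each parameter at its optimum (the tested value with minimal mean
#' error; ties break to the smallest value) before sweeping the next, and
#' optionally re-sweeps the first parameter at the end with all later
#' optima in place. The default search grids cover the standard ranges
#' (FGS 5-60 mm, NR 1-6, NSS 1000-7000, MNI 100-1000) and the default
#' initial context is NR = 4, NSS = 3000, MNI = 500.
#'
#' @param acquisitions as in [evaluate_params()].
#' @param search_space named list of value vectors for `fgs`, `nr`, `nss`,
#'   `mni` (any subset).
#' @param order parameter names in sweep order (default the order of
#'   `search_space`).
#' @param initial a [registration_params()] giving the fixed-parameter
#'   context for the first sweep.
#' @param resweep_first repeat the first parameter's sweep at the end.
#' @return list of `sweep_result` objects: parameter name, tested values,
#'   per-value mean and between-acquisition sd of the error, chosen optimum
#'   and the fixed-parameter context.
#' @export
sequential_sweep <- function(acquisitions,
                             search_space = list(fgs = c(5, 10, 15, 20, 30, 40, 60),
                                                 nr = 1:6,
                                                 nss = c(1000, 2000, 3000, 5000, 7000),
                                                 mni = c(100, 200, 500, 1000)),
                             order = names(search_space),
                             initial = registration_params(nr = 4),
                             resweep_first = TRUE) {
  if (!all(order %in% names(search_space)))
    stop("configuration error: order names missing from search_space")
  if (any(lengths(search_space) == 0))
    stop("configuration error: empty value list in search_space")
  current <- initial
  results <- list()
  sweep_one <- function(name) {
    values <- search_space[[name]]
    means <- numeric(length(values))
    sds <- numeric(length(values))
    for (v in seq_along(values)) {
      p <- current
      p[[name]] <- values[v]
      err <- evaluate_params(acquisitions, p)
      means[v] <- as.numeric(err)
      per <- attr(err, "per_acquisition")
      sds[v] <- if (sum(!is.na(per)) > 1) sd(per, na.rm = TRUE) else 0
    }
    ordv <- order(means, values)  # ties break to the smallest value
    chosen <- values[ordv[1]]
    structure(list(parameter = name, values = values, mean_error = means,
                   sd_error = sds, optimum = chosen,
                   context = current[c("fgs", "nr", "nss", "mni")]),
              class = "sweep_result")
  }
  for (name in order) {
    res <- sweep_one(name)
    results[[length(results) + 1]] <- res
    current[[res$parameter]] <- res$optimum
  }
  if (resweep_first && length(order) > 1) {
    res <- sweep_one(order[1])
    results[[length(results) + 1]] <- res
    current[[res$parameter]] <- res$optimum
  }
  attr(results, "optimal") <- current
  results
}

#' @export
print.sweep_result <- function(x, ...) {
  cat(sprintf("<sweep_result> %s: optimum %g\n", x$parameter, x$optimum))
  for (v in seq_along(x$values))
    cat(sprintf("  %-6g %.4f +- %.4f mm%s\n", x$values[v], x$mean_error[v],
                x$sd_error[v], if (x$values[v] == x$optimum) "  *" else ""))
  invisible(x)
}

#' Write sweep results as TSV + JSON
#'
#' @param results a [sequential_sweep()] result list.
#' @param dir output directory (created if needed).
#' @export
write_sweep <- function(results, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  rows <- do.call(rbind, lapply(seq_along(results), function(i) {
    r <- results[[i]]
    data.frame(sweep = i, parameter = r$parameter, value = r$values,
               mean_error_mm = r$mean_error, sd_error_mm = r$sd_error,
               chosen = r$values == r$optimum)
  }))
  write.table(rows, file.path(dir, "sweeps.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  jsonlite::write_json(lapply(results, unclass),
                       file.path(dir, "sweeps.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
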