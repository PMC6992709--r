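#' Doubling time from an OD600 growth curve
#'
#' Fits a smoothing spline to log2(OD) versus time, evaluates its first
#' derivative on the observation grid, and takes the maximum slope as
#' the maximum specific growth rate (log2 units per minute); the
#' doubling time is its reciprocal.  The spline operates on log2(OD) so
#' the slope is directly the specific growth rate and the estimate is
#' invariant to vertical scaling of the curve.
#'
#' @param time time points in minutes (strictly increasing, >= 8 points
#'   after trimming).
#' @param od OD600 readings (> 0; max/min >= 2 required, otherwise the
#'   curve has insufficient dynamic range).
#' @param smoothing optional `spar` passed to [stats::smooth.spline()];
#'   default NULL selects smoothing by generalized cross-validation.
#' @param trim_start minutes discarded at the start as equilibration
#'   (default 30; set 0 to keep everything).
#' @return object of class `doubling_estimate` with `doubling_min`,
#'   `max_specific_growth` (log2/min), `t_max` (time of maximum slope).
#' @export
doubling_time <- function(time, od, smoothing = NULL, trim_start = 30) {
  assert_that(length(time) == length(od), "time and od lengths differ")
  assert_that(!is.unsorted(time, strictly = TRUE),
              "time must be strictly increasing")
  keep <- time >= min(time) + trim_start
  time <- time[keep]; od <- od[keep]
  assert_that(length(time) >= 8, "need at least 8 points")
  assert_that(all(od > 0), "nonpositive OD readings")
  if (max(od) / min(od) < 2)
    stop_aneuvol("insufficient dynamic range (max/min OD < 2)",
                 class = "aneuvol_no_growth")
  y <- log2(od)
  fit <- if (is.null(smoothing)) smooth.spline(time, y)
         else smooth.spline(time, y, spar = smoothing)
  slope <- predict(fit, time, deriv = 1)$y
  i <- which.max(slope)
  assert_that(slope[i] > 0, "no positive growth detected")
  structure(list(doubling_min = 1 / slope[i],
                 max_specific_growth = slope[i],
                 t_max = time[i],
                 n_points = length(time)),
            class = "doubling_estimate")
}

#' @export
print.doubling_estimate <- function(x, ...) {
  cat(sprintf("doubling_estimate: %.1f min (max slope %.4g log2/min at t=%g)\n",
              x$doubling_min, x$max_specific_growth, x$t_max))
  invisible(x)
}

#' Doubling-time estimates for a long-format growth table
#'
#' @param curves data.frame with columns `sample_id`, `replicate`,
#'   `time_min`, `od` (the layout written by [simulate_growth()] or read
#'   from a plate-reader TSV).
#' @param ... passed to [doubling_time()].
#' @return data.frame per sample: `sample_id`, `doubling_min` (replicate
#'   mean), `sd`, `n_replicates`.
#' @export
doubling_time_table <- function(curves, ...) {
  out <- lapply(split(curves, curves$sample_id), function(d) {
    ests <- vapply(split(d, d$replicate), function(r)
      doubling_time(r$time_min, r$od, ...)$doubling_min, numeric(1))
    data.frame(sample_id = d$sample_id[1], doubling_min = mean(ests),
               sd = if (length(ests) > 1) sd(ests) else NA_real_,
               n_replicates = length(ests))
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Relative doubling-time change between ancestor and evolved line
#'
#' `100 * (ancestor - evolved) / ancestor`; positive values mean the
#' evolved line grows faster.
#'
#' @param ancestor,evolved doubling times (minutes or any common unit),
#'   or `doubling_estimate` objects.
#' @return percent change.
#' @export
relative_change <- function(ancestor, evolved) {
  a <- if (inherits(ancestor, "doubling_estimate")) ancestor$doubling_min
       else ancestor
  e <- if (inherits(evolved, "doubling_estimate")) evolved$doubling_min
       else evolved
  assert_that(all(a > 0) && all(e > 0), "doubling times must be positive")
  100 * (a - e) / a
}
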