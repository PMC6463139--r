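#' Integrate a circuit ODE system
#'
#' Stiff-capable integration (deSolve, \code{lsoda} by default) with dense
#' output at a fixed sampling interval. Solver settings are recorded in the
#' trajectory metadata.
#'
#' @param system a \code{dualosc_system} from [assembleOdes()].
#' @param initial full initial state; defaults to [defaultInitialState()].
#' @param t_end end time (min).
#' @param dt output sampling interval (min).
#' @param method deSolve method.
#' @param rtol,atol solver tolerances.
#' @return object of class \code{dualosc_trajectory}: list with
#'   \code{times}, \code{values} (matrix, one column per state variable),
#'   \code{metadata}.
#' @export
#' @examples
#' sys <- assembleOdes(circuitConfig("none"), oscillatorParameters(),
#'                     inducerCondition(1.0, 0.1))
#' traj <- integrateOdes(sys, t_end = 60)
#' range(traj$times)
integrateOdes <- function(system, initial = defaultInitialState(system),
                          t_end, dt = 0.5, method = "lsoda",
                          rtol = 1e-8, atol = 1e-8) {
  stopifnot(inherits(system, "dualosc_system"))
  if (t_end <= 0) stop("t_end must be > 0", call. = FALSE)
  if (length(initial) != system$n) {
    stop("initial state has length ", length(initial), ", expected ",
         system$n, call. = FALSE)
  }
  times <- seq(0, t_end, by = dt)
  func <- function(t, y, parms) list(unname(system$rhs(y)))
  out <- deSolve::ode(y = unname(initial), times = times, func = func,
                      parms = NULL, method = method, rtol = rtol, atol = atol)
  attr_ds <- attributes(out)
  if (!is.null(attr_ds$istate) && attr_ds$istate[1] < 0) {
    stop("ODE integration failed (istate = ", attr_ds$istate[1],
         "); last good time ", max(out[, 1]), call. = FALSE)
  }
  vals <- out[, -1, drop = FALSE]
  colnames(vals) <- system$state_names
  structure(
    list(times = out[, 1], values = vals,
         metadata = list(config = system$config,
                         condition = system$condition,
                         solver = list(method = method, rtol = rtol,
                                       atol = atol, dt = dt),
                         mrna = system$mrna)),
    class = "dualosc_trajectory"
  )
}

#' @export
print.dualosc_trajectory <- function(x, ...) {
  cat(sprintf("<trajectory> %d samples on [0, %g] min, %d variables\n",
              length(x$times), max(x$times), ncol(x$values)))
  invisible(x)
}

# Local maxima of a sampled series by derivative sign change, with a
# minimum separation of a quarter of the running inter-peak interval
# (closely spaced maxima keep the higher one).
find_peaks <- function(x, min_sep_frac = 0.25) {
  n <- length(x)
  if (n < 3) return(integer(0))
  dx <- diff(x)
  idx <- which(dx[-length(dx)] > 0 & dx[-1] <= 0) + 1L
  if (length(idx) >= 3) {
    est <- stats::median(diff(idx))
    min_sep <- max(1, floor(min_sep_frac * est))
    keep <- integer(0)
    for (i in idx) {
      if (!length(keep) || i - keep[length(keep)] >= min_sep) {
        keep <- c(keep, i)
      } else if (x[i] > x[keep[length(keep)]]) {
        keep[length(keep)] <- i
      }
    }
    idx <- keep
  }
  idx
}

#' Extract oscillation metrics from a trajectory
#'
#' Discards the transient window, then detects peaks on each requested
#' species. A species is oscillatory iff its post-transient swing exceeds
#' \code{amp_threshold} (default 1 molecule/cell: sub-molecule swings are
#' not called oscillations) and at least two full periods (three peaks) are
#' observed. The period is the mean inter-peak interval; the amplitude is
#' peak-to-trough (max - min) over the last full cycles, so a damped
#' transient that decays below threshold is classified fixed.
#'
#' @param traj a \code{dualosc_trajectory}.
#' @param species state-variable names to score (default the free-protein
#'   pools present).
#' @param transient_fraction fraction of the trajectory discarded as
#'   transient.
#' @param amp_threshold minimum sustained amplitude (molecules/cell).
#' @return object of class \code{dualosc_metrics}: per-species list with
#'   \code{classification} ("fixed"/"oscillatory"), \code{amplitude},
#'   \code{period} (NA when fixed), \code{peaks}, \code{troughs}
#'   (timestamps); plus an overall \code{classification} (oscillatory if
#'   any scored species is).
#' @export
#' @examples
#' t <- seq(0, 400, by = 0.5)
#' traj <- structure(list(times = t,
#'   values = cbind(x = 50 + 10 * sin(2 * pi * t / 40)),
#'   metadata = list()), class = "dualosc_trajectory")
#' m <- oscillationMetrics(traj, species = "x")
#' m$species$x$period
oscillationMetrics <- function(traj, species = NULL,
                               transient_fraction = 0.5,
                               amp_threshold = 1) {
  stopifnot(inherits(traj, "dualosc_trajectory"))
  if (transient_fraction < 0 || transient_fraction >= 1) {
    stop("transient_fraction must lie in [0, 1)", call. = FALSE)
  }
  if (is.null(species)) {
    species <- intersect(c("a", "l", "g"), colnames(traj$values))
  }
  missing <- setdiff(species, colnames(traj$values))
  if (length(missing)) {
    stop("trajectory lacks species: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  t_all <- traj$times
  cut <- transient_fraction * max(t_all)
  win <- t_all >= cut
  if (sum(win) < 5) stop("trajectory shorter than the transient window",
                         call. = FALSE)
  tw <- t_all[win]
  out <- list()
  for (sp in species) {
    x <- traj$values[win, sp]
    pk <- find_peaks(x)
    tr <- find_peaks(-x)
    res <- list(classification = "fixed", amplitude = 0, period = NA_real_,
                peaks = tw[pk], troughs = tw[tr])
    swing <- max(x) - min(x)
    if (length(pk) >= 3 && swing > amp_threshold) {
      # amplitude over the last two full cycles
      lastwin <- tw >= tw[pk[length(pk) - 2]]
      amp <- max(x[lastwin]) - min(x[lastwin])
      if (amp > amp_threshold) {
        res$classification <- "oscillatory"
        res$amplitude <- amp
        res$period <- mean(diff(tw[pk]))
      } else {
        res$amplitude <- amp
      }
    } else {
      res$amplitude <- swing
    }
    out[[sp]] <- res
  }
  structure(
    list(species = out,
         classification = if (any(vapply(out, function(r)
           r$classification == "oscillatory", logical(1))))
           "oscillatory" else "fixed",
         settings = list(transient_fraction = transient_fraction,
                         amp_threshold = amp_threshold,
                         amplitude_definition = "peak-to-trough")),
    class = "dualosc_metrics"
  )
}

#' @export
print.dualosc_metrics <- function(x, ...) {
  cat(sprintf("<oscillation metrics> overall: %s\n", x$classification))
  for (sp in names(x$species)) {
    r <- x$species[[sp]]
    cat(sprintf("  %s: %s, amplitude %.3g%s\n", sp, r$classification,
                r$amplitude,
                if (is.finite(r$period)) sprintf(", period %.3g min", r$period)
                else ""))
  }
  invisible(x)
}

#' Write oscillation metrics as a structured summary file
#'
#' @param metrics a \code{dualosc_metrics} object.
#' @param path output JSON path.
#' @return the path, invisibly.
#' @export
writeOscillationMetrics <- function(metrics, path) {
  stopifnot(inherits(metrics, "dualosc_metrics"))
  jsonlite::write_json(
    list(classification = metrics$classification,
         species = lapply(metrics$species, function(r)
           list(classification = r$classification,
                amplitude = r$amplitude,
                period = if (is.finite(r$period)) r$period else NULL,
                n_peaks = length(r$peaks))),
         settings = metrics$settings),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Write a trajectory as a wide-format delimited table
#'
#' @param traj a \code{dualosc_trajectory}.
#' @param path output file (tab-separated; time + one column per variable).
#' @export
writeTrajectory <- function(traj, path) {
  stopifnot(inherits(traj, "dualosc_trajectory"))
  df <- data.frame(time = traj$times, traj$values, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}
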