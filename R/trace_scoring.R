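#' Fluorescence trace container
#'
#' A single per-colony GFP intensity time course at one inducer condition,
#' as produced by time-lapse microscopy (or the synthetic generator).
#'
#' @param times sampling times (min), uniformly spaced, >= 2 samples.
#' @param intensity fluorescence intensities (arbitrary units), same
#'   length.
#' @param condition an [inducerCondition()].
#' @param trace_id identifier string.
#' @param source \code{"synthetic"} or \code{"measured"}.
#' @return object of class \code{dualosc_trace}.
#' @export
fluorescenceTrace <- function(times, intensity, condition,
                              trace_id = "trace", source = "synthetic") {
  times <- as.numeric(times); intensity <- as.numeric(intensity)
  if (length(times) < 2L || length(times) != length(intensity)) {
    stop("need >= 2 samples with matching times/intensity lengths",
         call. = FALSE)
  }
  dt <- diff(times)
  if (any(dt <= 0) || diff(range(dt)) > 1e-8 * max(dt)) {
    stop("times must be strictly increasing and uniformly spaced",
         call. = FALSE)
  }
  if (!inherits(condition, "dualosc_condition")) {
    stop("condition must be an inducerCondition()", call. = FALSE)
  }
  source <- match.arg(source, c("synthetic", "measured"))
  structure(list(times = times, intensity = intensity,
                 condition = condition, trace_id = as.character(trace_id),
                 source = source, interval = dt[1]),
            class = "dualosc_trace")
}

#' @export
print.dualosc_trace <- function(x, ...) {
  cat(sprintf("<fluorescence trace '%s'> %d samples every %g min (%s), ara %g%%, IPTG %g mM\n",
              x$trace_id, length(x$times), x$interval, x$source,
              x$condition$arabinose, x$condition$iptg))
  invisible(x)
}

# centred moving average; window trimmed at the ends
moving_average <- function(x, w) {
  if (w <= 1) return(x)
  n <- length(x)
  half <- (w - 1) / 2
  out <- numeric(n)
  for (i in seq_len(n)) {
    lo <- max(1, ceiling(i - half)); hi <- min(n, floor(i + half))
    out[i] <- mean(x[lo:hi])
  }
  out
}

# topographic prominence of a local minimum: on each side, the highest
# level reached before a point lower than the minimum (or the boundary);
# prominence = min(left, right) - depth.
min_prominence <- function(x, i) {
  xi <- x[i]
  left <- x[seq_len(i - 1)]
  right <- x[seq(i + 1, length(x))]
  lb <- which(left < xi)   # walk left until something lower is found
  lh <- if (length(lb)) max(left[seq(max(lb), length(left))]) else max(left)
  rb <- which(right < xi)  # walk right likewise
  rh <- if (length(rb)) max(right[seq_len(min(rb))]) else max(right)
  min(lh, rh) - xi
}

#' Detect oscillation bottoms (troughs) in a fluorescence trace
#'
#' Smooths the intensity with a centred moving average, then keeps the
#' interior local minima whose topographic prominence is at least
#' \code{min_prominence_fraction} of the mean post-smoothing intensity.
#' Referencing the mean level (rather than the intensity range) keeps the
#' criterion invariant to multiplying a trace by a positive constant while
#' still rejecting the weak multiplicative fluctuations of constitutive
#' traces, whose dips scale with the noise, not with the expression level.
#' Endpoints are never counted as bottoms, and a flat trace has none.
#'
#' @param trace a [fluorescenceTrace()].
#' @param smooth_window moving-average window in samples (>= 1; default 3,
#'   i.e. 9 min at the 3-min microscopy interval).
#' @param min_prominence_fraction prominence threshold as a fraction of
#'   the mean smoothed intensity, in (0, 1).
#' @return integer indices of the detected bottoms (into
#'   \code{trace$times}).
#' @export
#' @examples
#' co <- inducerCondition(1, 0.01)
#' t <- seq(0, 180, by = 3)
#' tr <- fluorescenceTrace(t, 100 + 20 * sin(2 * pi * t / 40), co)
#' tr$times[detectBottoms(tr)]  # minima near 30, 70, 110 and 150 min
detectBottoms <- function(trace, smooth_window = 3,
                          min_prominence_fraction = 0.1) {
  stopifnot(inherits(trace, "dualosc_trace"))
  if (smooth_window < 1) stop("smooth_window must be >= 1 sample",
                              call. = FALSE)
  if (min_prominence_fraction <= 0 || min_prominence_fraction >= 1) {
    stop("min_prominence_fraction must lie in (0, 1)", call. = FALSE)
  }
  x <- moving_average(trace$intensity, smooth_window)
  if (max(x) - min(x) <= 0) return(integer(0))
  ref <- mean(x)
  n <- length(x)
  # collapse runs of equal samples so a flat-sampled trough counts once
  runs <- rle(x)
  run_end <- cumsum(runs$lengths)
  run_start <- run_end - runs$lengths + 1L
  xr <- runs$values
  cand_r <- which(diff(sign(diff(xr))) > 0) + 1L
  cand <- as.integer(floor((run_start[cand_r] + run_end[cand_r]) / 2))
  cand <- cand[cand > 1 & cand < n]
  keep <- integer(0)
  for (i in cand) {
    if (min_prominence(x, i) >= min_prominence_fraction * ref) {
      keep <- c(keep, i)
    }
  }
  keep
}

#' Score one inducer condition from its traces
#'
#' Counts bottoms per trace, takes the fraction of traces with three or
#' more bottoms (the relative bottom count: a trace needs >= 3 troughs
#' within the observation window to be called oscillating), and builds the
#' cumulative distribution of bottom counts over traces sorted in
#' descending order.
#'
#' @param traces list of [fluorescenceTrace()] objects, all at the same
#'   inducer condition.
#' @param smooth_window,min_prominence_fraction passed to
#'   [detectBottoms()].
#' @param min_bottoms threshold count for calling a trace oscillating.
#' @return object of class \code{dualosc_bottom_summary}: list with
#'   \code{counts} (per trace), \code{relative_bottom_count},
#'   \code{cumulative} (data.frame \code{rank_fraction}, \code{bottoms},
#'   descending), \code{n_traces}, \code{condition}, \code{settings}.
#' @export
scoreCondition <- function(traces, smooth_window = 3,
                           min_prominence_fraction = 0.1, min_bottoms = 3) {
  if (!is.list(traces) || !length(traces) ||
      !all(vapply(traces, inherits, logical(1), "dualosc_trace"))) {
    stop("traces must be a non-empty list of fluorescence traces",
         call. = FALSE)
  }
  conds <- unique(t(vapply(traces, function(tr)
    c(tr$condition$arabinose, tr$condition$iptg), numeric(2))))
  if (nrow(conds) != 1L) {
    stop("all traces must share one inducer condition", call. = FALSE)
  }
  counts <- vapply(traces, function(tr)
    length(detectBottoms(tr, smooth_window, min_prominence_fraction)),
    integer(1))
  sorted <- sort(counts, decreasing = TRUE)
  structure(
    list(counts = counts,
         relative_bottom_count = mean(counts >= min_bottoms),
         cumulative = data.frame(
           rank_fraction = seq_along(sorted) / length(sorted),
           bottoms = sorted),
         n_traces = length(traces),
         condition = traces[[1]]$condition,
         settings = list(smooth_window = smooth_window,
                         min_prominence_fraction = min_prominence_fraction,
                         min_bottoms = min_bottoms)),
    class = "dualosc_bottom_summary"
  )
}

#' @export
print.dualosc_bottom_summary <- function(x, ...) {
  cat(sprintf("<bottom-count summary> %d traces at ara %g%%, IPTG %g mM: relative bottom count %.3f\n",
              x$n_traces, x$condition$arabinose, x$condition$iptg,
              x$relative_bottom_count))
  invisible(x)
}

#' Assemble per-condition scores into a grid-aligned heat-map matrix
#'
#' @param summaries list of [scoreCondition()] results, each at a
#'   condition lying on the grid.
#' @param grid a [gridSpec()].
#' @param tol relative tolerance for matching conditions to grid values.
#' @return numeric matrix (arabinose x IPTG) of relative bottom counts;
#'   cells without a summary are \code{NA}.
#' @export
conditionHeatmap <- function(summaries, grid, tol = 1e-6) {
  stopifnot(inherits(grid, "dualosc_grid"))
  if (!is.list(summaries) || !length(summaries) ||
      !all(vapply(summaries, inherits, logical(1), "dualosc_bottom_summary"))) {
    stop("summaries must be a non-empty list of bottom-count summaries",
         call. = FALSE)
  }
  na <- length(grid$arabinose); ni <- length(grid$iptg)
  mat <- matrix(NA_real_, na, ni,
                dimnames = list(arabinose = signif(grid$arabinose, 6),
                                iptg = signif(grid$iptg, 6)))
  match_axis <- function(v, axis) {
    d <- abs(axis - v) / pmax(abs(axis), .Machine$double.eps)
    i <- which.min(d)
    if (d[i] > tol) NA_integer_ else i
  }
  for (s in summaries) {
    i <- match_axis(s$condition$arabinose, grid$arabinose)
    j <- match_axis(s$condition$iptg, grid$iptg)
    if (is.na(i) || is.na(j)) {
      stop(sprintf("condition (ara %g, IPTG %g) is not on the grid",
                   s$condition$arabinose, s$condition$iptg), call. = FALSE)
    }
    mat[i, j] <- s$relative_bottom_count
  }
  mat
}

#' Read / write fluorescence traces as a long-format table
#'
#' Tab-separated columns: \code{trace_id}, \code{time}, \code{intensity},
#' \code{arabinose}, \code{iptg}, \code{source}.
#'
#' @param traces list of [fluorescenceTrace()] objects.
#' @param path file path.
#' @return \code{writeTraces}: the path, invisibly. \code{readTraces}: a
#'   list of traces.
#' @export
writeTraces <- function(traces, path) {
  rows <- do.call(rbind, lapply(traces, function(tr) {
    data.frame(trace_id = tr$trace_id, time = tr$times,
               intensity = tr$intensity,
               arabinose = tr$condition$arabinose,
               iptg = tr$condition$iptg, source = tr$source,
               stringsAsFactors = FALSE)
  }))
  utils::write.table(rows, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname writeTraces
#' @export
readTraces <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE)
  need <- c("trace_id", "time", "intensity", "arabinose", "iptg")
  missing <- setdiff(need, names(df))
  if (length(missing)) {
    stop("trace table lacks column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  lapply(split(df, df$trace_id), function(d) {
    d <- d[order(d$time), ]
    fluorescenceTrace(d$time, d$intensity,
                      inducerCondition(d$arabinose[1], d$iptg[1]),
                      trace_id = d$trace_id[1],
                      source = if ("source" %in% names(d)) d$source[1]
                               else "measured")
  })
}
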