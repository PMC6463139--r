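# Synthetic microscopy traces: the generator stands in for the study's
# time-lapse output so the scoring pipeline is testable without images.

with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  force(code)
}

# deterministic small-integer hash for per-trace seed derivation
derive_seed <- function(master, cell, replicate) {
  h <- (as.double(master) * 2654435761 + cell * 97561 + replicate * 1299721)
  as.integer(h %% 2147483629)
}

#' Specification of one synthetic fluorescence trace
#'
#' The generated intensity is
#' \deqn{I(t) = (b + d t + A e^{-\gamma t} \sin(2\pi t / T)) (1 + \epsilon_t)}
#' with i.i.d. zero-mean Gaussian multiplicative noise \eqn{\epsilon_t} of
#' the given scale, sampled every \code{interval} minutes over
#' \code{duration} minutes (defaults emulate the microscopy protocol:
#' every 3 min for 3 h). Damping \eqn{\gamma} turns a sustained oscillation
#' into a decaying one; amplitude 0 gives a constitutive trace with weak
#' fluctuations.
#'
#' @param duration total length (min).
#' @param interval sampling interval (min).
#' @param baseline baseline intensity (a.u., > 0).
#' @param amplitude oscillation amplitude (a.u.).
#' @param period oscillation period (min).
#' @param damping exponential damping rate of the oscillation (1/min).
#' @param noise_scale standard deviation of the multiplicative noise.
#' @param drift linear drift slope (a.u./min).
#' @param seed integer seed fixing the realisation.
#' @return object of class \code{dualosc_tracegen}.
#' @export
traceGenSpec <- function(duration = 180, interval = 3, baseline = 100,
                         amplitude = 20, period = 40, damping = 0,
                         noise_scale = 0.05, drift = 0, seed = 1) {
  if (duration <= 0 || interval <= 0) {
    stop("duration and interval must be positive", call. = FALSE)
  }
  if (noise_scale < 0) stop("noise_scale must be >= 0", call. = FALSE)
  if (period <= 0) stop("period must be positive", call. = FALSE)
  structure(list(duration = duration, interval = interval,
                 baseline = baseline, amplitude = amplitude,
                 period = period, damping = damping,
                 noise_scale = noise_scale, drift = drift,
                 seed = as.integer(seed)),
            class = "dualosc_tracegen")
}

#' Generate one synthetic fluorescence trace
#'
#' Deterministic per seed. The noise-free signal must stay positive over
#' the whole window (otherwise the spec is rejected); noisy samples are
#' floored at a tiny positive value.
#'
#' @param spec a [traceGenSpec()].
#' @param condition the [inducerCondition()] to stamp on the trace.
#' @param trace_id identifier.
#' @return a [fluorescenceTrace()].
#' @export
#' @examples
#' tr <- generateTrace(traceGenSpec(seed = 7), inducerCondition(1, 0.01))
#' length(tr$times)  # 61 samples: 180/3 + 1
generateTrace <- function(spec, condition = inducerCondition(0, 0),
                          trace_id = "synthetic") {
  stopifnot(inherits(spec, "dualosc_tracegen"))
  t <- seq(0, spec$duration, by = spec$interval)
  base <- spec$baseline + spec$drift * t +
    spec$amplitude * exp(-spec$damping * t) * sin(2 * pi * t / spec$period)
  if (any(base <= 0)) {
    stop("trace spec yields nonpositive noise-free intensity", call. = FALSE)
  }
  noise <- with_seed(spec$seed, stats::rnorm(length(t), 0, spec$noise_scale))
  intensity <- pmax(base * (1 + noise), .Machine$double.eps)
  fluorescenceTrace(t, intensity, condition, trace_id = trace_id,
                    source = "synthetic")
}

#' Generate a grid-spanning panel of synthetic traces
#'
#' \code{regime_map} assigns every grid cell a generator template the way
#' the study's conditions behave: sustained oscillation at high
#' arabinose/low IPTG, damped in between, constitutive (flat + weak
#' fluctuations) at low arabinose. Per-trace seeds are derived by hashing
#' (master seed, cell index, replicate index), so any sub-panel is
#' reproducible.
#'
#' @param grid a [gridSpec()].
#' @param regime_map function \code{(arabinose, iptg) -> traceGenSpec}
#'   (its \code{seed} field is overwritten by the derivation).
#' @param n_traces_per_cell replicates per condition (>= 1).
#' @param seed master seed.
#' @return list of [fluorescenceTrace()] objects.
#' @export
generatePanel <- function(grid, regime_map, n_traces_per_cell, seed = 1) {
  stopifnot(inherits(grid, "dualosc_grid"), is.function(regime_map))
  if (n_traces_per_cell < 1) {
    stop("n_traces_per_cell must be >= 1", call. = FALSE)
  }
  conds <- makeGrid(grid)
  out <- vector("list", nrow(conds) * n_traces_per_cell)
  k <- 0L
  for (ci in seq_len(nrow(conds))) {
    cond <- inducerCondition(conds$arabinose[ci], conds$iptg[ci])
    template <- regime_map(cond$arabinose, cond$iptg)
    stopifnot(inherits(template, "dualosc_tracegen"))
    for (r in seq_len(n_traces_per_cell)) {
      template$seed <- derive_seed(seed, ci, r)
      k <- k + 1L
      out[[k]] <- generateTrace(template, cond,
                                trace_id = sprintf("cell%03d_rep%02d", ci, r))
    }
  }
  out
}

#' Default regime map emulating the observed inducer dependence
#'
#' Sustained oscillation at high arabinose and low IPTG, damped
#' oscillation at high arabinose and high IPTG, constitutive elsewhere.
#'
#' @param ara_threshold arabinose (% w/v) above which cells oscillate.
#' @param iptg_threshold IPTG (mM) above which the oscillation is damped.
#' @param damping damping rate of the damped regime (1/min).
#' @return a function usable as \code{regime_map} in [generatePanel()].
#' @export
defaultRegimeMap <- function(ara_threshold = 0.1, iptg_threshold = 5,
                             damping = 0.03) {
  function(arabinose, iptg) {
    if (arabinose < ara_threshold) {
      traceGenSpec(amplitude = 0, noise_scale = 0.05)
    } else if (iptg > iptg_threshold) {
      traceGenSpec(amplitude = 30, damping = damping, noise_scale = 0.05)
    } else {
      traceGenSpec(amplitude = 30, damping = 0, noise_scale = 0.05)
    }
  }
}

#' Microscopy-like traces resampled from a model trajectory
#'
#' Takes the GFP variable of a simulated trajectory, resamples the last
#' \code{duration} minutes at the microscopy interval (linear
#' interpolation), and applies multiplicative noise per replicate. This
#' bridges the ODE model to the trace scorer for in-silico/in-vivo style
#' comparisons.
#'
#' @param traj a \code{dualosc_trajectory} containing a GFP column
#'   (\code{"g"}).
#' @param noise_scale multiplicative noise sd.
#' @param n number of replicate traces.
#' @param seed master seed.
#' @param duration,interval microscopy window (min) and sampling interval.
#' @param species trajectory column to sample.
#' @return list of [fluorescenceTrace()] objects.
#' @export
tracesFromModel <- function(traj, noise_scale = 0.05, n = 1, seed = 1,
                            duration = 180, interval = 3, species = "g") {
  stopifnot(inherits(traj, "dualosc_trajectory"))
  if (!species %in% colnames(traj$values)) {
    stop("trajectory has no '", species, "' variable", call. = FALSE)
  }
  t_max <- max(traj$times)
  if (t_max < duration) {
    stop("trajectory shorter than the sampling window (", duration, " min)",
         call. = FALSE)
  }
  t_out <- seq(t_max - duration, t_max, by = interval)
  g <- stats::approx(traj$times, traj$values[, species], xout = t_out)$y
  cond <- traj$metadata$condition
  if (is.null(cond)) cond <- inducerCondition(0, 0)
  lapply(seq_len(n), function(r) {
    noise <- with_seed(derive_seed(seed, 1L, r),
                       stats::rnorm(length(g), 0, noise_scale))
    fluorescenceTrace(t_out - t_out[1], pmax(g * (1 + noise), 0) +
                        .Machine$double.eps,
                      cond, trace_id = sprintf("model_rep%02d", r),
                      source = "synthetic")
  })
}
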