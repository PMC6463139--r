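#' Logarithmic two-inducer grid specification
#'
#' The experimental scan of the inducer plane: log-spaced arabinose and
#' IPTG axes with exact endpoints. The defaults reproduce the full-scale
#' scan (21 arabinose points on 0.01-1.0 % w/v, 46 IPTG points on
#' 0.001-31.6 mM); reduced grids keep the same ranges at lower resolution.
#'
#' @param ara_n,ara_min,ara_max arabinose axis: number of points and range
#'   (% w/v).
#' @param iptg_n,iptg_min,iptg_max IPTG axis: number of points and range
#'   (mM).
#' @return object of class \code{dualosc_grid} with \code{arabinose} and
#'   \code{iptg} axis vectors.
#' @export
#' @examples
#' g <- gridSpec()
#' length(g$arabinose); length(g$iptg)
gridSpec <- function(ara_n = 21, ara_min = 0.01, ara_max = 1.0,
                     iptg_n = 46, iptg_min = 0.001, iptg_max = 31.6) {
  if (ara_min <= 0 || iptg_min <= 0 || ara_max <= ara_min ||
      iptg_max <= iptg_min) {
    stop("axis bounds must be positive with max > min", call. = FALSE)
  }
  if (ara_n < 2 || iptg_n < 2) stop("each axis needs >= 2 points",
                                    call. = FALSE)
  ara <- exp(seq(log(ara_min), log(ara_max), length.out = ara_n))
  iptg <- exp(seq(log(iptg_min), log(iptg_max), length.out = iptg_n))
  ara[1] <- ara_min; ara[ara_n] <- ara_max
  iptg[1] <- iptg_min; iptg[iptg_n] <- iptg_max
  structure(list(arabinose = ara, iptg = iptg), class = "dualosc_grid")
}

#' @export
print.dualosc_grid <- function(x, ...) {
  cat(sprintf("<inducer grid> %d arabinose points [%g, %g] %%w/v x %d IPTG points [%g, %g] mM\n",
              length(x$arabinose), min(x$arabinose), max(x$arabinose),
              length(x$iptg), min(x$iptg), max(x$iptg)))
  invisible(x)
}

#' Expand a grid into inducer conditions
#'
#' @param grid a [gridSpec()].
#' @return data.frame with columns \code{arabinose}, \code{iptg} in
#'   row-major order (arabinose varying slowest).
#' @export
makeGrid <- function(grid) {
  stopifnot(inherits(grid, "dualosc_grid"))
  out <- expand.grid(iptg = grid$iptg, arabinose = grid$arabinose,
                     KEEP.OUT.ATTRS = FALSE)
  out[, c("arabinose", "iptg")]
}

#' Run a two-inducer phase-diagram sweep
#'
#' For every grid cell: assemble the ODE system, integrate from the
#' default initial state, classify the attractor from the post-transient
#' trajectory, and seed a Newton-Raphson equilibrium search with the
#' trajectory endpoint to confirm the linear stability of fixed cells. The
#' trajectory-based classification takes priority (a sustained limit cycle
#' wins even when a stable equilibrium coexists; such cells are flagged),
#' and per-cell failures are recorded in place without aborting the grid.
#' Deterministic given its inputs.
#'
#' @param config a [circuitConfig()].
#' @param params an [oscillatorParameters()] set.
#' @param grid a [gridSpec()].
#' @param t_end integration horizon per cell (min); long enough for ~10
#'   periods after the transient at the default.
#' @param dt output sampling interval (min).
#' @param equilibrium_check run the Newton/eigenvalue confirmation on
#'   cells whose trajectory settles (slower; the trajectory verdict is
#'   unchanged either way).
#' @param transient_fraction,amp_threshold passed to
#'   [oscillationMetrics()].
#' @return object of class \code{dualosc_sweep}: the grid, matrices
#'   (arabinose x IPTG) \code{classification} ("oscillatory",
#'   "stable_fixed", or "failed"), \code{amp_laci}, \code{amp_gfp},
#'   \code{period} (NA for non-oscillatory cells), \code{coexistence}
#'   (logical), and a config/params fingerprint.
#' @export
runSweep <- function(config, params, grid, t_end = 600, dt = 1,
                     equilibrium_check = FALSE,
                     transient_fraction = 0.5, amp_threshold = 1) {
  stopifnot(inherits(config, "dualosc_config"),
            inherits(grid, "dualosc_grid"))
  validate_parameters(params)
  na <- length(grid$arabinose); ni <- length(grid$iptg)
  dn <- list(arabinose = signif(grid$arabinose, 6),
             iptg = signif(grid$iptg, 6))
  cls <- matrix(NA_character_, na, ni, dimnames = dn)
  ampL <- ampG <- per <- matrix(NA_real_, na, ni, dimnames = dn)
  coex <- matrix(FALSE, na, ni, dimnames = dn)
  has_g <- config$reporter_kind != "none"
  for (i in seq_len(na)) {
    for (j in seq_len(ni)) {
      cellres <- tryCatch({
        cond <- inducerCondition(grid$arabinose[i], grid$iptg[j])
        sys <- assembleOdes(config, params, cond)
        traj <- integrateOdes(sys, t_end = t_end, dt = dt,
                              rtol = 1e-6, atol = 1e-6)
        m <- oscillationMetrics(traj, species = c("l", if (has_g) "g"),
                                transient_fraction = transient_fraction,
                                amp_threshold = amp_threshold)
        lm <- m$species$l
        osc <- lm$classification == "oscillatory"
        stable_eq <- NA
        if (equilibrium_check || !osc) {
          endpoint <- traj$values[nrow(traj$values), ]
          eq <- findEquilibria(sys, list(endpoint), tol = 1e-6)
          if (length(eq$equilibria)) stable_eq <- eq$equilibria[[1]]$stable
        }
        list(
          cls = if (osc) "oscillatory" else "stable_fixed",
          ampL = if (osc) lm$amplitude else NA_real_,
          ampG = if (osc && has_g) m$species$g$amplitude else NA_real_,
          per = if (osc) lm$period else NA_real_,
          coex = isTRUE(osc && identical(stable_eq, TRUE))
        )
      }, error = function(e) list(cls = "failed", ampL = NA, ampG = NA,
                                  per = NA, coex = FALSE))
      cls[i, j] <- cellres$cls
      ampL[i, j] <- cellres$ampL
      ampG[i, j] <- cellres$ampG
      per[i, j] <- cellres$per
      coex[i, j] <- cellres$coex
    }
  }
  structure(
    list(grid = grid, classification = cls, amp_laci = ampL,
         amp_gfp = ampG, period = per, coexistence = coex,
         config = config,
         fingerprint = list(reporter = config$reporter_kind,
                            retroactivity = config$retroactivity_on,
                            sharing = config$protease_sharing_on,
                            params = unclass(params),
                            t_end = t_end, dt = dt)),
    class = "dualosc_sweep"
  )
}

#' @export
print.dualosc_sweep <- function(x, ...) {
  n_osc <- sum(x$classification == "oscillatory", na.rm = TRUE)
  n_fix <- sum(x$classification == "stable_fixed", na.rm = TRUE)
  n_fail <- sum(x$classification == "failed", na.rm = TRUE)
  cat(sprintf("<sweep> %s reporter (retro %s, sharing %s): %d oscillatory, %d fixed%s of %d cells\n",
              x$config$reporter_kind,
              if (x$config$retroactivity_on) "on" else "off",
              if (x$config$protease_sharing_on) "on" else "off",
              n_osc, n_fix,
              if (n_fail) sprintf(", %d failed", n_fail) else "",
              length(x$classification)))
  invisible(x)
}

#' Compare two sweeps cell by cell
#'
#' @param a,b \code{dualosc_sweep} objects over the same grid.
#' @return list with oscillation-area counts (\code{n_osc_a},
#'   \code{n_osc_b}), set relations (\code{n_common}, \code{n_only_a},
#'   \code{n_only_b}, \code{n_sym_diff}), the per-cell LacI amplitude
#'   delta matrix \code{amp_delta} (a - b, NA off the common oscillatory
#'   set), and its \code{max_amp_delta} / \code{mean_amp_delta} absolute
#'   summaries.
#' @export
compareSweeps <- function(a, b) {
  stopifnot(inherits(a, "dualosc_sweep"), inherits(b, "dualosc_sweep"))
  if (!isTRUE(all.equal(a$grid$arabinose, b$grid$arabinose)) ||
      !isTRUE(all.equal(a$grid$iptg, b$grid$iptg))) {
    stop("sweeps use different grids", call. = FALSE)
  }
  oa <- a$classification == "oscillatory"
  ob <- b$classification == "oscillatory"
  common <- oa & ob
  deltas <- abs(a$amp_laci[common] - b$amp_laci[common])
  amp_delta <- a$amp_laci - b$amp_laci
  amp_delta[!common] <- NA_real_
  list(
    amp_delta = amp_delta,
    n_osc_a = sum(oa), n_osc_b = sum(ob),
    n_common = sum(common),
    n_only_a = sum(oa & !ob), n_only_b = sum(!oa & ob),
    n_sym_diff = sum(xor(oa, ob)),
    max_amp_delta = if (any(common)) max(deltas) else NA_real_,
    mean_amp_delta = if (any(common)) mean(deltas) else NA_real_
  )
}

#' Write a sweep result as delimited matrices plus a metadata sidecar
#'
#' One tab-separated matrix file per quantity (classification, LacI
#' amplitude, GFP amplitude, period, coexistence flag) with axis headers,
#' and a JSON sidecar with the grid and the config/params fingerprint.
#'
#' @param sweep a \code{dualosc_sweep}.
#' @param dir output directory (created if needed).
#' @return the directory, invisibly.
#' @export
writeSweepResult <- function(sweep, dir) {
  stopifnot(inherits(sweep, "dualosc_sweep"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  wr <- function(mat, name) {
    df <- data.frame(arabinose = rownames(mat), mat, check.names = FALSE)
    utils::write.table(df, file.path(dir, paste0(name, ".tsv")),
                       sep = "\t", row.names = FALSE, quote = FALSE)
  }
  wr(sweep$classification, "classification")
  wr(sweep$amp_laci, "amp_laci")
  wr(sweep$amp_gfp, "amp_gfp")
  wr(sweep$period, "period")
  wr(sweep$coexistence, "coexistence")
  jsonlite::write_json(sweep$fingerprint, file.path(dir, "metadata.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}
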