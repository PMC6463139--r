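#' Numerical Jacobian of an ODE right-hand side
#'
#' Central (symmetric) finite differences with a step scaled to each state
#' component: \code{h_i = eps * max(|x_i|, scale)}.
#'
#' @param f function mapping a numeric vector to its derivative.
#' @param x evaluation point.
#' @param eps relative step (default cube root of machine epsilon).
#' @param scale absolute step floor.
#' @return the square Jacobian matrix df/dx at x.
#' @export
numericJacobian <- function(f, x, eps = .Machine$double.eps^(1/3), scale = 1) {
  n <- length(x)
  f0 <- f(x)
  if (length(f0) != n) stop("f must map R^n to R^n", call. = FALSE)
  J <- matrix(0, n, n)
  for (j in seq_len(n)) {
    h <- eps * max(abs(x[[j]]), scale)
    xp <- x; xp[[j]] <- x[[j]] + h
    xm <- x; xm[[j]] <- x[[j]] - h
    J[, j] <- (f(xp) - f(xm)) / (2 * h)
  }
  J
}

#' Jacobian of an assembled circuit system at a state
#'
#' @param system a \code{dualosc_system} from [assembleOdes()].
#' @param state full state vector of the system's dimension.
#' @param reduced if TRUE (default) the Jacobian is taken in reduced
#'   coordinates with the conserved unbound state of each promoter class
#'   eliminated, so the structural zero modes of DNA-copy conservation do
#'   not contaminate the spectrum.
#' @return square numeric matrix.
#' @export
jacobianAt <- function(system, state, reduced = TRUE) {
  stopifnot(inherits(system, "dualosc_system"))
  if (length(state) != system$n) {
    stop("state has length ", length(state), ", expected ", system$n,
         call. = FALSE)
  }
  if (reduced) {
    red <- reduce_system(system)
    numericJacobian(red$rhs, unname(state[red$keep]))
  } else {
    numericJacobian(function(x) unname(system$rhs(x)), unname(state))
  }
}

# Characteristic polynomial coefficients by the Faddeev-LeVerrier trace
# recursion: det(sI - A) = s^n + c1 s^(n-1) + ... + cn. Independent of the
# eigenvalue solver used for the primary stability decision.
charpoly_coefficients <- function(A) {
  n <- nrow(A)
  coefs <- numeric(n + 1)
  coefs[1] <- 1
  M <- diag(1, n)
  for (k in seq_len(n)) {
    AM <- A %*% M
    ck <- -sum(diag(AM)) / k
    coefs[k + 1] <- ck
    M <- AM + diag(ck, n)
  }
  coefs
}

#' Routh-Hurwitz stability test on a characteristic polynomial
#'
#' Builds the Routh array of the polynomial
#' \code{c[1] s^n + c[2] s^(n-1) + ... + c[n+1]} with the standard epsilon
#' substitution for a zero first-column pivot and the auxiliary-polynomial
#' derivative for an all-zero row. The polynomial is Hurwitz-stable (all
#' roots with negative real part) iff there is no sign change down the
#' first column.
#'
#' @param coefs numeric coefficient vector, highest degree first; leading
#'   coefficient nonzero.
#' @return list with \code{stable} (logical), \code{sign_changes},
#'   \code{first_column}, and \code{degenerate} (TRUE if an epsilon or
#'   auxiliary-row substitution was needed).
#' @export
routhStable <- function(coefs) {
  coefs <- as.numeric(coefs)
  if (!all(is.finite(coefs))) stop("non-finite polynomial coefficients",
                                   call. = FALSE)
  if (abs(coefs[1]) == 0) stop("leading coefficient must be nonzero",
                               call. = FALSE)
  if (coefs[1] < 0) coefs <- -coefs
  n <- length(coefs) - 1L
  if (n == 0L) {
    return(list(stable = TRUE, sign_changes = 0L, first_column = coefs[1],
                degenerate = FALSE))
  }
  degenerate <- FALSE
  aux_row <- FALSE
  eps0 <- max(abs(coefs)) * 1e-30
  nrows <- n + 1L
  ncols <- ceiling((n + 1) / 2)
  R <- matrix(0, nrows, ncols)
  r1 <- coefs[seq(1, n + 1, by = 2)]
  r2 <- coefs[seq(2, n + 1, by = 2)]
  R[1, seq_along(r1)] <- r1
  if (length(r2)) R[2, seq_along(r2)] <- r2
  for (i in 3:nrows) {
    if (nrows < 3) break
    prev <- R[i - 1, ]
    prev2 <- R[i - 2, ]
    if (all(prev == 0)) {
      # auxiliary polynomial row: differentiate the row above it. A full
      # zero row means symmetric root pairs; with no subsequent sign
      # change they lie on the imaginary axis, so the polynomial is at
      # best marginal, never strictly Hurwitz.
      degenerate <- TRUE
      aux_row <- TRUE
      deg <- n - (i - 2) + 1
      powers <- seq(deg, by = -2, length.out = ncols)
      prev <- prev2 * pmax(powers, 0)
      R[i - 1, ] <- prev
    }
    piv <- prev[1]
    if (piv == 0) {
      degenerate <- TRUE
      piv <- eps0
      R[i - 1, 1] <- piv
    }
    for (j in seq_len(ncols - 1)) {
      R[i, j] <- (piv * prev2[j + 1] - prev2[1] * prev[j + 1]) / piv
    }
  }
  fc <- R[, 1]
  fc_nz <- fc[fc != 0]
  changes <- sum(diff(sign(fc_nz)) != 0)
  list(stable = changes == 0L && length(fc_nz) == nrows && !aux_row,
       sign_changes = changes, first_column = fc, degenerate = degenerate)
}

#' Classify linear stability of a Jacobian matrix
#'
#' Primary decision: numerically computed eigenvalues; the point is stable
#' iff all real parts are negative. A real part within the marginal band of
#' zero is flagged \code{marginal = TRUE} rather than silently classified.
#' As an independent cross-check, a Routh-Hurwitz test is run on the
#' characteristic polynomial (Faddeev-LeVerrier coefficients) for systems
#' up to \code{routh_max} states; larger characteristic polynomials are too
#' ill-conditioned in double precision for the array to be meaningful. A
#' disagreement between the two routes is reported in
#' \code{routh_agrees = FALSE} with a warning.
#'
#' @param jac square numeric Jacobian matrix.
#' @param marginal_band half-width of the band around zero (scaled by the
#'   spectral magnitude) within which a leading real part is flagged
#'   marginal.
#' @param routh_max largest dimension at which the Routh cross-check runs.
#' @return list with \code{stable}, \code{marginal}, \code{eigenvalues},
#'   \code{max_real}, \code{method_flags} (character), \code{routh_agrees}
#'   (logical or NA if not run).
#' @export
#' @examples
#' classifyStability(matrix(c(0, -1, 1, -0.1), 2, 2))$stable  # damped
classifyStability <- function(jac, marginal_band = 1e-8, routh_max = 12) {
  jac <- as.matrix(jac)
  if (nrow(jac) != ncol(jac) || !all(is.finite(jac))) {
    stop("jacobian must be a finite square matrix", call. = FALSE)
  }
  ev <- eigen(jac, only.values = TRUE)$values
  max_real <- max(Re(ev))
  scale <- max(abs(ev), 1)
  marginal <- abs(max_real) < marginal_band * scale
  stable <- max_real < 0
  flags <- "eigenvalue"
  routh_agrees <- NA
  if (nrow(jac) <= routh_max) {
    co <- charpoly_coefficients(jac)
    rt <- tryCatch(routhStable(co), error = function(e) NULL)
    if (!is.null(rt)) {
      flags <- c(flags, "routh")
      routh_agrees <- identical(rt$stable, stable)
      if (!marginal && !routh_agrees) {
        warning("Routh-Hurwitz cross-check disagrees with eigenvalue ",
                "classification (max Re = ", signif(max_real, 4), ")",
                call. = FALSE)
      }
    }
  }
  list(stable = stable, marginal = marginal, eigenvalues = ev,
       max_real = max_real, method_flags = flags, routh_agrees = routh_agrees)
}

#' Find equilibria of a circuit system by damped Newton-Raphson
#'
#' Solves \code{rhs(x) = 0} in reduced coordinates (conserved promoter
#' totals eliminated) from each initial guess, with symmetric-difference
#' Jacobians and step halving when the residual norm fails to decrease.
#' Converged roots are deduplicated by relative distance and classified by
#' [classifyStability()] on the reduced Jacobian; guesses that fail to
#' converge are reported, never silently dropped.
#'
#' @param system a \code{dualosc_system}.
#' @param initial_guesses list of full state vectors (e.g.
#'   [defaultInitialState()] or trajectory endpoints).
#' @param tol residual norm tolerance for convergence.
#' @param max_iter maximum Newton iterations per guess.
#' @param dedup_tol relative distance under which two roots are the same.
#' @return object of class \code{dualosc_equilibria}: list with
#'   \code{equilibria} (list of reports: point, residual_norm,
#'   eigenvalues, stable, marginal, method_flags) and \code{failed}
#'   (list of failed guesses with diagnostics).
#' @export
findEquilibria <- function(system, initial_guesses, tol = 1e-8,
                           max_iter = 100, dedup_tol = 1e-6) {
  stopifnot(inherits(system, "dualosc_system"))
  if (!is.list(initial_guesses) || length(initial_guesses) < 1L) {
    stop("at least one initial guess is required", call. = FALSE)
  }
  if (tol <= 0) stop("tol must be > 0", call. = FALSE)
  red <- reduce_system(system)
  roots <- list()
  failed <- list()
  for (gi in seq_along(initial_guesses)) {
    g <- initial_guesses[[gi]]
    if (length(g) != system$n) {
      failed[[length(failed) + 1]] <- list(guess = gi,
                                           reason = "wrong dimension")
      next
    }
    y <- unname(g[red$keep])
    ok <- FALSE
    reason <- "max iterations reached"
    for (it in seq_len(max_iter)) {
      r <- red$rhs(y)
      rn <- sqrt(sum(r^2))
      if (!is.finite(rn)) { reason <- "non-finite residual"; break }
      if (rn <= tol) { ok <- TRUE; break }
      J <- numericJacobian(red$rhs, y)
      step <- tryCatch(solve(J, -r), error = function(e) NULL)
      if (is.null(step)) { reason <- "singular Jacobian"; break }
      lam <- 1
      improved <- FALSE
      for (k in 1:30) {
        y2 <- y + lam * step
        r2 <- red$rhs(y2)
        rn2 <- sqrt(sum(r2^2))
        if (is.finite(rn2) && rn2 < rn) { y <- y2; improved <- TRUE; break }
        lam <- lam / 2
      }
      if (!improved) { reason <- "line search stalled"; break }
    }
    if (ok) {
      roots[[length(roots) + 1]] <- y
    } else {
      failed[[length(failed) + 1]] <- list(guess = gi, reason = reason)
    }
  }
  # deduplicate converged roots
  uniq <- list()
  for (y in roots) {
    dup <- FALSE
    for (u in uniq) {
      if (sqrt(sum((y - u)^2)) <= dedup_tol * (1 + sqrt(sum(u^2)))) {
        dup <- TRUE; break
      }
    }
    if (!dup) uniq[[length(uniq) + 1]] <- y
  }
  reports <- lapply(uniq, function(y) {
    full <- red$expand(y)
    r <- red$rhs(y)
    J <- numericJacobian(red$rhs, y)
    cls <- classifyStability(J)
    list(point = full, residual_norm = sqrt(sum(r^2)),
         eigenvalues = cls$eigenvalues, stable = cls$stable,
         marginal = cls$marginal, method_flags = cls$method_flags)
  })
  structure(list(equilibria = reports, failed = failed,
                 tol = tol, system_dim = system$n),
            class = "dualosc_equilibria")
}

#' @export
print.dualosc_equilibria <- function(x, ...) {
  cat(sprintf("<equilibrium report> %d equilibria (%d failed guesses)\n",
              length(x$equilibria), length(x$failed)))
  for (i in seq_along(x$equilibria)) {
    e <- x$equilibria[[i]]
    cat(sprintf("  [%d] %s%s, |rhs| = %.3g, max Re(eig) = %.3g\n", i,
                if (e$stable) "stable" else "unstable",
                if (e$marginal) " (marginal)" else "",
                e$residual_norm, max(Re(e$eigenvalues))))
  }
  invisible(x)
}

#' Write an equilibrium report to disk
#'
#' One tab-separated row per equilibrium (stability, residual norm,
#' leading eigenvalue real part, free-protein coordinates) plus a JSON
#' summary with counts, tolerances and failed guesses.
#'
#' @param eq a \code{dualosc_equilibria} object.
#' @param dir output directory (created if needed).
#' @return the directory, invisibly.
#' @export
writeEquilibriumReport <- function(eq, dir) {
  stopifnot(inherits(eq, "dualosc_equilibria"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.table(as.data.frame(eq), file.path(dir, "equilibria.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  jsonlite::write_json(
    list(n_equilibria = length(eq$equilibria),
         n_failed = length(eq$failed),
         tol = eq$tol,
         failed = eq$failed),
    file.path(dir, "summary.json"), auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Tabulate an equilibrium report
#'
#' One row per equilibrium: stability, residual norm, leading eigenvalue
#' real part, and the free-protein coordinates.
#'
#' @param x a \code{dualosc_equilibria} object.
#' @param ... unused.
#' @return data.frame.
#' @export
as.data.frame.dualosc_equilibria <- function(x, ...) {
  if (!length(x$equilibria)) {
    return(data.frame(stable = logical(0), marginal = logical(0),
                      residual_norm = numeric(0), max_real = numeric(0)))
  }
  do.call(rbind, lapply(x$equilibria, function(e) {
    pt <- e$point
    df <- data.frame(stable = e$stable, marginal = e$marginal,
                     residual_norm = e$residual_norm,
                     max_real = max(Re(e$eigenvalues)))
    for (nm in intersect(c("a", "l", "g"), names(pt))) df[[nm]] <- pt[[nm]]
    df
  }))
}
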