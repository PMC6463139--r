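#' Shared-protease degradation fluxes
#'
#' Degradation of the SsrA-tagged proteins by the limited ClpXP pool,
#' modelled as competitive Michaelis-Menten kinetics over the free protein
#' pools. With sharing on, AraC (a), LacI (l) and GFP (g) all queue for the
#' same protease: \code{flux_x = V_max * x / (K_M + a + l + g)}. With
#' sharing off, the circuit proteins a and l keep their shared denominator
#' (a + l) while GFP is degraded through an identical but independent
#' channel with its own denominator. The summed flux through a channel
#' never exceeds \code{V_max}.
#'
#' @param a,l,g free active AraC dimers, LacI tetramers, GFP monomers
#'   (molecules/cell; nonnegative).
#' @param params an [oscillatorParameters()] set (uses \code{V_max},
#'   \code{K_M}).
#' @param sharing_on logical: does GFP share the protease with a and l?
#' @return named numeric vector \code{c(a=, l=, g=)} of degradation rates
#'   (molecules/min).
#' @export
#' @examples
#' p <- oscillatorParameters()
#' degradationFlux(100, 0, 0, p, TRUE)  # single-substrate Michaelis-Menten
degradationFlux <- function(a, l, g, params, sharing_on = TRUE) {
  if (sharing_on) {
    den <- params$K_M + a + l + g
    c(a = params$V_max * a / den,
      l = params$V_max * l / den,
      g = params$V_max * g / den)
  } else {
    den_al <- params$K_M + a + l
    c(a = params$V_max * a / den_al,
      l = params$V_max * l / den_al,
      g = params$V_max * g / (params$K_M + g))
  }
}

# Promoter classes present in a circuit: class id, promoter kind, plasmid
# copy number, the gene it drives (NA for the decoy) and whether it is a
# downstream (reporter-side) class subject to the retroactivity toggle.
circuit_classes <- function(config) {
  cls <- list(
    list(id = "reg_act", kind = "lac_ara_regulatory",
         copies = config$n_activator_dna, gene = "araC", downstream = FALSE),
    list(id = "reg_rep", kind = "lac_ara_regulatory",
         copies = config$n_repressor_dna, gene = "lacI", downstream = FALSE)
  )
  if (config$reporter_kind == "lac_ara") {
    cls <- c(cls, list(list(id = "rep", kind = "lac_ara_reporter",
                            copies = config$n_activator_dna, gene = "gfp",
                            downstream = TRUE)))
  } else if (config$reporter_kind == "lac") {
    cls <- c(cls, list(list(id = "rep", kind = "lac_reporter",
                            copies = config$n_activator_dna, gene = "gfp",
                            downstream = TRUE)))
  } else if (config$reporter_kind == "lac_decoy") {
    cls <- c(cls, list(
      list(id = "rep", kind = "lac_reporter",
           copies = config$n_activator_dna, gene = "gfp", downstream = TRUE),
      list(id = "decoy", kind = "arac_decoy",
           copies = config$n_activator_dna, gene = NA, downstream = TRUE)
    ))
  }
  cls
}

#' Assemble the full deterministic ODE system of a circuit
#'
#' Builds the right-hand side of the master-equation/protein ODE system for
#' a circuit configuration under one inducer condition: promoter microstate
#' occupancy for every promoter class (weighted by plasmid copy number),
#' optional explicit mRNA stages, free-protein pools coupled to the binding
#' fluxes, shared-protease degradation and first-order dilution on proteins
#' and mRNA (not on DNA). The two competition toggles act only on
#' downstream terms: with \code{retroactivity_on = FALSE} the
#' reporter/decoy occupancies still evolve but exchange no molecules with
#' the free pools ("sense but do not consume"); with
#' \code{protease_sharing_on = FALSE} GFP leaves the shared ClpXP queue.
#'
#' @param config a [circuitConfig()].
#' @param params an [oscillatorParameters()] set.
#' @param condition an [inducerCondition()].
#' @param mrna logical: explicit mRNA stage (default) or lumped production
#'   at the quasi-steady mRNA level.
#' @return an object of class \code{dualosc_system} with elements
#'   \code{rhs(state)} (named derivative), \code{state_names}, \code{n},
#'   \code{classes} (index ranges and copy numbers per promoter class),
#'   \code{config}, \code{params}, \code{condition}.
#' @export
#' @examples
#' sys <- assembleOdes(circuitConfig("lac_ara"), oscillatorParameters(),
#'                     inducerCondition(1.0, 0.01))
#' sys$n
assembleOdes <- function(config, params, condition, mrna = TRUE) {
  stopifnot(inherits(config, "dualosc_config"))
  validate_parameters(params)
  if (!inherits(condition, "dualosc_condition")) {
    stop("condition must be an inducerCondition()", call. = FALSE)
  }
  fr <- activeFractions(condition, params)
  fa <- fr$arac
  fl <- fr$laci

  cls_def <- circuit_classes(config)
  compiled <- lapply(cls_def, function(cd) {
    cp <- compile_promoter(buildPromoterModel(cd$kind), params)
    cp$id <- cd$id; cp$copies <- cd$copies
    cp$gene <- cd$gene; cp$downstream <- cd$downstream
    cp
  })

  has_reporter <- config$reporter_kind != "none"
  genes <- c("araC", "lacI", if (has_reporter) "gfp")
  # state layout: promoter occupancies, then mRNA (optional), then proteins
  state_names <- character(0)
  class_index <- list()
  pos <- 0L
  for (cp in compiled) {
    idx <- pos + seq_len(cp$n)
    class_index[[cp$id]] <- idx
    state_names <- c(state_names, paste(cp$id, cp$states, sep = ":"))
    pos <- pos + cp$n
  }
  mrna_index <- NULL
  if (mrna) {
    mrna_index <- stats::setNames(pos + seq_along(genes), genes)
    state_names <- c(state_names, paste0("m_", genes))
    pos <- pos + length(genes)
  }
  prot <- c("a", "l", if (has_reporter) "g")
  prot_index <- stats::setNames(pos + seq_along(prot), prot)
  state_names <- c(state_names, prot)
  n <- pos + length(prot)

  sharing <- config$protease_sharing_on
  retro <- config$retroactivity_on
  V_max <- params$V_max; K_M <- params$K_M
  k_tl <- params$k_tl; delta_m <- params$delta_m; lambda <- params$lambda
  stoich <- c(araC = 2, lacI = 4, gfp = 1)  # monomers per functional unit

  rhs <- function(state) {
    if (length(state) != n) {
      stop("state has length ", length(state), " but system dimension is ", n,
           call. = FALSE)
    }
    d <- numeric(n)
    a <- state[[prot_index[["a"]]]]
    l <- state[[prot_index[["l"]]]]
    g <- if (has_reporter) state[[prot_index[["g"]]]] else 0

    da_ex <- 0; dl_ex <- 0
    tx <- c(araC = 0, lacI = 0, gfp = 0)
    for (cp in compiled) {
      idx <- class_index[[cp$id]]
      P <- state[idx]
      Q <- cp$Qfix + (fa * a) * cp$Qa + (fl * l) * cp$Ql
      d[idx] <- Q %*% P
      if (!cp$downstream || retro) {
        da_ex <- da_ex - fa * a * sum(cp$ca * P) + sum(cp$ra * P)
        dl_ex <- dl_ex - fl * l * sum(cp$cl * P) + sum(cp$rl * P)
      }
      if (!is.na(cp$gene)) tx[cp$gene] <- tx[cp$gene] + sum(cp$activity * P)
    }

    if (mrna) {
      prod <- numeric(0)
      for (gn in genes) {
        mi <- mrna_index[[gn]]
        d[mi] <- tx[[gn]] - (delta_m + lambda) * state[[mi]]
      }
      prod_a <- k_tl * state[[mrna_index[["araC"]]]] / stoich[["araC"]]
      prod_l <- k_tl * state[[mrna_index[["lacI"]]]] / stoich[["lacI"]]
      prod_g <- if (has_reporter) k_tl * state[[mrna_index[["gfp"]]]] else 0
    } else {
      mss <- tx / (delta_m + lambda)
      prod_a <- k_tl * mss[["araC"]] / stoich[["araC"]]
      prod_l <- k_tl * mss[["lacI"]] / stoich[["lacI"]]
      prod_g <- if (has_reporter) k_tl * mss[["gfp"]] else 0
    }

    if (sharing) {
      den <- K_M + a + l + g
      deg_a <- V_max * a / den
      deg_l <- V_max * l / den
      deg_g <- V_max * g / den
    } else {
      den <- K_M + a + l
      deg_a <- V_max * a / den
      deg_l <- V_max * l / den
      deg_g <- V_max * g / (K_M + g)
    }

    d[prot_index[["a"]]] <- prod_a + da_ex - deg_a - lambda * a
    d[prot_index[["l"]]] <- prod_l + dl_ex - deg_l - lambda * l
    if (has_reporter) {
      d[prot_index[["g"]]] <- prod_g - deg_g - lambda * g
    }
    names(d) <- state_names
    d
  }

  structure(
    list(rhs = rhs, state_names = state_names, n = n,
         classes = lapply(compiled, function(cp) {
           list(id = cp$id, kind = NULL, index = class_index[[cp$id]],
                copies = cp$copies, unbound = class_index[[cp$id]][cp$unbound],
                activity = cp$activity, gene = cp$gene,
                downstream = cp$downstream)
         }),
         mrna_index = mrna_index, prot_index = prot_index,
         config = config, params = params, condition = condition,
         mrna = mrna),
    class = "dualosc_system"
  )
}

#' @export
print.dualosc_system <- function(x, ...) {
  cat(sprintf("<dualosc ODE system> %d states (%s reporter, retro %s, sharing %s)\n",
              x$n, x$config$reporter_kind,
              if (x$config$retroactivity_on) "on" else "off",
              if (x$config$protease_sharing_on) "on" else "off"))
  cat(sprintf("  condition: arabinose %g %%, IPTG %g mM\n",
              x$condition$arabinose, x$condition$iptg))
  invisible(x)
}

#' Default initial state for a circuit system
#'
#' All promoter copies start fully unbound, small seed pools of the free
#' proteins, and zero mRNA/GFP.
#'
#' @param system a \code{dualosc_system}.
#' @param a0,l0 initial free AraC / LacI pools (molecules/cell).
#' @return named numeric state vector.
#' @export
defaultInitialState <- function(system, a0 = 10, l0 = 10) {
  s <- stats::setNames(numeric(system$n), system$state_names)
  for (cl in system$classes) s[cl$unbound] <- cl$copies
  s[system$prot_index[["a"]]] <- a0
  s[system$prot_index[["l"]]] <- l0
  s
}

# Reduced coordinates for equilibrium/stability work: the conserved total
# occupancy of each promoter class makes the full Jacobian structurally
# singular, so the fully-unbound state of every class is eliminated and
# reconstructed as copies - sum(other states).
reduce_system <- function(system) {
  drop_idx <- vapply(system$classes, function(cl) cl$unbound, numeric(1))
  keep <- setdiff(seq_len(system$n), drop_idx)
  expand <- function(yred) {
    s <- numeric(system$n)
    s[keep] <- yred
    for (cl in system$classes) {
      others <- setdiff(cl$index, cl$unbound)
      s[cl$unbound] <- cl$copies - sum(s[others])
    }
    names(s) <- system$state_names
    s
  }
  rhs_red <- function(yred) {
    d <- system$rhs(expand(yred))
    unname(d[keep])
  }
  list(rhs = rhs_red, expand = expand, keep = keep, drop = drop_idx,
       n = length(keep), names = system$state_names[keep])
}
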