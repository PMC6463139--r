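#' Circuit configuration: reporter variant and competition toggles
#'
#' The upstream regulatory core is always the same dual-feedback (Smolen)
#' oscillator: \emph{araC} and \emph{lacI} each transcribed from a lac/ara
#' promoter (one AraC site, two lac operators) on their respective plasmids.
#' The downstream reporter gene varies:
#' \describe{
#'   \item{none}{no reporter; the bare oscillator.}
#'   \item{lac_ara}{GFP from a lac/ara promoter (one AraC site + two
#'     operators) on the activator plasmid.}
#'   \item{lac}{GFP from a lac promoter (two operators, no AraC site).}
#'   \item{lac_decoy}{GFP from a lac promoter plus a transcriptionally
#'     inert AraC decoy site, equalising total binding-site counts with the
#'     lac/ara reporter.}
#' }
#' Two competitions from the downstream gene back onto the core can be
#' toggled independently:
#' \describe{
#'   \item{retroactivity_on}{downstream binding sites sequester free
#'     regulatory proteins. When off, downstream occupancy still evolves
#'     (it senses the free pools) but exchanges no molecules with them.}
#'   \item{protease_sharing_on}{GFP competes with AraC and LacI for the
#'     shared ClpXP pool. When off, GFP is degraded through an identical
#'     but independent channel.}
#' }
#'
#' @param reporter_kind one of \code{"none"}, \code{"lac_ara"},
#'   \code{"lac"}, \code{"lac_decoy"}.
#' @param retroactivity_on logical toggle for binding-site titration.
#' @param protease_sharing_on logical toggle for shared degradation.
#' @param n_activator_dna copies/cell of the activator (araC + reporter)
#'   plasmid.
#' @param n_repressor_dna copies/cell of the repressor (lacI) plasmid.
#' @return an object of class \code{dualosc_config}.
#' @export
#' @examples
#' circuitConfig("lac", retroactivity_on = FALSE)
circuitConfig <- function(reporter_kind = c("lac_ara", "lac", "lac_decoy", "none"),
                          retroactivity_on = TRUE,
                          protease_sharing_on = TRUE,
                          n_activator_dna = 50,
                          n_repressor_dna = 25) {
  reporter_kind <- match.arg(reporter_kind)
  stopifnot(is.logical(retroactivity_on), length(retroactivity_on) == 1L,
            is.logical(protease_sharing_on), length(protease_sharing_on) == 1L)
  for (nm in c("n_activator_dna", "n_repressor_dna")) {
    v <- get(nm)
    if (length(v) != 1L || !is.finite(v) || v <= 0 || v != round(v)) {
      stop(nm, " must be a positive integer (plasmid copies/cell)",
           call. = FALSE)
    }
  }
  structure(
    list(reporter_kind = reporter_kind,
         retroactivity_on = isTRUE(retroactivity_on),
         protease_sharing_on = isTRUE(protease_sharing_on),
         n_activator_dna = as.integer(n_activator_dna),
         n_repressor_dna = as.integer(n_repressor_dna)),
    class = "dualosc_config"
  )
}

#' @export
print.dualosc_config <- function(x, ...) {
  cat("<dualosc circuit config>\n")
  cat("  reporter:            ", x$reporter_kind, "\n")
  cat("  retroactivity:       ", if (x$retroactivity_on) "on" else "off", "\n")
  cat("  protease sharing:    ", if (x$protease_sharing_on) "on" else "off", "\n")
  cat("  activator plasmid:   ", x$n_activator_dna, "copies/cell\n")
  cat("  repressor plasmid:   ", x$n_repressor_dna, "copies/cell\n")
  invisible(x)
}

# LacI occupancy patterns of a two-operator promoter. A single tetramer
# forms the DNA loop (L); two independently bound tetramers give B.
laci_patterns <- function() c("E", "O1", "O2", "B", "L")

laci_pattern_info <- function() {
  data.frame(
    pattern = laci_patterns(),
    bound_tetramers = c(0L, 1L, 1L, 2L, 1L),
    free_operators = c(2L, 1L, 1L, 0L, 0L),
    repressed = c(FALSE, TRUE, TRUE, TRUE, TRUE),
    stringsAsFactors = FALSE
  )
}

# Transitions among LacI patterns. `protein` names the free pool consumed
# ("l") by a transition; `releases` the pool replenished. Loop formation and
# opening move the already-bound tetramer without touching the free pool;
# full loop dissociation (k_loop_diss) releases it. Loop opening returns to
# either singly-bound pattern with an even split so the total opening rate
# is k_unloop.
laci_transitions <- function() {
  tr <- function(from, to, rate, mult = 1, protein = NA, releases = NA) {
    data.frame(from = from, to = to, rate_param = rate, mult = mult,
               protein = protein, releases = releases,
               stringsAsFactors = FALSE)
  }
  rbind(
    tr("E",  "O1", "kr_on", 1, protein = "l"),
    tr("E",  "O2", "kr_on", 1, protein = "l"),
    tr("O1", "E",  "kr_off", 1, releases = "l"),
    tr("O2", "E",  "kr_off", 1, releases = "l"),
    tr("O1", "B",  "kr_on", 1, protein = "l"),
    tr("O2", "B",  "kr_on", 1, protein = "l"),
    tr("B",  "O1", "kr_off", 1, releases = "l"),
    tr("B",  "O2", "kr_off", 1, releases = "l"),
    tr("O1", "L",  "k_loop", 1),
    tr("O2", "L",  "k_loop", 1),
    tr("L",  "O1", "k_unloop", 0.5),
    tr("L",  "O2", "k_unloop", 0.5),
    tr("L",  "E",  "k_loop_diss", 1, releases = "l")
  )
}

arac_transitions <- function() {
  data.frame(
    from = c("U", "A"), to = c("A", "U"),
    rate_param = c("ka_on", "ka_off"), mult = 1,
    protein = c("a", NA), releases = c(NA, "a"),
    stringsAsFactors = FALSE
  )
}

#' Enumerate the microstates and transitions of one promoter class
#'
#' Builds the full occupancy model of a single DNA copy of the given
#' promoter class: every combination of AraC-site occupancy (where a site
#' exists) and LacI-operator pattern, the transition-rate templates between
#' them (referencing parameter-set field names), and the per-state
#' transcription activity class. Active transcription requires a bound AraC
#' site (where one exists) and no LacI bound; the unbound, unrepressed
#' state of a lac/ara promoter transcribes at the basal rate; any
#' LacI-occupied state is silent. The lac promoter needs no activator: its
#' empty state transcribes at its maximum rate.
#'
#' @param promoter_kind one of \code{"lac_ara_regulatory"},
#'   \code{"lac_ara_reporter"}, \code{"lac_reporter"}, \code{"arac_decoy"}.
#' @return an object of class \code{dualosc_promoter} with elements
#'   \code{kind}, \code{states} (data.frame: name, arac_bound,
#'   laci_bound, free_arac_sites, free_operators, activity_param),
#'   and \code{transitions} (data.frame: from, to, rate_param, mult,
#'   protein, releases).
#' @export
#' @examples
#' pm <- buildPromoterModel("lac_ara_regulatory")
#' nrow(pm$states)  # 10 microstates: 2 AraC x 5 LacI patterns
buildPromoterModel <- function(promoter_kind) {
  kinds <- c("lac_ara_regulatory", "lac_ara_reporter", "lac_reporter",
             "arac_decoy")
  if (length(promoter_kind) != 1L || !promoter_kind %in% kinds) {
    stop("unknown promoter_kind: ", paste(promoter_kind, collapse = ", "),
         "; expected one of ", paste(kinds, collapse = ", "), call. = FALSE)
  }
  has_arac <- promoter_kind %in% c("lac_ara_regulatory", "lac_ara_reporter",
                                   "arac_decoy")
  has_laci <- promoter_kind != "arac_decoy"
  li <- laci_pattern_info()

  if (has_arac && has_laci) {
    grid <- expand.grid(arac = c("U", "A"), pattern = li$pattern,
                        stringsAsFactors = FALSE)
    states <- data.frame(
      name = paste(grid$arac, grid$pattern, sep = "."),
      arac_bound = as.integer(grid$arac == "A"),
      laci_bound = li$bound_tetramers[match(grid$pattern, li$pattern)],
      free_arac_sites = as.integer(grid$arac == "U"),
      free_operators = li$free_operators[match(grid$pattern, li$pattern)],
      stringsAsFactors = FALSE
    )
    repressed <- li$repressed[match(grid$pattern, li$pattern)]
    max_param <- if (promoter_kind == "lac_ara_regulatory") "tx_active" else "tx_rep_lacara"
    states$activity_param <- ifelse(repressed, "zero",
                                    ifelse(grid$arac == "A", max_param, "tx_basal"))
    # LacI transitions replicated at each AraC level; AraC transitions at
    # each LacI pattern.
    tl <- laci_transitions()
    ta <- arac_transitions()
    trans <- rbind(
      do.call(rbind, lapply(c("U", "A"), function(alev) {
        data.frame(from = paste(alev, tl$from, sep = "."),
                   to = paste(alev, tl$to, sep = "."),
                   rate_param = tl$rate_param, mult = tl$mult,
                   protein = tl$protein, releases = tl$releases,
                   stringsAsFactors = FALSE)
      })),
      do.call(rbind, lapply(li$pattern, function(pat) {
        data.frame(from = paste(ta$from, pat, sep = "."),
                   to = paste(ta$to, pat, sep = "."),
                   rate_param = ta$rate_param, mult = ta$mult,
                   protein = ta$protein, releases = ta$releases,
                   stringsAsFactors = FALSE)
      }))
    )
  } else if (has_laci) {
    states <- data.frame(
      name = li$pattern,
      arac_bound = 0L,
      laci_bound = li$bound_tetramers,
      free_arac_sites = 0L,
      free_operators = li$free_operators,
      stringsAsFactors = FALSE
    )
    states$activity_param <- ifelse(li$repressed, "zero", "tx_rep_lac")
    trans <- laci_transitions()
  } else {
    states <- data.frame(
      name = c("U", "A"),
      arac_bound = c(0L, 1L),
      laci_bound = 0L,
      free_arac_sites = c(1L, 0L),
      free_operators = 0L,
      activity_param = "zero",
      stringsAsFactors = FALSE
    )
    trans <- arac_transitions()
  }

  pm <- structure(list(kind = promoter_kind, states = states,
                       transitions = trans),
                  class = "dualosc_promoter")
  check_promoter_model(pm)
  pm
}

# Structural validity: transition endpoints exist, exactly one fully
# unbound state, and the transition graph is strongly connected.
check_promoter_model <- function(pm) {
  st <- pm$states$name
  if (!all(pm$transitions$from %in% st) || !all(pm$transitions$to %in% st)) {
    stop("transition references an unknown state", call. = FALSE)
  }
  unbound <- pm$states$arac_bound == 0 & pm$states$laci_bound == 0
  if (sum(unbound) != 1L) {
    stop("promoter model must have exactly one fully-unbound state",
         call. = FALSE)
  }
  n <- length(st)
  adj <- matrix(FALSE, n, n, dimnames = list(st, st))
  adj[cbind(pm$transitions$from, pm$transitions$to)] <- TRUE
  reach <- function(A) {
    R <- A | diag(TRUE, n)
    for (k in seq_len(n)) R <- R | (R %*% R > 0)
    R
  }
  if (!all(reach(adj))) {
    stop("promoter transition graph is not strongly connected", call. = FALSE)
  }
  invisible(pm)
}

#' @export
print.dualosc_promoter <- function(x, ...) {
  cat(sprintf("<promoter model> %s: %d microstates, %d transitions\n",
              x$kind, nrow(x$states), nrow(x$transitions)))
  invisible(x)
}

# Compile a promoter model against a numeric parameter set into the
# matrices used by the assembled RHS. The occupancy master equation of one
# class is dP = (Qfix + fa*a*Qa + fl*l*Ql) P, where Qa/Ql carry the
# per-molecule on-rates of protein-consuming transitions and Qfix all
# protein-independent rates. ca/cl give per-state free-pool consumption
# coefficients (flux = fa*a*sum(ca*P)); ra/rl per-state release rates.
compile_promoter <- function(pm, params) {
  st <- pm$states$name
  n <- length(st)
  Qfix <- Qa <- Ql <- matrix(0, n, n, dimnames = list(st, st))
  ca <- cl <- ra <- rl <- stats::setNames(numeric(n), st)
  for (i in seq_len(nrow(pm$transitions))) {
    trn <- pm$transitions[i, ]
    rate <- params[[trn$rate_param]] * trn$mult
    f <- trn$from; t2 <- trn$to
    tgt <- if (is.na(trn$protein)) NULL else trn$protein
    if (is.null(tgt)) {
      Qfix[t2, f] <- Qfix[t2, f] + rate
      Qfix[f, f] <- Qfix[f, f] - rate
    } else if (tgt == "a") {
      Qa[t2, f] <- Qa[t2, f] + rate
      Qa[f, f] <- Qa[f, f] - rate
      ca[f] <- ca[f] + rate
    } else {
      Ql[t2, f] <- Ql[t2, f] + rate
      Ql[f, f] <- Ql[f, f] - rate
      cl[f] <- cl[f] + rate
    }
    if (!is.na(trn$releases)) {
      if (trn$releases == "a") ra[f] <- ra[f] + rate
      else rl[f] <- rl[f] + rate
    }
  }
  act_map <- c(zero = 0, tx_active = params$tx_active,
               tx_basal = params$tx_basal,
               tx_rep_lacara = params$tx_rep_lacara,
               tx_rep_lac = params$tx_rep_lac)
  activity <- unname(act_map[pm$states$activity_param])
  list(states = st, n = n, Qfix = Qfix, Qa = Qa, Ql = Ql,
       ca = ca, cl = cl, ra = ra, rl = rl, activity = activity,
       unbound = which(pm$states$arac_bound == 0 & pm$states$laci_bound == 0))
}
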