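# shared helpers for the dualosc test suite

default_params <- oscillatorParameters()

# a trajectory object wrapped around an analytic signal
analytic_trajectory <- function(times, values_list, condition = NULL) {
  vals <- do.call(cbind, values_list)
  colnames(vals) <- names(values_list)
  structure(list(times = times, values = vals,
                 metadata = list(condition = condition)),
            class = "dualosc_trajectory")
}

# perturb a state without breaking promoter-copy conservation: only the
# mRNA/protein coordinates move
perturb_offmanifold_free <- function(system, state, factor = 1.5, add = 1) {
  idx <- c(system$mrna_index, system$prot_index)
  state[idx] <- state[idx] * factor + add
  state
}

make_system <- function(reporter = "lac_ara", ara = 1.0, iptg = 0.01,
                        retro = TRUE, share = TRUE, params = default_params,
                        mrna = TRUE) {
  assembleOdes(circuitConfig(reporter, retroactivity_on = retro,
                             protease_sharing_on = share),
               params, inducerCondition(ara, iptg), mrna = mrna)
}

random_valid_state <- function(system, scale = 50) {
  s <- defaultInitialState(system)
  # random occupancy split within each promoter class, preserving the total
  for (cl in system$classes) {
    w <- stats::runif(length(cl$index))
    s[cl$index] <- cl$copies * w / sum(w)
  }
  idx <- c(system$mrna_index, system$prot_index)
  s[idx] <- stats::runif(length(idx), 0, scale)
  s
}
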