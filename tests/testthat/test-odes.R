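test_that("shared-protease fluxes follow competitive Michaelis-Menten", {
  p <- oscillatorParameters()
  # degenerate pool: single-substrate MM
  f <- degradationFlux(100, 0, 0, p, sharing_on = TRUE)
  expect_equal(f[["a"]], p$V_max * 100 / (p$K_M + 100))
  expect_equal(f[["l"]], 0); expect_equal(f[["g"]], 0)
  # doubling g strictly decreases the flux on a
  f1 <- degradationFlux(50, 20, 100, p, TRUE)
  f2 <- degradationFlux(50, 20, 200, p, TRUE)
  expect_lt(f2[["a"]], f1[["a"]])
  # total shared flux bounded by V_max
  expect_lte(sum(f1), p$V_max)
  expect_equal(sum(f1), p$V_max * 170 / (p$K_M + 170))
  # sharing off: a and l keep a shared denominator, g independent
  g_off <- degradationFlux(50, 20, 1e6, p, FALSE)
  g_on <- degradationFlux(50, 20, 1e6, p, TRUE)
  expect_equal(g_off[["a"]], p$V_max * 50 / (p$K_M + 70))
  expect_gt(g_off[["a"]], g_on[["a"]])  # g no longer steals capacity
  expect_equal(g_off[["g"]], p$V_max * 1e6 / (p$K_M + 1e6))
})

test_that("promoter-copy totals are conserved by the assembled RHS", {
  set.seed(101)
  for (rep_kind in c("none", "lac_ara", "lac", "lac_decoy")) {
    sys <- make_system(rep_kind)
    for (k in 1:5) {
      s <- random_valid_state(sys)
      d <- sys$rhs(s)
      for (cl in sys$classes) {
        expect_lt(abs(sum(d[cl$index])), 1e-10)
      }
    }
  }
})

test_that("with production and protease off, proteins decay as exp(-lambda t)", {
  p <- oscillatorParameters(tx_active = 0, tx_basal = 0, tx_rep_lacara = 0,
                            tx_rep_lac = 0, V_max = 0, ka_on = 0, kr_on = 0)
  sys <- assembleOdes(circuitConfig("lac_ara"), p, inducerCondition(1, 0.01))
  s0 <- defaultInitialState(sys, a0 = 100, l0 = 80)
  s0[sys$prot_index[["g"]]] <- 50
  traj <- integrateOdes(sys, initial = s0, t_end = 60, dt = 1,
                        rtol = 1e-10, atol = 1e-10)
  for (sp in c("a", "l", "g")) {
    expect_equal(traj$values[, sp],
                 s0[[sys$prot_index[[sp]]]] * exp(-p$lambda * traj$times),
                 tolerance = 1e-6)
  }
})

test_that("with no reporter, the competition toggles do not touch the RHS", {
  set.seed(7)
  sys_ref <- make_system("none", retro = TRUE, share = TRUE)
  sys_a <- make_system("none", retro = FALSE, share = TRUE)
  sys_b <- make_system("none", retro = TRUE, share = FALSE)
  for (k in 1:5) {
    s <- random_valid_state(sys_ref)
    d <- sys_ref$rhs(s)
    expect_identical(d, sys_a$rhs(s))
    expect_identical(d, sys_b$rhs(s))
  }
})

test_that("toggles act only on downstream terms", {
  set.seed(13)
  sys_on <- make_system("lac_decoy", retro = TRUE, share = TRUE)
  sys_noretro <- make_system("lac_decoy", retro = FALSE, share = TRUE)
  sys_noshare <- make_system("lac_decoy", retro = TRUE, share = FALSE)
  up_idx <- unlist(lapply(Filter(function(cl) !cl$downstream, sys_on$classes),
                          function(cl) cl$index))
  down_idx <- unlist(lapply(Filter(function(cl) cl$downstream, sys_on$classes),
                            function(cl) cl$index))
  for (k in 1:5) {
    s <- random_valid_state(sys_on)
    d_on <- sys_on$rhs(s)
    d_nr <- sys_noretro$rhs(s)
    # retroactivity off: occupancy dynamics identical everywhere (sense,
    # don't consume); only the free a/l balance terms change
    expect_identical(d_on[up_idx], d_nr[up_idx])
    expect_identical(d_on[down_idx], d_nr[down_idx])
    expect_identical(d_on[sys_on$prot_index[["g"]]],
                     d_nr[sys_on$prot_index[["g"]]])
    expect_false(isTRUE(all.equal(d_on[sys_on$prot_index[["a"]]],
                                  d_nr[sys_on$prot_index[["a"]]])))
    # sharing off: only the degradation terms of a, l, g change
    d_ns <- sys_noshare$rhs(s)
    expect_identical(d_on[c(up_idx, down_idx)], d_ns[c(up_idx, down_idx)])
    expect_identical(d_on[sys_on$mrna_index], d_ns[sys_on$mrna_index])
    expect_false(isTRUE(all.equal(d_on[sys_on$prot_index[["g"]]],
                                  d_ns[sys_on$prot_index[["g"]]])))
  }
})

test_that("downstream occupancy still senses the pools when titration is off", {
  sys <- make_system("lac", retro = FALSE)
  s <- defaultInitialState(sys, a0 = 20, l0 = 40)
  d <- sys$rhs(s)
  rep_idx <- Filter(function(cl) cl$downstream, sys$classes)[[1]]$index
  expect_gt(max(abs(d[rep_idx])), 0)  # occupancy evolves
})

test_that("reporter_kind none omits all reporter state variables", {
  sys <- make_system("none")
  expect_false("g" %in% sys$state_names)
  expect_false("m_gfp" %in% sys$state_names)
  expect_equal(length(sys$classes), 2L)
})

test_that("trajectories from nonnegative starts stay nonnegative", {
  set.seed(23)
  for (rep_kind in c("lac_ara", "lac_decoy")) {
    sys <- make_system(rep_kind, ara = 0.5, iptg = 0.1)
    traj <- integrateOdes(sys, t_end = 300, dt = 1, rtol = 1e-8, atol = 1e-8)
    expect_gt(min(traj$values), -1e-6)
  }
})

test_that("lumped production mode drops the mRNA stage but keeps structure", {
  sys <- make_system("lac_ara", mrna = FALSE)
  expect_false(any(grepl("^m_", sys$state_names)))
  s <- random_valid_state(sys)
  d <- sys$rhs(s)
  for (cl in sys$classes) expect_lt(abs(sum(d[cl$index])), 1e-10)
})

test_that("dimension mismatch is rejected", {
  sys <- make_system("lac")
  expect_error(sys$rhs(rep(1, sys$n + 1)), "dimension")
})
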