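test_that("a pure sinusoid is scored with its amplitude and period", {
  t <- seq(0, 400, by = 0.5)
  traj <- analytic_trajectory(t, list(x = 50 + 10 * sin(2 * pi * t / 40)))
  m <- oscillationMetrics(traj, species = "x")
  r <- m$species$x
  expect_equal(r$classification, "oscillatory")
  expect_equal(r$amplitude, 20, tolerance = 0.01)
  expect_equal(r$period, 40, tolerance = 0.02)
})

test_that("constant and strongly damped signals are classified fixed", {
  t <- seq(0, 400, by = 0.5)
  flat <- analytic_trajectory(t, list(x = rep(25, length(t))))
  m <- oscillationMetrics(flat, species = "x")
  expect_equal(m$species$x$classification, "fixed")
  expect_equal(m$species$x$amplitude, 0)
  # envelope decays below the 1-molecule threshold before the window
  damped <- analytic_trajectory(t,
    list(x = 50 + 40 * exp(-0.05 * t) * sin(2 * pi * t / 40)))
  md <- oscillationMetrics(damped, species = "x")
  expect_equal(md$species$x$classification, "fixed")
})

test_that("sub-molecule swings are not called oscillations", {
  t <- seq(0, 400, by = 0.5)
  tiny <- analytic_trajectory(t, list(x = 5 + 0.4 * sin(2 * pi * t / 40)))
  expect_equal(oscillationMetrics(tiny, species = "x")$species$x$classification,
               "fixed")
})

test_that("metrics are invariant to the sampling interval", {
  for (dt in c(0.5, 1, 2)) {
    t <- seq(0, 400, by = dt)
    traj <- analytic_trajectory(t, list(x = 50 + 30 * sin(2 * pi * t / 35)))
    r <- oscillationMetrics(traj, species = "x")$species$x
    expect_equal(r$period, 35, tolerance = 2 * dt / 35)
    expect_equal(r$amplitude, 60, tolerance = 0.05)
  }
})

test_that("integration reproduces pure dilution decay to 1e-6 relative", {
  p <- oscillatorParameters(tx_active = 0, tx_basal = 0, tx_rep_lacara = 0,
                            tx_rep_lac = 0, V_max = 0, ka_on = 0, kr_on = 0)
  sys <- assembleOdes(circuitConfig("none"), p, inducerCondition(0, 0))
  s0 <- defaultInitialState(sys, a0 = 1000, l0 = 500)
  traj <- integrateOdes(sys, initial = s0, t_end = 50, dt = 0.5,
                        rtol = 1e-10, atol = 1e-10)
  expect_equal(traj$values[, "a"] / (1000 * exp(-p$lambda * traj$times)),
               rep(1, length(traj$times)), tolerance = 1e-6)
})

test_that("halving solver tolerances leaves the endpoint unchanged", {
  sys <- make_system("lac", ara = 0.3, iptg = 0.1)
  t1 <- integrateOdes(sys, t_end = 200, dt = 1, rtol = 1e-6, atol = 1e-6)
  t2 <- integrateOdes(sys, t_end = 200, dt = 1, rtol = 5e-7, atol = 5e-7)
  end1 <- t1$values[nrow(t1$values), ]
  end2 <- t2$values[nrow(t2$values), ]
  expect_lt(max(abs(end1 - end2)) / (1 + max(abs(end1))), 1e-3)
})

test_that("promoter-class occupancy sums stay at the copy number along a trajectory", {
  sys <- make_system("lac_decoy", ara = 1.0, iptg = 0.01)
  traj <- integrateOdes(sys, t_end = 300, dt = 1, rtol = 1e-8, atol = 1e-8)
  for (cl in sys$classes) {
    sums <- rowSums(traj$values[, cl$index, drop = FALSE])
    expect_equal(sums, rep(cl$copies, length(sums)), tolerance = 1e-6)
  }
})

test_that("trajectory metadata records solver settings and writes wide tables", {
  sys <- make_system("none", ara = 0.01, iptg = 0.001)
  traj <- integrateOdes(sys, t_end = 30, dt = 3)
  expect_equal(traj$metadata$solver$dt, 3)
  expect_equal(traj$metadata$solver$method, "lsoda")
  tmp <- tempfile(fileext = ".tsv")
  writeTrajectory(traj, tmp)
  back <- utils::read.table(tmp, header = TRUE, sep = "\t",
                            check.names = FALSE)
  expect_equal(nrow(back), length(traj$times))
  expect_equal(back$a, unname(traj$values[, "a"]))
  mfile <- tempfile(fileext = ".json")
  writeOscillationMetrics(oscillationMetrics(traj), mfile)
  summ <- jsonlite::read_json(mfile)
  expect_equal(summ$settings$amp_threshold, 1)
  expect_true(summ$classification %in% c("fixed", "oscillatory"))
})

test_that("without competition the three reporter circuits share the period but not GFP level", {
  # high arabinose, low IPTG; both competitions disabled
  res <- lapply(c("lac_ara", "lac", "lac_decoy"), function(k) {
    sys <- make_system(k, ara = 1.0, iptg = 0.01, retro = FALSE,
                       share = FALSE)
    traj <- integrateOdes(sys, t_end = 600, dt = 1, rtol = 1e-6, atol = 1e-6)
    m <- oscillationMetrics(traj, species = c("l", "g"))
    gmean <- mean(traj$values[traj$times >= 300, "g"])
    list(period = m$species$l$period, class = m$species$l$classification,
         gmean = gmean)
  })
  names(res) <- c("lac_ara", "lac", "lac_decoy")
  for (r in res) expect_equal(r$class, "oscillatory")
  periods <- vapply(res, `[[`, numeric(1), "period")
  expect_lt(diff(range(periods)) / mean(periods), 0.02)
  # the lac promoter needs no activator: its GFP expression level is higher
  expect_gt(res$lac$gmean, res$lac_ara$gmean)
  expect_gt(res$lac_decoy$gmean, res$lac_ara$gmean)
})
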