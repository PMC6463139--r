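test_that("the default microscopy emulation yields 61 samples", {
  tr <- generateTrace(traceGenSpec(seed = 2))
  expect_length(tr$times, 61)  # 180 / 3 + 1
  expect_equal(tr$interval, 3)
  expect_equal(tr$source, "synthetic")
})

test_that("generation is deterministic per seed and distinct across seeds", {
  s <- traceGenSpec(seed = 11)
  t1 <- generateTrace(s); t2 <- generateTrace(s)
  expect_identical(t1$intensity, t2$intensity)
  t3 <- generateTrace(traceGenSpec(seed = 12))
  expect_false(identical(t1$intensity, t3$intensity))
  # generation must not disturb the caller's RNG stream
  set.seed(99); before <- rnorm(1)
  set.seed(99); invisible(generateTrace(s)); after <- rnorm(1)
  expect_identical(before, after)
})

test_that("noise-free sinusoid bottoms are recovered exactly by the scorer", {
  spec <- traceGenSpec(noise_scale = 0, damping = 0, drift = 0, period = 40)
  tr <- generateTrace(spec)
  bottoms <- detectBottoms(tr, smooth_window = 1)
  expect_equal(tr$times[bottoms], c(30, 70, 110, 150), tolerance = 0.05)
  # period-consistent count: floor(duration/period) +- 1
  spec2 <- traceGenSpec(noise_scale = 0, period = 30)
  n2 <- length(detectBottoms(generateTrace(spec2), smooth_window = 1))
  expect_lte(abs(n2 - floor(180 / 30)), 1)
})

test_that("nonpositive noise-free intensity is rejected", {
  expect_error(generateTrace(traceGenSpec(baseline = 10, amplitude = 50)),
               "nonpositive")
  expect_error(traceGenSpec(duration = -1), "positive")
  expect_error(traceGenSpec(noise_scale = -0.1), ">= 0")
})

test_that("panels cover the grid deterministically with per-cell regimes", {
  g <- gridSpec(ara_n = 2, iptg_n = 2, ara_min = 0.01, ara_max = 1,
                iptg_min = 0.001, iptg_max = 31.6)
  panel <- generatePanel(g, defaultRegimeMap(), n_traces_per_cell = 3,
                         seed = 5)
  expect_length(panel, 12)
  panel2 <- generatePanel(g, defaultRegimeMap(), n_traces_per_cell = 3,
                          seed = 5)
  expect_identical(lapply(panel, `[[`, "intensity"),
                   lapply(panel2, `[[`, "intensity"))
  expect_error(generatePanel(g, defaultRegimeMap(), n_traces_per_cell = 0),
               ">= 1")
})

test_that("constitutive panels score near 0 and sustained panels near 1", {
  g <- gridSpec(ara_n = 2, iptg_n = 2)
  flat_map <- function(ara, iptg) traceGenSpec(amplitude = 0)
  osc_map <- function(ara, iptg) traceGenSpec(amplitude = 30, period = 40)
  score_panel <- function(map) {
    panel <- generatePanel(g, map, n_traces_per_cell = 10, seed = 21)
    key <- vapply(panel, function(tr)
      sprintf("%g|%g", tr$condition$arabinose, tr$condition$iptg),
      character(1))
    mean(vapply(split(panel, key), function(trs)
      scoreCondition(trs)$relative_bottom_count, numeric(1)))
  }
  expect_lt(score_panel(flat_map), 0.05)
  expect_gt(score_panel(osc_map), 0.95)
})

test_that("model-derived traces bridge simulation to scoring", {
  sys <- make_system("lac_ara", ara = 1.0, iptg = 0.01)
  traj <- integrateOdes(sys, t_end = 500, dt = 1, rtol = 1e-6, atol = 1e-6)
  # zero noise, n = 1: the trace equals the resampled GFP trajectory
  tr <- tracesFromModel(traj, noise_scale = 0, n = 1, seed = 1)[[1]]
  t_abs <- tr$times + (max(traj$times) - 180)
  expect_equal(tr$intensity,
               stats::approx(traj$times, traj$values[, "g"], xout = t_abs)$y,
               tolerance = 1e-10)
  # the oscillatory trajectory yields >= 3 bottoms at zero noise
  expect_gte(length(detectBottoms(tr)), 3)
  # a fixed-point trajectory yields none
  sys_fix <- make_system("lac_ara", ara = 0.01, iptg = 0.001)
  traj_fix <- integrateOdes(sys_fix, t_end = 500, dt = 1,
                            rtol = 1e-6, atol = 1e-6)
  tr_fix <- tracesFromModel(traj_fix, noise_scale = 0, n = 1, seed = 1)[[1]]
  expect_length(detectBottoms(tr_fix), 0)
  # too-short trajectories are rejected
  short <- integrateOdes(sys, t_end = 100, dt = 1, rtol = 1e-6, atol = 1e-6)
  expect_error(tracesFromModel(short), "shorter than the sampling window")
})

test_that("relative bottom count decreases with the damping rate", {
  rbc_at <- function(damping) {
    traces <- lapply(1:10, function(r)
      generateTrace(traceGenSpec(amplitude = 30, period = 40,
                                 damping = damping, seed = 300 + r),
                    inducerCondition(1, 0.01), trace_id = paste0("d", r)))
    scoreCondition(traces)$relative_bottom_count
  }
  scores <- vapply(c(0, 0.01, 0.02, 0.05), rbc_at, numeric(1))
  expect_true(all(diff(scores) <= 0))
  expect_equal(scores[1], 1)
  expect_lt(scores[4], 0.5)
})

test_that("constitutive traces with default weak noise stay under 3 bottoms", {
  for (seed in 1:5) {
    tr <- generateTrace(traceGenSpec(amplitude = 0, noise_scale = 0.05,
                                     seed = seed))
    expect_lt(length(detectBottoms(tr)), 3)
  }
})
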