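test_that("a scalar birth-death system has its closed-form equilibrium", {
  # build via the package: zero binding, zero protease, basal production
  p <- oscillatorParameters(ka_on = 0, kr_on = 0, V_max = 0,
                            tx_active = 0, tx_rep_lacara = 0, tx_rep_lac = 0)
  sys <- assembleOdes(circuitConfig("none"), p, inducerCondition(0, 0))
  eq <- findEquilibria(sys, list(defaultInitialState(sys)))
  expect_length(eq$equilibria, 1)
  e <- eq$equilibria[[1]]
  expect_lte(e$residual_norm, 1e-8)
  # closed form: m* = b/(delta_m+lambda), protein* = k_tl m*/stoich/lambda
  m_star <- sys$classes[[1]]$copies * p$tx_basal / (p$delta_m + p$lambda)
  expect_equal(e$point[["m_araC"]], m_star, tolerance = 1e-6)
  expect_equal(e$point[["a"]], p$k_tl * m_star / 2 / p$lambda,
               tolerance = 1e-6)
  expect_equal(e$point[["l"]],
               (sys$classes[[2]]$copies * p$tx_basal / (p$delta_m + p$lambda)) *
                 p$k_tl / 4 / p$lambda, tolerance = 1e-6)
  expect_true(e$stable)
})

test_that("the numeric Jacobian of a linear map is the matrix itself", {
  set.seed(5)
  A <- matrix(rnorm(25), 5)
  J <- numericJacobian(function(x) as.numeric(A %*% x), rnorm(5))
  expect_equal(J, A, tolerance = 1e-7)
})

test_that("Jacobian rows of a conserved promoter class sum to zero", {
  sys <- make_system("lac_ara", ara = 0.5, iptg = 0.1)
  set.seed(11)
  s <- random_valid_state(sys)
  J <- jacobianAt(sys, s, reduced = FALSE)
  for (cl in sys$classes) {
    # d/dx of sum over class occupancy derivative is 0 for every direction
    expect_lt(max(abs(colSums(J[cl$index, ]))), 1e-6)
  }
})

test_that("stability classification handles the textbook cases", {
  expect_true(classifyStability(matrix(-1, 1, 1))$stable)
  expect_false(classifyStability(matrix(1, 1, 1))$stable)
  # companion matrix of s^2 + 0.1 s + 1: real parts -0.05
  A <- matrix(c(0, -1, 1, -0.1), 2, 2)
  cls <- classifyStability(A)
  expect_true(cls$stable)
  expect_equal(sort(Re(cls$eigenvalues)), c(-0.05, -0.05))
  expect_true("routh" %in% cls$method_flags)
  expect_true(cls$routh_agrees)
  # marginal: pure rotation
  rot <- matrix(c(0, -1, 1, 0), 2, 2)
  expect_true(classifyStability(rot)$marginal)
})

test_that("Routh-Hurwitz agrees with eigenvalue signs on 1000 random systems", {
  set.seed(42)
  disagreements <- 0L
  for (i in 1:1000) {
    n <- sample(2:6, 1)
    A <- matrix(rnorm(n * n), n)
    ev_stable <- max(Re(eigen(A, only.values = TRUE)$values)) < 0
    rt <- routhStable(dualosc:::charpoly_coefficients(A))
    if (!identical(rt$stable, ev_stable)) disagreements <- disagreements + 1L
  }
  expect_equal(disagreements, 0L)
})

test_that("Routh array survives zero-pivot degeneracies", {
  # s^4 + s^3 + 2s^2 + 2s + 1: zero pivot in the array, roots near the axis
  r <- routhStable(c(1, 1, 2, 2, 1))
  expect_true(r$degenerate)
  # s^2 + 1: marginal (auxiliary row), must not be declared Hurwitz-stable
  expect_false(routhStable(c(1, 0, 1))$stable)
  expect_error(routhStable(c(0, 1, 1)), "leading coefficient")
})

test_that("classification is invariant under permutation and rescaling", {
  set.seed(9)
  sys <- make_system("lac", ara = 0.01, iptg = 0.001)
  traj <- integrateOdes(sys, t_end = 300, dt = 1, rtol = 1e-6, atol = 1e-6)
  J <- jacobianAt(sys, traj$values[nrow(traj$values), ])
  base <- classifyStability(J)$stable
  n <- nrow(J)
  perm <- sample(n)
  expect_equal(classifyStability(J[perm, perm])$stable, base)
  d <- diag(exp(runif(n, -1, 1)))
  expect_equal(classifyStability(d %*% J %*% solve(d))$stable, base)
})

test_that("Newton equilibria match integrate-to-steady-state on a stable cell", {
  sys <- make_system("lac_ara", ara = 0.01, iptg = 0.001)
  burn <- integrateOdes(sys, t_end = 300, dt = 1, rtol = 1e-8, atol = 1e-8)
  eq <- findEquilibria(sys, list(burn$values[nrow(burn$values), ]))
  expect_gte(length(eq$equilibria), 1)
  e <- eq$equilibria[[1]]
  expect_true(e$stable)
  expect_lte(e$residual_norm, 1e-8)
  # perturb the free molecules (the conserved DNA stays on its manifold)
  s2 <- perturb_offmanifold_free(sys, e$point)
  traj <- integrateOdes(sys, initial = s2, t_end = 400, dt = 2,
                        rtol = 1e-8, atol = 1e-8)
  final <- traj$values[nrow(traj$values), ]
  expect_lt(sqrt(sum((final - e$point)^2)) / (1 + sqrt(sum(e$point^2))),
            1e-3)
})

test_that("nonconverged guesses are reported, not dropped", {
  sys <- make_system("none", ara = 0.01, iptg = 0.001)
  bad <- defaultInitialState(sys)
  eq <- findEquilibria(sys, list(bad, rep(1, 3)), max_iter = 100)
  expect_equal(length(eq$failed), 1L)
  expect_match(eq$failed[[1]]$reason, "dimension")
  df <- as.data.frame(eq)
  expect_true(all(c("stable", "residual_norm", "a", "l") %in% names(df)))
  dir <- tempfile()
  writeEquilibriumReport(eq, dir)
  expect_true(file.exists(file.path(dir, "equilibria.tsv")))
  summ <- jsonlite::read_json(file.path(dir, "summary.json"))
  expect_equal(summ$n_failed, 1)
})
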