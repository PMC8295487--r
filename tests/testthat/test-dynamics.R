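test_that("one update step matches the scalar closed form", {
  # single neuron, no coupling: V1 = exp(-h)*V0 + (1 - exp(-h))*S
  a1 <- layer_architecture(1, 1, c(0, 1))
  m <- ddnf_model(a1, discretization_params(0.8, c(0, 1)),
                  connectivity = chain_connectivity(a1, 0, 0, 0),
                  activation = activation_spec("heaviside"),
                  stimulus = stimulus_spec(nu = -0.5, U = "zero"))
  s1 <- ddnf_step(field_state(matrix(-1.5, 1, 1)), m)
  expect_equal(drop(s1$V), exp(-0.8) * (-1.5) + (1 - exp(-0.8)) * (-0.5),
               tolerance = 1e-15)
  expect_identical(s1$n, 1)
})

test_that("with no coupling and no stimulus the field decays geometrically", {
  W0 <- matrix(0, 4, 4)
  m <- explicit_model(W0, nu = 0)
  V0 <- matrix(c(1, -2, 0.5, 3), 1, 4)
  tr <- simulate_ddnf(m, V0 = V0, N = 10)
  al <- m$discretization$alpha
  for (n in 0:10) expect_equal(tr$V[n + 1, 1, ], al^n * drop(V0),
                               tolerance = 1e-12)
})

test_that("overriding alpha to one freezes the field", {
  arch <- layer_architecture(1, 10, c(-20, 20))
  m <- ddnf_model(arch, discretization_params(0.8, c(-20, 20), alpha = 1),
                  kernel = kernel_preset("gauss_diff_sec35"),
                  stimulus = stimulus_spec(-0.5, "gaussian_space"))
  tr <- simulate_ddnf(m, V0 = -1.5, N = 5)
  for (n in 0:5) expect_identical(tr$V[n + 1, , ], tr$V[1, , ])
})

test_that("the Heaviside closed form reproduces the simulator exactly", {
  # frozen value: alpha^2 * (-1.5) + (-0.5) * (1 - alpha^2), alpha = exp(-0.8)
  d <- discretization_params(0.8, c(-20, 20))
  expect_equal(heaviside_closed_form(-1.5, d, -0.5, 2), -0.70189651799465,
               tolerance = 1e-12)
  expect_identical(heaviside_closed_form(-1.5, d, -0.5, 0), -1.5)
  expect_equal(heaviside_closed_form(-1.5, d, -0.5, 500), -0.5)
  # cross-check against two explicit steps
  sp <- small_fig5(M = 10, N = 2)
  tr <- simulate_ddnf(sp$model, V0 = -1.5, N = 2)
  expect_equal(tr$V[3, 1, ], rep(heaviside_closed_form(-1.5, d, -0.5, 2), 10),
               tolerance = 1e-15)
  # entrywise agreement over a long horizon (all-negative trajectory)
  sp <- small_fig5(M = 20, N = 200)
  tr <- simulate_ddnf(sp$model, V0 = -1.5, N = 200)
  for (n in c(1, 7, 50, 200))
    expect_equal(tr$V[n + 1, 1, ],
                 rep(heaviside_closed_form(-1.5, d, -0.5, n), 20),
                 tolerance = 1e-12)
})

test_that("Heaviside trajectories respect the a-priori bound at every step", {
  sp <- scenario_spec("fig7", M = 25, N = 60)
  tr <- simulate_ddnf(sp$model, V0 = -1.5, N = 60)
  bounds <- trajectory_bound(sp$model, -1.5, 0:60)
  for (n in 0:60) expect_lte(max(abs(tr$V[n + 1, , ])), bounds[n + 1])
  # degenerate case: no weights, no stimulus
  m0 <- explicit_model(matrix(0, 3, 3), nu = 0,
                       activation = activation_spec("heaviside"))
  expect_equal(trajectory_bound(m0, matrix(c(-2, 1, 0.5), 1, 3), 0:4),
               exp(-0.8)^(0:4) * 2)
  # geometric-series limit S_bar + |Omega| * W_bar
  sb <- max(abs(sp$model$S)); wb <- kernel_bound(sp$model$connectivity)
  expect_equal(trajectory_bound(sp$model, -1.5, 4000), sb + 40 * wb,
               tolerance = 1e-9)
  expect_error(trajectory_bound(explicit_model(matrix(0, 2, 2)), 0, 1),
               "Heaviside")
})

test_that("with no coupling the field relaxes to the stimulus at rate alpha", {
  m <- explicit_model(matrix(0, 3, 3), nu = -0.7, h = 0.8)
  tr <- simulate_ddnf(m, V0 = 2, N = 25)
  res <- vapply(0:25, function(n) max(abs(tr$V[n + 1, 1, ] - (-0.7))),
                numeric(1))
  slope <- stats::coef(stats::lm(log(res) ~ I(0:25)))[2]
  expect_equal(unname(slope), -0.8, tolerance = 1e-9)
})

test_that("Mann iteration converges and certifies contraction", {
  # zero map: T(V) = 0, fixed point is the zero field
  m0 <- explicit_model(matrix(0, 3, 3), nu = 0)
  r0 <- mann_iterate(m0, V0 = 5, tol = 1e-12)
  expect_true(r0$converged)
  expect_equal(max(abs(r0$V_star$V)), 0, tolerance = 1e-11)
  # sigmoid theta = 1 (C = 1/4) with weight bound * |Omega| = 2:
  # contraction product 0.5 <= 1 -> convergence guaranteed
  m <- explicit_model(matrix(c(2, -1, 0.5, 1), 2, 2) / 2, nu = -0.3,
                      domain = c(0, 2),
                      activation = activation_spec("sigmoid", theta = 1))
  expect_equal(kernel_bound(m$connectivity) * m$discretization$omega, 2)
  r <- mann_iterate(m, V0 = 0, tol = 1e-11)
  expect_equal(r$contraction, 0.5)
  expect_true(r$guaranteed)
  expect_true(r$converged)
  expect_lt(fixed_point_residual(r$V_star, m), 10 * r$tol)
  # residual log-slope is negative under contraction
  fit <- stats::coef(stats::lm(log(r$residuals) ~ seq_along(r$residuals)))[2]
  expect_lt(unname(fit), 0)
  # Heaviside: diagnostic unavailable, no exception
  mh <- explicit_model(matrix(0.1, 2, 2), nu = -0.5,
                       activation = activation_spec("heaviside"))
  expect_true(is.na(mann_iterate(mh, V0 = -1, max_iter = 50)$contraction))
  # non-convergence is a result, not an error
  mu <- explicit_model(matrix(0, 1, 1), nu = 0)
  ru <- mann_iterate(mu, V0 = 10, tol = 1e-300, max_iter = 3)
  expect_false(ru$converged)
  expect_identical(ru$iterations, 3L)
})

test_that("the fixed-point residual measures violation of V = Gamma G(V) + S", {
  m <- explicit_model(matrix(0, 3, 3), nu = 0.4)
  V <- matrix(0.4, 1, 3)
  expect_equal(fixed_point_residual(V, m), 0)
  Vp <- V; Vp[1, 2] <- 0.4 + 0.015
  expect_equal(fixed_point_residual(Vp, m), 0.015)
})

test_that("cobweb returns the diagonal-map polyline", {
  sp <- small_fig5(M = 5, N = 1)
  tr <- simulate_ddnf(sp$model, V0 = -1.5, N = 1)
  cw <- cobweb(tr, 1, 3)
  expect_identical(nrow(cw), 2L)
  expect_identical(cw$segment, c("diagonal", "map"))
  expect_identical(cw$x[1], cw$y[1])
  # constant trajectory lies on the diagonal
  m <- explicit_model(matrix(0, 2, 2), nu = 0.3)
  trc <- simulate_ddnf(m, V0 = 0.3, N = 5)
  cwc <- cobweb(trc, 1, 1)
  expect_equal(cwc$x, cwc$y, tolerance = 1e-14)
  # resting-level convergence of the second coordinate
  tr5 <- simulate_ddnf(small_fig5(M = 10, N = 80)$model, V0 = -1.5, N = 80)
  cw5 <- cobweb(tr5, 1, 5)
  expect_equal(cw5$y[nrow(cw5)], -0.5, tolerance = 1e-6)
  expect_error(cobweb(tr5, 2, 1), "out of range")
})

test_that("trajectories are deterministic and state extraction is consistent", {
  sp <- scenario_spec("fig6", M = 15, N = 30)
  t1 <- simulate_ddnf(sp$model, V0 = -1.5, N = 30)
  t2 <- simulate_ddnf(sp$model, V0 = -1.5, N = 30)
  expect_identical(t1$V, t2$V)
  st <- trajectory_state(t1, 17)
  expect_identical(st$V[1, ], t1$V[18, 1, ])
  expect_identical(st$n, 17)
  t0 <- simulate_ddnf(sp$model, V0 = -1.5, N = 0)
  expect_identical(dim(t0$V)[1], 1L)
})
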