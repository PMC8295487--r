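test_that("the Heaviside Jacobian reduces to diag(alpha) off threshold", {
  sp <- small_fig5(M = 12, N = 100)
  tr <- simulate_ddnf(sp$model, V0 = -1.5, N = 100)
  rep <- build_jacobian(sp$model, trajectory_state(tr))
  al <- sp$model$discretization$alpha
  expect_identical(rep$A, diag(al, 12))
  expect_equal(rep$rho, al)
  expect_identical(rep$classification, "stable")
  # a fixed point on the Dirac mass is rejected
  expect_error(build_jacobian(sp$model, field_state(matrix(0, 1, 12))),
               "threshold")
})

test_that("the Jacobian matches finite differences of the step map", {
  # scalar case: A = [alpha + (1-alpha) * |Omega| * w * G'(V*)]
  w <- 0.8
  m <- explicit_model(matrix(w, 1, 1), nu = -0.1,
                      activation = activation_spec("sigmoid", theta = 2))
  Vs <- matrix(0.3, 1, 1)
  g <- activation_derivative(m$activation, 0.3)
  al <- m$discretization$alpha
  rep <- build_jacobian(m, Vs)
  expect_equal(drop(rep$A), al + (1 - al) * w * g, tolerance = 1e-12)
  expect_equal(drop(rep$A), drop(fd_jacobian(m, Vs)), tolerance = 1e-6)
  # seeded random multilayer sigmoid models
  for (seed in 1:20) {
    fx <- generate_fixture(seed, "unconstrained", L_range = c(1, 3),
                           M_range = c(2, 5))
    arch <- fx$model$architecture
    V <- matrix(0, arch$L, arch$Mmax)
    set.seed(1000 + seed)
    for (k in seq_len(arch$L))
      V[k, seq_len(arch$M[k])] <- runif(arch$M[k], -1, 1)
    A <- build_jacobian(fx$model, V)$A
    J <- fd_jacobian(fx$model, V)
    expect_equal(A, J, tolerance = 1e-6)
  }
})

test_that("non-adjacent layer blocks of the super-adjacency matrix are zero", {
  arch <- layer_architecture(3, 2, c(0, 1))
  m <- ddnf_model(arch, discretization_params(0.5, c(0, 1)),
                  kernel = kernel_spec("gaussian", sigma = 0.5),
                  activation = activation_spec("sigmoid"))
  rep <- build_jacobian(m, field_state(0, model = m))
  expect_identical(rep$A[1:2, 5:6], matrix(0, 2, 2))
  expect_identical(rep$A[5:6, 1:2], matrix(0, 2, 2))
  expect_false(all(rep$A[3:4, 5:6] == 0))
})

test_that("single-layer mu values match the brute-force row means", {
  # W == 0 -> trivial fixed solution, all mu zero, criterion satisfied
  m0 <- explicit_model(matrix(0, 4, 4))
  mu0 <- mu_single_layer(m0, 0)
  expect_identical(as.numeric(mu0), rep(0, 4))
  expect_true(attr(mu0, "flag"))
  # random model: mu_i = |Omega| * mean_j(W_ij G'(V_j*))
  set.seed(5)
  W <- matrix(runif(25, -1, 1), 5, 5)
  m <- explicit_model(W, domain = c(0, 2),
                      activation = activation_spec("sigmoid", theta = 1.7))
  V <- matrix(runif(5, -1, 1), 1, 5)
  gp <- activation_derivative(m$activation, drop(V))
  oracle <- 2 * rowMeans(sweep(W, 2, gp, `*`))
  mu <- mu_single_layer(m, V)
  expect_equal(as.numeric(mu), oracle, tolerance = 1e-12)
  # row-sum norm bound ||A||_inf <= alpha + (1-alpha) max|mu_i| under the
  # positive-connectivity hypothesis (signed sums need absolute row sums)
  Wp <- abs(W)
  mp <- explicit_model(Wp, domain = c(0, 2),
                       activation = activation_spec("sigmoid", theta = 1.7))
  mup <- mu_single_layer(mp, V)
  Ap <- build_jacobian(mp, V)$A
  al <- mp$discretization$alpha
  expect_lte(max(rowSums(abs(Ap))), al + (1 - al) * max(abs(mup)) + 1e-12)
  expect_error(mu_single_layer(generate_fixture(3, L_range = c(2, 2))$model, 0),
               "single-layer")
})

test_that("spectral-radius classification follows the unit circle", {
  out <- spectral_radius_classify(diag(exp(-0.8), 3))
  expect_equal(out$rho, exp(-0.8))
  expect_identical(out$classification, "stable")
  expect_identical(spectral_radius_classify(diag(3))$classification,
                   "inconclusive")
  nil <- matrix(c(0, 0, 2, 0), 2, 2)
  expect_identical(spectral_radius_classify(nil)$rho, 0)
  expect_identical(spectral_radius_classify(diag(1.5, 2))$classification,
                   "unstable")
})

test_that("closed-form tridiagonal eigenvalues match the dense solver", {
  expect_identical(tridiagonal_eigenvalues(3.2, 5, 4, 1), 3.2)
  expect_identical(tridiagonal_eigenvalues(1.1, 0, 2, 4), rep(1.1, 4))
  expect_equal(sort(tridiagonal_eigenvalues(2, 1, 1, 3)),
               c(2 - sqrt(2), 2, 2 + sqrt(2)), tolerance = 1e-12)
  # dense oracle: when bc >= 0 the chain is similar to the symmetric
  # tridiagonal with off-diagonal sqrt(bc), whose dense spectrum is accurate
  set.seed(31)
  for (r in 1:30) {
    L <- sample(1:50, 1)
    a <- runif(1, -2, 2)
    b <- runif(1, -2, 2)
    c <- b * runif(1, 0, 3)  # same sign: bc >= 0
    lam <- tridiagonal_eigenvalues(a, b, c, L)
    s <- sqrt(b * c)
    dense <- eigen(dense_chain(rep(a, L), rep(s, max(L - 1, 0)),
                               rep(s, max(L - 1, 0))),
                   symmetric = TRUE, only.values = TRUE)$values
    expect_lt(max(abs(sort(lam) - sort(dense))), 1e-10)
  }
  expect_error(tridiagonal_eigenvalues(1, 1, -1, 3), "dense")
})

test_that("multilayer chain spectrum matches its tridiagonal matrix", {
  d <- discretization_params(0.8, c(0, 1))
  # K1 = K2 = 0, L = 1: mu_1 = alpha + (1-alpha)|Omega|K0
  expect_equal(as.numeric(mu_multilayer(d, 0.5, 0, 0, 1)),
               d$alpha + (1 - d$alpha) * 0.5)
  expect_equal(as.numeric(mu_multilayer(d, 0, 0, 0, 3)), rep(d$alpha, 3))
  expect_true(attr(mu_multilayer(d, 0, 0, 0, 3), "flag"))
  mu <- mu_multilayer(d, 0.5, 0.1, 0.1, 4)
  abc <- attr(mu, "abc")
  dense <- eigen(dense_chain(rep(abc["a"], 4), rep(abc["b"], 3),
                             rep(abc["c"], 3)), only.values = TRUE)$values
  expect_equal(sort(as.numeric(mu)), sort(Re(dense)), tolerance = 1e-12)
  # the closed-form bound dominates every finite-L maximum and is approached
  # as the chain grows
  expect_gte(attr(mu, "mu_max"), max(abs(mu)))
  mu_big <- mu_multilayer(d, 0.5, 0.1, 0.1, 2000)
  expect_equal(attr(mu_big, "mu_max"), max(abs(mu_big)), tolerance = 1e-5)
  expect_warning(mu_multilayer(d, -0.5, 0.1, 0.1, 2), "positive")
})

test_that("transfer-matrix determinants equal dense determinants", {
  expect_identical(transfer_matrix_det(4.5, lam = 0.7), 4.5 - 0.7)
  set.seed(41)
  for (r in 1:40) {
    L <- sample(3:12, 1)
    a <- runif(L, -2, 2); b <- runif(L - 1, -2, 2); c <- runif(L - 1, -2, 2)
    lam <- runif(1, -1, 1); bL <- runif(1, -2, 2); c0 <- runif(1, -2, 2)
    do <- det(dense_chain(a, b, c) - lam * diag(L))
    dc <- det(dense_chain(a, b, c, TRUE, bL, c0) - lam * diag(L))
    expect_equal(transfer_matrix_det(a, b, c, lam), do,
                 tolerance = 1e-8 * max(1, abs(do)))
    expect_equal(transfer_matrix_det(a, b, c, lam, TRUE, bL, c0), dc,
                 tolerance = 1e-8 * max(1, abs(dc)))
  }
  # closed 10-layer reference chain
  ref <- det(dense_chain(rep(4, 10), rep(3, 9), rep(5, 9), TRUE, 10, 7))
  expect_equal(transfer_matrix_det(rep(4, 10), rep(3, 9), rep(5, 9), 0,
                                   TRUE, 10, 7), ref,
               tolerance = 1e-8 * abs(ref))
  expect_error(transfer_matrix_det(1:2, 3, 4, closed = TRUE, b_L = 1, c_0 = 1),
               "L >= 3")
  expect_error(transfer_matrix_det(1:3, c(1, 1), c(1, 1), closed = TRUE),
               "corner")
})

test_that("two-layer reports agree with the determinant-trace criterion", {
  d <- discretization_params(0.8, c(0, 1))
  # all K zero: A = alpha * I, stable
  r0 <- two_layer_stability(d, 0, 0, 0, 0)
  expect_identical(r0$A, diag(d$alpha, 2))
  expect_identical(r0$classification, "stable")
  # K12 * K21 = 0 -> theta = 1, closed-form conditions fail
  r1 <- two_layer_stability(d, 0.2, 0.1, 0, 0.5)
  expect_identical(r1$theta, 1)
  expect_false(r1$flags[["conditions"]])
  # trace-det criterion is exactly the eigenvalue test; the closed-form
  # condition set is sufficient for it
  set.seed(51)
  for (r in 1:1000) {
    dd <- discretization_params(runif(1, 0.1, 2), c(0, runif(1, 0.5, 3)))
    K <- runif(4, 0, 2 / dd$omega)
    rep <- two_layer_stability(dd, K[1], K[2], K[3], K[4])
    expect_identical(rep$flags[["trace_det"]],
                     all(Mod(rep$eigenvalues) < 1))
    if (rep$flags[["conditions"]])
      expect_true(rep$flags[["trace_det"]])
  }
})

test_that("classification predicts the nonlinear dynamics near the fixed point", {
  # stable fixtures: a 1e-3 perturbation contracts below 1e-6 within 500 steps
  for (seed in 1:4) {
    fx <- generate_fixture(seed, "stable", M_range = c(3, 5))
    expect_identical(build_jacobian(fx$model, fx$V_star)$classification,
                     "stable")
    M <- fx$model$architecture$M[1]
    set.seed(100 + seed)
    V <- fx$V_star$V + matrix(c(1e-3, runif(M - 1, -1e-3, 1e-3)), 1, M)
    st <- field_state(V)
    for (n in 1:500) {
      st <- ddnf_step(st, fx$model)
      if (max(abs(st$V)) < 1e-6) break
    }
    expect_lt(max(abs(st$V)), 1e-6)
  }
  # unstable fixtures: the perturbation grows tenfold
  for (seed in 11:14) {
    fx <- generate_fixture(seed, "unstable", M_range = c(3, 5))
    expect_identical(build_jacobian(fx$model, fx$V_star)$classification,
                     "unstable")
    M <- fx$model$architecture$M[1]
    set.seed(200 + seed)
    V <- fx$V_star$V + matrix(runif(M, -1e-3, 1e-3), 1, M)
    st <- field_state(V)
    grew <- FALSE
    for (n in 1:500) {
      st <- ddnf_step(st, fx$model)
      if (max(abs(st$V)) >= 1e-2) { grew <- TRUE; break }
    }
    expect_true(grew)
  }
})
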