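# Independent oracles used across the suite.

# Central finite-difference Jacobian of the one-step map, independent of
# build_jacobian: perturbs every active entry of the field.
fd_jacobian <- function(model, V_star, eps = 1e-6) {
  arch <- model$architecture
  V <- if (inherits(V_star, "ddnf_field")) V_star$V else V_star
  idx <- do.call(rbind, lapply(seq_len(arch$L), function(k)
    cbind(k, seq_len(arch$M[k]))))
  MM <- nrow(idx)
  J <- matrix(0, MM, MM)
  for (j in seq_len(MM)) {
    Vp <- V; Vm <- V
    Vp[idx[j, 1], idx[j, 2]] <- Vp[idx[j, 1], idx[j, 2]] + eps
    Vm[idx[j, 1], idx[j, 2]] <- Vm[idx[j, 1], idx[j, 2]] - eps
    Fp <- ddnf_step(field_state(Vp), model)$V
    Fm <- ddnf_step(field_state(Vm), model)$V
    J[, j] <- (Fp[idx] - Fm[idx]) / (2 * eps)
  }
  J
}

# Dense (possibly closed) tridiagonal chain matrix.
dense_chain <- function(a, b, c, closed = FALSE, bL = NULL, c0 = NULL) {
  L <- length(a)
  A <- diag(a, L, L)
  for (k in seq_len(L - 1)) { A[k, k + 1] <- b[k]; A[k + 1, k] <- c[k] }
  if (closed) { A[1, L] <- c0; A[L, 1] <- bL }
  A
}

# Single-layer model with an explicit weight matrix and constant stimulus.
explicit_model <- function(W, domain = c(0, 1), h = 0.8, nu = 0,
                           activation = activation_spec("sigmoid")) {
  M <- nrow(W)
  arch <- layer_architecture(1, M, domain = domain)
  conn <- build_connectivity(arch, blocks = list("1,1" = W))
  ddnf_model(arch, discretization_params(h, domain = domain),
             activation = activation, connectivity = conn,
             stimulus = stimulus_spec(nu = nu, U = "zero"))
}

# Reference single-layer Heaviside scenario at reduced grid size for speed.
small_fig5 <- function(M = 20, N = 100) {
  scenario_spec("fig5", M = M, N = N)
}
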