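# Coupling term T(V)[k, i] = sum_{l in L_k} sum_j beta_l W_ij^(k,l) G(V_j^(l)) + S[k, i]
coupling_map <- function(V, model) {
  arch <- model$architecture
  G <- evaluate_activation
  TV <- matrix(0, arch$L, arch$Mmax)
  gV <- vector("list", arch$L)
  for (l in seq_len(arch$L))
    gV[[l]] <- G(model$activation, V[l, seq_len(arch$M[l])])
  for (k in seq_len(arch$L)) {
    acc <- numeric(arch$M[k])
    for (l in arch$neighbors[[k]])
      acc <- acc + model$beta[l] *
        drop(model$connectivity$blocks[[k]][[l]] %*% gV[[l]])
    TV[k, seq_len(arch$M[k])] <- acc + model$S[k, seq_len(arch$M[k])]
  }
  TV
}

#' One step of the DDNF update
#'
#' Applies the update `V <- alpha * V + (1 - alpha) * (Gamma %*% G(V) + S)`
#' entrywise over all layers, where the bracket is the Riemann-sum coupling
#' through the block connectivity tensor plus the stimulus. Padded entries of
#' ragged layers remain 0.
#'
#' @param state A [field_state()] (or bare matrix / scalar).
#' @param model A [ddnf_model()].
#' @return A `ddnf_field` with the time index incremented.
#' @export
ddnf_step <- function(state, model) {
  n <- if (inherits(state, "ddnf_field")) state$n else 0
  V <- as_field_matrix(state, model)
  al <- model$discretization$alpha
  Vn <- al * V + (1 - al) * coupling_map(V, model)
  arch <- model$architecture
  for (k in seq_len(arch$L))
    if (arch$M[k] < arch$Mmax) Vn[k, (arch$M[k] + 1):arch$Mmax] <- 0
  if (any(!is.finite(Vn)))
    stop("field overflow at time index ", n + 1, call. = FALSE)
  field_state(Vn, n = n + 1)
}

#' Simulate a DDNF trajectory
#'
#' Repeatedly applies [ddnf_step()] for `N` steps. Deterministic given the
#' model and the initial field.
#'
#' @param model A [ddnf_model()].
#' @param V0 Initial field: a [field_state()], matrix, or scalar.
#' @param N Number of steps (`N = 0` returns just the initial state).
#' @return A `ddnf_trajectory`: array `V` of dimension `(N+1) x L x Mmax`
#'   (time index along the first margin, `V[n+1, , ]` is the field at time
#'   `n`), with the model attached.
#' @export
simulate_ddnf <- function(model, V0 = -1.5, N = 100) {
  stopifnot(inherits(model, "ddnf_model"), N >= 0)
  arch <- model$architecture
  V <- as_field_matrix(V0, model)
  out <- array(0, dim = c(N + 1, arch$L, arch$Mmax))
  out[1, , ] <- V
  st <- field_state(V, n = 0)
  if (N > 0) for (n in seq_len(N)) {
    st <- ddnf_step(st, model)
    out[n + 1, , ] <- st$V
  }
  structure(list(V = out, N = N, model = model), class = "ddnf_trajectory")
}

#' Extract the field at one time index of a trajectory
#'
#' @param traj A `ddnf_trajectory`.
#' @param n Time index in `0..N`.
#' @return A `ddnf_field`.
#' @export
trajectory_state <- function(traj, n = traj$N) {
  stopifnot(inherits(traj, "ddnf_trajectory"), n >= 0, n <= traj$N)
  V <- traj$V[n + 1, , , drop = FALSE]
  dim(V) <- dim(traj$V)[2:3]
  field_state(V, n = n)
}

#' Closed-form Heaviside trajectory without external input
#'
#' For a single-layer Heaviside model with `U = 0` and a trajectory that stays
#' strictly below the firing threshold, the kernel sum vanishes at every step
#' and the update reduces to the scalar recursion `V <- alpha*V + (1-alpha)*nu`
#' whose solution is the geometric partial sum
#' \deqn{V_n = \alpha^n V_0 + \nu (1 - \alpha^n),}
#' converging to the resting level `nu`. The caller is responsible for the
#' below-threshold premise.
#'
#' @param V0_entry Initial value(s).
#' @param params A [discretization_params()].
#' @param nu Resting level.
#' @param n Nonnegative time index (vectorized).
#' @export
heaviside_closed_form <- function(V0_entry, params, nu, n) {
  stopifnot(inherits(params, "ddnf_discretization"), all(n >= 0))
  al <- params$alpha
  al^n * V0_entry + nu * (1 - al^n)
}

#' A-priori bound on a Heaviside trajectory
#'
#' With stimulus bounded by `S_bar` and weights bounded by `W_bar`, every
#' entry of a Heaviside trajectory satisfies
#' \deqn{|V_{i,n}| \le \alpha^n \max_i |V_{i,0}| + Y_m
#'   \frac{1 - \alpha^{n+1}}{1 - \alpha}, \qquad
#'   Y_m = (1-\alpha)(\bar S + |\Omega| \bar W),}
#' so the field stays bounded and settles (limit `S_bar + |Omega| * W_bar` for
#' the second term).
#'
#' @param model A Heaviside [ddnf_model()].
#' @param V0 Initial field.
#' @param n Nonnegative time index (vectorized).
#' @return The bound (scalar or vector along `n`).
#' @export
trajectory_bound <- function(model, V0, n) {
  stopifnot(inherits(model, "ddnf_model"), all(n >= 0))
  if (model$activation$family != "heaviside")
    stop("the trajectory bound is derived for Heaviside models", call. = FALSE)
  al <- model$discretization$alpha
  s_bar <- max(abs(model$S))
  w_bar <- kernel_bound(model$connectivity)
  v0max <- max(abs(as_field_matrix(V0, model)))
  if (al == 1) return(rep(v0max, length(n)))
  ym <- (1 - al) * (s_bar + model$discretization$omega * w_bar)
  al^n * v0max + ym * (1 - al^(n + 1)) / (1 - al)
}

#' Violation of the fixed-point condition
#'
#' A time-constant field is a fixed point of the DDNF when
#' `V = Gamma %*% G(V) + S`. This returns the sup-norm residual
#' `max |V - (Gamma %*% G(V) + S)|` over the active entries.
#'
#' @param V Field (matrix, scalar, or `ddnf_field`).
#' @param model A [ddnf_model()] with time-constant stimulus.
#' @export
fixed_point_residual <- function(V, model) {
  V <- as_field_matrix(V, model)
  arch <- model$architecture
  R <- V - coupling_map(V, model)
  m <- 0
  for (k in seq_len(arch$L))
    m <- max(m, max(abs(R[k, seq_len(arch$M[k])])))
  m
}

#' Mann-type fixed-point iteration
#'
#' Runs the averaged iteration `V <- alpha * V + (1 - alpha) * T(V)` with
#' `T(V) = Gamma %*% G(V) + S` until the sup-norm step `||V_{m+1} - V_m||`
#' falls below `tol`. When `G` is Lipschitz with constant `C` (sigmoid:
#' `theta/4`) and the weights are bounded by `W0`, the contraction product
#' `C * W0 * |Omega|` bounds the Lipschitz constant of `T` (the Riemann
#' weights over one layer sum to `|Omega|`); a product at most 1 guarantees a
#' weak solution, below 1 geometric convergence. For the Heaviside function no
#' Lipschitz constant exists and the diagnostic is reported as `NA`.
#'
#' Non-convergence within `max_iter` is reported in the result, not raised.
#'
#' @param model A [ddnf_model()].
#' @param V0 Initial field.
#' @param tol Positive sup-norm tolerance. Default `1e-10`.
#' @param max_iter Iteration cap. Default 1000.
#' @return A `ddnf_mann` object: fields `V_star` (final field), `residuals`
#'   (per-iteration sup-norm steps), `contraction` (the product, or `NA`),
#'   `guaranteed` (`contraction <= 1`), `converged`, `iterations`.
#' @export
mann_iterate <- function(model, V0 = 0, tol = 1e-10, max_iter = 1000) {
  stopifnot(inherits(model, "ddnf_model"), tol > 0, max_iter >= 1)
  al <- model$discretization$alpha
  contraction <- if (model$activation$family == "heaviside") NA_real_
  else lipschitz_constant(model$activation) * kernel_bound(model$connectivity) *
    model$discretization$omega
  V <- as_field_matrix(V0, model)
  res <- numeric(0)
  converged <- FALSE
  it <- 0L
  while (it < max_iter) {
    it <- it + 1L
    Vn <- al * V + (1 - al) * coupling_map(V, model)
    r <- max(abs(Vn - V))
    res[it] <- r
    V <- Vn
    if (r < tol) { converged <- TRUE; break }
  }
  structure(list(V_star = field_state(V, n = it), residuals = res,
                 contraction = contraction,
                 guaranteed = isTRUE(contraction <= 1),
                 converged = converged, iterations = it, tol = tol),
            class = "ddnf_mann")
}

#' Cobweb polyline of a scalar coordinate of a trajectory
#'
#' The ordered pairs `(V_n, V_n), (V_n, V_{n+1})` for `n = 0..N-1`: the path a
#' cobweb plot draws between the diagonal and the map graph to visualize
#' convergence or oscillation of the coordinate `(layer, i)`.
#'
#' @param traj A `ddnf_trajectory`.
#' @param layer Layer index.
#' @param i Neuron index within the layer.
#' @return A tibble with columns `x`, `y`, `n`, `segment`
#'   (`"diagonal"`/`"map"`), `2N` rows.
#' @export
cobweb <- function(traj, layer = 1, i = 1) {
  stopifnot(inherits(traj, "ddnf_trajectory"))
  arch <- traj$model$architecture
  if (layer < 1 || layer > arch$L || i < 1 || i > arch$M[layer])
    stop("cobweb index out of range", call. = FALSE)
  v <- traj$V[, layer, i]
  N <- traj$N
  if (N < 1) stop("cobweb needs at least one step", call. = FALSE)
  n <- seq_len(N) - 1L
  tibble::tibble(
    x = rep(v[seq_len(N)], each = 2),
    y = as.vector(rbind(v[seq_len(N)], v[seq_len(N) + 1])),
    n = rep(n, each = 2),
    segment = rep(c("diagonal", "map"), N))
}

#' @export
print.ddnf_trajectory <- function(x, ...) {
  cat("<ddnf_trajectory>", x$N, "step(s) of a", x$model$architecture$L,
      "layer field; final range [",
      signif(min(x$V[x$N + 1, , ]), 6), ",",
      signif(max(x$V[x$N + 1, , ]), 6), "]\n")
  invisible(x)
}

#' @export
print.ddnf_mann <- function(x, ...) {
  cat("<ddnf_mann>", if (x$converged) "converged" else "NOT converged",
      "after", x$iterations, "iteration(s); final step",
      signif(x$residuals[x$iterations], 4),
      "| contraction product", signif(x$contraction, 4), "\n")
  invisible(x)
}
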