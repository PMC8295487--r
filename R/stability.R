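#' Jacobian (super-adjacency matrix) of the DDNF map at a fixed point
#'
#' Assembles the dense Jacobian of the update map at a reference field
#' `V_star`, blocked by layer: with `MM = sum(M_k)` rows ordered layer by
#' layer, block `(k, m)` is
#' \deqn{A^{(k,m)} = \alpha \delta_{ij} 1\{m = k\} + (1-\alpha) \beta_m
#'   W^{(k,m)}_{ij} G'(V^{(m)}_{j,*}), \quad m \in L_k,}
#' and exactly zero for non-adjacent layers. For a single layer this is the
#' familiar `alpha * I + (1-alpha) * (|Omega|/M) * W * diag(G'(V_star))`. With
#' a Heaviside pulse emission at an off-threshold fixed point every `G'`
#' vanishes and the matrix reduces to `diag(alpha)`; a fixed point with any
#' entry within `tol` of the threshold sits on the Dirac mass of the
#' distributional derivative and is rejected.
#'
#' @param model A [ddnf_model()].
#' @param V_star Reference field (fixed point).
#' @param tol Tolerance for classification and for the Heaviside threshold
#'   band. Default `1e-9`.
#' @return A `ddnf_stability` report: `A`, `eigenvalues`, `rho`,
#'   `classification`, `mu_single` plus the `theorem13` flag when `L = 1`,
#'   and the layer index map.
#' @export
build_jacobian <- function(model, V_star, tol = 1e-9) {
  stopifnot(inherits(model, "ddnf_model"))
  V <- as_field_matrix(V_star, model)
  arch <- model$architecture
  al <- model$discretization$alpha
  gp <- vector("list", arch$L)
  for (l in seq_len(arch$L))
    gp[[l]] <- activation_derivative(model$activation,
                                     V[l, seq_len(arch$M[l])], tol = tol)
  MM <- sum(arch$M)
  offs <- cumsum(c(0L, arch$M))
  A <- matrix(0, MM, MM)
  for (k in seq_len(arch$L)) {
    ri <- offs[k] + seq_len(arch$M[k])
    for (m in arch$neighbors[[k]]) {
      ci <- offs[m] + seq_len(arch$M[m])
      blk <- (1 - al) * model$beta[m] *
        sweep(model$connectivity$blocks[[k]][[m]], 2, gp[[m]], `*`)
      if (m == k) blk <- blk + diag(al, arch$M[k])
      A[ri, ci] <- blk
    }
  }
  sr <- spectral_radius_classify(A, tol = tol)
  rep <- list(A = A, eigenvalues = sr$eigenvalues, rho = sr$rho,
              classification = sr$classification, tol = tol,
              layer_offsets = offs, M = arch$M,
              mu_single = NULL, flags = logical(0))
  if (arch$L == 1) {
    mu <- mu_single_layer(model, V)
    rep$mu_single <- as.numeric(mu)
    rep$flags <- c(theorem13 = attr(mu, "flag"))
  }
  structure(rep, class = "ddnf_stability")
}

#' Single-layer weighted emission-rate averages
#'
#' For a single-layer model, `mu_i = (|Omega|/M) * sum_j W_ij * G'(V_j*)`:
#' the weighted average rate of change of pulse emission seen by neuron `i`
#' at the fixed point. `max_i |mu_i| < 1` certifies asymptotic stability,
#' since the row-sum norm of the Jacobian is then bounded by
#' `alpha + (1-alpha) * max_i |mu_i| < 1`.
#'
#' @param model A single-layer [ddnf_model()].
#' @param V_star Reference field.
#' @return Numeric vector of length `M` with attribute `flag` (`TRUE` when
#'   `max |mu_i| < 1`).
#' @export
mu_single_layer <- function(model, V_star) {
  stopifnot(inherits(model, "ddnf_model"))
  if (model$architecture$L != 1)
    stop("`mu_single_layer` applies to single-layer models only", call. = FALSE)
  V <- as_field_matrix(V_star, model)
  M <- model$architecture$M[1]
  gp <- activation_derivative(model$activation, V[1, seq_len(M)])
  mu <- model$beta[1] * drop(model$connectivity$blocks[[1]][[1]] %*% gp)
  attr(mu, "flag") <- max(abs(mu)) < 1
  mu
}

#' Spectral-radius classification of a fixed point
#'
#' Computes all eigenvalues with a dense general (non-symmetric) eigensolver
#' and classifies the fixed point: `rho < 1 - tol` asymptotically stable,
#' `rho > 1 + tol` unstable, otherwise inconclusive (the linearization is
#' silent at `rho = 1`).
#'
#' @param A Square numeric matrix.
#' @param tol Classification tolerance around `rho = 1`. Default `1e-9`.
#' @return List with `rho`, `classification`, `eigenvalues` (complex).
#' @export
spectral_radius_classify <- function(A, tol = 1e-9) {
  A <- as.matrix(A)
  stopifnot(nrow(A) == ncol(A), all(is.finite(A)))
  ev <- tryCatch(eigen(A, only.values = TRUE)$values,
                 error = function(e)
                   stop("dense eigensolver failed (dim ", nrow(A),
                        ", condition est. ", signif(kappa(A), 3), "): ",
                        conditionMessage(e), call. = FALSE))
  rho <- max(Mod(ev))
  cls <- if (rho < 1 - tol) "stable" else if (rho > 1 + tol) "unstable"
  else "inconclusive"
  list(rho = rho, classification = cls, eigenvalues = ev)
}

#' Closed-form eigenvalues of a constant tridiagonal matrix
#'
#' For the `L x L` Toeplitz tridiagonal matrix with diagonal `a`, superdiagonal
#' `b` and subdiagonal `c` with `b*c >= 0`, the eigenvalues are
#' \deqn{\lambda_k = a - 2 \sqrt{bc} \cos(\pi k / (L+1)), \quad k = 1..L.}
#' When `b*c < 0` the spectrum is complex and this closed form does not apply;
#' use the dense eigensolver instead.
#'
#' @param a,b,c Scalar diagonal, super- and subdiagonal entries.
#' @param L Matrix dimension.
#' @return Numeric vector `lambda_k`, `k = 1..L`, in index order.
#' @export
tridiagonal_eigenvalues <- function(a, b, c, L) {
  stopifnot(L >= 1)
  if (b * c < 0)
    stop("closed form requires b*c >= 0; use the dense eigensolver", call. = FALSE)
  k <- seq_len(L)
  a - 2 * sqrt(b * c) * cospi(k / (L + 1))
}

#' Stability spectrum of a single-neuron multilayer chain
#'
#' For `L` layers of one neuron each with identical intra-layer weighted
#' emission rate `K0`, upward transitional rate `K1` and downward rate `K2`,
#' the super-adjacency matrix is the constant tridiagonal matrix with
#' `a = alpha + (1-alpha)*|Omega|*K0`, `b = a*|Omega|*K2`, `c = a*|Omega|*K1`,
#' and its eigenvalues have the closed form
#' \deqn{\mu_k = [\alpha + (1-\alpha)|\Omega| K_0]
#'   [1 - 2 |\Omega| \sqrt{K_1 K_2} \cos(\pi k/(L+1))].}
#' The fixed point is asymptotically stable iff `max_k |mu_k| < 1`. The
#' quantity `[alpha + (1-alpha)*|Omega|*K0] * [1 + 2*|Omega|*sqrt(K1*K2)]`
#' bounds `max_k |mu_k|` from above for every `L` (the bound is approached as
#' `L` grows, since `cos(pi*L/(L+1)) -> -1`), so keeping it below 1 certifies
#' stability for any chain length.
#'
#' Negative `K` inputs fall outside the positive-connectivity hypothesis of
#' the closed form; values are still computed but a warning is issued.
#'
#' @param params A [discretization_params()].
#' @param K0,K1,K2 Weighted emission rates (intra-layer, upward, downward).
#' @param L Number of layers.
#' @return Numeric vector `mu_k` with attributes `flag`
#'   (`max |mu_k| < 1`), `mu_max` (the length-independent closed-form upper
#'   bound), and `abc` (the tridiagonal coefficients).
#' @export
mu_multilayer <- function(params, K0, K1, K2, L) {
  stopifnot(inherits(params, "ddnf_discretization"), L >= 1)
  if (K0 < 0 || K1 < 0 || K2 < 0)
    warning("negative K values are outside the positive-connectivity hypothesis")
  al <- params$alpha
  om <- params$omega
  a <- al + (1 - al) * om * K0
  k <- seq_len(L)
  mu <- a * (1 - 2 * om * sqrt(K1 * K2) * cospi(k / (L + 1)))
  attr(mu, "flag") <- max(abs(mu)) < 1
  attr(mu, "mu_max") <- abs(a) * (1 + 2 * om * sqrt(K1 * K2))
  attr(mu, "abc") <- c(a = a, b = a * om * K2, c = a * om * K1)
  mu
}

#' Transfer-matrix determinant of a (possibly closed) tridiagonal chain
#'
#' Evaluates `det(A - lambda*I)` for the `L x L` tridiagonal matrix with
#' diagonal `diag`, superdiagonal `upper` and subdiagonal `lower` by the 2x2
#' transfer-matrix product (Molinari's formula): the determinant is the trace
#' of
#' \deqn{\prod_{k=L}^{2} \begin{pmatrix} a_k-\lambda & -b_{k-1} c_{k-1} \\ 1 &
#'   0\end{pmatrix} \begin{pmatrix} a_1-\lambda & 0 \\ 1 & 0 \end{pmatrix}.}
#' For the closed graph (corner entries `A[1, L] = c_0`, `A[L, 1] = b_L`
#' joining the last layer back to the first) the corner matrix becomes
#' `[[a_1-lambda, -b_L*c_0], [1, 0]]` and the boundary term
#' `(-1)^(L+1) * (prod(b_i, i=1..L) + prod(c_i, i=0..L-1))` is added.
#'
#' @param diag Length-`L` diagonal `a_k`.
#' @param upper Length-`L-1` superdiagonal `b_k`.
#' @param lower Length-`L-1` subdiagonal `c_k`.
#' @param lam Scalar shift `lambda`.
#' @param closed Logical; evaluate the closed-graph variant.
#' @param b_L,c_0 Corner weights, required when `closed = TRUE` (`L >= 3`).
#' @return The determinant `det(A - lambda*I)`.
#' @export
transfer_matrix_det <- function(diag, upper = numeric(0), lower = numeric(0),
                                lam = 0, closed = FALSE,
                                b_L = NULL, c_0 = NULL) {
  L <- length(diag)
  if (L < 1) stop("chain length must be at least 1", call. = FALSE)
  stopifnot(length(upper) == L - 1, length(lower) == L - 1)
  if (closed) {
    if (is.null(b_L) || is.null(c_0))
      stop("closed chains require the corner weights `b_L` and `c_0`", call. = FALSE)
    if (L < 3)
      stop("closed chains need L >= 3 (corners would collide with the band)",
           call. = FALSE)
  }
  if (L == 1) return(diag[1] - lam)
  P <- base::diag(2)
  for (k in L:2)
    P <- P %*% matrix(c(diag[k] - lam, 1, -upper[k - 1] * lower[k - 1], 0), 2, 2)
  if (!closed)
    return(sum(base::diag(P %*% matrix(c(diag[1] - lam, 1, 0, 0), 2, 2))))
  tr <- sum(base::diag(P %*% matrix(c(diag[1] - lam, 1, -b_L * c_0, 0), 2, 2)))
  tr + (-1)^(L + 1) * (prod(upper) * b_L + prod(lower) * c_0)
}

#' Two-layer single-neuron stability report
#'
#' For two layers of one neuron each with weighted emission rates `K11`, `K22`
#' (intra-layer) and `K12`, `K21` (cross-layer), the super-adjacency matrix is
#' `A = [[a1, b1], [c1, a2]]` with `a_k = alpha + (1-alpha)*|Omega|*Kkk`,
#' `b1 = a1*|Omega|*K12`, `c1 = a2*|Omega|*K21`. The report evaluates
#'
#' * the composite quantities `theta = 1 - |Omega|^2*K12*K21`,
#'   `mu0 = |Omega|*(K11 + K22)`,
#'   `mu = alpha*(K11 + K22) + (1-alpha)*|Omega|*K11*K22`;
#' * the three closed-form conditions `0 < theta < 1`, `mu < 1`,
#'   `(mu*theta + 2 - mu0)^2 < 4*theta*(mu*theta + 1 - mu0)` (flag
#'   `conditions`);
#' * the determinant--trace criterion `|tr(A)| - 1 < det(A) < 1` (flag
#'   `trace_det`), which is exactly equivalent to both eigenvalues lying
#'   inside the unit circle;
#' * the dense eigenvalues and spectral-radius classification.
#'
#' The three closed-form conditions are a sufficient certificate only; see the
#' package vignette for an analysis of their relation to the determinant--trace
#' criterion (in particular the discriminant condition is unattainably strict
#' for `theta < 1`).
#'
#' @param params A [discretization_params()].
#' @param K11,K22,K12,K21 Weighted emission rates.
#' @return A `ddnf_stability` report with the 2x2 matrix, eigenvalues, `rho`,
#'   classification, intermediates (`theta`, `mu0`, `mu`, `a1`, `b1`, `c1`,
#'   `a2`) and the flags described above.
#' @export
two_layer_stability <- function(params, K11, K22, K12, K21) {
  stopifnot(inherits(params, "ddnf_discretization"),
            is.finite(K11), is.finite(K22), is.finite(K12), is.finite(K21))
  al <- params$alpha
  om <- params$omega
  a1 <- al + (1 - al) * om * K11
  a2 <- al + (1 - al) * om * K22
  b1 <- a1 * om * K12
  c1 <- a2 * om * K21
  A <- matrix(c(a1, c1, b1, a2), 2, 2)
  theta <- 1 - om^2 * K12 * K21
  mu0 <- om * (K11 + K22)
  mu <- al * (K11 + K22) + (1 - al) * om * K11 * K22
  cond1 <- theta > 0 && theta < 1
  cond2 <- mu < 1
  cond3 <- (mu * theta + 2 - mu0)^2 < 4 * theta * (mu * theta + 1 - mu0)
  trA <- a1 + a2
  detA <- a1 * a2 - b1 * c1
  trace_det <- (abs(trA) - 1 < detA) && (detA < 1)
  sr <- spectral_radius_classify(A)
  structure(list(A = A, eigenvalues = sr$eigenvalues, rho = sr$rho,
                 classification = sr$classification,
                 theta = theta, mu0 = mu0, mu = mu,
                 a1 = a1, b1 = b1, c1 = c1, a2 = a2,
                 trace = trA, det = detA,
                 flags = c(theta_in_01 = cond1, mu_below_1 = cond2,
                           discriminant = cond3,
                           conditions = cond1 && cond2 && cond3,
                           trace_det = trace_det)),
            class = "ddnf_stability")
}

#' @export
print.ddnf_stability <- function(x, ...) {
  cat("<ddnf_stability>", nrow(x$A), "x", ncol(x$A),
      "| rho =", signif(x$rho, 6), "->", x$classification, "\n")
  if (!is.null(x$mu_single))
    cat("  max |mu_i| =", signif(max(abs(x$mu_single)), 6), "\n")
  if (length(x$flags))
    cat("  flags:", paste(names(x$flags), x$flags, sep = "=", collapse = ", "), "\n")
  invisible(x)
}
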