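#' Discretization parameters of the field equation
#'
#' The nearly exact discretization of the neural field equation replaces the
#' time derivative by a difference quotient with time scale
#' `phi(h) = 1 - exp(-h)`, giving the per-step memory factor
#' `alpha = 1 - phi(h) = exp(-h)` in `(0, 1)`. The spatial integral becomes a
#' Riemann sum over a midpoint grid on the interval `[a, b]` with per-layer
#' weight `beta_k = |Omega| / M_k`.
#'
#' @param h Positive time step.
#' @param domain Numeric `c(a, b)` with `a < b`; `|Omega| = b - a`.
#' @param alpha Optional override of the memory factor (e.g. `alpha = 1`
#'   freezes the field). Defaults to `exp(-h)`.
#' @return An object of class `ddnf_discretization` with fields `h`, `alpha`,
#'   `phi = 1 - alpha`, `a`, `b`, `omega = b - a`.
#' @export
discretization_params <- function(h, domain = c(-20, 20), alpha = NULL) {
  stopifnot(is.numeric(h), length(h) == 1, h > 0,
            is.numeric(domain), length(domain) == 2, domain[1] < domain[2])
  if (is.null(alpha)) alpha <- exp(-h)
  stopifnot(alpha > 0, alpha <= 1)
  structure(list(h = h, alpha = alpha, phi = 1 - alpha,
                 a = domain[1], b = domain[2], omega = diff(domain)),
            class = "ddnf_discretization")
}

#' Midpoint grid on the field domain
#'
#' Coordinates of `M` neurons equispaced on `[a, b]` at the midpoints of the
#' Riemann partition: `x_i = a + (i - 1/2) * |Omega| / M`.
#'
#' @param params A [discretization_params()] (or a numeric `c(a, b)` domain).
#' @param M Number of grid points, at least 1.
#' @return Numeric vector of length `M`.
#' @examples
#' make_grid(c(0, 1), 1)    # 0.5
#' make_grid(c(-20, 20), 200)[2] - make_grid(c(-20, 20), 200)[1]  # 0.2
#' @export
make_grid <- function(params, M) {
  if (is.numeric(params) && length(params) == 2)
    params <- list(a = params[1], b = params[2], omega = diff(params))
  if (!is.numeric(M) || length(M) != 1 || M < 1)
    stop("grid size `M` must be a positive integer", call. = FALSE)
  params$a + (seq_len(M) - 0.5) * params$omega / M
}

#' Multilayer architecture
#'
#' Layer counts, per-layer neuron positions, and the neighbor sets `L_k`: layer
#' 1 talks to layers `{1, 2}`, interior layers to `{k-1, k, k+1}`, layer `L` to
#' `{L-1, L}`, and a single layer only to itself. By default every layer gets
#' the same midpoint grid on the domain; with `stacked = TRUE` (used for chains
#' of one-neuron layers) layer `k` instead receives the single coordinate
#' `z_k = a + (k - 1/2) * |Omega| / L`, so the layer index plays the role of
#' the spatial position.
#'
#' @param L Number of layers.
#' @param M Per-layer neuron counts (scalar recycled, or length-`L` vector).
#' @param domain Numeric `c(a, b)`.
#' @param positions Optional list of per-layer coordinate vectors overriding
#'   the grids.
#' @param stacked Logical; place one-neuron layers along the domain.
#' @return An object of class `ddnf_architecture` with fields `L`, `M`,
#'   `Mmax`, `domain`, `positions`, `neighbors`.
#' @export
layer_architecture <- function(L, M = 1, domain = c(-20, 20),
                               positions = NULL, stacked = FALSE) {
  stopifnot(L >= 1, all(M >= 1))
  L <- as.integer(L)
  M <- rep_len(as.integer(M), L)
  if (is.null(positions)) {
    if (stacked) {
      if (any(M != 1L))
        stop("`stacked = TRUE` requires one neuron per layer", call. = FALSE)
      z <- make_grid(domain, L)
      positions <- as.list(z)
    } else {
      positions <- lapply(M, function(m) make_grid(domain, m))
    }
  }
  stopifnot(length(positions) == L, all(lengths(positions) == M))
  for (p in positions)
    if (any(p < domain[1] - 1e-12) || any(p > domain[2] + 1e-12))
      stop("neuron positions must lie in the domain interval", call. = FALSE)
  neighbors <- lapply(seq_len(L), function(k) {
    if (L == 1) 1L
    else if (k == 1) c(1L, 2L)
    else if (k == L) c(L - 1L, L)
    else c(k - 1L, k, k + 1L)
  })
  structure(list(L = as.integer(L), M = M, Mmax = max(M),
                 domain = domain, positions = positions, neighbors = neighbors),
            class = "ddnf_architecture")
}

#' External stimulus specification
#'
#' The stimulus is `S_i^(k) = nu + U_i^(k)`: a constant resting level `nu`
#' (negative so the field produces no output absent external input) plus a
#' time-constant external input `U`. `U` is either identically zero, the
#' standard-normal density bump `U_i = (2*pi)^(-1/2) * exp(-x_i^2 / 2)`
#' evaluated at the neuron positions, or an explicit per-neuron matrix.
#'
#' @param nu Resting level (typically negative). Default -0.5.
#' @param U `"zero"`, `"gaussian_space"`, or `"custom"`.
#' @param U_values `L x Mmax` matrix of input values when `U = "custom"`.
#' @return An object of class `ddnf_stimulus`.
#' @export
stimulus_spec <- function(nu = -0.5, U = c("zero", "gaussian_space", "custom"),
                          U_values = NULL) {
  U <- match.arg(U)
  stopifnot(is.numeric(nu), length(nu) == 1, is.finite(nu))
  if (U == "custom" && is.null(U_values))
    stop("`U_values` required for a custom stimulus", call. = FALSE)
  structure(list(nu = nu, U = U, U_values = U_values), class = "ddnf_stimulus")
}

stimulus_matrix <- function(stim, arch) {
  S <- matrix(0, arch$L, arch$Mmax)
  for (k in seq_len(arch$L)) {
    x <- arch$positions[[k]]
    u <- switch(stim$U,
                zero = 0,
                gaussian_space = exp(-x^2 / 2) / sqrt(2 * pi),
                custom = stim$U_values[k, seq_len(arch$M[k])])
    S[k, seq_len(arch$M[k])] <- stim$nu + u
  }
  if (any(!is.finite(S))) stop("non-finite stimulus", call. = FALSE)
  S
}

#' Assemble a DDNF model
#'
#' Bundles architecture, discretization, connectivity, activation and stimulus
#' into one model object implementing the update
#' \deqn{V_{i,n+1}^{(k)} = \alpha V_{i,n}^{(k)} + (1-\alpha) \sum_{\ell \in L_k}
#'   \sum_j \beta_\ell W_{ij}^{(k,\ell)} G(V_{j,n}^{(\ell)}) +
#'   (1-\alpha) S_i^{(k)}.}
#'
#' @param architecture A [layer_architecture()].
#' @param discretization A [discretization_params()].
#' @param kernel A [kernel_spec()] used to build the connectivity, or `NULL`
#'   when `connectivity` is supplied directly.
#' @param activation An [activation_spec()].
#' @param stimulus A [stimulus_spec()].
#' @param connectivity Optional prebuilt `ddnf_connectivity` tensor.
#' @return An object of class `ddnf_model`. The per-layer Riemann weights
#'   `beta_k = |Omega| / M_k` and the stimulus matrix `S` are precomputed.
#' @export
ddnf_model <- function(architecture, discretization, kernel = NULL,
                       activation = activation_spec(), stimulus = stimulus_spec(),
                       connectivity = NULL) {
  stopifnot(inherits(architecture, "ddnf_architecture"),
            inherits(discretization, "ddnf_discretization"),
            inherits(activation, "ddnf_activation"),
            inherits(stimulus, "ddnf_stimulus"))
  if (is.null(connectivity)) {
    if (is.null(kernel)) stop("supply either `kernel` or `connectivity`", call. = FALSE)
    connectivity <- build_connectivity(architecture, kernel)
  }
  stopifnot(inherits(connectivity, "ddnf_connectivity"),
            identical(connectivity$M, architecture$M))
  structure(list(
    architecture = architecture,
    discretization = discretization,
    kernel = kernel,
    connectivity = connectivity,
    activation = activation,
    stimulus = stimulus,
    beta = discretization$omega / architecture$M,
    S = stimulus_matrix(stimulus, architecture)
  ), class = "ddnf_model")
}

#' Field state
#'
#' The `L x Mmax` matrix of membrane potentials at one time index, zero-padded
#' on rows of ragged layers (`M_k < Mmax`); padded entries are masked out of
#' the update and stay 0.
#'
#' @param V Numeric matrix (`L x Mmax`), or a scalar recycled over all active
#'   entries when `model` is given.
#' @param n Time index (default 0).
#' @param model Optional `ddnf_model` used to shape a scalar `V`.
#' @return An object of class `ddnf_field`.
#' @export
field_state <- function(V, n = 0, model = NULL) {
  if (length(V) == 1 && !is.null(model)) {
    arch <- model$architecture
    m <- matrix(0, arch$L, arch$Mmax)
    for (k in seq_len(arch$L)) m[k, seq_len(arch$M[k])] <- V
    V <- m
  }
  V <- as.matrix(V)
  if (any(!is.finite(V))) stop("field values must be finite", call. = FALSE)
  structure(list(V = V, n = n), class = "ddnf_field")
}

as_field_matrix <- function(V, model) {
  arch <- model$architecture
  if (inherits(V, "ddnf_field")) V <- V$V
  if (length(V) == 1) V <- field_state(V, model = model)$V
  V <- as.matrix(V)
  if (nrow(V) != arch$L || ncol(V) != arch$Mmax)
    stop("field shape (", nrow(V), "x", ncol(V), ") does not match the model (",
         arch$L, "x", arch$Mmax, ")", call. = FALSE)
  V
}

#' @export
print.ddnf_model <- function(x, ...) {
  a <- x$architecture
  cat("<ddnf_model> L =", a$L, "layer(s), M =",
      if (length(unique(a$M)) == 1) a$M[1] else paste(range(a$M), collapse = "-"),
      "| domain [", a$domain[1], ",", a$domain[2], "], h =", x$discretization$h,
      "(alpha =", signif(x$discretization$alpha, 6), ")\n")
  cat("  activation:", x$activation$family,
      "| stimulus: nu =", x$stimulus$nu, ", U =", x$stimulus$U,
      "| W0 =", signif(x$connectivity$W0, 6), "\n")
  invisible(x)
}

#' @export
print.ddnf_field <- function(x, ...) {
  cat("<ddnf_field> n =", x$n, ",", nrow(x$V), "x", ncol(x$V),
      "| range [", signif(min(x$V), 6), ",", signif(max(x$V), 6), "]\n")
  invisible(x)
}
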