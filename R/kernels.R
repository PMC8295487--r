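#' Connection-intensity (kernel) specification
#'
#' Describes the lateral connectivity function `W(x, y)` between two neuron
#' positions. Four families are supported:
#'
#' * `"gaussian"`: `Gau(x, y, sigma) = (sigma * sqrt(2*pi))^-1 *
#'   exp(-||x - y||^2 / (2 * sigma^2))` -- normalized so it integrates to 1.
#' * `"laplacian"`: `Lap(x, y, sigma) = (2*sigma)^-1 * exp(-||x - y|| / sigma)`.
#' * `"tanh"`: `Thyp(x, y, beta, r) = 1 + tanh(beta * x * y + r)`. Note this is
#'   an inner-product kernel and is asymmetric by construction; no
#'   symmetrization is applied.
#' * `"difference"`: the "Mexican hat" `sigma_plus * base(x, y, p1) -
#'   sigma_minus * base(x, y, p2)`, where `base` is one of the three families
#'   above. Short-range excitation (`sigma_plus`, width `sigma1`/`beta1`) minus
#'   long-range inhibition (`sigma_minus`, width `sigma2`/`beta2`).
#'
#' Positions are scalar coordinates on a one-dimensional domain; the distance
#' `||x - y||` is the absolute difference (Euclidean norm in 1-D).
#'
#' @param family One of `"gaussian"`, `"laplacian"`, `"tanh"`, `"difference"`.
#' @param sigma Positive width of the gaussian/laplacian kernel.
#' @param beta,r Slope and offset of the tanh kernel.
#' @param sigma_plus,sigma_minus Nonnegative excitatory / inhibitory amplitudes
#'   of the difference kernel.
#' @param sigma1,sigma2 Positive widths of the two difference components
#'   (gaussian or laplacian base).
#' @param beta1,beta2 Slopes of the two components when `base_family = "tanh"`.
#' @param base_family Base family of the difference kernel: `"gaussian"`
#'   (default), `"laplacian"`, or `"tanh"`.
#' @return An object of class `ddnf_kernel`.
#' @seealso [kernel_preset()], [evaluate_kernel()], [build_connectivity()]
#' @examples
#' k <- kernel_spec("difference", sigma_plus = 4, sigma_minus = 1.5,
#'                  sigma1 = 1, sigma2 = 4.5)
#' evaluate_kernel(k, 0, 0)
#' @export
kernel_spec <- function(family = c("gaussian", "laplacian", "tanh", "difference"),
                        sigma = 1, beta = 1, r = 0,
                        sigma_plus = 1, sigma_minus = 1,
                        sigma1 = 1, sigma2 = 1,
                        beta1 = 1, beta2 = 1,
                        base_family = c("gaussian", "laplacian", "tanh")) {
  family <- match.arg(family)
  base_family <- match.arg(base_family)
  spec <- structure(list(family = family, base_family = base_family,
                         sigma = sigma, beta = beta, r = r,
                         sigma_plus = sigma_plus, sigma_minus = sigma_minus,
                         sigma1 = sigma1, sigma2 = sigma2,
                         beta1 = beta1, beta2 = beta2),
                    class = "ddnf_kernel")
  validate_kernel_spec(spec)
  spec
}

validate_kernel_spec <- function(spec) {
  stopifnot(inherits(spec, "ddnf_kernel"))
  fam <- spec$family
  if (fam %in% c("gaussian", "laplacian")) {
    if (!is.finite(spec$sigma) || spec$sigma <= 0)
      stop("kernel width `sigma` must be strictly positive", call. = FALSE)
  }
  if (fam == "difference") {
    if (spec$sigma_plus < 0 || spec$sigma_minus < 0)
      stop("difference amplitudes `sigma_plus`, `sigma_minus` must be nonnegative",
           call. = FALSE)
    if (spec$base_family %in% c("gaussian", "laplacian")) {
      if (spec$sigma1 <= 0 || spec$sigma2 <= 0)
        stop("difference component widths `sigma1`, `sigma2` must be strictly positive",
             call. = FALSE)
    }
  }
  invisible(spec)
}

#' Named kernel presets
#'
#' Shorthand parameter sets used by the shipped simulation scenarios.
#' `"gauss_diff_sec35"` is the scenario default (difference of normalized
#' Gaussians with `sigma_plus = 4`, `sigma_minus = 1.5`, `sigma1 = 1`,
#' `sigma2 = 4.5`). The `"fig3_*"` presets use `sigma_plus = 4.5` and cover the
#' gaussian, laplacian and tanh bases.
#'
#' @param name One of `"gauss_diff_sec35"`, `"fig3_gauss_diff"`,
#'   `"fig3_lap_diff"`, `"fig3_tanh_diff"`.
#' @return A `ddnf_kernel` object.
#' @export
kernel_preset <- function(name = c("gauss_diff_sec35", "fig3_gauss_diff",
                                   "fig3_lap_diff", "fig3_tanh_diff")) {
  name <- match.arg(name)
  switch(name,
    gauss_diff_sec35 = kernel_spec("difference", sigma_plus = 4,
                                   sigma_minus = 1.5, sigma1 = 1, sigma2 = 4.5,
                                   base_family = "gaussian"),
    fig3_gauss_diff = kernel_spec("difference", sigma_plus = 4.5,
                                  sigma_minus = 1.5, sigma1 = 1, sigma2 = 4.5,
                                  base_family = "gaussian"),
    fig3_lap_diff = kernel_spec("difference", sigma_plus = 4.5,
                                sigma_minus = 1.5, sigma1 = 1, sigma2 = 4.5,
                                base_family = "laplacian"),
    fig3_tanh_diff = kernel_spec("difference", sigma_plus = 4.5,
                                 sigma_minus = 1.5, beta1 = 0.1, beta2 = 0.5,
                                 r = -0.1, base_family = "tanh"))
}

kernel_base_value <- function(family, x, y, sigma = 1, beta = 1, r = 0) {
  switch(family,
    gaussian = exp(-((x - y)^2) / (2 * sigma^2)) / (sigma * sqrt(2 * pi)),
    laplacian = exp(-abs(x - y) / sigma) / (2 * sigma),
    tanh = 1 + tanh(beta * x * y + r),
    stop("unknown kernel family: ", family, call. = FALSE))
}

#' Evaluate a connectivity kernel at a pair of positions
#'
#' Vectorized over `x` and `y`.
#'
#' @param spec A [kernel_spec()].
#' @param x,y Finite scalar coordinates (or equal-length vectors).
#' @return Kernel value(s) `W(x, y)`.
#' @export
evaluate_kernel <- function(spec, x, y) {
  validate_kernel_spec(spec)
  if (any(!is.finite(x)) || any(!is.finite(y)))
    stop("kernel coordinates must be finite", call. = FALSE)
  if (spec$family != "difference")
    return(kernel_base_value(spec$family, x, y,
                             sigma = spec$sigma, beta = spec$beta, r = spec$r))
  if (spec$base_family == "tanh") {
    p1 <- kernel_base_value("tanh", x, y, beta = spec$beta1, r = spec$r)
    p2 <- kernel_base_value("tanh", x, y, beta = spec$beta2, r = spec$r)
  } else {
    p1 <- kernel_base_value(spec$base_family, x, y, sigma = spec$sigma1)
    p2 <- kernel_base_value(spec$base_family, x, y, sigma = spec$sigma2)
  }
  spec$sigma_plus * p1 - spec$sigma_minus * p2
}

#' Assemble the block connectivity tensor of a multilayer architecture
#'
#' Block `(k, l)` holds the weights `W_ij^(k,l) = W(x_i^(k), y_j^(l))` between
#' every neuron `i` on layer `k` and every neuron `j` on layer `l`, for `l` in
#' the neighbor set `L_k` (the layer itself plus adjacent layers). Blocks for
#' non-adjacent layers are structurally zero and are not stored; use
#' [connectivity_block()] to retrieve any block including the zeros.
#'
#' @param arch A [layer_architecture()].
#' @param spec A [kernel_spec()], or `NULL` together with `blocks` to supply
#'   precomputed block matrices.
#' @param blocks Optional named list of precomputed blocks (`"k,l"` keys);
#'   advanced use, e.g. direct numeric weight overrides.
#' @return An object of class `ddnf_connectivity` with fields `blocks`
#'   (list-of-lists indexed `[[k]][[l]]`), `M` (per-layer sizes), and `W0`
#'   (maximum absolute weight, see [kernel_bound()]).
#' @export
build_connectivity <- function(arch, spec = NULL, blocks = NULL) {
  stopifnot(inherits(arch, "ddnf_architecture"))
  if (any(arch$M < 1)) stop("every layer must contain at least one neuron", call. = FALSE)
  L <- arch$L
  out <- vector("list", L)
  for (k in seq_len(L)) {
    out[[k]] <- vector("list", L)
    for (l in arch$neighbors[[k]]) {
      if (!is.null(blocks)) {
        blk <- blocks[[paste(k, l, sep = ",")]]
        if (is.null(blk)) stop("missing block (", k, ",", l, ")", call. = FALSE)
        blk <- matrix(as.numeric(blk), arch$M[k], arch$M[l])
      } else {
        blk <- outer(arch$positions[[k]], arch$positions[[l]],
                     function(xx, yy) evaluate_kernel(spec, xx, yy))
      }
      if (any(!is.finite(blk)))
        stop("non-finite connectivity weight in block (", k, ",", l, ")",
             call. = FALSE)
      out[[k]][[l]] <- blk
    }
  }
  w0 <- 0
  for (k in seq_len(L))
    for (l in arch$neighbors[[k]])
      w0 <- max(w0, max(abs(out[[k]][[l]])))
  structure(list(blocks = out, M = arch$M, L = L,
                 neighbors = arch$neighbors, W0 = w0),
            class = "ddnf_connectivity")
}

#' Retrieve one block of a connectivity tensor
#'
#' Returns the stored `M_k x M_l` weight matrix, or the zero matrix when layer
#' `l` is not in the neighbor set of layer `k`.
#'
#' @param W A `ddnf_connectivity` tensor.
#' @param k,l Layer indices.
#' @export
connectivity_block <- function(W, k, l) {
  stopifnot(inherits(W, "ddnf_connectivity"))
  if (k < 1 || k > W$L || l < 1 || l > W$L)
    stop("layer index out of range", call. = FALSE)
  blk <- W$blocks[[k]][[l]]
  if (is.null(blk)) matrix(0, W$M[k], W$M[l]) else blk
}

#' Uniform bound on the connectivity weights
#'
#' The maximum absolute entry `W0` over all blocks, used in the Mann-iteration
#' contraction diagnostic (`C * W0 * |Omega| <= 1` with `C` the Lipschitz
#' constant of the pulse-emission function).
#'
#' @param W A `ddnf_connectivity` tensor.
#' @return Nonnegative scalar.
#' @export
kernel_bound <- function(W) {
  stopifnot(inherits(W, "ddnf_connectivity"))
  W$W0
}

#' @export
print.ddnf_kernel <- function(x, ...) {
  cat("<ddnf_kernel> family:", x$family)
  if (x$family == "difference") cat(" of", x$base_family)
  cat("\n")
  ps <- switch(x$family,
    gaussian = , laplacian = c(sigma = x$sigma),
    tanh = c(beta = x$beta, r = x$r),
    difference = c(`sigma+` = x$sigma_plus, `sigma-` = x$sigma_minus,
                   if (x$base_family == "tanh") c(beta1 = x$beta1, beta2 = x$beta2, r = x$r)
                   else c(sigma1 = x$sigma1, sigma2 = x$sigma2)))
  cat(" ", paste(names(ps), signif(unname(ps), 6), sep = "=", collapse = ", "), "\n")
  invisible(x)
}

#' @export
print.ddnf_connectivity <- function(x, ...) {
  cat("<ddnf_connectivity>", x$L, "layer(s), sizes:",
      paste(x$M, collapse = ", "), "| W0 =", signif(x$W0, 6), "\n")
  invisible(x)
}
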