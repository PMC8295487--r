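#' Pulse-emission rate function specification
#'
#' The gain `G` mapping membrane potential to firing activity. Two families:
#'
#' * `"sigmoid"`: `G(v) = (1 + exp(-theta * (v - v0)))^-1`, steepness
#'   `theta > 0`, threshold `v0`.
#' * `"heaviside"`: the indicator of the open interval `(v0, Inf)`, i.e. 1 for
#'   `v > v0` and 0 otherwise (the threshold itself maps to 0).
#'
#' @param family `"sigmoid"` or `"heaviside"`.
#' @param theta Sigmoid steepness (ignored for heaviside). Default 1.
#' @param v0 Threshold. Default 0.
#' @return An object of class `ddnf_activation`.
#' @export
activation_spec <- function(family = c("sigmoid", "heaviside"),
                            theta = 1, v0 = 0) {
  family <- match.arg(family)
  if (family == "sigmoid" && (!is.finite(theta) || theta <= 0))
    stop("sigmoid steepness `theta` must be strictly positive", call. = FALSE)
  structure(list(family = family, theta = theta, v0 = v0),
            class = "ddnf_activation")
}

#' Evaluate the pulse-emission function
#'
#' @param spec An [activation_spec()].
#' @param v Membrane potential(s).
#' @return `G(v)`, in `(0, 1)` for the sigmoid and `{0, 1}` for the Heaviside.
#' @export
evaluate_activation <- function(spec, v) {
  stopifnot(inherits(spec, "ddnf_activation"))
  if (spec$family == "sigmoid")
    1 / (1 + exp(-spec$theta * (v - spec$v0)))
  else
    as.numeric(v > spec$v0)
}

#' Derivative of the pulse-emission function
#'
#' For the sigmoid, `G'(v) = theta * G(v) * (1 - G(v))`. The Heaviside
#' derivative exists only distributionally: it is 0 away from the threshold and
#' a Dirac mass at `v0`; evaluating within `tol` of the threshold signals the
#' singularity as an error rather than silently returning 0.
#'
#' @param spec An [activation_spec()].
#' @param v Membrane potential(s).
#' @param tol Absolute half-width of the forbidden band around the Heaviside
#'   threshold. Default `1e-9`.
#' @export
activation_derivative <- function(spec, v, tol = 1e-9) {
  stopifnot(inherits(spec, "ddnf_activation"))
  if (spec$family == "sigmoid") {
    g <- evaluate_activation(spec, v)
    return(spec$theta * g * (1 - g))
  }
  if (any(abs(v - spec$v0) <= tol))
    stop("Heaviside derivative requested at the threshold (Dirac mass at v0)",
         call. = FALSE)
  rep(0, length(v))
}

#' Lipschitz constant of the pulse-emission function
#'
#' The sigmoid derivative `theta * G * (1 - G)` is maximized at `G = 1/2`,
#' giving the constant `theta / 4`. The Heaviside function is discontinuous and
#' has no finite Lipschitz constant; requesting it is an error.
#'
#' @param spec An [activation_spec()].
#' @return `theta / 4` for the sigmoid.
#' @export
lipschitz_constant <- function(spec) {
  stopifnot(inherits(spec, "ddnf_activation"))
  if (spec$family == "heaviside")
    stop("the Heaviside function is discontinuous and not Lipschitz", call. = FALSE)
  spec$theta / 4
}

#' @export
print.ddnf_activation <- function(x, ...) {
  if (x$family == "sigmoid")
    cat("<ddnf_activation> sigmoid, theta =", x$theta, ", v0 =", x$v0, "\n")
  else
    cat("<ddnf_activation> heaviside, v0 =", x$v0, "\n")
  invisible(x)
}
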