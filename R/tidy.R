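#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy a trajectory into a long tibble
#'
#' @param x A `ddnf_trajectory`.
#' @param ... Unused.
#' @return A tibble with columns `n` (time index), `layer`, `neuron`,
#'   `position` (grid coordinate), `value` (membrane potential), one row per
#'   active entry per time step.
#' @export
tidy.ddnf_trajectory <- function(x, ...) {
  arch <- x$model$architecture
  out <- vector("list", arch$L)
  for (k in seq_len(arch$L)) {
    m <- arch$M[k]
    out[[k]] <- tibble::tibble(
      n = rep(0:x$N, times = m),
      layer = k,
      neuron = rep(seq_len(m), each = x$N + 1),
      position = rep(arch$positions[[k]], each = x$N + 1),
      value = as.vector(x$V[, k, seq_len(m)]))
  }
  do.call(rbind, out)
}

#' One-row summary of a trajectory
#'
#' @param x A `ddnf_trajectory`.
#' @param tol Convergence tolerance on the sup-norm step. Default `1e-6`.
#' @param ... Unused.
#' @return A tibble: `steps`, `layers`, `neurons`, final-field `final_min` /
#'   `final_max` / `final_mean`, and `converged_step` (first step whose
#'   sup-norm change is below `tol`; `NA` if never).
#' @export
glance.ddnf_trajectory <- function(x, tol = 1e-6, ...) {
  fin <- x$V[x$N + 1, , , drop = FALSE]
  steps <- if (x$N >= 1)
    vapply(seq_len(x$N), function(n)
      max(abs(x$V[n + 1, , ] - x$V[n, , ])), numeric(1))
  else numeric(0)
  conv <- which(steps < tol)
  tibble::tibble(
    steps = x$N,
    layers = x$model$architecture$L,
    neurons = sum(x$model$architecture$M),
    final_min = min(fin), final_max = max(fin), final_mean = mean(fin),
    converged_step = if (length(conv)) conv[1] else NA_integer_)
}

#' Tidy the eigenvalues of a stability report
#'
#' @param x A `ddnf_stability`.
#' @param ... Unused.
#' @return A tibble with `real`, `imag`, `modulus` per eigenvalue.
#' @export
tidy.ddnf_stability <- function(x, ...) {
  tibble::tibble(real = Re(x$eigenvalues), imag = Im(x$eigenvalues),
                 modulus = Mod(x$eigenvalues))
}

#' One-row summary of a stability report
#'
#' @param x A `ddnf_stability`.
#' @param ... Unused.
#' @export
glance.ddnf_stability <- function(x, ...) {
  tibble::tibble(
    dim = nrow(x$A),
    rho = x$rho,
    classification = x$classification,
    mu_max = if (!is.null(x$mu_single)) max(abs(x$mu_single)) else NA_real_)
}

#' Tidy a Mann-iteration residual history
#'
#' @param x A `ddnf_mann`.
#' @param ... Unused.
#' @export
tidy.ddnf_mann <- function(x, ...) {
  tibble::tibble(iteration = seq_along(x$residuals), residual = x$residuals)
}

#' One-row summary of a Mann iteration
#'
#' @param x A `ddnf_mann`.
#' @param ... Unused.
#' @export
glance.ddnf_mann <- function(x, ...) {
  tibble::tibble(converged = x$converged, iterations = x$iterations,
                 final_residual = x$residuals[x$iterations],
                 contraction = x$contraction, guaranteed = x$guaranteed)
}

#' Space-time plot of a trajectory
#'
#' Single-layer trajectories are drawn as a raster of `V` over time and
#' position; multilayer ones over time and layer index.
#'
#' @param object A `ddnf_trajectory`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.ddnf_trajectory <- function(object, ...) {
  df <- tidy(object)
  single <- object$model$architecture$L == 1
  if (single) {
    ggplot2::ggplot(df, ggplot2::aes(x = .data$n, y = .data$position,
                                     fill = .data$value)) +
      ggplot2::geom_raster() +
      ggplot2::labs(x = "time step n", y = "position x",
                    fill = "V") +
      ggplot2::scale_fill_viridis_c()
  } else {
    ggplot2::ggplot(df, ggplot2::aes(x = .data$n, y = .data$layer,
                                     fill = .data$value)) +
      ggplot2::geom_raster() +
      ggplot2::labs(x = "time step n", y = "layer k", fill = "V") +
      ggplot2::scale_fill_viridis_c()
  }
}

#' Cobweb plot of one field coordinate
#'
#' Draws the iteration path of [cobweb()] against the diagonal.
#'
#' @param traj A `ddnf_trajectory`.
#' @param layer,i Coordinate to probe.
#' @return A ggplot.
#' @export
plot_cobweb <- function(traj, layer = 1, i = 1) {
  cw <- cobweb(traj, layer, i)
  ggplot2::ggplot(cw, ggplot2::aes(x = .data$x, y = .data$y)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 2,
                         colour = "grey50") +
    ggplot2::geom_path(colour = "firebrick") +
    ggplot2::geom_point(data = cw[1, ], colour = "darkgreen", size = 2) +
    ggplot2::labs(x = expression(V[n]), y = expression(V[n + 1]))
}

#' @importFrom ggplot2 .data
NULL
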