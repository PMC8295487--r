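#' Reference simulation scenarios
#'
#' Fully resolved model configurations for the seven shipped scenarios. All
#' share the defaults: domain `[-20, 20]`, `h = 0.8`, `N = 100` steps,
#' difference-of-Gaussians kernel (`sigma_plus = 4`, `sigma_minus = 1.5`,
#' `sigma1 = 1`, `sigma2 = 4.5`), resting level `nu = -0.5`, and initial field
#' `V_0 = -1.5` everywhere. They differ in the activation / input / layout
#' combination:
#'
#' | name  | layout              | activation | external input U |
#' |-------|---------------------|-----------|-------------------|
#' | fig5  | 1 layer, M = 200    | heaviside | zero              |
#' | fig6  | 1 layer, M = 200    | sigmoid   | zero              |
#' | fig7  | 1 layer, M = 200    | heaviside | gaussian bump     |
#' | fig8  | 1 layer, M = 200    | sigmoid   | gaussian bump     |
#' | fig9  | 200 layers, M = 1   | sigmoid   | zero              |
#' | fig10 | 200 layers, M = 1   | sigmoid   | gaussian bump     |
#' | fig11 | 1 layer, M = 200    | sigmoid   | gaussian bump, swept over alpha |
#'
#' The sigmoid uses `theta = 1`, `v0 = 0` by default. The multilayer scenarios
#' place one neuron per layer at `z_k = a + (k - 1/2)|Omega|/L` and couple the
#' chain through the kernel at those coordinates. `fig11` re-runs the
#' single-layer model on a grid of 50 evenly spaced memory factors
#' `alpha = 0.02, 0.04, ..., 1` (including `alpha = 1` exactly, the frozen
#' case) and records the final field for each.
#'
#' @param name Scenario name, `"fig5"` ... `"fig11"`.
#' @param M Neurons per layer (single-layer scenarios). Default 200.
#' @param L Layers for the multilayer scenarios. Default 200.
#' @param N Steps. Default 100.
#' @param h Time step. Default 0.8.
#' @param theta,v0 Sigmoid parameters. Defaults 1 and 0.
#' @param nu Resting level. Default -0.5.
#' @param V0 Initial field value. Default -1.5.
#' @param domain Field domain. Default `c(-20, 20)`.
#' @param kernel Kernel override; default [kernel_preset]`("gauss_diff_sec35")`.
#' @param probe Probe coordinate for the cobweb output: a position on the
#'   domain (single layer) or a layer index (multilayer), mapped to the
#'   nearest grid point. Default per scenario.
#' @param n_alpha Size of the `fig11` alpha grid. Default 50.
#' @return A `ddnf_scenario`: the resolved `model`, `N`, `V0`, `probe`, and
#'   for `fig11` the `alpha_grid`.
#' @export
scenario_spec <- function(name = c("fig5", "fig6", "fig7", "fig8",
                                   "fig9", "fig10", "fig11"),
                          M = 200, L = 200, N = 100, h = 0.8,
                          theta = 1, v0 = 0, nu = -0.5, V0 = -1.5,
                          domain = c(-20, 20),
                          kernel = kernel_preset("gauss_diff_sec35"),
                          probe = NULL, n_alpha = 50) {
  name <- match.arg(name)
  multilayer <- name %in% c("fig9", "fig10")
  activation <- switch(name,
    fig5 = , fig7 = activation_spec("heaviside", v0 = v0),
    activation_spec("sigmoid", theta = theta, v0 = v0))
  U <- switch(name,
    fig5 = , fig6 = , fig9 = "zero",
    "gaussian_space")
  arch <- if (multilayer)
    layer_architecture(L, 1, domain = domain, stacked = TRUE)
  else
    layer_architecture(1, M, domain = domain)
  disc <- discretization_params(h, domain = domain)
  model <- ddnf_model(arch, disc, kernel = kernel, activation = activation,
                      stimulus = stimulus_spec(nu = nu, U = U))
  if (is.null(probe))
    probe <- switch(name, fig6 = 9.548, fig7 = 2.111, fig8 = -18.79,
                    fig9 = 114, fig10 = 114, 0)
  structure(list(name = name, model = model, N = N, V0 = V0, probe = probe,
                 alpha_grid = if (name == "fig11") seq_len(n_alpha) / n_alpha),
            class = "ddnf_scenario")
}

probe_index <- function(spec) {
  arch <- spec$model$architecture
  if (arch$L == 1) {
    i <- which.min(abs(arch$positions[[1]] - spec$probe))
    c(layer = 1L, i = as.integer(i))
  } else {
    c(layer = as.integer(min(max(1, round(spec$probe)), arch$L)), i = 1L)
  }
}

#' Run a scenario and write its outputs
#'
#' Simulates the scenario, then writes into `out_dir`:
#'
#' * `trajectory.csv` -- one row per time step (`fig11`: one row per alpha
#'   with the final field),
#' * `stability.json` -- the spectral report at the final state (skipped with
#'   a note when the Heaviside Jacobian is undefined on the threshold),
#' * `cobweb.csv` -- the cobweb polyline at the probe index,
#' * `summary.json` -- final-field statistics and the first step at which the
#'   sup-norm change drops below `1e-6`,
#' * `manifest.json` -- file list with md5 checksums.
#'
#' Runs are deterministic: repeated invocations produce byte-identical CSVs.
#'
#' @param spec A [scenario_spec()] (or a scenario name).
#' @param out_dir Output directory, created if needed.
#' @param ... Passed to [scenario_spec()] when `spec` is a name.
#' @return Invisibly, a list with the trajectory, the summary, and the file
#'   manifest.
#' @export
run_scenario <- function(spec, out_dir, ...) {
  if (is.character(spec)) spec <- scenario_spec(spec, ...)
  stopifnot(inherits(spec, "ddnf_scenario"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

  if (spec$name == "fig11") {
    base <- spec$model
    arch <- base$architecture
    finals <- matrix(0, length(spec$alpha_grid), arch$Mmax)
    for (ai in seq_along(spec$alpha_grid)) {
      d <- base$discretization
      d$alpha <- spec$alpha_grid[ai]
      d$phi <- 1 - d$alpha
      m <- base
      m$discretization <- d
      tr <- simulate_ddnf(m, V0 = spec$V0, N = spec$N)
      finals[ai, ] <- tr$V[spec$N + 1, 1, ]
    }
    path <- file.path(out_dir, "trajectory.csv")
    hdr <- c("alpha", paste0("1:", seq_len(arch$Mmax)))
    write_full_precision_csv(cbind(spec$alpha_grid, finals), hdr, path)
    traj <- simulate_ddnf(base, V0 = spec$V0, N = spec$N)  # native-alpha run
  } else {
    traj <- simulate_ddnf(spec$model, V0 = spec$V0, N = spec$N)
    write_trajectory_csv(traj, file.path(out_dir, "trajectory.csv"))
  }

  report <- tryCatch(
    build_jacobian(spec$model, trajectory_state(traj)),
    error = function(e) conditionMessage(e))
  if (inherits(report, "ddnf_stability"))
    write_stability_json(report, file.path(out_dir, "stability.json"))

  if (spec$N >= 1) {
    pi <- probe_index(spec)
    cw <- cobweb(traj, pi["layer"], pi["i"])
    write_full_precision_csv(cbind(cw$x, cw$y, cw$n),
                             c("x", "y", "n"), file.path(out_dir, "cobweb.csv"))
  }

  fin <- traj$V[spec$N + 1, , , drop = FALSE]
  steps <- if (spec$N >= 1)
    vapply(seq_len(spec$N), function(n)
      max(abs(traj$V[n + 1, , ] - traj$V[n, , ])), numeric(1))
  else numeric(0)
  conv <- which(steps < 1e-6)
  summary <- list(
    scenario = spec$name, N = spec$N,
    final_min = min(fin), final_max = max(fin), final_mean = mean(fin),
    convergence_step = if (length(conv)) conv[1] else NA_integer_,
    stability = if (inherits(report, "ddnf_stability"))
      list(rho = report$rho, classification = report$classification)
    else list(note = as.character(report)))
  jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       na = "null")

  manifest <- write_manifest(out_dir)
  invisible(list(trajectory = traj, summary = summary, manifest = manifest))
}

#' Seeded random model generator
#'
#' Draws a random DDNF instance for property tests and stability experiments.
#' The reference field is the zero field, made an exact fixed point by the
#' custom stimulus `S = -Gamma %*% G(0)`; the `regime` argument then rescales
#' the connectivity around that fixed point:
#'
#' * `"stable"` (single layer): weights rescaled so `max_i |mu_i| = 0.85 < 0.9`
#'   at the zero field, certifying asymptotic stability.
#' * `"unstable"` (single layer): weights rescaled so the Jacobian spectral
#'   radius is `1.2 > 1` (the Jacobian eigenvalues are affine in the scale,
#'   so the scale is found by a monotone search on the dense spectrum).
#' * `"unconstrained"`: no rescaling; `L` and `M_k` drawn from their ranges.
#'
#' Identical seeds produce bit-identical models; the global RNG state is left
#' untouched.
#'
#' @param seed Integer seed.
#' @param regime `"unconstrained"`, `"stable"`, or `"unstable"`.
#' @param L_range,M_range Integer ranges for layer count / per-layer neurons
#'   (unconstrained regime; stability regimes force `L = 1`).
#' @param theta_range Sigmoid steepness range.
#' @param domain Field domain. Default `c(0, 1)`.
#' @param h Time step. Default 0.8.
#' @return A list: `model` (`ddnf_model`) and `V_star` (the zero reference
#'   field, an exact fixed point).
#' @export
generate_fixture <- function(seed, regime = c("unconstrained", "stable", "unstable"),
                             L_range = c(1, 3), M_range = c(2, 5),
                             theta_range = c(0.5, 3), domain = c(0, 1),
                             h = 0.8) {
  regime <- match.arg(regime)
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()), add = TRUE)
  set.seed(as.integer(seed))

  draw_int <- function(rng, n = 1) {
    v <- seq(rng[1], rng[2])
    v[sample.int(length(v), n, replace = TRUE)]
  }
  L <- if (regime == "unconstrained") draw_int(L_range) else 1L
  M <- draw_int(M_range, L)
  arch <- layer_architecture(L, M, domain = domain)
  disc <- discretization_params(h, domain = domain)
  kern <- kernel_spec("gaussian", sigma = stats::runif(1, 0.2, 2))
  act <- activation_spec("sigmoid", theta = stats::runif(1, theta_range[1], theta_range[2]))
  W <- build_connectivity(arch, kern)
  # random sign/magnitude jitter so draws are not all positive-definite-like
  for (k in seq_len(L))
    for (l in arch$neighbors[[k]])
      W$blocks[[k]][[l]] <- W$blocks[[k]][[l]] *
        matrix(stats::runif(M[k] * M[l], -1, 1), M[k], M[l])

  scale_blocks <- function(W, s) {
    for (k in seq_len(L))
      for (l in arch$neighbors[[k]])
        W$blocks[[k]][[l]] <- W$blocks[[k]][[l]] * s
    W$W0 <- W$W0 * abs(s)
    W
  }
  finish <- function(W) {
    # make the zero field an exact fixed point: S = -Gamma %*% G(0)
    m0 <- ddnf_model(arch, disc, activation = act, connectivity = W,
                     stimulus = stimulus_spec(nu = 0, U = "zero"))
    Z <- matrix(0, L, arch$Mmax)
    S <- -(coupling_map(Z, m0) - m0$S)
    ddnf_model(arch, disc, activation = act, connectivity = W,
               stimulus = stimulus_spec(nu = 0, U = "custom", U_values = S))
  }

  if (regime == "stable") {
    # scale on the absolute row sums so the certificate covers mixed-sign
    # weights: ||A||_inf <= alpha + (1-alpha) * 0.85 < 1, and a fortiori
    # max |mu_i| <= 0.85 < 0.9
    gp <- activation_derivative(act, rep(0, M[1]))
    mu_abs <- (disc$omega / M[1]) *
      rowSums(abs(sweep(W$blocks[[1]][[1]], 2, gp, `*`)))
    if (max(mu_abs) == 0) stop("degenerate draw: zero connectivity", call. = FALSE)
    W <- scale_blocks(W, 0.85 / max(mu_abs))
    mdl <- finish(W)
  } else if (regime == "unstable") {
    al <- disc$alpha
    gp <- activation_derivative(act, rep(0, M[1]))
    B0 <- (disc$omega / M[1]) * sweep(W$blocks[[1]][[1]], 2, gp, `*`)
    lam <- eigen(B0, only.values = TRUE)$values
    if (max(Mod(lam)) == 0) stop("degenerate draw: zero coupling", call. = FALSE)
    rho_at <- function(s) max(Mod(al + s * (1 - al) * lam))
    s <- 1
    tries <- 0
    while (rho_at(s) < 1.2 && tries < 60) { s <- s * 1.5; tries <- tries + 1 }
    if (rho_at(s) < 1.2) stop("could not reach the unstable regime", call. = FALSE)
    s <- stats::uniroot(function(z) rho_at(z) - 1.2, c(0, s))$root
    W <- scale_blocks(W, s)
    mdl <- finish(W)
  } else {
    mdl <- finish(W)
  }
  list(model = mdl, V_star = field_state(0, model = mdl))
}

#' @export
print.ddnf_scenario <- function(x, ...) {
  cat("<ddnf_scenario>", x$name, "| N =", x$N, "| V0 =", x$V0,
      "| probe =", x$probe, "\n")
  print(x$model)
  invisible(x)
}
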