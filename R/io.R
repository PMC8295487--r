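# Serialization: trajectories as CSV (full double precision, %.17g), reports
# and manifests as JSON. Writers are deterministic so repeated runs are
# byte-identical and round trips are exact.

write_full_precision_csv <- function(mat, header, path) {
  mat <- as.matrix(mat)
  con <- file(path, open = "wb")  # binary: fixed \n line endings
  on.exit(close(con))
  writeLines(paste(header, collapse = ","), con, sep = "\n")
  if (nrow(mat))
    writeLines(apply(mat, 1, function(r)
      paste(sprintf("%.17g", r), collapse = ",")), con, sep = "\n")
  invisible(path)
}

#' Write a trajectory to CSV
#'
#' One row per time step: first column `n`, remaining columns headed
#' `k:i` (layer:neuron) over the active entries, values at full double
#' precision (17 significant digits).
#'
#' @param traj A `ddnf_trajectory`.
#' @param path Output file.
#' @return The path, invisibly.
#' @export
write_trajectory_csv <- function(traj, path) {
  stopifnot(inherits(traj, "ddnf_trajectory"))
  arch <- traj$model$architecture
  cols <- do.call(rbind, lapply(seq_len(arch$L), function(k)
    cbind(k, seq_len(arch$M[k]))))
  vals <- matrix(0, traj$N + 1, nrow(cols))
  for (j in seq_len(nrow(cols)))
    vals[, j] <- traj$V[, cols[j, 1], cols[j, 2]]
  write_full_precision_csv(cbind(0:traj$N, vals),
                           c("n", paste0(cols[, 1], ":", cols[, 2])), path)
}

#' Read a trajectory CSV back into a tibble
#'
#' Inverse of [write_trajectory_csv()]: values round-trip exactly.
#'
#' @param path CSV file written by [write_trajectory_csv()].
#' @return A tibble with the `n` column and one `k:i` column per neuron.
#' @export
read_trajectory_csv <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE, colClasses = "numeric")
  tibble::as_tibble(df)
}

write_stability_json <- function(report, path) {
  stopifnot(inherits(report, "ddnf_stability"))
  obj <- list(
    rho = report$rho,
    classification = report$classification,
    eigenvalues = data.frame(re = Re(report$eigenvalues),
                             im = Im(report$eigenvalues)),
    flags = as.list(report$flags))
  for (f in c("mu_single", "theta", "mu0", "mu", "a1", "b1", "c1", "a2",
              "trace", "det"))
    if (!is.null(report[[f]])) obj[[f]] <- report[[f]]
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

write_manifest <- function(out_dir) {
  files <- setdiff(list.files(out_dir), "manifest.json")
  manifest <- list(files = lapply(files, function(f) list(
    name = f,
    md5 = unname(tools::md5sum(file.path(out_dir, f))),
    bytes = file.size(file.path(out_dir, f)))))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  manifest
}

#' Write scenario outputs for a precomputed trajectory
#'
#' Lower-level sibling of [run_scenario()]: writes the trajectory CSV, an
#' optional stability report JSON, and the checksum manifest for an already
#' simulated trajectory.
#'
#' @param traj A `ddnf_trajectory`.
#' @param report Optional `ddnf_stability` report.
#' @param out_dir Output directory, created if needed.
#' @return The manifest, invisibly.
#' @export
write_outputs <- function(traj, report = NULL, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  write_trajectory_csv(traj, file.path(out_dir, "trajectory.csv"))
  if (!is.null(report))
    write_stability_json(report, file.path(out_dir, "stability.json"))
  invisible(write_manifest(out_dir))
}

#' Read a model configuration from JSON
#'
#' The schema mirrors the model constructors:
#' ```json
#' {
#'   "domain": [-20, 20], "h": 0.8, "alpha": null,
#'   "layers": {"L": 1, "M": 200, "stacked": false},
#'   "kernel": {"preset": "gauss_diff_sec35"},
#'   "activation": {"family": "sigmoid", "theta": 1, "v0": 0},
#'   "stimulus": {"nu": -0.5, "U": "zero"},
#'   "V0": -1.5, "N": 100
#' }
#' ```
#' `kernel` may instead give `family` plus the [kernel_spec()] parameters, and
#' for one-neuron-per-layer chains a `connectivity` object
#' `{"intra": K0, "up": K1, "down": K2}` overrides the kernel with constant
#' chain weights.
#'
#' @param path JSON file.
#' @return A list with `model` (`ddnf_model`), `V0`, and `N`.
#' @export
read_model_config <- function(path) {
  cfg <- jsonlite::read_json(path, simplifyVector = TRUE)
  domain <- as.numeric(cfg$domain %||% c(-20, 20))
  lay <- cfg$layers %||% list()
  L <- as.integer(lay$L %||% 1)
  M <- as.integer(lay$M %||% 200)
  stacked <- isTRUE(lay$stacked)
  arch <- layer_architecture(L, M, domain = domain, stacked = stacked)
  disc <- discretization_params(cfg$h %||% 0.8, domain = domain,
                                alpha = cfg$alpha)
  acfg <- cfg$activation %||% list()
  act <- activation_spec(acfg$family %||% "sigmoid",
                         theta = acfg$theta %||% 1, v0 = acfg$v0 %||% 0)
  scfg <- cfg$stimulus %||% list()
  stim <- stimulus_spec(nu = scfg$nu %||% -0.5, U = scfg$U %||% "zero",
                        U_values = if (!is.null(scfg$U_values))
                          matrix(as.numeric(unlist(scfg$U_values)),
                                 arch$L, arch$Mmax, byrow = TRUE))
  conn <- NULL
  kern <- NULL
  if (!is.null(cfg$connectivity)) {
    cc <- cfg$connectivity
    conn <- chain_connectivity(arch, intra = cc$intra %||% 0,
                               up = cc$up %||% 0, down = cc$down %||% 0)
  } else {
    kcfg <- cfg$kernel %||% list(preset = "gauss_diff_sec35")
    kern <- if (!is.null(kcfg$preset)) kernel_preset(kcfg$preset)
    else do.call(kernel_spec, kcfg)
  }
  model <- ddnf_model(arch, disc, kernel = kern, activation = act,
                      stimulus = stim, connectivity = conn)
  list(model = model, V0 = cfg$V0 %||% -1.5, N = as.integer(cfg$N %||% 100))
}

#' Constant-weight chain connectivity
#'
#' Direct numeric weights for a one-neuron-per-layer chain: every intra-layer
#' block is `intra`, every upward block (`k-1 -> k`) is `up`, every downward
#' block (`k -> k+1`) is `down`.
#'
#' @param arch A one-neuron-per-layer [layer_architecture()].
#' @param intra,up,down Scalar weights.
#' @return A `ddnf_connectivity`.
#' @export
chain_connectivity <- function(arch, intra, up, down) {
  stopifnot(inherits(arch, "ddnf_architecture"), all(arch$M == 1))
  blocks <- list()
  for (k in seq_len(arch$L))
    for (l in arch$neighbors[[k]])
      blocks[[paste(k, l, sep = ",")]] <-
        if (l == k) intra else if (l < k) up else down
  build_connectivity(arch, blocks = blocks)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
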