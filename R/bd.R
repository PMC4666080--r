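#' Brownian dynamics configuration
#'
#' Settings for the Ermak-McCammon integrator. The default time step of
#' 0.1 ps gives `H * dt / zeta ~ 0.035` for the default spring constant and
#' bead friction `zeta = 6 pi eta_s sigma`, inside the stability bound of
#' 0.05 enforced here; sampling accuracy at this step is validated against
#' Boltzmann quadrature in the test suite.
#'
#' @param n_steps number of production steps.
#' @param dt time step (ps).
#' @param hi logical: include hydrodynamic interaction (RPY tensor with
#'   correlated Gaussian displacements)? Free-draining when `FALSE`.
#' @param seed integer RNG seed, recorded in the trajectory.
#' @param snapshot_every store a snapshot every this many steps.
#' @param equilibration_steps steps to discard before production.
#' @param cholesky_every refactorize the RPY Cholesky factor every this many
#'   steps (HI only; 1 = every step).
#' @param params a [model_parameters()] object (for the stability check).
#' @return An object of class `bd_config`.
#' @export
bd_config <- function(n_steps, dt = 0.1, hi = FALSE, seed = 1,
                      snapshot_every = max(1L, n_steps %/% 1000L),
                      equilibration_steps = 0,
                      cholesky_every = 1, params = model_parameters()) {
  stopifnot(dt > 0, n_steps >= 0, snapshot_every >= 1, cholesky_every >= 1,
            equilibration_steps >= 0)
  # stability: H dt / zeta = H dt D0 in internal units (kBT = 1)
  crit <- params$H * dt * params$D0
  if (crit > 0.05)
    stop(sprintf("unstable time step: H*dt/zeta = %.3f > 0.05; reduce dt",
                 crit))
  structure(list(n_steps = as.integer(n_steps), dt = dt, hi = hi,
                 seed = as.integer(seed),
                 snapshot_every = as.integer(snapshot_every),
                 equilibration_steps = as.integer(equilibration_steps),
                 cholesky_every = as.integer(cholesky_every)),
            class = "bd_config")
}

#' RPY diffusion supermatrix of a conformation
#'
#' Rotne-Prager-Yamakawa pair mobilities for equal beads, including the
#' overlap (r < 2 sigma) regularization, so the matrix is symmetric
#' positive definite for any non-coincident configuration. Diagonal blocks
#' are the Stokes-Einstein `kBT / (6 pi eta_s sigma) I`.
#'
#' @param conf N x 3 coordinate matrix (Angstrom).
#' @param params a [model_parameters()] object (bead radius, viscosity,
#'   temperature).
#' @return 3N x 3N matrix in cm^2/s.
#' @export
rpy_mobility <- function(conf, params = model_parameters()) {
  stopifnot(is.matrix(conf), ncol(conf) == 3)
  cpp_rpy_matrix(conf, params$sigma, params$D0_cgs)
}

#' Run a Brownian dynamics trajectory
#'
#' Ermak-McCammon propagation: `dr = (dt/kBT) D F + R` with `E[R] = 0` and
#' `Cov[R] = 2 D dt`. Free-draining runs use independent Gaussian
#' displacements scaled by `sqrt(2 D0 dt)`; HI runs draw correlated
#' displacements through the Cholesky factor of the RPY supermatrix. The
#' RPY divergence is zero, so no drift correction is applied. Equilibration
#' steps are discarded; snapshots, energies and Rg are recorded every
#' `snapshot_every` production steps. Aborts with a diagnostic if any
#' spring stretches beyond 3 times its equilibrium length.
#'
#' @param conf N x 3 starting coordinates (Angstrom).
#' @param ff an [forcefield()] object.
#' @param config a [bd_config()] object.
#' @param noise_scale Gaussian displacement scale factor (1 = physical;
#'   0 gives the deterministic force-driven limit, for testing).
#' @return An `rnabd_traj`: list with `coords` (N x 3 x S array), `times`
#'   (ps, production time of each snapshot), `energy` and `rg` traces,
#'   `final` coordinates, and the `config`.
#' @export
run_bd <- function(conf, ff, config, noise_scale = 1) {
  stopifnot(inherits(ff, "rnabd_ff"), inherits(config, "bd_config"),
            is.matrix(conf), nrow(conf) == ff$net$n_beads)
  p <- ff$params
  set.seed(config$seed)
  X <- conf
  if (config$equilibration_steps > 0) {
    eq <- cpp_bd_run(X, ff$springs0, ff$conn, ff$eps_lj, ff$sigma_lj,
                     ff$lj_cutoff, config$dt, config$equilibration_steps,
                     config$equilibration_steps, config$hi, p$sigma, p$D0,
                     config$cholesky_every, noise_scale, 3)
    X <- eq$final
  }
  if (config$n_steps == 0) {
    traj <- list(coords = array(X, c(nrow(X), 3, 1)), times = 0,
                 energy = total_forces(X, ff)$energy, rg = rg_of(X),
                 final = X, config = config)
    class(traj) <- "rnabd_traj"
    return(traj)
  }
  out <- cpp_bd_run(X, ff$springs0, ff$conn, ff$eps_lj, ff$sigma_lj,
                    ff$lj_cutoff, config$dt, config$n_steps,
                    config$snapshot_every, config$hi, p$sigma, p$D0,
                    config$cholesky_every, noise_scale, 3)
  ns <- out$n_snapshots
  traj <- list(coords = out$snapshots[, , seq_len(ns), drop = FALSE],
               times = config$dt * config$snapshot_every * seq_len(ns),
               energy = out$energy[seq_len(ns)],
               rg = out$rg[seq_len(ns)],
               final = out$final, config = config)
  class(traj) <- "rnabd_traj"
  traj
}

rg_of <- function(X) {
  cm <- colMeans(X)
  sqrt(mean(rowSums((X - matrix(cm, nrow(X), 3, byrow = TRUE))^2)))
}

#' Single Ermak-McCammon step
#'
#' Thin wrapper over [run_bd()] for one step; mainly useful in tests and
#' demonstrations.
#'
#' @inheritParams run_bd
#' @param dt time step (ps).
#' @param hi include hydrodynamic interaction?
#' @param seed RNG seed.
#' @return N x 3 updated coordinates.
#' @export
bd_step <- function(conf, ff, dt = 0.1, hi = FALSE, seed = 1,
                    noise_scale = 1) {
  cfg <- bd_config(n_steps = 1, dt = dt, hi = hi, seed = seed,
                   snapshot_every = 1, params = ff$params)
  run_bd(conf, ff, cfg, noise_scale = noise_scale)$final
}

#' @export
print.rnabd_traj <- function(x, ...) {
  ns <- dim(x$coords)[3]
  cat(sprintf(
    "BD trajectory: %d beads, %d snapshots (every %.1f ps, %.3f ns total), %s\n",
    dim(x$coords)[1], ns, diff(x$times[1:2]),
    x$times[ns] / 1000, if (x$config$hi) "with HI" else "free-draining"))
  invisible(x)
}

#' Write / read a trajectory as multi-frame XYZ
#'
#' Plain-text persistence; frame comments carry times, and a header comment
#' in the companion `.meta` file records dt, seed and HI flag.
#'
#' @param traj an `rnabd_traj`.
#' @param path output XYZ path.
#' @return `write_trajectory()` returns `path`; `read_trajectory()` returns
#'   an `rnabd_traj` (with a minimal reconstructed config).
#' @export
write_trajectory <- function(traj, path) {
  frames <- lapply(seq_len(dim(traj$coords)[3]),
                   function(s) traj$coords[, , s])
  write_xyz(frames, path, times = traj$times)
  meta <- c(sprintf("dt: %g", traj$config$dt),
            sprintf("seed: %d", traj$config$seed),
            sprintf("hi: %s", traj$config$hi),
            sprintf("snapshot_every: %d", traj$config$snapshot_every))
  writeLines(meta, paste0(path, ".meta"))
  invisible(path)
}

#' @rdname write_trajectory
#' @export
read_trajectory <- function(path) {
  xyz <- read_xyz(path)
  meta_path <- paste0(path, ".meta")
  dt <- 0.1; seed <- 1L; hi <- FALSE; snap <- 1L
  if (file.exists(meta_path)) {
    m <- readLines(meta_path)
    gv <- function(k) sub(paste0("^", k, ": "), "", grep(paste0("^", k, ":"),
                                                         m, value = TRUE)[1])
    dt <- as.numeric(gv("dt")); seed <- as.integer(gv("seed"))
    hi <- as.logical(gv("hi")); snap <- as.integer(gv("snapshot_every"))
  }
  S <- length(xyz$frames)
  N <- nrow(xyz$frames[[1]])
  coords <- array(0, c(N, 3, S))
  for (s in seq_len(S)) coords[, , s] <- xyz$frames[[s]]
  cfg <- bd_config(n_steps = S * snap, dt = dt, hi = hi, seed = seed,
                   snapshot_every = snap)
  traj <- list(coords = coords, times = xyz$times,
               energy = rep(NA_real_, S),
               rg = apply(coords, 3, rg_of), final = coords[, , S],
               config = cfg)
  class(traj) <- "rnabd_traj"
  traj
}
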