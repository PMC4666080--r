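#' End-to-end solution-property pipeline
#'
#' Orchestrates the full workflow for one RNA: build the elastic network
#' and initial conformation, equilibrate with free-draining BD, run a
#' free-draining production trajectory sized in units of the molecule's
#' estimated rotational relaxation time, apply the rigid-body treatment to
#' every snapshot, and report block-averaged solution properties (plus
#' inter-arm angle statistics when an [arm_definition()] is given).
#'
#' Trajectory lengths are specified in relaxation times: `tau_h` is first
#' estimated from the relaxed initial conformation (for equilibration) and
#' re-estimated from the equilibrated one (for production). Optionally a
#' hydrodynamic-interaction production run is appended and the Einstein
#' (center-of-mass MSD) estimate of `D_t` computed from it - the reference
#' route for dynamics, at considerably higher cost.
#'
#' @param ss an `rna_ss`, or a fixture list from [load_fixture()].
#' @param params a [model_parameters()] object.
#' @param seed integer master seed (build, equilibration and production
#'   draw distinct seeds from it).
#' @param equilibration_relax equilibration length in estimated relaxation
#'   times.
#' @param production_relax production length in estimated relaxation times.
#' @param target_snapshots approximate number of stored snapshots.
#' @param arms optional [arm_definition()]; taken from the fixture when
#'   `ss` is one.
#' @param hi logical: also run an HI production trajectory and compute the
#'   MSD diffusion coefficient.
#' @param hi_relax length of the optional HI run (relaxation times).
#' @param dt integrator time step (ps).
#' @param dry_run validate the configuration and build the topology, then
#'   return before any simulation.
#' @param traj optionally, a previously computed production `rnabd_traj`:
#'   simulation is skipped and the analysis re-run on it.
#' @param verbose print stage progress.
#' @return An `rnabd_report`: list with the topology summary, `properties`
#'   (a `solution_properties`), `theta` statistics (when arms are given),
#'   the production `trajectory`, seeds, and timing metadata. For
#'   `dry_run = TRUE`, the validated topology summary only.
#' @export
run_pipeline <- function(ss, params = model_parameters(), seed = 1,
                         equilibration_relax = 10, production_relax = 20,
                         target_snapshots = 600, arms = NULL, hi = FALSE,
                         hi_relax = 5, dt = 0.1, dry_run = FALSE,
                         traj = NULL, verbose = TRUE) {
  if (is.list(ss) && !inherits(ss, "rna_ss") && !is.null(ss$ss)) {
    if (is.null(arms)) arms <- ss$arms
    ss <- ss$ss
  }
  stopifnot(inherits(ss, "rna_ss"))
  say <- function(...) if (verbose) message(sprintf(...))

  say("[build] %d nt, %d helices", ss$n_residues, nrow(ss$helices))
  ref <- ideal_conformation(ss, params)
  net <- assign_equilibrium_lengths(build_spring_network(ss, params), ref,
                                    params)
  ff <- forcefield(net, params)
  conf0 <- assemble_initial_conformation(ss, params, seed = seed)
  topo <- list(n_beads = net$n_beads, n_springs = nrow(net$springs),
               spring_kinds = table(net$springs$kind),
               topology_hash = topology_fingerprint(net))
  if (dry_run) {
    say("[dry-run] topology valid (%d springs); exiting before simulation",
        topo$n_springs)
    return(structure(list(topology = topo, dry_run = TRUE),
                     class = "rnabd_report"))
  }

  if (is.null(traj)) {
    tau0 <- rigid_body_hydro(conf0, params)$tau_h # ns
    eq_steps <- max(1000L, as.integer(round(equilibration_relax * tau0 *
                                              1000 / dt)))
    say("[equilibrate] tau_h(initial) = %.1f ns -> %d steps", tau0, eq_steps)
    eq <- run_bd(conf0, ff,
                 bd_config(n_steps = 0, dt = dt, seed = seed + 1L,
                           equilibration_steps = eq_steps, params = params))
    # pilot ensemble (~1 relaxation time, 25 snapshots) for a stable
    # estimate of tau_h; a single snapshot is too noisy to size the run
    pilot_steps <- max(1000L, as.integer(round(tau0 * 1000 / dt)))
    pilot <- run_bd(eq$final, ff,
                    bd_config(n_steps = pilot_steps, dt = dt,
                              seed = seed + 4L,
                              snapshot_every = max(1L, pilot_steps %/% 25L),
                              params = params))
    tau1 <- 1 / (6 * mean(vapply(seq_len(dim(pilot$coords)[3]), function(s)
      rigid_body_hydro(pilot$coords[, , s], params)$D_r, numeric(1)))) * 1e9
    prod_steps <- max(1000L, as.integer(round(production_relax * tau1 *
                                                1000 / dt)))
    snap_every <- max(1L, prod_steps %/% as.integer(target_snapshots))
    say("[produce] tau_h(equilibrated) = %.1f ns -> %d steps, snapshot every %d",
        tau1, prod_steps, snap_every)
    traj <- run_bd(pilot$final, ff,
                   bd_config(n_steps = prod_steps, dt = dt,
                             seed = seed + 2L, snapshot_every = snap_every,
                             params = params))
  } else {
    say("[resume] analyzing supplied trajectory (%d snapshots)",
        dim(traj$coords)[3])
  }

  say("[rigid-body ensemble] %d snapshots", dim(traj$coords)[3])
  props <- ensemble_properties(traj, params)

  theta <- NULL
  if (!is.null(arms)) {
    tr <- angle_trace(traj, arms)
    bs <- block_stats(tr, props$n_blocks)
    hist <- angle_histogram(traj, arms)
    modal <- which.max(hist$frequency)
    theta <- list(mean = bs$mean, sd = bs$sd, trace = tr, histogram = hist,
                  modal_bin = c(hist$bin_lo[modal], hist$bin_hi[modal]))
    say("[angle] mean theta = %.1f deg", bs$mean)
  }

  msd <- NULL
  if (hi) {
    tauh <- props$tau_h
    hi_steps <- max(1000L, as.integer(round(hi_relax * tauh * 1000 / dt)))
    say("[HI production] %d steps", hi_steps)
    hi_traj <- run_bd(traj$final, ff,
                      bd_config(n_steps = hi_steps, dt = dt, hi = TRUE,
                                seed = seed + 3L,
                                snapshot_every = max(1L, hi_steps %/% 2000L),
                                params = params))
    msd <- msd_diffusion(hi_traj)
    say("[MSD] D_t = %.3e cm^2/s", msd$D_t)
  }

  structure(list(topology = topo, properties = props, theta = theta,
                 msd = msd, trajectory = traj, seed = seed,
                 params = params, dry_run = FALSE),
            class = "rnabd_report")
}

topology_fingerprint <- function(net) {
  s <- paste(net$springs$i, net$springs$j, net$springs$kind,
             round(net$springs$l_e, 4), collapse = ";")
  # small content hash (djb2) so runs can be matched to a topology
  h <- 5381
  for (ch in utf8ToInt(s)) h <- (h * 33 + ch) %% 2^31
  sprintf("%08x", h)
}

#' @export
print.rnabd_report <- function(x, ...) {
  cat("rnabd pipeline report\n")
  cat(sprintf("  topology: %d beads, %d springs (hash %s)\n",
              x$topology$n_beads, x$topology$n_springs,
              x$topology$topology_hash))
  if (isTRUE(x$dry_run)) {
    cat("  dry run: no simulation performed\n")
    return(invisible(x))
  }
  p <- x$properties
  cat(sprintf("  %-28s %8s %10s\n", "property", "value", "block SD"))
  cat(sprintf("  %-28s %8.2f %10.2f\n", "D_t (1e-7 cm^2/s)",
              p$D_t * 1e7, p$D_t_sd * 1e7))
  cat(sprintf("  %-28s %8.1f %10.1f\n", "tau_h (ns)", p$tau_h, p$tau_h_sd))
  cat(sprintf("  %-28s %8.1f %10.1f\n", "R_g (A)", p$R_g, p$R_g_sd))
  if (!is.null(x$theta))
    cat(sprintf("  %-28s %8.1f %10.1f\n", "inter-arm angle (deg)",
                x$theta$mean, x$theta$sd))
  if (!is.null(x$msd))
    cat(sprintf("  %-28s %8.2f\n", "D_t from HI MSD (1e-7 cm^2/s)",
                x$msd$D_t * 1e7))
  invisible(x)
}

#' Write a pipeline report to JSON and TSV
#'
#' Produces `report.json` (summary numbers, block values, metadata) and,
#' when present, `theta_trace.tsv` and `theta_histogram.tsv` under `dir`.
#'
#' @param report an `rnabd_report`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_report <- function(report, dir) {
  if (!requireNamespace("jsonlite", quietly = TRUE))
    stop("write_report() needs the jsonlite package")
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  p <- report$properties
  out <- list(
    topology = list(n_beads = report$topology$n_beads,
                    n_springs = report$topology$n_springs,
                    hash = report$topology$topology_hash),
    seed = report$seed,
    D_t_cm2_s = p$D_t, D_t_sd = p$D_t_sd,
    tau_h_ns = p$tau_h, tau_h_sd = p$tau_h_sd,
    R_g_A = p$R_g, R_g_sd = p$R_g_sd,
    blocks = p$blocks)
  if (!is.null(report$theta))
    out$theta <- list(mean = report$theta$mean, sd = report$theta$sd,
                      modal_bin = report$theta$modal_bin)
  if (!is.null(report$msd))
    out$D_t_msd_cm2_s <- report$msd$D_t
  jsonlite::write_json(out, file.path(dir, "report.json"),
                       auto_unbox = TRUE, digits = NA)
  if (!is.null(report$theta)) {
    utils::write.table(
      data.frame(time_ps = report$trajectory$times,
                 theta_deg = report$theta$trace),
      file.path(dir, "theta_trace.tsv"), sep = "\t", quote = FALSE,
      row.names = FALSE)
    utils::write.table(report$theta$histogram,
                       file.path(dir, "theta_histogram.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }
  invisible(dir)
}
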