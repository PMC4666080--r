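#' Force field for a spring network
#'
#' Bundles the elastic network with the excluded-volume interaction. All
#' bead pairs not joined by any spring interact through the full 12-6
#' Lennard-Jones potential (attractive tail included; good-solvent
#' conditions); sprung pairs feel only their Hooke spring. Energies are in
#' kBT units, lengths in Angstrom.
#'
#' @param net a `spring_network` with equilibrium lengths assigned.
#' @param params a [model_parameters()] object.
#' @param lj_cutoff optional Lennard-Jones cutoff distance (Angstrom);
#'   `NULL` (the default) evaluates all pairs. A cutoff of `3 * sigma_lj`
#'   changes energies by well under 1e-3 kBT per pair and is offered for
#'   speed only.
#' @return An object of class `rnabd_ff`.
#' @export
forcefield <- function(net, params = model_parameters(), lj_cutoff = NULL) {
  stopifnot(inherits(net, "spring_network"))
  if (anyNA(net$springs$l_e))
    stop("spring network has unset equilibrium lengths; ",
         "call assign_equilibrium_lengths() first")
  shift <- matrix(rep(c(1, 1, 0, 0), each = nrow(net$springs)),
                  ncol = 4) # index columns to 0-based
  structure(list(
    net = net,
    springs0 = as.matrix(net$springs[, c("i", "j", "l_e", "H")]) - shift,
    conn = connectivity_matrix(net),
    eps_lj = params$eps_lj, sigma_lj = params$sigma_lj,
    lj_cutoff = if (is.null(lj_cutoff)) -1 else lj_cutoff,
    params = params), class = "rnabd_ff")
}

#' Hooke spring energy
#'
#' `V = H * (l - l_e)^2 / 2`, the harmonic form of the model's spring
#' potential, zero at the equilibrium length.
#'
#' @param l instantaneous spring length (Angstrom), > 0.
#' @param l_e equilibrium length (Angstrom).
#' @param H force constant (kBT/Angstrom^2).
#' @return Energy in kBT units.
#' @examples
#' p <- model_parameters()
#' spring_energy(1.05 * p$l_e1, p$l_e1, p$H) # 0.25 kBT
#' @export
spring_energy <- function(l, l_e, H) {
  stopifnot(all(l > 0), all(l_e > 0), all(H > 0))
  0.5 * H * (l - l_e)^2
}

#' Lennard-Jones excluded-volume energy
#'
#' Full 12-6 form `4 eps [(sigma/r)^12 - (sigma/r)^6]`; zero at
#' `r = sigma_lj`, minimum `-eps_lj` at `2^(1/6) sigma_lj`.
#'
#' @param r_ij pair distance (Angstrom), > 0.
#' @param eps_lj well depth (kBT).
#' @param sigma_lj zero-crossing distance (Angstrom).
#' @return Energy in kBT units.
#' @export
lj_energy <- function(r_ij, eps_lj, sigma_lj) {
  if (any(r_ij <= 0)) stop("singularity: r_ij must be > 0")
  s6 <- (sigma_lj / r_ij)^6
  4 * eps_lj * (s6 * s6 - s6)
}

#' Total forces and energy of a conformation
#'
#' `F = -grad V` summed over all springs and all non-connected pairs.
#' The net force sums to zero (Newton's third law).
#'
#' @param conf N x 3 coordinate matrix (Angstrom).
#' @param ff an [forcefield()] object.
#' @return List with `forces` (N x 3, kBT/Angstrom), `energy`,
#'   `energy_spring`, `energy_lj` (kBT), and `max_extension_ratio`
#'   (max spring length over its `l_e`).
#' @export
total_forces <- function(conf, ff) {
  stopifnot(inherits(ff, "rnabd_ff"), is.matrix(conf),
            nrow(conf) == ff$net$n_beads)
  cpp_forces(conf, ff$springs0, ff$conn, ff$eps_lj, ff$sigma_lj,
             ff$lj_cutoff)
}

#' Energy decomposition report
#'
#' Per-spring-kind and excluded-volume energies of one conformation,
#' returned (and optionally written) as a table for debugging.
#'
#' @param conf N x 3 coordinate matrix.
#' @param ff an [forcefield()] object.
#' @param path optional TSV output path.
#' @return Data frame with columns `term` and `energy_kBT`.
#' @export
energy_report <- function(conf, ff, path = NULL) {
  sp <- ff$net$springs
  d <- conf[sp$i, , drop = FALSE] - conf[sp$j, , drop = FALSE]
  l <- sqrt(rowSums(d^2))
  e_kind <- tapply(spring_energy(l, sp$l_e, sp$H), sp$kind, sum)
  tot <- total_forces(conf, ff)
  out <- data.frame(term = c(names(e_kind), "excluded_volume"),
                    energy_kBT = c(as.numeric(e_kind), tot$energy_lj))
  if (!is.null(path))
    utils::write.table(out, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  out
}
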