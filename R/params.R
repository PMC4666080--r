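#' Physical constants (CGS)
#' @noRd
.kB <- 1.380649e-16 # erg/K
.Rgas <- 8.31446261815324e7 # erg/(mol K)

#' Model parameters for the coarse-grained RNA bead model
#'
#' One bead per nucleotide, all beads with the same hydrodynamic radius
#' `sigma`. Double-helical regions follow ideal A-form geometry (right-handed,
#' 11 bp per turn, 2.8 Angstrom rise, helix radius 10 Angstrom) with the
#' complementary strand offset by the azimuthal phase angle `phase_angle`.
#' All springs share the force constant `H = H_factor * kBT / l_e1^2`;
#' non-connected beads repel/attract through a 12-6 Lennard-Jones potential
#' with depth `eps_lj * kBT` and zero-crossing `sigma_lj_factor * l_e1`.
#'
#' The groove widths and base inclination are descriptive A-form metadata:
#' with a single bead per nucleotide the rise, twist and phase angle fully
#' determine bead placement, so they do not enter the builder.
#'
#' @param sigma bead hydrodynamic radius (Angstrom).
#' @param helix_radius A-form helix radius (Angstrom).
#' @param rise axial rise per base pair (Angstrom).
#' @param bp_per_turn base pairs per helical turn.
#' @param inclination base-pair inclination (degrees, metadata only).
#' @param phase_angle azimuthal offset between paired strands (degrees).
#' @param major_groove,minor_groove A-form groove widths (Angstrom, metadata).
#' @param H_factor spring constant in units of `kBT / l_e1^2`.
#' @param eps_lj Lennard-Jones well depth in kBT units.
#' @param sigma_lj_factor Lennard-Jones zero-crossing in units of `l_e1`.
#' @param eta_s solvent viscosity (poise).
#' @param temperature absolute temperature (K).
#'
#' @return An object of class `rnabd_params`: a list with the arguments plus
#'   derived quantities `l_e1 = 2 * sigma` (Angstrom), `H` (kBT/Angstrom^2),
#'   `sigma_lj` (Angstrom), `kBT` (erg), `D0_cgs` (cm^2/s) and `D0`
#'   (Angstrom^2/ps), the Stokes-Einstein diffusion coefficient of a single
#'   bead.
#' @examples
#' p <- model_parameters()
#' p$l_e1           # 6.3 Angstrom, touching beads
#' p$D0_cgs         # ~6.81e-6 cm^2/s
#' @export
model_parameters <- function(sigma = 3.15, helix_radius = 10, rise = 2.8,
                             bp_per_turn = 11, inclination = 16.1,
                             phase_angle = 200, major_groove = 3.8,
                             minor_groove = 10.9, H_factor = 200,
                             eps_lj = 0.1, sigma_lj_factor = 0.8,
                             eta_s = 0.01, temperature = 293) {
  stopifnot(sigma > 0, helix_radius > 0, rise > 0, bp_per_turn > 1,
            phase_angle >= 0, phase_angle < 360, H_factor > 0, eps_lj >= 0,
            sigma_lj_factor > 0, eta_s > 0, temperature > 0)
  l_e1 <- 2 * sigma
  kBT <- .kB * temperature
  D0_cgs <- kBT / (6 * pi * eta_s * sigma * 1e-8) # cm^2/s
  p <- list(sigma = sigma, l_e1 = l_e1, helix_radius = helix_radius,
            rise = rise, bp_per_turn = bp_per_turn, inclination = inclination,
            phase_angle = phase_angle, major_groove = major_groove,
            minor_groove = minor_groove, H_factor = H_factor,
            eps_lj = eps_lj, sigma_lj_factor = sigma_lj_factor,
            sigma_lj = sigma_lj_factor * l_e1, eta_s = eta_s,
            temperature = temperature,
            H = H_factor / l_e1^2,   # kBT / Angstrom^2
            kBT = kBT, D0_cgs = D0_cgs,
            D0 = D0_cgs * 1e4)       # Angstrom^2/ps
  class(p) <- "rnabd_params"
  p
}

#' @export
print.rnabd_params <- function(x, ...) {
  cat("Coarse-grained RNA model parameters\n")
  cat(sprintf("  bead radius sigma     %.2f A (l_e1 = %.2f A)\n",
              x$sigma, x$l_e1))
  cat(sprintf("  A-form: radius %.1f A, rise %.1f A, %d bp/turn, phase %.0f deg\n",
              x$helix_radius, x$rise, x$bp_per_turn, x$phase_angle))
  cat(sprintf("  springs: H = %.0f kBT/l_e1^2 = %.3f kBT/A^2\n",
              x$H_factor, x$H))
  cat(sprintf("  LJ: eps %.2f kBT, sigma_LJ %.2f A\n", x$eps_lj, x$sigma_lj))
  cat(sprintf("  solvent: eta %.3f P, T %.0f K (D0 = %.3e cm^2/s)\n",
              x$eta_s, x$temperature, x$D0_cgs))
  invisible(x)
}
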