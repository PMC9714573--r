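#' Reduced unit system and physical-time mapping
#'
#' The simulation works in reduced (Lennard-Jones-style) units: the length
#' unit \eqn{\sigma} is one disaccharide bead (1 nm), the mass unit is one
#' bead mass, and energies are measured in the model energy unit
#' \eqn{\epsilon_E}. The derived time unit is
#' \eqn{\tau = \sigma \sqrt{m/\epsilon_E}}. To express results in seconds a
#' physical bead mass and energy must be assigned: the defaults take a
#' disaccharide mass of 400 g/mol and derive \eqn{\epsilon_E} from the
#' carbon-carbon coarse-graining value 0.15 kJ/mol, which corresponds to an
#' LJ well depth of 0.73 \eqn{\epsilon_E}; this gives \eqn{\tau \approx} 44 ps.
#'
#' @param length_nm Length unit \eqn{\sigma} in nanometres.
#' @param mass_g_mol Physical bead mass in g/mol.
#' @param energy_kJ_mol Physical value of one \eqn{\epsilon_E} in kJ/mol.
#' @param kT Thermal energy in units of \eqn{\epsilon_E}. The default 2.804
#'   makes the reduced bending constant \eqn{\beta K_\mathrm{bend} = 5}, for
#'   which the discrete worm-like-chain relation
#'   \eqn{l_p \approx 2 K_\mathrm{bend} r_0 / kT} gives the calibrated
#'   persistence length of 10 nm.
#' @return An object of class `unit_system`: a list with the inputs plus
#'   `tau_seconds`, the derived time unit in seconds.
#' @examples
#' u <- unit_system()
#' u$tau_seconds            # about 4.4e-11 s
#' physical_time(200, dt = 0.005, units = u)  # one tau, in seconds
#' @export
unit_system <- function(length_nm = 1, mass_g_mol = 400,
                        energy_kJ_mol = 0.15 / 0.73, kT = 2.804) {
  stopifnot(length_nm > 0, mass_g_mol > 0, energy_kJ_mol > 0, kT > 0)
  avogadro <- 6.02214076e23
  sigma_m <- length_nm * 1e-9
  mass_kg <- mass_g_mol * 1e-3 / avogadro
  eps_J <- energy_kJ_mol * 1e3 / avogadro
  tau <- sigma_m * sqrt(mass_kg / eps_J)
  structure(list(length_nm = length_nm, mass_g_mol = mass_g_mol,
                 energy_kJ_mol = energy_kJ_mol, kT = kT,
                 tau_seconds = tau),
            class = "unit_system")
}

#' @rdname unit_system
#' @param n_steps Number of integration steps.
#' @param dt Time step in units of \eqn{\tau}.
#' @param units A `unit_system`.
#' @return `physical_time()`: elapsed time in seconds.
#' @export
physical_time <- function(n_steps, dt, units = unit_system()) {
  if (!inherits(units, "unit_system") || is.null(units$tau_seconds))
    stop("a complete unit_system with a physical mass/energy assignment is required")
  stopifnot(n_steps >= 0, dt > 0)
  n_steps * dt * units$tau_seconds
}

#' Convert a reduced diffusion constant to SI units
#'
#' @param D Diffusion constant in \eqn{\sigma^2/\tau}.
#' @param units A [unit_system()].
#' @return Diffusion constant in m^2/s.
#' @export
diffusion_si <- function(D, units = unit_system()) {
  sigma_m <- units$length_nm * 1e-9
  D * sigma_m^2 / units$tau_seconds
}

#' @export
print.unit_system <- function(x, ...) {
  cat("Reduced unit system\n")
  cat(sprintf("  sigma  = %g nm\n", x$length_nm))
  cat(sprintf("  mass   = %g g/mol\n", x$mass_g_mol))
  cat(sprintf("  eps_E  = %g kJ/mol\n", x$energy_kJ_mol))
  cat(sprintf("  kT     = %g eps_E\n", x$kT))
  cat(sprintf("  tau    = %.4g s\n", x$tau_seconds))
  invisible(x)
}
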