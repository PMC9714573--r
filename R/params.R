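#' Force-field parameters
#'
#' Interaction constants for the coarse-grained brush model: a truncated
#' 12-6 Lennard-Jones potential between all beads (cut at its minimum,
#' \eqn{2^{1/6}\sigma_{LJ}}, for good-solvent conditions and energy-shifted
#' so it is continuous there), a harmonic stretching potential
#' \eqn{K_\mathrm{bond}(r-r_0)^2} on bonded pairs, a harmonic bending
#' potential \eqn{K_\mathrm{bend}(\theta-\theta_0)^2} on bonded triples, and
#' a Debye-Hueckel screened Coulomb potential
#' \eqn{(C/\epsilon)\, q_i q_j e^{-\kappa r}/r} between charged beads.
#'
#' The electrostatic prefactor is parameterized through the Bjerrum length
#' of water at physiological temperature (0.7 nm): in reduced units
#' \eqn{C/\epsilon = l_B kT}, with charges in units of e.
#'
#' @param eps_lj LJ well depth (\eqn{\epsilon_E}).
#' @param rc_factor LJ cutoff as a multiple of the pair sigma; the default
#'   \eqn{2^{1/6}} truncates at the minimum (purely repulsive, good solvent).
#' @param shift_lj Shift the LJ energy so it is continuous (and zero) at the
#'   cutoff. Forces are unaffected; only absolute energy bookkeeping changes.
#' @param k_bond Bond constant (\eqn{\epsilon_E/\sigma^2}).
#' @param r0 Equilibrium bond length (\eqn{\sigma}).
#' @param k_bend Bending constant (\eqn{\epsilon_E/\mathrm{rad}^2}).
#' @param theta0 Equilibrium bond angle (rad); \eqn{\pi} means straight.
#' @param bjerrum Bjerrum length in \eqn{\sigma}.
#' @param kT Thermal energy used to convert the Bjerrum length into the
#'   energy prefactor.
#' @param kappa Inverse Debye screening length (\eqn{1/\sigma}).
#' @param r_cut_debye Debye cutoff (\eqn{\sigma}).
#' @param chain_charge Charge of each chain bead, in units of e.
#' @return An object of class `ff_params`.
#' @examples
#' p <- forcefield_params()
#' p$coulomb   # l_B * kT = 0.7 * 2.804
#' @export
forcefield_params <- function(eps_lj = 0.73, rc_factor = 2^(1 / 6),
                              shift_lj = TRUE, k_bond = 140.2, r0 = 1,
                              k_bend = 14.02, theta0 = pi,
                              bjerrum = 0.7, kT = 2.804, kappa = 1,
                              r_cut_debye = 3, chain_charge = -1) {
  stopifnot(rc_factor > 0, r_cut_debye > 0, kappa > 0, r0 > 0,
            k_bond >= 0, k_bend >= 0, eps_lj >= 0, bjerrum > 0, kT > 0)
  structure(list(eps_lj = eps_lj, rc_factor = rc_factor, shift_lj = shift_lj,
                 k_bond = k_bond, r0 = r0, k_bend = k_bend, theta0 = theta0,
                 coulomb = bjerrum * kT, bjerrum = bjerrum, kT = kT,
                 kappa = kappa, r_cut_debye = r_cut_debye,
                 chain_charge = chain_charge),
            class = "ff_params")
}

#' Brush simulation configuration
#'
#' Geometry, tracer properties, Langevin settings and run lengths for one
#' brush system. Four system types are supported: `"dynamic"` (chains and
#' tracer both integrated), `"static"` (chains equilibrated, then frozen
#' while the tracer diffuses), `"no_stiffness"` (dynamic, bending term
#' removed) and `"straight"` (chains straightened and frozen; no chain
#' equilibration).
#'
#' The tracer damping coefficient follows the Stokes drag
#' \eqn{\gamma = 6\pi a \eta}: it scales linearly with the tracer radius
#' relative to a chain bead (radius 0.5 \eqn{\sigma}), and the tracer mass
#' scales with radius cubed.
#'
#' @param d Tether grid spacing (\eqn{\sigma}).
#' @param grid_n Chains per side of the quadratic tether grid.
#' @param n_beads Beads per chain (the two tether beads are counted inside
#'   this number).
#' @param n_tether Immobile tether beads per chain.
#' @param tracer_radius Tracer radius \eqn{a} (\eqn{\sigma}); the tracer LJ
#'   size is \eqn{2a}.
#' @param tracer_charge Tracer charge in units of e.
#' @param mode One of `"dynamic"`, `"static"`, `"straight"`, `"no_stiffness"`.
#' @param gamma Damping coefficient of a chain bead (mass/\eqn{\tau}).
#' @param dt Time step (\eqn{\tau}). The default 0.005 resolves the stiffest
#'   mode (the bond vibration, \eqn{\omega \approx 24/\tau}) with over 50
#'   steps per period.
#' @param kT Thermal energy (\eqn{\epsilon_E}).
#' @param n_equil_steps,n_prod_steps,dump_every Equilibration length,
#'   production length and sampling stride in steps.
#' @param seed Base random seed.
#' @param n_realizations Number of independent realizations.
#' @return An object of class `brush_config`.
#' @export
brush_config <- function(d = 3, grid_n = 3, n_beads = 101, n_tether = 2,
                         tracer_radius = 0.5, tracer_charge = 0,
                         mode = c("dynamic", "static", "straight", "no_stiffness"),
                         gamma = 1, dt = 0.005, kT = 2.804,
                         n_equil_steps = 20000, n_prod_steps = 20000,
                         dump_every = 100, seed = 1, n_realizations = 100) {
  mode <- match.arg(mode)
  stopifnot(d > 0, grid_n >= 1, n_beads >= n_tether, n_tether >= 1,
            tracer_radius > 0, gamma >= 0, dt > 0, kT > 0,
            n_equil_steps >= 0, n_prod_steps > 0, dump_every >= 1,
            n_realizations >= 1)
  if (dt > 0.02)
    stop("dt above the stability bound for the bond stiffness (dt <= 0.02 tau)")
  structure(list(d = d, grid_n = grid_n, n_beads = n_beads,
                 n_tether = n_tether, tracer_radius = tracer_radius,
                 tracer_charge = tracer_charge, mode = mode, gamma = gamma,
                 dt = dt, kT = kT, n_equil_steps = n_equil_steps,
                 n_prod_steps = n_prod_steps, dump_every = dump_every,
                 seed = seed, n_realizations = n_realizations),
            class = "brush_config")
}

#' @export
print.brush_config <- function(x, ...) {
  cat(sprintf("brush_config: %dx%d grid, d = %g sigma, N = %d, mode = %s\n",
              x$grid_n, x$grid_n, x$d, x$n_beads, x$mode))
  cat(sprintf("  tracer: a = %g sigma, q = %+g e\n",
              x$tracer_radius, x$tracer_charge))
  cat(sprintf("  run: dt = %g, equil %d + prod %d steps, dump every %d\n",
              x$dt, x$n_equil_steps, x$n_prod_steps, x$dump_every))
  invisible(x)
}

# flat internal parameter list handed to the C++ kernels
.ff_cpp <- function(params, k_bend = NULL) {
  list(eps_lj = params$eps_lj, rc_factor = params$rc_factor,
       shift_lj = isTRUE(params$shift_lj), k_bond = params$k_bond,
       r0 = params$r0,
       k_bend = if (is.null(k_bend)) params$k_bend else k_bend,
       theta0 = params$theta0, coulomb = params$coulomb,
       kappa = params$kappa, rc_debye = params$r_cut_debye)
}
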