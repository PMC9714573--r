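#' Pairwise and bonded potential energies
#'
#' Scalar/vectorized forms of the four interaction terms. `lj_pair_energy()`
#' is the truncated 12-6 Lennard-Jones potential, zero at and beyond the
#' cutoff; with `shift = TRUE` the energy is shifted up by the (unshifted)
#' value at the cutoff so it is continuous there — with the good-solvent
#' cutoff at the minimum this is the WCA form, everywhere non-negative.
#' `bond_energy()` and `bend_energy()` are the harmonic stretch and bend
#' terms. `debye_pair_energy()` is the screened Coulomb interaction between
#' two point charges (in units of e), zero beyond the cutoff or when either
#' charge vanishes.
#'
#' @param r Separation distance(s), \eqn{\sigma}.
#' @param eps_lj,sigma_lj,r_cut,shift LJ well depth, size, cutoff, shift flag.
#' @return Energy in \eqn{\epsilon_E}.
#' @examples
#' lj_pair_energy(2^(1/6))                 # 0 (shifted); minimum of the well
#' lj_pair_energy(2^(1/6), shift = FALSE)  # -eps_lj
#' bond_energy(1.1)                        # 140.2 * 0.1^2
#' @export
lj_pair_energy <- function(r, eps_lj = 0.73, sigma_lj = 1,
                           r_cut = 2^(1 / 6) * sigma_lj, shift = TRUE) {
  if (any(r <= 0)) stop("singularity error: r must be positive")
  sr6 <- (sigma_lj / r)^6
  u <- 4 * eps_lj * (sr6^2 - sr6)
  if (shift) {
    src6 <- (sigma_lj / r_cut)^6
    u <- u - 4 * eps_lj * (src6^2 - src6)
  }
  ifelse(r < r_cut, u, 0)
}

#' @rdname lj_pair_energy
#' @param k_bond,r0 Harmonic bond constant and equilibrium length.
#' @export
bond_energy <- function(r, k_bond = 140.2, r0 = 1) {
  if (any(r <= 0)) stop("r must be positive")
  k_bond * (r - r0)^2
}

#' @rdname lj_pair_energy
#' @param theta Bond angle(s) in radians, in \eqn{[0, \pi]}.
#' @param k_bend,theta0 Harmonic bend constant and equilibrium angle.
#' @export
bend_energy <- function(theta, k_bend = 14.02, theta0 = pi) {
  if (any(theta < 0 | theta > pi + 1e-12)) stop("theta must lie in [0, pi]")
  k_bend * (theta - theta0)^2
}

#' @rdname lj_pair_energy
#' @param qi,qj Charges in units of e.
#' @param coulomb_const Energy prefactor \eqn{C/\epsilon}
#'   (\eqn{\epsilon_E \sigma / e^2}); the default is the Bjerrum-length
#'   parameterization \eqn{l_B kT} with \eqn{l_B = 0.7} nm and kT = 2.804.
#' @param kappa Inverse screening length (\eqn{1/\sigma}).
#' @export
debye_pair_energy <- function(r, qi, qj, coulomb_const = 0.7 * 2.804,
                              kappa = 1, r_cut = 3) {
  if (any(r <= 0)) stop("singularity error: r must be positive")
  ifelse(r < r_cut, coulomb_const * qi * qj * exp(-kappa * r) / r, 0)
}

.species_code <- function(species) {
  match(species, c("wall", "tether", "chain", "tracer")) - 1L
}

#' Total potential energy and forces of a system
#'
#' Evaluates all four interaction terms over the whole system — including
#' pairs involving immobile beads — under the minimum-image convention in
#' x and y, using an exact cell list. Returns the energy breakdown
#' (`u_total` is the sum of the four terms), per-bead partial energies
#' (pair energies split half/half, bond energies half/half, bend energies
#' assigned to the centre bead) and per-bead force vectors.
#'
#' @param state A `brush_system`.
#' @param params Force-field parameters; defaults to those stored in `state`.
#' @return A list with `u_lj`, `u_bond`, `u_bend`, `u_debye`, `u_total`,
#'   `per_bead` (length-N vector) and `forces` (N x 3 matrix).
#' @export
total_energy_forces <- function(state, params = state$params) {
  k_bend <- if (state$config$mode == "no_stiffness") 0 else NULL
  cpp_energy_forces(state$positions, state$mobile, state$mass, state$gamma,
                    state$charge, state$sigma, .species_code(state$species),
                    .as_imat(state$bonds, 2), .as_imat(state$angles, 3),
                    .as_imat(state$exclusions, 2), .ff_cpp(params, k_bend),
                    state$box, per_bead = TRUE)
}

.as_imat <- function(m, ncol) {
  if (is.null(m) || length(m) == 0) return(matrix(integer(0), 0, ncol))
  storage.mode(m) <- "integer"
  m
}
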