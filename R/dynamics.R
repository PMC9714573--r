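#' Advance a system by Langevin dynamics
#'
#' Integrates the underdamped Langevin equation
#' \eqn{m \dot v = F - \gamma v + B(t)} for all mobile beads with a BAOAB
#' splitting of velocity-Verlet type: the noise amplitude follows the
#' fluctuation-dissipation theorem, and at \eqn{\gamma = 0} the scheme
#' reduces exactly to velocity Verlet (NVE). Immobile beads never move but
#' participate in all interactions. Positions are kept unwrapped; the
#' minimum-image convention handles periodicity.
#'
#' @param state A `brush_system`.
#' @param n_steps Number of time steps.
#' @param dt Time step (\eqn{\tau}); defaults to the config value.
#' @param kT Thermal energy; defaults to the config value.
#' @return The updated `brush_system` (positions and velocities advanced).
#' @export
langevin_step <- function(state, n_steps = 1, dt = state$config$dt,
                          kT = state$config$kT) {
  k_bend <- if (state$config$mode == "no_stiffness") 0 else NULL
  res <- cpp_run_langevin(state$positions, state$velocities, state$mobile,
                          state$mass, state$gamma, state$charge, state$sigma,
                          .species_code(state$species),
                          .as_imat(state$bonds, 2), .as_imat(state$angles, 3),
                          .as_imat(state$exclusions, 2),
                          .ff_cpp(state$params, k_bend), state$box, dt, kT,
                          as.integer(n_steps), as.integer(n_steps),
                          tracer = 0L, record_energy = FALSE)
  state$positions <- res$positions
  state$velocities <- res$velocities
  state
}

# Maxwell-Boltzmann velocities for mobile beads
.thermalize <- function(state, kT = state$config$kT) {
  mob <- which(state$mobile)
  sv <- sqrt(kT / state$mass[mob])
  state$velocities[mob, ] <- sv * matrix(rnorm(3 * length(mob)), ncol = 3)
  state
}

#' Run one realization of the brush + tracer system
#'
#' Builds the system from `config` with the given seed, equilibrates, then
#' runs production while sampling the tracer every `dump_every` steps.
#' Mode handling: in `"dynamic"` and `"no_stiffness"` modes chains stay
#' mobile throughout; in `"static"` mode the chains are frozen after
#' equilibration (at the same coordinates a dynamic run with the same seed
#' would have at that instant); `"straight"` mode skips chain equilibration
#' entirely and uses frozen vertical rods.
#'
#' During equilibration a running mean of the chain radius of gyration is
#' monitored over the two halves of the run; a change above 1% triggers a
#' non-convergence warning.
#'
#' @param config A [brush_config()].
#' @param params A [forcefield_params()].
#' @param seed Seed for this realization (use distinct seeds per
#'   realization, e.g. `base_seed + i`).
#' @return An object of class `brush_trajectory`: production-frame `times`
#'   (starting at 0), unwrapped `tracer` positions (frames x 3), an
#'   instantaneous `in_brush` flag (tracer z at or below the instantaneous
#'   maximum chain-bead z), per-frame tracer interaction energy and chain
#'   energy per bead, `max_chain_z`, the final `state`, and the seed.
#' @export
run_realization <- function(config = brush_config(),
                            params = forcefield_params(),
                            seed = config$seed) {
  state <- build_brush_system(config, params, rng_seed = seed)
  k_bend <- if (config$mode == "no_stiffness") 0 else NULL
  ffp <- .ff_cpp(params, k_bend)
  state <- .thermalize(state)

  run <- function(st, n_steps, dump, energy) {
    cpp_run_langevin(st$positions, st$velocities, st$mobile, st$mass,
                     st$gamma, st$charge, st$sigma,
                     .species_code(st$species), .as_imat(st$bonds, 2),
                     .as_imat(st$angles, 3), .as_imat(st$exclusions, 2),
                     ffp, st$box, config$dt, config$kT,
                     as.integer(n_steps), as.integer(dump),
                     tracer = st$tracer, record_energy = energy)
  }

  chains_mobile <- config$mode %in% c("dynamic", "static", "no_stiffness")
  if (chains_mobile && config$n_equil_steps > 0) {
    half <- max(1L, config$n_equil_steps %/% 2L)
    rg <- numeric(2)
    for (h in 1:2) {
      res <- run(state, half, half, FALSE)
      state$positions <- res$positions
      state$velocities <- res$velocities
      rg[h] <- mean(radius_of_gyration(state))
    }
    if (abs(rg[2] - rg[1]) / rg[2] > 0.01)
      warning(sprintf(
        "equilibration may not have converged: <Rg> moved %.1f%% in the second half",
        100 * abs(rg[2] - rg[1]) / rg[2]))
  }
  if (config$mode == "static")
    state$mobile <- state$species == "tracer"

  res <- run(state, config$n_prod_steps, config$dump_every, TRUE)
  state$positions <- res$positions
  state$velocities <- res$velocities

  structure(list(times = res$times, tracer = res$tracer_pos,
                 in_brush = res$tracer_pos[, 3] <= res$max_chain_z,
                 tracer_energy = res$tracer_energy,
                 chain_energy_per_bead = res$chain_energy_per_bead,
                 max_chain_z = res$max_chain_z,
                 state = state, seed = seed, config = config),
            class = "brush_trajectory")
}

#' Run an ensemble of realizations
#'
#' Convenience loop over [run_realization()] with counter-based seeding
#' (`base_seed + i`), so distinct realizations use independent streams.
#'
#' @inheritParams run_realization
#' @param n Number of realizations.
#' @param base_seed First seed; realization i uses `base_seed + i - 1`.
#' @return A list of `brush_trajectory` objects.
#' @export
run_ensemble <- function(config = brush_config(), params = forcefield_params(),
                         n = config$n_realizations, base_seed = config$seed) {
  lapply(seq_len(n), function(i)
    run_realization(config, params, seed = base_seed + i - 1L))
}

#' Simulate an isolated free chain
#'
#' Langevin dynamics of a single untethered bead-spring chain governed by
#' the bond and bend terms only (the ideal discrete worm-like chain whose
#' angle statistics set the persistence length; nonbonded terms are
#' switched off by default). Used to calibrate and verify the
#' persistence length against the bond-correlation decay.
#'
#' The slowest orientational (Rouse) mode of a 101-bead chain relaxes over
#' roughly \eqn{\gamma N^2 r_0^2 / (3\pi^2 kT) \approx 120\,\tau} (25k steps
#' at the default time step), so the default equilibration discards five of
#' those times and samples are drawn from several independent chains.
#'
#' @param n_beads Beads in the chain.
#' @param n_samples Number of configurations returned per chain.
#' @param sample_every Steps between samples.
#' @param n_equil_steps Discarded equilibration steps.
#' @param n_chains Independent chains pooled (seeds `seed`, `seed + 1`, ...).
#' @param params Force-field parameters (bond/bend constants).
#' @param dt,kT,gamma Langevin settings.
#' @param seed Seed.
#' @param nonbonded Include the LJ/Debye terms (excluded volume and
#'   intrachain electrostatics) as well.
#' @param init Initial configuration: `"wlc"` draws an equilibrium
#'   worm-like-chain configuration (recommended: the longest bending modes
#'   of a semiflexible chain relax over times that scale like the fourth
#'   power of the chain length and cannot be pumped up from a straight
#'   start on any reasonable run length); `"straight"` starts from a
#'   near-straight line.
#' @return A list of `n_chains * n_samples` coordinate matrices
#'   (`n_beads` x 3).
#' @export
run_free_chain <- function(n_beads = 101, n_samples = 40, sample_every = 5000,
                           n_equil_steps = 50000, n_chains = 1,
                           params = forcefield_params(),
                           dt = 0.005, kT = 2.804, gamma = 1, seed = 1,
                           nonbonded = FALSE, init = c("wlc", "straight")) {
  init <- match.arg(init)
  if (n_chains > 1) {
    return(unlist(lapply(seq_len(n_chains) - 1L, function(k)
      run_free_chain(n_beads, n_samples, sample_every, n_equil_steps,
                     n_chains = 1, params = params, dt = dt, kT = kT,
                     gamma = gamma, seed = seed + k, nonbonded = nonbonded,
                     init = init)),
      recursive = FALSE))
  }
  n <- n_beads
  if (init == "wlc") {
    beta_k <- params$k_bend / kT
    pos <- sample_discrete_wlc(n, beta_k, 1, seed = seed, r0 = params$r0)[[1]]
    set.seed(seed)
  } else {
    set.seed(seed)
    pos <- cbind(runif(1, 0, 10) + cumsum(c(0, runif(n - 1, -0.02, 0.02))),
                 runif(1, 0, 10) + cumsum(c(0, runif(n - 1, -0.02, 0.02))),
                 seq_len(n) * params$r0)
  }
  bonds <- cbind(1:(n - 1), 2:n)
  angles <- cbind(1:(n - 2), 2:(n - 1), 3:n)
  excl <- rbind(bonds, cbind(1:(n - 2), 3:n))
  ffp <- .ff_cpp(params)
  if (!nonbonded) {
    ffp$eps_lj <- 0
    ffp$coulomb <- 0
  }
  charge <- rep(if (nonbonded) params$chain_charge else 0, n)
  vel <- sqrt(kT) * matrix(rnorm(3 * n), n, 3)
  run <- function(p, v, n_steps, dump) {
    cpp_run_langevin(p, v, rep(TRUE, n), rep(1, n), rep(gamma, n), charge,
                     rep(1, n), rep(2L, n), .as_imat(bonds, 2),
                     .as_imat(angles, 3), .as_imat(excl, 2), ffp,
                     c(1e6, 1e6), dt, kT, as.integer(n_steps),
                     as.integer(dump), tracer = 0L, record_energy = FALSE,
                     record_chain = TRUE)
  }
  res <- run(pos, vel, as.integer(n_equil_steps), as.integer(max(1, n_equil_steps)))
  res <- run(res$positions, res$velocities,
             as.integer(n_samples * sample_every), as.integer(sample_every))
  res$frames[-1]  # drop the (correlated) initial frame
}

#' Free-particle (bulk) trajectory ensemble
#'
#' Simulates non-interacting tracers governed only by drag and thermal
#' noise (the \eqn{F = 0} limit of the Langevin equation) with the same
#' BAOAB stepping as the full model, for measuring the bulk diffusion
#' constant. The damping scales with the tracer radius
#' (\eqn{\gamma \propto a}, Stokes drag at fixed viscosity) and the mass
#' with radius cubed, relative to a chain bead of radius 0.5 \eqn{\sigma}.
#'
#' @param tracer_radius Tracer radius (\eqn{\sigma}).
#' @param n_realizations Ensemble size.
#' @param n_steps,dump_every Production length and sampling stride.
#' @param dt,kT,gamma0 Time step, thermal energy and chain-bead damping.
#' @param seed Seed for the noise stream.
#' @return A list of `brush_trajectory` objects (no chains; `in_brush` is
#'   all TRUE so the dual-MSD machinery applies unchanged).
#' @export
run_bulk <- function(tracer_radius = 0.5, n_realizations = 100,
                     n_steps = 20000, dump_every = 100, dt = 0.005,
                     kT = 2.804, gamma0 = 1, seed = 1) {
  stopifnot(tracer_radius > 0, n_realizations >= 1)
  set.seed(seed)
  m <- (tracer_radius / 0.5)^3
  g <- gamma0 * tracer_radius / 0.5
  res <- cpp_run_free(as.integer(n_realizations),
                      rep(m, n_realizations), rep(g, n_realizations),
                      dt, kT, as.integer(n_steps), as.integer(dump_every))
  pos <- res$positions  # frames x n x 3
  nf <- length(res$times)
  lapply(seq_len(n_realizations), function(i) {
    structure(list(times = res$times,
                   tracer = cbind(pos[, i, 1], pos[, i, 2], pos[, i, 3]),
                   in_brush = rep(TRUE, nf), seed = seed),
              class = "brush_trajectory")
  })
}

#' @export
print.brush_trajectory <- function(x, ...) {
  cat(sprintf("brush_trajectory: %d frames, t in [0, %g] tau, seed %s\n",
              length(x$times), max(x$times), format(x$seed)))
  if (!is.null(x$in_brush))
    cat(sprintf("  in brush at last frame: %s\n", x$in_brush[length(x$in_brush)]))
  invisible(x)
}
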