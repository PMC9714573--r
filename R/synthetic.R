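#' Synthetic anisotropic Brownian trajectories
#'
#' Generates ideal overdamped Brownian walkers with independent Gaussian
#' increments, Var(dx) = Var(dy) = 2 D_par dt and Var(dz) = 2 D_perp dt,
#' optionally with exponentially distributed brush-exit times (hazard
#' `exit_rate`) that set the per-frame in-brush flag. These fixtures have
#' exactly the statistical structure the MSD/diffusion analysis assumes,
#' so every analysis stage can be validated without molecular dynamics;
#' they are emitted in the same trajectory format as the simulator.
#'
#' @param n_trajectories Ensemble size.
#' @param n_steps Frames per trajectory (after the origin).
#' @param dt Frame spacing (\eqn{\tau}).
#' @param D_par,D_perp Diffusion constants (\eqn{\sigma^2/\tau}).
#' @param exit_rate Exit hazard per unit time (0 = never exits).
#' @param seed Seed; generation is fully deterministic given the seed.
#' @return A list of `brush_trajectory` objects.
#' @export
generate_brownian <- function(n_trajectories = 100, n_steps = 200, dt = 0.5,
                              D_par = 1, D_perp = 1, exit_rate = 0, seed = 1) {
  stopifnot(D_par >= 0, D_perp >= 0, exit_rate >= 0, n_steps >= 1)
  set.seed(seed)
  times <- (0:n_steps) * dt
  lapply(seq_len(n_trajectories), function(i) {
    dx <- matrix(rnorm(3 * n_steps), n_steps, 3)
    dx[, 1:2] <- dx[, 1:2] * sqrt(2 * D_par * dt)
    dx[, 3] <- dx[, 3] * sqrt(2 * D_perp * dt)
    pos <- rbind(0, apply(dx, 2, cumsum))
    inb <- rep(TRUE, n_steps + 1)
    if (exit_rate > 0) {
      t_exit <- stats::rexp(1, exit_rate)
      inb <- times < t_exit
      inb[1] <- TRUE
    }
    structure(list(times = times, tracer = pos, in_brush = inb, seed = seed),
              class = "brush_trajectory")
  })
}

#' Synthetic ballistic-to-diffusive crossover trajectories
#'
#' Velocity Ornstein-Uhlenbeck process with relaxation time
#' `crossover_time` and long-time diffusion constant `D` per direction:
#' the MSD grows ballistically (\eqn{\propto t^2}) for
#' \eqn{t \ll} `crossover_time` and linearly for \eqn{t \gg}
#' `crossover_time`. Used to validate that the diffusion fit-window rule
#' excludes the inertial transient.
#'
#' @inheritParams generate_brownian
#' @param D Asymptotic diffusion constant per direction.
#' @param crossover_time Velocity relaxation time (\eqn{\tau}).
#' @param substeps Integration substeps per frame.
#' @return A list of `brush_trajectory` objects.
#' @export
generate_ou_crossover <- function(n_trajectories = 100, n_steps = 200,
                                  dt = 0.5, D = 1, crossover_time = 5,
                                  substeps = 10, seed = 1) {
  stopifnot(crossover_time > 0, D > 0)
  set.seed(seed)
  h <- dt / substeps
  c1 <- exp(-h / crossover_time)
  sv <- sqrt(D / crossover_time)        # stationary velocity scale
  c3 <- sv * sqrt(1 - c1^2)
  times <- (0:n_steps) * dt
  lapply(seq_len(n_trajectories), function(i) {
    v <- sv * rnorm(3)
    pos <- matrix(0, n_steps + 1, 3)
    x <- c(0, 0, 0)
    for (f in seq_len(n_steps)) {
      for (s in seq_len(substeps)) {
        x <- x + 0.5 * h * v
        v <- c1 * v + c3 * rnorm(3)
        x <- x + 0.5 * h * v
      }
      pos[f + 1, ] <- x
    }
    structure(list(times = times, tracer = pos,
                   in_brush = rep(TRUE, n_steps + 1), seed = seed),
              class = "brush_trajectory")
  })
}

#' Sample ideal discrete worm-like chains
#'
#' Builds chains joint by joint with the bend angle between consecutive
#' bond vectors drawn from the Boltzmann density
#' \eqn{p(\gamma) \propto e^{-\beta K \gamma^2} \sin\gamma} (harmonic bend
#' about the straight configuration, solid-angle weight) and uniform
#' azimuth; no excluded volume. This is the exact ensemble behind the
#' discrete worm-like-chain persistence-length relation
#' \eqn{l_p = -r_0 / \ln\langle\cos\gamma\rangle}, so it serves as the
#' independent oracle for the persistence-length estimator.
#'
#' @param n_beads Beads per chain.
#' @param beta_k_bend Reduced bending constant \eqn{K_\mathrm{bend}/kT}.
#' @param n_samples Number of chains.
#' @param seed Seed.
#' @param r0 Bond length.
#' @return A list of `n_samples` coordinate matrices (`n_beads` x 3).
#' @export
sample_discrete_wlc <- function(n_beads = 101, beta_k_bend = 5,
                                n_samples = 100, seed = 1, r0 = 1) {
  stopifnot(beta_k_bend >= 0, n_beads >= 2)
  set.seed(seed)
  # inverse-CDF sampler for p(gamma) on a fine grid
  g <- seq(0, pi, length.out = 4001)
  w <- exp(-beta_k_bend * g^2) * sin(g)
  cdf <- cumsum(w); cdf <- cdf / cdf[length(cdf)]
  keep <- !duplicated(cdf)
  qgamma_ <- function(u) approx(cdf[keep], g[keep], xout = u, rule = 2)$y
  nb <- n_beads - 1
  lapply(seq_len(n_samples), function(s) {
    gam <- qgamma_(runif(nb - 1))
    phi <- runif(nb - 1, 0, 2 * pi)
    b <- matrix(0, nb, 3)
    b[1, ] <- c(0, 0, 1)
    for (j in seq_len(nb - 1)) {
      t_ <- b[j, ]
      # orthonormal frame around t_
      a <- if (abs(t_[3]) < 0.9) c(0, 0, 1) else c(1, 0, 0)
      e1 <- a - sum(a * t_) * t_
      e1 <- e1 / sqrt(sum(e1^2))
      e2 <- c(t_[2] * e1[3] - t_[3] * e1[2],
              t_[3] * e1[1] - t_[1] * e1[3],
              t_[1] * e1[2] - t_[2] * e1[1])
      b[j + 1, ] <- cos(gam[j]) * t_ +
        sin(gam[j]) * (cos(phi[j]) * e1 + sin(phi[j]) * e2)
    }
    rbind(0, apply(b * r0, 2, cumsum))
  })
}

#' Worm-like-chain angle average by quadrature
#'
#' Independent closed-form oracle for the discrete worm-like chain:
#' \eqn{\langle\cos\gamma\rangle} under the density
#' \eqn{p(\gamma) \propto e^{-\beta K \gamma^2}\sin\gamma}, evaluated by
#' numerical quadrature, and the implied persistence length
#' \eqn{l_p = -r_0/\ln\langle\cos\gamma\rangle}.
#'
#' @inheritParams sample_discrete_wlc
#' @return A list with `cos_gamma` and `lp`.
#' @export
wlc_quadrature <- function(beta_k_bend, r0 = 1) {
  f <- function(g) exp(-beta_k_bend * g^2) * sin(g)
  num <- integrate(function(g) cos(g) * f(g), 0, pi)$value
  den <- integrate(f, 0, pi)$value
  cg <- num / den
  list(cos_gamma = cg, lp = if (cg <= 0) 0 else -r0 / log(cg))
}
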