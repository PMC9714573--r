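test_that("MSD bookkeeping: additivity, zero case, exit exclusion", {
  # stationary tracer: all curves identically zero
  tr0 <- manual_trajectory(matrix(1, 6, 3))
  m0 <- compute_msd(list(tr0))
  expect_true(all(m0$msd_xy_all == 0) && all(m0$msd_z_all == 0))

  # two hand-made walkers, one exiting at frame 3
  p1 <- cbind(0:4, 0, 0)                      # moves +1 in x per frame
  p2 <- cbind(0, 0, 2 * (0:4))                # moves +2 in z per frame
  tr1 <- manual_trajectory(p1)
  tr2 <- manual_trajectory(p2, in_brush = c(TRUE, TRUE, FALSE, TRUE, TRUE))
  m <- compute_msd(list(tr1, tr2))
  # additivity at every time
  expect_equal(m$msd_total_all, m$msd_xy_all + m$msd_z_all)
  # all-particle curve includes both walkers at every frame
  expect_equal(m$msd_z_all, (0:4)^2 * 4 / 2 + 0)
  # walker 2 leaves the in-brush ensemble from frame 3 onwards (flag at
  # frame 3 is FALSE, so it never re-enters the survivor set)
  expect_equal(m$n_inbrush, c(2, 2, 1, 1, 1))
  expect_equal(m$msd_xy_inbrush[3:5], (2:4)^2)   # only walker 1 remains
})

test_that("diffusion fit recovers exact and stochastic inputs", {
  # exact linear MSD: msd_xy = 4 D t with D = 0.25, msd_z = 2 D t with D = 0.4
  t <- 0:50
  mk <- function() manual_trajectory(cbind(sqrt(2 * 0.25 * t), sqrt(2 * 0.25 * t),
                                           sqrt(2 * 0.4 * t)))
  est <- fit_diffusion(replicate(10, mk(), simplify = FALSE), n_groups = 10,
                       fit_window = c(5, 50))
  expect_equal(est$D_par, 0.25, tolerance = 1e-10)
  expect_equal(est$D_perp, 0.4, tolerance = 1e-10)
  expect_equal(est$D_par_sd, 0)

  # synthetic anisotropic Brownian ensemble
  trajs <- generate_brownian(1000, n_steps = 250, dt = 0.4, D_par = 2,
                             D_perp = 1, seed = 42)
  est2 <- fit_diffusion(trajs, n_groups = 10)
  expect_equal(est2$n_groups, 10)
  expect_lt(abs(est2$D_par - 2), 3 * est2$D_par_sd)
  expect_lt(abs(est2$D_perp - 1), 3 * est2$D_perp_sd)
  # bias below 5% up to the sampling error of the group mean
  expect_lt(abs(est2$D_par - 2) / 2,
            0.05 + 2 * est2$D_par_sd / sqrt(10) / 2)
  expect_lt(abs(est2$D_perp - 1) / 1,
            0.05 + 2 * est2$D_perp_sd / sqrt(10))
})

test_that("ten error groups are formed regardless of ensemble size", {
  trajs <- generate_brownian(40, n_steps = 120, dt = 0.5, seed = 3)
  est <- fit_diffusion(trajs, n_groups = 10)
  expect_equal(nrow(est$groups), 10)
  expect_error(fit_diffusion(trajs[1:5], n_groups = 10))
})

test_that("radius of gyration matches closed forms", {
  expect_equal(radius_of_gyration(matrix(c(1, 2, 3), 1, 3)), 0)
  expect_equal(radius_of_gyration(cbind(0, 0, c(0, 2))), 1)  # two beads, b/2
  rod <- cbind(0, 0, 1:101)
  expect_equal(radius_of_gyration(rod), sqrt((101^2 - 1) / 12),
               tolerance = 1e-12)
})

test_that("brush height and correlation length have the documented geometry", {
  cfg <- tiny_config(n_beads = 101, mode = "straight", n_prod_steps = 10,
                     dump_every = 10)
  sys <- build_brush_system(cfg, rng_seed = 1)
  expect_equal(brush_height(list(sys)), 101)
  # straight parallel chains at separation d: xi = d
  expect_equal(correlation_length(sys), cfg$d)

  # brute-force double-loop oracle on a perturbed small system
  cfg2 <- tiny_config(n_beads = 12, d = 2)
  s2 <- build_brush_system(cfg2, rng_seed = 6)
  s2$positions[s2$mobile, ] <- s2$positions[s2$mobile, ] +
    matrix(rnorm(sum(s2$mobile) * 3, sd = 0.2), ncol = 3)
  oracle <- local({
    ids <- s2$chain_id; keep <- ids > 0
    pos <- s2$positions[keep, ]; cid <- ids[keep]; L <- s2$box
    nn <- numeric(nrow(pos))
    for (i in seq_len(nrow(pos))) {
      best <- Inf
      for (j in seq_len(nrow(pos))) {
        if (cid[j] == cid[i]) next
        dx <- abs(pos[i, 1] - pos[j, 1]); dx <- min(dx, L[1] - dx)
        dy <- abs(pos[i, 2] - pos[j, 2]); dy <- min(dy, L[2] - dy)
        r <- sqrt(dx^2 + dy^2 + (pos[i, 3] - pos[j, 3])^2)
        if (r < best) best <- r
      }
      nn[i] <- best
    }
    mean(nn)
  })
  expect_equal(correlation_length(s2), oracle, tolerance = 1e-12)
  # single chain: undefined
  s1 <- build_brush_system(tiny_config(grid_n = 1, n_beads = 6), rng_seed = 1)
  expect_error(correlation_length(s1), "two chains")
})

test_that("persistence length estimator agrees with the quadrature oracle", {
  # straight rigid chain: divergent
  pl_inf <- persistence_length(cbind(0, 0, 1:30))
  expect_equal(pl_inf$lp, Inf)

  # ideal discrete WLC at beta K = 5: lp about 10 sigma
  w <- sample_discrete_wlc(101, 5, 250, seed = 12)
  pl <- persistence_length(w)
  oracle <- wlc_quadrature(5)
  expect_equal(pl$lp, oracle$lp, tolerance = 0.05)

  # freely jointed limit: correlations are at the noise floor around zero,
  # which the estimator reports as a fit-range failure
  w0 <- sample_discrete_wlc(41, 0, 300, seed = 5)
  expect_error(persistence_length(w0), "fit-range")
})

test_that("energy statistics satisfy the bookkeeping identity", {
  tr <- list(times = 0:9, tracer_energy = c(rep(0, 6), 0.4, 0.2, 0, 0.4),
             chain_energy_per_bead = rep(2, 10))
  class(tr) <- "brush_trajectory"
  es <- energy_stats(tr)
  expect_equal(es$interacting_fraction, 0.3)
  expect_equal(es$mean_energy_when_interacting, 1 / 3)
  expect_equal(es$mean_energy_per_step,
               es$mean_energy_when_interacting * es$interacting_fraction)
  # never-interacting tracer: zeros with flag
  tr2 <- tr; tr2$tracer_energy <- rep(0, 10)
  es2 <- energy_stats(tr2)
  expect_equal(es2$interacting_fraction, 0)
  expect_equal(es2$mean_energy_when_interacting, 0)
  expect_true(es2$never_interacting)
})
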